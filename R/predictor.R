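#' Guarded prediction protocol configuration
#'
#' The ensemble prediction protocol: individual member predictions outside
#' `sanity_range` are discarded as applicability-domain failures; if more
#' than `max_fail_fraction` of the members fail, the prediction fails;
#' surviving values are clipped to `clip_range`, their mean and (population)
#' standard deviation reported; if the standard deviation exceeds
#' `max_sd_fraction` of the clip-range width, the prediction fails.
#'
#' @param sanity_range Plausible endpoint interval (default \[-2.5, 2.5\]).
#' @param clip_range Acceptable endpoint interval (default \[-2, 2\]).
#' @param max_fail_fraction Maximum tolerated fraction of out-of-range
#'   members (strictly greater fails; default 0.5).
#' @param max_sd_fraction Maximum ensemble standard deviation as a fraction
#'   of the clip-range width (strictly greater fails; default 0.3).
#' @return An object of class `prediction_config`.
#' @export
prediction_config <- function(sanity_range = c(-2.5, 2.5),
                              clip_range = c(-2, 2),
                              max_fail_fraction = 0.5,
                              max_sd_fraction = 0.3) {
  stopifnot(length(sanity_range) == 2, length(clip_range) == 2,
            clip_range[1] >= sanity_range[1], clip_range[2] <= sanity_range[2],
            max_fail_fraction > 0, max_fail_fraction < 1,
            max_sd_fraction > 0, max_sd_fraction < 1)
  structure(list(sanity_range = sanity_range, clip_range = clip_range,
                 max_fail_fraction = max_fail_fraction,
                 max_sd_fraction = max_sd_fraction),
            class = "prediction_config")
}

# featurization settings recorded on the ensemble at training time
ensemble_featurize <- function(ensemble) {
  ensemble$featurize %||% list(max_atoms = 10, levels = 1:3)
}

# population standard deviation (ensemble spread descriptor, not estimator)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# raw member predictions for one compound (original endpoint scale);
# NA marks featurization failure (no selected fragment present)
member_raw_predictions <- function(ensemble, counts_row) {
  vapply(ensemble$members, function(m) {
    xr <- counts_row[m$selected]
    xr[is.na(xr)] <- 0
    if (all(xr == 0)) return(NA_real_)  # unknown-only fragments
    member_predict_scaledmat(m, matrix(xr, nrow = 1,
                                       dimnames = list(NULL, m$selected)))
  }, numeric(1))
}

# apply the guarded protocol to a vector of raw member predictions
apply_protocol <- function(raw, config) {
  n_members <- length(raw)
  sane <- !is.na(raw) & raw >= config$sanity_range[1] &
    raw <= config$sanity_range[2]
  n_failed <- sum(!sane)
  if (n_failed / n_members > config$max_fail_fraction) {
    return(list(status = "failure", mean = NA_real_, sd = NA_real_,
                n_valid = as.integer(sum(sane)),
                failure_reason = "too_many_out_of_range"))
  }
  surv <- pmin(pmax(raw[sane], config$clip_range[1]), config$clip_range[2])
  m <- mean(surv)
  s <- sd_pop(surv)
  width <- diff(config$clip_range)
  if (s > config$max_sd_fraction * width) {
    return(list(status = "failure", mean = m, sd = s,
                n_valid = as.integer(length(surv)),
                failure_reason = "sd_too_large"))
  }
  list(status = "ok", mean = m, sd = s, n_valid = as.integer(length(surv)),
       failure_reason = "none")
}

#' Predict LogBB for a single compound with the guarded protocol
#'
#' @param ensemble A `bbb_ensemble` from [run_double_cv()].
#' @param compound A `molgraph`, a SMILES string, or a named numeric vector
#'   of raw fragment counts.
#' @param config A [prediction_config()].
#' @return A one-row tibble: `id`, `status`, `mean`, `sd`, `n_valid`,
#'   `failure_reason`.
#' @export
predict_one <- function(ensemble, compound, config = prediction_config()) {
  stopifnot(inherits(ensemble, "bbb_ensemble"))
  if (is.character(compound)) {
    compound <- parse_structure(compound, "smiles", id = compound)
  }
  if (inherits(compound, "molgraph")) {
    fz <- ensemble_featurize(ensemble)
    fc <- count_fragments(compound, max_atoms = fz$max_atoms,
                          levels = fz$levels)
    counts_row <- stats::setNames(fc$count, fc$key)
    id <- compound$id
  } else {
    counts_row <- compound
    id <- attr(compound, "id") %||% "compound"
  }
  raw <- member_raw_predictions(ensemble, counts_row)
  res <- apply_protocol(raw, config)
  tibble::tibble(id = id, status = res$status, mean = res$mean, sd = res$sd,
                 n_valid = res$n_valid, failure_reason = res$failure_reason)
}

#' Predict LogBB for a compound table
#'
#' Runs the guarded prediction protocol on every row. When experimental
#' values are present, summary statistics are computed over the successfully
#' predicted compounds: Pearson R, RMSE, counts of absolute errors above 1.0
#' and 1.5 log units, and the correlation between the ensemble standard
#' deviation and the absolute error (the applicability-warning signal).
#'
#' @param ensemble A `bbb_ensemble`.
#' @param compounds Tibble with `id` plus `graph` or `smiles` (and optionally
#'   `logbb`).
#' @param config A [prediction_config()].
#' @return A list of class `batch_prediction`: `predictions` (tibble) and
#'   `summary` (one-row tibble, only when experimental values were given).
#' @export
predict_batch <- function(ensemble, compounds,
                          config = prediction_config()) {
  stopifnot(inherits(ensemble, "bbb_ensemble"))
  if (!"graph" %in% names(compounds)) {
    parsed <- parse_compounds(compounds)
    failed <- parsed$rejects
    compounds <- parsed$compounds
  } else {
    failed <- tibble::tibble(id = character(0), reason = character(0))
  }
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    predict_one(ensemble, compounds$graph[[i]], config) |>
      dplyr::mutate(id = compounds$id[i])
  })
  preds <- dplyr::bind_rows(rows)
  if (nrow(failed)) {
    preds <- dplyr::bind_rows(
      preds,
      tibble::tibble(id = failed$id, status = "failure", mean = NA_real_,
                     sd = NA_real_, n_valid = 0L,
                     failure_reason = "featurization_failure")
    )
  }
  out <- list(predictions = preds, summary = NULL)
  if ("logbb" %in% names(compounds) && any(!is.na(compounds$logbb))) {
    joined <- dplyr::left_join(preds,
                               compounds[, c("id", "logbb")], by = "id") |>
      dplyr::filter(.data$status == "ok", !is.na(.data$logbb))
    err <- joined$mean - joined$logbb
    r <- if (nrow(joined) < 2 || sd_pop(joined$mean) == 0 ||
             sd_pop(joined$logbb) == 0) NA_real_ else
      cor(joined$mean, joined$logbb)
    out$summary <- tibble::tibble(
      n_ok = nrow(joined),
      r = r,
      r_degenerate = is.na(r),
      rmse = sqrt(mean(err^2)),
      n_abs_err_gt_1 = sum(abs(err) > 1.0),
      n_abs_err_gt_1.5 = sum(abs(err) > 1.5),
      sd_error_cor = if (nrow(joined) < 3 || sd_pop(joined$sd) == 0)
        NA_real_ else cor(joined$sd, abs(err))
    )
  }
  structure(out, class = "batch_prediction")
}

#' @export
print.batch_prediction <- function(x, ...) {
  n <- nrow(x$predictions)
  ok <- sum(x$predictions$status == "ok")
  cat("<batch_prediction> ", ok, "/", n, " compounds predicted\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
tidy.batch_prediction <- function(x, ...) x$predictions

#' @export
glance.batch_prediction <- function(x, ...) {
  x$summary %||% tibble::tibble(n_ok = sum(x$predictions$status == "ok"))
}

#' Gradient-based fragment contributions
#'
#' For each compound, every ensemble member's analytic gradient of the scaled
#' output with respect to its scaled inputs is multiplied elementwise by the
#' compound's scaled inputs, averaged over members (a member that does not
#' carry a fragment contributes zero sensitivity to it), and then averaged
#' over the compound set. Fragments absent from a compound contribute exactly
#' zero for that compound.
#'
#' @param ensemble A `bbb_ensemble`.
#' @param compounds Tibble with `id` plus `graph` or `smiles` columns.
#' @return An object of class `contribution_report`: `per_fragment` (tibble
#'   `key`, `mean_contribution`, `sd_contribution`, ranked most negative to
#'   most positive) and `per_compound` (long tibble).
#' @export
fragment_contributions <- function(ensemble, compounds) {
  stopifnot(inherits(ensemble, "bbb_ensemble"))
  if (!"graph" %in% names(compounds)) {
    compounds <- parse_compounds(compounds)$compounds
  }
  all_keys <- sort(unique(unlist(lapply(ensemble$members, `[[`, "selected"))))
  n_members <- length(ensemble$members)
  per_cmpd <- matrix(0, nrow = nrow(compounds), ncol = length(all_keys),
                     dimnames = list(compounds$id, all_keys))
  fz <- ensemble_featurize(ensemble)
  for (i in seq_len(nrow(compounds))) {
    fc <- count_fragments(compounds$graph[[i]], max_atoms = fz$max_atoms,
                          levels = fz$levels)
    counts_row <- stats::setNames(fc$count, fc$key)
    acc <- stats::setNames(rep(0, length(all_keys)), all_keys)
    for (m in ensemble$members) {
      xr <- counts_row[m$selected]
      xr[is.na(xr)] <- 0
      xs <- scale_apply(m$x_scaler,
                        matrix(xr, nrow = 1,
                               dimnames = list(NULL, m$selected)))
      grad <- drop(net_input_gradient(m$network, xs))
      acc[m$selected] <- acc[m$selected] + grad * drop(xs)
    }
    per_cmpd[i, ] <- acc / n_members
  }
  per_fragment <- tibble::tibble(
    key = all_keys,
    mean_contribution = colMeans(per_cmpd),
    sd_contribution = apply(per_cmpd, 2, sd_pop)
  ) |> dplyr::arrange(.data$mean_contribution)
  per_compound <- tibble::as_tibble(as.data.frame.table(
    per_cmpd, responseName = "contribution", stringsAsFactors = FALSE)) |>
    stats::setNames(c("id", "key", "contribution"))
  structure(list(per_fragment = per_fragment, per_compound = per_compound),
            class = "contribution_report")
}

#' Aggregate fragment contributions over the refinement hierarchy
#'
#' Descriptor selection treats a fragment's level-1, level-2 and level-3
#' writings as distinct (and mutually collinear) columns, so the credit for
#' one substructure can land on any of them. For each target key this sums
#' the mean contributions of every report fragment that projects to it at
#' the target's classification level, giving the total credit assigned to
#' the substructure regardless of the specificity level the selection
#' happened to pick.
#'
#' @param report A `contribution_report`.
#' @param keys Canonical fragment keys to aggregate onto (level 1 or 2).
#' @return Tibble with `key` and `total_contribution`.
#' @export
aggregate_contributions <- function(report, keys) {
  stopifnot(inherits(report, "contribution_report"))
  pf <- report$per_fragment
  pf_level <- fragment_key_info(pf$key)$level
  out <- vapply(keys, function(k) {
    lvl <- fragment_key_info(k)$level
    eligible <- pf_level >= lvl
    proj <- project_fragment_key(pf$key[eligible], level = lvl)
    sum(pf$mean_contribution[eligible][proj == k], na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(key = keys, total_contribution = unname(out))
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("<contribution_report> ", nrow(x$per_fragment), " fragments over ",
      length(unique(x$per_compound$id)), " compounds\n", sep = "")
  invisible(x)
}

#' @export
tidy.contribution_report <- function(x, ...) x$per_fragment

#' @export
autoplot.contribution_report <- function(object, n_top = 10, ...) {
  pf <- object$per_fragment
  top <- dplyr::bind_rows(head(pf, n_top), utils::tail(pf, n_top)) |>
    dplyr::distinct() |>
    dplyr::mutate(key = factor(.data$key, levels = .data$key))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mean_contribution,
                                    y = .data$key,
                                    fill = .data$mean_contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "mean fragment contribution (scaled units)", y = NULL)
}

#' Export a prediction or contribution result as CSV
#'
#' @param x A `batch_prediction` or `contribution_report`.
#' @param path Output path.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "batch_prediction")) {
    readr::write_csv(x$predictions, path)
  } else if (inherits(x, "contribution_report")) {
    readr::write_csv(x$per_fragment, path)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  invisible(path)
}
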