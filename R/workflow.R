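#' Dataset curation configuration
#'
#' @param endpoint_range Records with endpoint values outside this interval
#'   are rejected as unrealistic (default \[-2.5, 2.5\]).
#' @param max_duplicate_spread Duplicate structures whose endpoint values
#'   span at most this range (log units, the experimental error level) are
#'   merged to their mean; wider conflicts reject all copies.
#' @param element_whitelist Allowed elements (the organic subset); a
#'   molecule must additionally contain at least one carbon.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(endpoint_range = c(-2.5, 2.5),
                            max_duplicate_spread = 0.3,
                            element_whitelist = c("C", "H", "N", "O", "S",
                                                  "P", "F", "Cl", "Br", "I",
                                                  "B", "Si")) {
  stopifnot(length(endpoint_range) == 2, all(is.finite(endpoint_range)))
  structure(list(endpoint_range = endpoint_range,
                 max_duplicate_spread = max_duplicate_spread,
                 element_whitelist = element_whitelist),
            class = "curation_config")
}

#' Curate a compound table
#'
#' Applies the dataset preparation rules: drop unparseable rows, rows whose
#' endpoint lies outside the plausible range, molecules without carbon or
#' with non-organic elements; deduplicate by canonical structure key
#' (duplicates with agreeing values are merged to their mean, conflicting
#' ones are all rejected). Every input row appears exactly once across the
#' kept table and the rejects report. Idempotent.
#'
#' @param compounds Tibble with `id`, `smiles` and optionally `logbb`.
#' @param config A [curation_config()].
#' @return A list with `kept` (tibble `id`, `smiles`, `logbb`, `graph`,
#'   `key`, `merged`) and `rejects` (tibble `id`, `reason`).
#' @export
curate <- function(compounds, config = curation_config()) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  if (!"logbb" %in% names(compounds)) compounds$logbb <- NA_real_
  rejects <- tibble::tibble(id = character(0), reason = character(0))
  reject <- function(ids, reason) {
    rejects <<- dplyr::bind_rows(rejects,
                                 tibble::tibble(id = ids, reason = reason))
  }

  parsed <- parse_compounds(compounds[, c("id", "smiles", "logbb")])
  if (nrow(parsed$rejects)) reject(parsed$rejects$id, "parse_failure")
  df <- parsed$compounds

  out_of_range <- !is.na(df$logbb) &
    (df$logbb < config$endpoint_range[1] | df$logbb > config$endpoint_range[2])
  reject(df$id[out_of_range], "out_of_range")
  df <- df[!out_of_range, , drop = FALSE]

  organic <- vapply(df$graph, function(g) {
    any(g$atoms$element == "C") &&
      all(g$atoms$element %in% config$element_whitelist)
  }, logical(1))
  reject(df$id[!organic], "inorganic")
  df <- df[organic, , drop = FALSE]

  if (nrow(df) == 0) {
    return(list(kept = dplyr::mutate(df, key = character(0), merged = FALSE),
                rejects = rejects))
  }
  df$key <- vapply(df$graph, canonical_structure_key, character(1))
  df$merged <- FALSE
  groups <- split(seq_len(nrow(df)), df$key)
  keep_rows <- logical(nrow(df))
  for (rows in groups) {
    if (length(rows) == 1) {
      keep_rows[rows] <- TRUE
      next
    }
    vals <- df$logbb[rows]
    if (all(is.na(vals)) ||
        diff(range(vals, na.rm = TRUE)) <= config$max_duplicate_spread) {
      rep_row <- rows[1]
      keep_rows[rep_row] <- TRUE
      df$logbb[rep_row] <- mean(vals, na.rm = TRUE)
      df$merged[rep_row] <- TRUE
      reject(df$id[rows[-1]], "merged_duplicate")
    } else {
      reject(df$id[rows], "conflicting_duplicate")
    }
  }
  kept <- df[keep_rows, , drop = FALSE]
  list(kept = tibble::as_tibble(kept), rejects = rejects)
}

#' Structure overlap between two compound sets
#'
#' Membership is decided by canonical structure key, so the same molecule
#' drawn differently (or supplied as SMILES in one set and SDF in the other)
#' is detected.
#'
#' @param set_a,set_b Tibbles with `id` and `smiles` (or `graph`) columns.
#' @return A list with `overlapping` and `non_overlapping` (ids of `set_a`)
#'   and `keys_b` (keys of `set_b`).
#' @export
find_overlap <- function(set_a, set_b) {
  key_of <- function(df) {
    if ("graph" %in% names(df)) {
      vapply(df$graph, canonical_structure_key, character(1))
    } else {
      canonical_structure_key(df$smiles)
    }
  }
  ka <- key_of(set_a)
  kb <- key_of(set_b)
  hit <- !is.na(ka) & ka %in% kb[!is.na(kb)]
  list(overlapping = set_a$id[hit],
       non_overlapping = set_a$id[!hit],
       keys_b = kb)
}

#' External validation report
#'
#' Predicts an external set with the guarded protocol and reports the
#' statistics used to judge transferability: N predicted, Pearson R, RMSE,
#' counts and percentages of absolute errors above 1.0 and 1.5 log units,
#' the ensemble-sd-versus-error correlation, and (when a training table is
#' supplied) the same statistics stratified by structural overlap with the
#' training set plus an outlier table.
#'
#' External records are excluded only when their endpoint is outside the
#' plausible range; no further curation is applied.
#'
#' @param ensemble A `bbb_ensemble`.
#' @param external Tibble with `id`, `smiles`, `logbb`.
#' @param config A [prediction_config()].
#' @param train Optional training tibble (`id`, `smiles`, `logbb`) for
#'   overlap stratification.
#' @param endpoint_range Unrealistic-value exclusion interval.
#' @return A list of class `external_validation`: `summary`, `by_overlap`,
#'   `outliers`, `predictions`, `n_excluded`.
#' @export
validate_external <- function(ensemble, external,
                              config = prediction_config(),
                              train = NULL,
                              endpoint_range = c(-2.5, 2.5)) {
  stopifnot(all(c("id", "smiles") %in% names(external)))
  if (!"logbb" %in% names(external)) external$logbb <- NA_real_
  if (nrow(external) == 0) {
    return(structure(list(summary = tibble::tibble(), by_overlap = NULL,
                          outliers = tibble::tibble(),
                          predictions = tibble::tibble(), n_excluded = 0L),
                     class = "external_validation"))
  }
  unrealistic <- !is.na(external$logbb) &
    (external$logbb < endpoint_range[1] | external$logbb > endpoint_range[2])
  excluded <- external[unrealistic, , drop = FALSE]
  external <- external[!unrealistic, , drop = FALSE]

  bp <- predict_batch(ensemble, external, config)
  preds <- dplyr::left_join(bp$predictions,
                            external[, c("id", "smiles", "logbb")],
                            by = "id")
  preds$abs_error <- abs(preds$mean - preds$logbb)

  by_overlap <- NULL
  if (!is.null(train)) {
    ov <- find_overlap(external, train)
    preds$overlapping <- preds$id %in% ov$overlapping
    by_overlap <- preds |>
      dplyr::filter(.data$status == "ok", !is.na(.data$logbb)) |>
      dplyr::group_by(.data$overlapping) |>
      dplyr::summarise(
        n = dplyr::n(),
        r = if (dplyr::n() >= 2) cor(.data$mean, .data$logbb) else NA_real_,
        rmse = sqrt(mean((.data$mean - .data$logbb)^2)),
        n_abs_err_gt_1 = sum(.data$abs_error > 1.0),
        n_abs_err_gt_1.5 = sum(.data$abs_error > 1.5),
        .groups = "drop"
      )
    train_vals <- stats::setNames(train$logbb, canonical_structure_key(train$smiles))
  }

  ok <- preds[preds$status == "ok" & !is.na(preds$logbb), , drop = FALSE]
  summary <- tibble::tibble(
    n = nrow(ok),
    n_excluded_unrealistic = nrow(excluded),
    n_failed = sum(preds$status != "ok"),
    r = if (nrow(ok) >= 2 && sd_pop(ok$mean) > 0) cor(ok$mean, ok$logbb)
        else NA_real_,
    rmse = if (nrow(ok)) sqrt(mean((ok$mean - ok$logbb)^2)) else NA_real_,
    n_abs_err_gt_1 = sum(ok$abs_error > 1.0),
    pct_abs_err_gt_1 = 100 * mean(ok$abs_error > 1.0),
    n_abs_err_gt_1.5 = sum(ok$abs_error > 1.5),
    pct_abs_err_gt_1.5 = 100 * mean(ok$abs_error > 1.5),
    sd_error_cor = if (nrow(ok) >= 3 && sd_pop(ok$sd) > 0)
      cor(ok$sd, ok$abs_error) else NA_real_
  )

  outliers <- ok[ok$abs_error > 1.0, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$abs_error)) |>
    dplyr::select("id", validation_logbb = "logbb", predicted = "mean",
                  "abs_error")
  if (!is.null(train)) {
    keys <- canonical_structure_key(
      external$smiles[match(outliers$id, external$id)])
    outliers$training_logbb <- unname(train_vals[keys])
  }

  structure(list(summary = summary, by_overlap = by_overlap,
                 outliers = tibble::as_tibble(outliers),
                 predictions = preds, n_excluded = nrow(excluded)),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("<external_validation>\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.external_validation <- function(x, ...) x$summary

#' End-to-end model training from a compound table
#'
#' Curation, featurization (fragment enumeration and descriptor matrix),
#' global rare-fragment and variance filters, and repeated double
#' cross-validation with local descriptor selection. The returned ensemble
#' carries its featurization settings so prediction and interpretation are
#' self-contained.
#'
#' @param compounds Tibble with `id`, `smiles`, `logbb`.
#' @param max_atoms,levels Fragment enumeration settings.
#' @param min_support Global rare-fragment filter threshold.
#' @param variance_threshold Global low-variance filter threshold (applied
#'   to range-scaled columns).
#' @param curation `NULL` to skip curation, or a [curation_config()].
#' @param dcv A [dcv_spec()].
#' @param selection Local selection settings, see [run_double_cv()].
#' @param ... Passed to [run_double_cv()].
#' @return A list of class `bbb_model`: `ensemble`, `cv`, `dm` (filtered
#'   descriptor matrix), `curation` (rejects report), `manifest`.
#' @export
train_logbb_model <- function(compounds, max_atoms = 8, levels = 1:3,
                              min_support = 5, variance_threshold = 1e-6,
                              curation = curation_config(),
                              dcv = dcv_spec(),
                              selection = list(method = "stepwise_pls",
                                               k = 200, score = "f_value"),
                              ...) {
  cur_rejects <- tibble::tibble(id = character(0), reason = character(0))
  if (!is.null(curation)) {
    cur <- curate(compounds, curation)
    compounds <- cur$kept
    cur_rejects <- cur$rejects
  }
  if (!"graph" %in% names(compounds)) {
    compounds <- parse_compounds(compounds)$compounds
  }
  dm <- build_descriptor_matrix(compounds, max_atoms = max_atoms,
                                levels = levels)
  dm <- filter_rare(dm, min_support = min_support)
  scaled <- scale_apply(fit_scaler(dm$counts, "range01"), dm$counts)
  keep <- variance_filter(scaled, variance_threshold)
  dm <- new_descriptor_matrix(dm$counts[, keep, drop = FALSE],
                              rejects = dm$rejects,
                              max_atoms = max_atoms, levels = levels)
  res <- run_double_cv(dm, compounds$logbb, dcv = dcv,
                       selection = selection, ...)
  res$ensemble$featurize <- list(max_atoms = max_atoms, levels = levels)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fragbb")),
    n_compounds = nrow(compounds),
    max_atoms = max_atoms, levels = levels, min_support = min_support,
    variance_threshold = variance_threshold,
    dcv = unclass(dcv), selection = selection,
    n_descriptors = ncol(dm$counts),
    dataset_fingerprint = dataset_fingerprint(compounds)
  )
  structure(list(ensemble = res$ensemble, cv = res$cv, dm = dm,
                 curation = cur_rejects, manifest = manifest),
            class = "bbb_model")
}

# order-independent fingerprint of ids + endpoint values, sufficient to
# detect that a replay used the same dataset
dataset_fingerprint <- function(compounds) {
  s <- paste(sort(paste(compounds$id, round(compounds$logbb, 6))),
             collapse = ";")
  sprintf("n%d-h%08x", nrow(compounds),
          sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.bbb_model <- function(x, ...) {
  cat("<bbb_model>\n")
  print(x$cv)
  print(x$ensemble)
  invisible(x)
}

#' @export
glance.bbb_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$cv), glance(x$ensemble)[, c("n_members",
                                                        "median_stopped_epoch",
                                                        "max_stopped_epoch")])
}

#' Write a run manifest as JSON
#'
#' @param model A `bbb_model`.
#' @param path Output path.
#' @export
write_manifest <- function(model, path) {
  jsonlite::write_json(model$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
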