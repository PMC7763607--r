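#' Double cross-validation specification
#'
#' The default 5 x 4 scheme splits the dataset into `n_outer` validation
#' folds; for each outer fold the remaining compounds are split into
#' `n_inner` subsets, each used once as the early-termination stop set while
#' the others train a network. The whole procedure can be repeated `n_rep`
#' times with freshly shuffled splits.
#'
#' @param n_outer,n_inner,n_rep Fold and repetition counts.
#' @param seed Integer seed governing all shuffles.
#' @return An object of class `dcv_spec`.
#' @export
dcv_spec <- function(n_outer = 5, n_inner = 4, n_rep = 1, seed = 1) {
  stopifnot(n_outer >= 2, n_inner >= 2, n_rep >= 1)
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 n_rep = as.integer(n_rep), seed = as.integer(seed)),
            class = "dcv_spec")
}

#' Build the fold plan for a double cross-validation run
#'
#' Outer folds partition all compounds into subsets whose sizes differ by at
#' most one; inner folds partition each outer-training complement the same
#' way. Splits are reshuffled independently for every repetition, but the
#' whole plan is deterministic given the seed.
#'
#' @param n Number of compounds.
#' @param spec A [dcv_spec()].
#' @return A list of class `fold_plan`: one element per repetition, each with
#'   `outer` (fold id per compound) and `inner` (list over outer folds of
#'   inner fold ids for the complement rows, named by row index).
#' @export
make_fold_plan <- function(n, spec = dcv_spec()) {
  stopifnot(inherits(spec, "dcv_spec"))
  if (n < spec$n_outer * spec$n_inner) {
    stop(sprintf("n = %d is too small for a %d x %d double cross-validation",
                 n, spec$n_outer, spec$n_inner), call. = FALSE)
  }
  plan <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_rep), function(r) {
      outer <- sample(rep_len(seq_len(spec$n_outer), n))
      inner <- lapply(seq_len(spec$n_outer), function(o) {
        rows <- which(outer != o)
        f <- sample(rep_len(seq_len(spec$n_inner), length(rows)))
        stats::setNames(f, rows)
      })
      list(outer = outer, inner = inner)
    })
  })
  structure(plan, class = "fold_plan", n = n, spec = spec)
}

#' Consolidate out-of-fold predictions into cross-validation statistics
#'
#' PRESS is the sum of squared out-of-fold prediction errors on the original
#' endpoint scale (averaged over repetitions when `n_rep > 1`), SS the sum of
#' squared deviations of the endpoint from its mean; Q2 = 1 - PRESS/SS and
#' RMSEcv = sqrt(PRESS/N).
#'
#' @param predictions Tibble with columns `row`, `rep`, `predicted` (one row
#'   per compound per repetition, original endpoint scale).
#' @param y Endpoint vector (original scale), indexed by `row`.
#' @param ids Optional compound identifiers.
#' @return An object of class `cv_result`.
#' @export
consolidate_cv <- function(predictions, y, ids = NULL) {
  stopifnot(all(c("row", "rep", "predicted") %in% names(predictions)))
  n <- length(y)
  if (!all(seq_len(n) %in% predictions$row)) {
    stop("every compound needs at least one out-of-fold prediction",
         call. = FALSE)
  }
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("constant endpoint: SS = 0", call. = FALSE)
  predictions$observed <- y[predictions$row]
  predictions$residual <- predictions$predicted - predictions$observed
  # per compound: mean squared error over repetitions, summed over compounds
  per_compound <- predictions |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(mse = mean(.data$residual^2), .groups = "drop")
  press <- sum(per_compound$mse)
  if (!is.null(ids)) predictions$id <- ids[predictions$row]
  structure(
    list(predictions = tibble::as_tibble(predictions),
         PRESS = press, SS = ss, N = n,
         Q2 = 1 - press / ss, RMSEcv = sqrt(press / n)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> N = %d, Q2 = %.3f, RMSEcv = %.3f (PRESS = %.2f, SS = %.2f)\n",
    x$N, x$Q2, x$RMSEcv, x$PRESS, x$SS))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(N = x$N, PRESS = x$PRESS, SS = x$SS, Q2 = x$Q2,
                 RMSEcv = x$RMSEcv)
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "experimental LogBB", y = "cross-validated prediction")
}

#' Run repeated double cross-validation and build the model ensemble
#'
#' For every repetition, outer fold and inner split: a range scaler and a
#' local descriptor selection are fitted on the inner-training rows only, a
#' network is trained with early termination on the inner stop set, and the
#' outer validation rows are predicted. Outer predictions are averaged over
#' the inner models of each fold and consolidated into Q2 / RMSEcv on the
#' original endpoint scale. The trained members (with their scalers and
#' selected descriptors) form the prediction ensemble.
#'
#' @param x Descriptor matrix (compounds x fragments) after the global rare
#'   and variance filters, or a `descriptor_matrix`.
#' @param y Endpoint vector (original LogBB scale).
#' @param dcv A [dcv_spec()].
#' @param selection List: `method` (`"stepwise_pls"`, `"univariate"`,
#'   `"rfe"`, or `"none"`), `k`, `score`; see the selection functions.
#' @param hidden_ratios,dropout_p Network architecture, as [network_spec()].
#' @param scaler Scaling method for descriptors and endpoint.
#' @param max_epochs,patience,learn_rate,batch_size Training controls.
#' @param min_member_fraction Abort when fewer than this fraction of ensemble
#'   members train successfully.
#' @return A list with `ensemble` (class `bbb_ensemble`) and `cv`
#'   (class `cv_result`).
#' @export
run_double_cv <- function(x, y, dcv = dcv_spec(),
                          selection = list(method = "stepwise_pls", k = 200,
                                           score = "f_value"),
                          hidden_ratios = 0.3, dropout_p = 0,
                          scaler = "range01",
                          max_epochs = 1000, patience = 20,
                          learn_rate = 1e-3, batch_size = 32,
                          min_member_fraction = 0.8) {
  if (inherits(x, "descriptor_matrix")) x <- x$counts
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  plan <- make_fold_plan(nrow(x), dcv)

  members <- list()
  failures <- 0L
  total <- dcv$n_rep * dcv$n_outer * dcv$n_inner
  pred_rows <- list()

  for (r in seq_len(dcv$n_rep)) {
    outer_assign <- plan[[r]]$outer
    for (o in seq_len(dcv$n_outer)) {
      val_rows <- which(outer_assign == o)
      inner_assign <- plan[[r]]$inner[[o]]
      inner_rows <- as.integer(names(inner_assign))
      val_pred <- matrix(NA_real_, nrow = length(val_rows),
                         ncol = dcv$n_inner)
      for (i in seq_len(dcv$n_inner)) {
        stop_rows <- inner_rows[inner_assign == i]
        train_rows <- inner_rows[inner_assign != i]
        member_seed <- dcv$seed + 7919L * r + 101L * o + i
        member <- tryCatch(
          fit_dcv_member(x, y, train_rows, stop_rows, selection,
                         hidden_ratios, dropout_p, scaler, max_epochs,
                         patience, learn_rate, batch_size, member_seed),
          error = function(e) {
            warning(sprintf("member rep %d outer %d inner %d failed: %s",
                            r, o, i, conditionMessage(e)), call. = FALSE)
            NULL
          }
        )
        if (is.null(member)) {
          failures <- failures + 1L
          next
        }
        member$rep <- r; member$outer <- o; member$inner <- i
        member$train_rows <- train_rows; member$stop_rows <- stop_rows
        members[[length(members) + 1L]] <- member
        val_pred[, i] <- member_predict_scaledmat(member, x[val_rows, ,
                                                            drop = FALSE])
      }
      if (all(is.na(val_pred))) next
      pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
        row = val_rows, rep = r,
        predicted = rowMeans(val_pred, na.rm = TRUE)
      )
    }
  }

  if ((total - failures) / total < min_member_fraction) {
    stop(sprintf("only %d of %d ensemble members trained successfully",
                 total - failures, total), call. = FALSE)
  }

  ensemble <- structure(
    list(members = members, dcv = dcv, n_failed = failures,
         catalog_keys = colnames(x),
         training = list(ids = ids, y = y)),
    class = "bbb_ensemble"
  )
  cv <- consolidate_cv(dplyr::bind_rows(pred_rows), y, ids = ids)
  list(ensemble = ensemble, cv = cv)
}

# Fit one ensemble member: scalers + local selection on the training rows,
# network trained with early stopping on the stop rows.
fit_dcv_member <- function(x, y, train_rows, stop_rows, selection,
                           hidden_ratios, dropout_p, scaler, max_epochs,
                           patience, learn_rate, batch_size, seed) {
  xtr <- x[train_rows, , drop = FALSE]
  ytr <- y[train_rows]

  sel_keys <- local_selection(xtr, ytr, selection)
  xtr <- xtr[, sel_keys, drop = FALSE]

  x_scaler <- fit_scaler(xtr, method = scaler)
  y_scaler <- fit_scaler(ytr, method = scaler)
  xs <- scale_apply(x_scaler, xtr)
  ys <- scale_apply(y_scaler, ytr)
  xst <- scale_apply(x_scaler, x[stop_rows, sel_keys, drop = FALSE])
  yst <- scale_apply(y_scaler, y[stop_rows])

  spec <- network_spec(length(sel_keys), hidden_ratios = hidden_ratios,
                       dropout_p = dropout_p)
  net <- init_network(spec, seed = seed)
  net <- train_network(net, xs, ys, xst, yst, max_epochs = max_epochs,
                       patience = patience, learn_rate = learn_rate,
                       batch_size = batch_size, seed = seed)
  list(network = net, x_scaler = x_scaler, y_scaler = y_scaler,
       selected = sel_keys)
}

local_selection <- function(xtr, ytr, selection) {
  method <- selection$method %||% "stepwise_pls"
  k <- selection$k %||% 200
  score <- selection$score %||% "f_value"
  if (method == "none") return(colnames(xtr))
  k <- min(k, ncol(xtr))
  res <- switch(method,
    stepwise_pls = select_stepwise_pls(xtr, ytr, k, score = score),
    univariate = select_univariate(xtr, ytr, k, score = score),
    rfe = select_rfe(xtr, ytr, k,
                     base_model = selection$base_model %||% "pls"),
    stop(sprintf("unknown selection method '%s'", method), call. = FALSE)
  )
  sort(res$selected)
}

# predict original-scale endpoint for raw count rows with one member
member_predict_scaledmat <- function(member, x_raw) {
  xs <- scale_apply(member$x_scaler,
                    x_raw[, member$selected, drop = FALSE])
  scale_invert(member$y_scaler, net_forward(member$network, xs))
}

#' @export
print.bbb_ensemble <- function(x, ...) {
  cat("<bbb_ensemble> ", length(x$members), " trained member(s), ",
      x$dcv$n_rep, " x ", x$dcv$n_outer, " x ", x$dcv$n_inner,
      " double cross-validation\n", sep = "")
  invisible(x)
}

#' @export
glance.bbb_ensemble <- function(x, ...) {
  epochs <- vapply(x$members, function(m) m$network$stopped_epoch, numeric(1))
  tibble::tibble(
    n_members = length(x$members),
    n_failed = x$n_failed,
    n_rep = x$dcv$n_rep, n_outer = x$dcv$n_outer, n_inner = x$dcv$n_inner,
    median_stopped_epoch = median(epochs),
    max_stopped_epoch = max(epochs)
  )
}
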