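#' Fit a per-column scaler
#'
#' Supported methods: `range01` (linear map of the fitted minimum to 0 and
#' maximum to 1 - the default used for both descriptors and the endpoint),
#' `zscore` (center/unit variance), `robust_median_iqr` (median/IQR) and
#' `quantile` (empirical CDF to approximately uniform \[0, 1\]).
#' Constant columns map to 0 by convention for every method.
#'
#' Scalers are fitted on training rows only; out-of-range values produced by
#' new data are transformed by the same affine map and are deliberately not
#' clipped.
#'
#' @param x Numeric matrix or vector (one column).
#' @param method One of `"range01"`, `"zscore"`, `"robust_median_iqr"`,
#'   `"quantile"`.
#' @return An object of class `fitted_scaler`.
#' @export
fit_scaler <- function(x, method = c("range01", "zscore", "robust_median_iqr",
                                     "quantile")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("cannot fit a scaler on zero rows", call. = FALSE)
  params <- switch(method,
    range01 = list(lo = apply(x, 2, min), hi = apply(x, 2, max)),
    zscore = list(mu = colMeans(x), s = apply(x, 2, sd)),
    robust_median_iqr = list(
      med = apply(x, 2, median),
      iqr = apply(x, 2, function(v) diff(quantile(v, c(0.25, 0.75))))
    ),
    quantile = list(sorted = apply(x, 2, sort, simplify = FALSE))
  )
  structure(list(method = method, params = params, p = ncol(x)),
            class = "fitted_scaler")
}

#' @export
print.fitted_scaler <- function(x, ...) {
  cat("<fitted_scaler> ", x$method, ", ", x$p, " column(s)\n", sep = "")
  invisible(x)
}

#' Apply a fitted scaler
#'
#' @param scaler A `fitted_scaler`.
#' @param x Matrix or vector with the same columns the scaler was fitted on.
#' @return Scaled matrix (or vector if the input was a vector).
#' @export
scale_apply <- function(scaler, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  stopifnot(ncol(x) == scaler$p)
  out <- switch(scaler$method,
    range01 = {
      span <- scaler$params$hi - scaler$params$lo
      span[span == 0] <- Inf  # constant column -> 0
      sweep(sweep(x, 2, scaler$params$lo), 2, span, "/")
    },
    zscore = {
      s <- scaler$params$s
      s[s == 0] <- Inf
      sweep(sweep(x, 2, scaler$params$mu), 2, s, "/")
    },
    robust_median_iqr = {
      iqr <- scaler$params$iqr
      iqr[iqr == 0] <- Inf
      sweep(sweep(x, 2, scaler$params$med), 2, iqr, "/")
    },
    quantile = {
      out <- x
      for (j in seq_len(ncol(x))) {
        s <- scaler$params$sorted[[j]]
        if (s[1] == s[length(s)]) {
          out[, j] <- 0
        } else {
          # mid-rank empirical CDF, linearly interpolated
          out[, j] <- (findInterval(x[, j], s) +
                         findInterval(x[, j], s, left.open = TRUE)) /
            (2 * length(s))
        }
      }
      out
    }
  )
  if (vec) drop(out) else out
}

#' Invert a fitted scaler
#'
#' Exact inverse for the affine methods on non-constant columns; for the
#' quantile method the inverse interpolates the fitted quantiles.
#'
#' @inheritParams scale_apply
#' @export
scale_invert <- function(scaler, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  stopifnot(ncol(x) == scaler$p)
  out <- switch(scaler$method,
    range01 = {
      span <- scaler$params$hi - scaler$params$lo
      sweep(sweep(x, 2, span, "*"), 2, scaler$params$lo, "+")
    },
    zscore = sweep(sweep(x, 2, scaler$params$s, "*"), 2,
                   scaler$params$mu, "+"),
    robust_median_iqr = sweep(sweep(x, 2, scaler$params$iqr, "*"), 2,
                              scaler$params$med, "+"),
    quantile = {
      out <- x
      for (j in seq_len(ncol(x))) {
        s <- scaler$params$sorted[[j]]
        out[, j] <- quantile(s, pmin(pmax(x[, j], 0), 1), names = FALSE,
                             type = 7)
      }
      out
    }
  )
  if (vec) drop(out) else out
}

#' Remove low-variance descriptor columns
#'
#' @param x Numeric matrix (scaled or raw).
#' @param threshold Minimum column variance to keep (default `1e-6`).
#' @return Character vector of surviving column names (or indices when the
#'   matrix has no column names).
#' @export
variance_filter <- function(x, threshold = 1e-6) {
  v <- apply(x, 2, var)
  keep <- which(v >= threshold)
  if (is.null(colnames(x))) keep else colnames(x)[keep]
}

# F statistic of the univariate regression of y on each column of x;
# monotone in squared correlation: F = r^2 (n-2) / (1 - r^2)
f_scores <- function(x, y) {
  n <- nrow(x)
  r <- suppressWarnings(as.vector(cor(x, y)))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  r2 * (n - 2) / (1 - r2)
}

# Kraskov-type k-nearest-neighbour mutual information between each column of
# x and y (KSG estimator 1, Chebyshev metric). Deterministic: distance ties
# are broken by a vanishing jitter derived from the row index.
mi_scores <- function(x, y, k = 3) {
  n <- length(y)
  apply(x, 2, function(v) mi_knn_single(v, y, k = k))
}

mi_knn_single <- function(x, y, k = 3) {
  n <- length(y)
  if (var(x) == 0 || var(y) == 0) return(0)
  # tiny deterministic jitter so discrete counts do not create zero distances
  eps_x <- diff(range(x)) * 1e-10 * seq_len(n)
  eps_y <- diff(range(y)) * 1e-10 * seq_len(n)
  xs <- x + eps_x
  ys <- y + eps_y
  dx <- abs(outer(xs, xs, "-"))
  dy <- abs(outer(ys, ys, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  nx <- numeric(n)
  ny <- numeric(n)
  for (i in seq_len(n)) {
    r <- sort(dz[i, ])[k]
    nx[i] <- sum(dx[i, -i] < r)
    ny[i] <- sum(dy[i, -i] < r)
  }
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(mi, 0)
}

new_selection_result <- function(method, selected, scores,
                                 early_stopped = FALSE) {
  structure(
    list(method = method, selected = selected, scores = scores,
         early_stopped = early_stopped),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$selected),
      " descriptor(s)", if (x$early_stopped) " (early stop)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$scores

# common guard: cap k at the number of available columns
check_k <- function(k, p) {
  if (k > p) {
    warning(sprintf("requested %d descriptors but only %d available", k, p),
            call. = FALSE)
    p
  } else {
    as.integer(k)
  }
}

#' Univariate descriptor selection
#'
#' Ranks descriptors by the F value of the univariate regression against the
#' endpoint, or by a non-parametric k-nearest-neighbour mutual information
#' score, and keeps the top `k`. Ties break by ascending column name.
#'
#' @param x Numeric descriptor matrix (training rows only).
#' @param y Endpoint vector aligned with `x`.
#' @param k Number of descriptors to keep.
#' @param score `"f_value"` or `"mutual_information"`.
#' @return A `selection_result` with the selected column names in rank order.
#' @export
select_univariate <- function(x, y, k,
                              score = c("f_value", "mutual_information")) {
  score <- match.arg(score)
  stopifnot(nrow(x) == length(y), k >= 1)
  k <- check_k(k, ncol(x))
  s <- if (score == "f_value") f_scores(x, y) else mi_scores(x, y)
  keys <- colnames(x) %||% as.character(seq_len(ncol(x)))
  ord <- order(-s, keys)
  sel <- keys[ord[seq_len(k)]]
  new_selection_result(
    paste0("univariate_", sub("_value", "", score)),
    sel,
    tibble::tibble(key = keys, score = s)[ord, ]
  )
}

#' Recursive feature elimination
#'
#' Iteratively drops the least important descriptors according to a base
#' model until `k` remain. Importances: absolute PLS regression coefficients
#' (`pls`), permutation-free impurity importance (`random_forest`), squared
#' primal weights of a linear SVM (`linear_svm`), or absolute coefficients of
#' a cross-validated elastic-net / lasso fit.
#'
#' @inheritParams select_univariate
#' @param base_model One of `"pls"`, `"random_forest"`, `"linear_svm"`,
#'   `"elastic_net"`, `"lasso"`.
#' @param step_frac Fraction of remaining descriptors eliminated per round.
#' @return A `selection_result`.
#' @export
select_rfe <- function(x, y, k,
                       base_model = c("pls", "random_forest", "linear_svm",
                                      "elastic_net", "lasso"),
                       step_frac = 0.2) {
  base_model <- match.arg(base_model)
  stopifnot(nrow(x) == length(y), k >= 1)
  k <- check_k(k, ncol(x))
  keys <- colnames(x) %||% as.character(seq_len(ncol(x)))
  colnames(x) <- keys
  current <- keys
  while (length(current) > k) {
    imp <- tryCatch(
      model_importance(x[, current, drop = FALSE], y, base_model),
      error = function(e) {
        stop(sprintf("RFE base model '%s' failed with %d descriptors: %s",
                     base_model, length(current), conditionMessage(e)),
             call. = FALSE)
      }
    )
    n_drop <- max(1L, min(length(current) - k,
                          floor(step_frac * length(current))))
    # drop lowest importance; ties resolved against descending key order so
    # the survivor among duplicated columns is the one with the smaller key
    ord <- order(imp, -rank(current))
    current <- sort(setdiff(current, current[ord[seq_len(n_drop)]]))
  }
  imp <- model_importance(x[, current, drop = FALSE], y, base_model)
  ord <- order(-imp, current)
  new_selection_result(
    paste0("rfe_", base_model),
    current[ord],
    tibble::tibble(key = current, score = imp)[ord, ]
  )
}

model_importance <- function(x, y, base_model) {
  switch(base_model,
    pls = abs(pls_fit(x, y)$coef),
    random_forest = {
      requireNamespace("randomForest", quietly = TRUE) ||
        stop("package 'randomForest' is required", call. = FALSE)
      fit <- withr::with_seed(1,
        randomForest::randomForest(x, y, ntree = 100, importance = FALSE))
      imp <- randomForest::importance(fit)[, 1]
      imp[colnames(x)]
    },
    linear_svm = {
      requireNamespace("e1071", quietly = TRUE) ||
        stop("package 'e1071' is required", call. = FALSE)
      fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      (w^2)[colnames(x)]
    },
    elastic_net = glmnet_importance(x, y, alpha = 0.5),
    lasso = glmnet_importance(x, y, alpha = 1)
  )
}

glmnet_importance <- function(x, y, alpha) {
  requireNamespace("glmnet", quietly = TRUE) ||
    stop("package 'glmnet' is required", call. = FALSE)
  foldid <- rep_len(1:5, nrow(x))  # deterministic folds
  fit <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                           standardize = FALSE)
  abs(as.vector(stats::coef(fit, s = "lambda.min"))[-1])
}

# Partial least squares regression fit (mixOmics backend); returns the
# regression coefficient vector and training fitted values.
pls_fit <- function(x, y, ncomp = NULL) {
  x <- as.matrix(x)
  keys <- colnames(x) %||% as.character(seq_len(ncol(x)))
  colnames(x) <- keys
  ncomp <- ncomp %||% min(5L, ncol(x), nrow(x) - 1L)
  ncomp <- max(1L, ncomp)
  # drop constant columns: they carry no covariance and break the fit
  keep <- which(apply(x, 2, var) > 0)
  if (length(keep) == 0 || var(y) == 0) {
    coefs <- stats::setNames(rep(0, ncol(x)), keys)
    return(list(coef = coefs, fitted = rep(mean(y), nrow(x))))
  }
  xk <- x[, keep, drop = FALSE]
  if (ncol(xk) == 1) {
    # one predictor: the PLS solution coincides with ordinary least squares
    xc <- xk[, 1] - mean(xk[, 1])
    b <- sum(xc * (y - mean(y))) / sum(xc^2)
    coefs <- stats::setNames(rep(0, ncol(x)), keys)
    coefs[colnames(xk)] <- b
    return(list(coef = coefs, fitted = mean(y) + b * xc))
  }
  ncomp <- min(ncomp, ncol(xk))
  fit <- mixOmics::pls(xk, y, ncomp = ncomp, scale = FALSE,
                       mode = "regression")
  pred <- predict(fit, xk)
  b <- pred$B.hat[, 1, ncomp]
  coefs <- stats::setNames(rep(0, ncol(x)), keys)
  coefs[names(b)] <- b
  list(coef = coefs, fitted = as.vector(pred$predict[, 1, ncomp]))
}

#' Stepwise descriptor selection against partial least squares residuals
#'
#' Starts from the empty set; at each step a PLS regression is fitted on the
#' currently selected descriptors, the residual endpoint is computed, and the
#' descriptor with the highest F value (or mutual information score) against
#' that residual is added. Stops at `k` descriptors, or earlier when the
#' residual variance vanishes. This is the package's default selection
#' method: the PLS surrogate is cheap, stable, and different enough from the
#' downstream networks to avoid selection-induced overfitting.
#'
#' @inheritParams select_univariate
#' @param ncomp_max Cap on PLS components (default 5).
#' @return A `selection_result`; `early_stopped` flags residual degeneration.
#' @export
select_stepwise_pls <- function(x, y, k,
                                score = c("f_value", "mutual_information"),
                                ncomp_max = 5) {
  score <- match.arg(score)
  stopifnot(nrow(x) == length(y), k >= 1)
  k <- check_k(k, ncol(x))
  keys <- colnames(x) %||% as.character(seq_len(ncol(x)))
  colnames(x) <- keys
  selected <- character(0)
  sel_scores <- numeric(0)
  residual <- y
  early <- FALSE
  for (step in seq_len(k)) {
    if (var(residual) < 1e-12) {
      early <- TRUE
      break
    }
    cand <- setdiff(keys, selected)
    s <- if (score == "f_value") {
      f_scores(x[, cand, drop = FALSE], residual)
    } else {
      mi_scores(x[, cand, drop = FALSE], residual)
    }
    best <- cand[order(-s, cand)[1]]
    selected <- c(selected, best)
    sel_scores <- c(sel_scores, s[match(best, cand)])
    fit <- pls_fit(x[, selected, drop = FALSE], y,
                   ncomp = min(ncomp_max, length(selected)))
    residual <- y - fit$fitted
  }
  new_selection_result(
    paste0("stepwise_pls_", sub("_value", "", score)),
    selected,
    tibble::tibble(key = selected, score = sel_scores),
    early_stopped = early
  )
}
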