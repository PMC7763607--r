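#' Hyperparameter search loss
#'
#' Combines model predictivity and wall-clock cost: `-q2 + log(time)/100`,
#' with time in seconds. The logarithm base defaults to natural log and is a
#' declared constant of the workflow (`base = exp(1)`); a base-10 variant can
#' be configured.
#'
#' @param q2 Cross-validated Q2 of the trial.
#' @param time_seconds Wall-clock duration of the double-CV run (> 0).
#' @param base Logarithm base.
#' @return The scalar loss (lower is better).
#' @export
hyper_loss <- function(q2, time_seconds, base = exp(1)) {
  if (any(time_seconds <= 0)) {
    stop("time_seconds must be strictly positive", call. = FALSE)
  }
  -q2 + log(time_seconds, base = base) / 100
}

#' Hyperparameter search space
#'
#' @param max_fragment_atoms Candidate fragment-size caps.
#' @param n_selected Range of descriptor-subset sizes.
#' @param hidden_ratio Range of hidden-layer ratios.
#' @param dropout_p Range of dropout probabilities.
#' @param selection_method,scaler_method Candidate categorical settings.
#' @return A list of class `search_space`.
#' @export
search_space <- function(max_fragment_atoms = c(6, 8, 10),
                         n_selected = c(100, 1000),
                         hidden_ratio = c(0.2, 0.6),
                         dropout_p = c(0, 0.5),
                         selection_method = "stepwise_pls",
                         scaler_method = "range01") {
  structure(list(max_fragment_atoms = max_fragment_atoms,
                 n_selected = n_selected, hidden_ratio = hidden_ratio,
                 dropout_p = dropout_p,
                 selection_method = selection_method,
                 scaler_method = scaler_method),
            class = "search_space")
}

#' Search workflow hyperparameters over repeated double-CV runs
#'
#' Samples the space with a Latin hypercube (uniform coverage; a random
#' search in the sense that no surrogate model steers it), runs a full
#' double cross-validation per trial, and scores each trial with
#' [hyper_loss()]. Trials that error out or exceed `time_limit` are recorded
#' as discarded. For hardware-independent tests the elapsed time entering
#' the loss can be injected through `time_fn(hyperparameters)`.
#'
#' @param dms Named list of descriptor matrices keyed by fragment-size cap
#'   (e.g. `list("6" = dm6, "8" = dm8)`), or a single matrix /
#'   `descriptor_matrix` when the fragment size is fixed.
#' @param y Endpoint vector.
#' @param space A [search_space()].
#' @param budget Number of trials.
#' @param dcv A [dcv_spec()] template (its seed is offset per trial).
#' @param seed Seed for the hypercube sample.
#' @param time_limit Wall-clock limit per trial in seconds.
#' @param time_fn Optional function of the hyperparameter list returning the
#'   time (seconds) to use in the loss instead of measured time.
#' @param ... Further arguments passed to [run_double_cv()].
#' @return A list of class `hyper_search`: `best` (one-row tibble) and
#'   `trials` (tibble, one row per trial).
#' @export
run_hypersearch <- function(dms, y, space = search_space(), budget = 10,
                            dcv = dcv_spec(), seed = 1, time_limit = Inf,
                            time_fn = NULL, ...) {
  stopifnot(budget >= 1)
  if (!is.list(dms) || inherits(dms, "descriptor_matrix")) {
    dms <- stats::setNames(list(dms), as.character(space$max_fragment_atoms[1]))
    space$max_fragment_atoms <- space$max_fragment_atoms[1]
  }
  requireNamespace("lhs", quietly = TRUE) ||
    stop("package 'lhs' is required for the hyperparameter search",
         call. = FALSE)
  u <- withr::with_seed(seed, lhs::randomLHS(budget, 4))
  trials <- vector("list", budget)
  for (t in seq_len(budget)) {
    hp <- list(
      max_fragment_atoms = space$max_fragment_atoms[
        1 + min(floor(u[t, 1] * length(space$max_fragment_atoms)),
                length(space$max_fragment_atoms) - 1)],
      n_selected = round(space$n_selected[1] +
                           u[t, 2] * diff(range(space$n_selected))),
      hidden_ratio = space$hidden_ratio[1] +
        u[t, 3] * diff(range(space$hidden_ratio)),
      dropout_p = space$dropout_p[1] + u[t, 4] * diff(range(space$dropout_p)),
      selection_method = space$selection_method[1],
      scaler_method = space$scaler_method[1]
    )
    dm <- dms[[as.character(hp$max_fragment_atoms)]]
    trial_dcv <- dcv
    trial_dcv$seed <- dcv$seed + t
    t0 <- Sys.time()
    res <- tryCatch(
      run_double_cv(dm, y, dcv = trial_dcv,
                    selection = list(method = hp$selection_method,
                                     k = hp$n_selected, score = "f_value"),
                    hidden_ratios = hp$hidden_ratio,
                    dropout_p = hp$dropout_p,
                    scaler = hp$scaler_method, ...),
      error = function(e) e
    )
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    time_used <- if (!is.null(time_fn)) time_fn(hp) else max(elapsed, 1)
    failed <- inherits(res, "error") || elapsed > time_limit
    trials[[t]] <- tibble::tibble(
      trial = t,
      max_fragment_atoms = hp$max_fragment_atoms,
      n_selected = hp$n_selected,
      hidden_ratio = hp$hidden_ratio,
      dropout_p = hp$dropout_p,
      q2 = if (failed) NA_real_ else res$cv$Q2,
      time = time_used,
      loss = if (failed) NA_real_ else hyper_loss(res$cv$Q2, time_used),
      status = if (failed) "discarded" else "ok",
      seed = trial_dcv$seed
    )
  }
  trials <- dplyr::bind_rows(trials)
  ok <- dplyr::filter(trials, .data$status == "ok")
  if (nrow(ok) == 0) stop("all hyperparameter trials were discarded",
                          call. = FALSE)
  best <- ok[which.min(ok$loss), ]
  structure(list(best = best, trials = trials), class = "hyper_search")
}

#' @export
print.hyper_search <- function(x, ...) {
  cat("<hyper_search> ", nrow(x$trials), " trials, best loss ",
      signif(x$best$loss, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hyper_search <- function(x, ...) x$trials

#' @export
glance.hyper_search <- function(x, ...) x$best

#' Write the trial log as JSON lines
#'
#' One JSON record per trial; the log is append-only and replayable (each
#' record carries the seed of its double-CV run).
#'
#' @param x A `hyper_search`.
#' @param path Output path.
#' @export
write_trials_jsonl <- function(x, path) {
  lines <- vapply(seq_len(nrow(x$trials)), function(i) {
    jsonlite::toJSON(as.list(x$trials[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
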