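#' Configuration for the singular transduction search
#'
#' @param learner a `survival_learner` (see [cox_learner()], [svrc_learner()])
#'   with its hyperparameters fixed
#' @param time_point time horizon for the sensitivity/specificity term of the
#'   search criterion
#' @param grid_size number of increments `m` between a censored time and the
#'   maximum observed time; each censored record is searched over `m + 1`
#'   equally spaced candidates including both endpoints (default 10)
#' @param seed optional integer seed set before the search, for learners with
#'   stochastic internals (the built-in learners are deterministic)
#' @param verbose print per-instance progress
#' @return object of class `transduction_config`
#' @export
transduction_config <- function(learner, time_point, grid_size = 10L,
                                seed = NULL, verbose = FALSE) {
  stopifnot(is.list(learner), is.function(learner$fit))
  grid_size <- as.integer(grid_size)
  if (grid_size < 1L) stop("`grid_size` must be >= 1", call. = FALSE)
  if (!is.finite(time_point) || time_point <= 0) {
    stop("`time_point` must be a positive number", call. = FALSE)
  }
  structure(
    list(learner = learner, time_point = time_point, grid_size = grid_size,
         seed = seed, verbose = isTRUE(verbose)),
    class = "transduction_config"
  )
}

#' Candidate target times for one censored record
#'
#' An arithmetic grid of `m + 1` equally spaced values from the censored time
#' `U_i` (always the first candidate — "leave it unchanged" is always on the
#' table) to the maximum observed time `t_max`, both inclusive. Degenerates
#' to the single candidate `U_i` when `U_i = t_max`.
#'
#' @param u censored observed time
#' @param t_max maximum observed time in the dataset
#' @param m number of increments (grid has `m + 1` points)
#' @return numeric vector of candidate times, increasing
#' @export
candidate_grid <- function(u, t_max, m) {
  if (u > t_max) stop("censored time exceeds t_max", call. = FALSE)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (u == t_max) return(u)
  seq(u, t_max, length.out = m + 1L)
}

# Fit the learner on `d_mod` and score it against the ORIGINAL dataset
# `d_orig`. The threshold for the classification term is re-selected on the
# original data for each candidate fit (training-data policy).
search_criterion <- function(d_mod, d_orig, cfg) {
  model <- fit_learner(cfg$learner, d_mod)
  scores <- predict(model, d_orig)
  ev <- evaluate_scores(d_orig, scores, cfg$time_point)
  list(criterion = ev$criterion, evaluation = ev, model = model)
}

#' Transduce a single censored record's target time
#'
#' The unit step of singular transduction: for censored record `i`, each
#' candidate time in [candidate_grid()] replaces `U_i` (only that record; the
#' event indicator stays censored), the learner is refit, and the combined
#' criterion `CI + sens * spec` is computed on the training data against the
#' ORIGINAL observed times — never the candidate, which would let the search
#' grade its own homework. The best candidate is kept; ties break toward the
#' smallest candidate, i.e. the least departure from the observed censoring
#' time. Candidates whose fit fails are skipped with a warning.
#'
#' @param d the original [survival_dataset()]
#' @param i index of a censored record (`event[i] == 0`)
#' @param cfg a [transduction_config()]
#' @return list with `best_time`, `best_criterion`, and `trace` — a data
#'   frame with one row per candidate (`candidate`, `criterion`, `ok`)
#' @export
transduce_instance <- function(d, i, cfg) {
  stopifnot(inherits(d, "survival_dataset"), inherits(cfg, "transduction_config"))
  i <- as.integer(i)
  if (i < 1L || i > n_records(d)) stop("record index out of range", call. = FALSE)
  if (d$event[i] != 0L) {
    stop(sprintf("record %d is an event; only censored targets are transduced", i),
         call. = FALSE)
  }
  grid <- candidate_grid(d$time[i], d$t_max, cfg$grid_size)
  crit <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    res <- tryCatch(
      search_criterion(replace_time(d, i, grid[k]), d, cfg),
      error = function(e) {
        warning(sprintf("candidate %g for record %d skipped: %s",
                        grid[k], i, conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (!is.null(res)) crit[k] <- res$criterion
  }
  if (all(is.na(crit))) {
    stop(sprintf("every candidate fit failed for record %d", i), call. = FALSE)
  }
  # strict improvement required to move off an earlier (smaller) candidate
  best_k <- which(crit >= max(crit, na.rm = TRUE) - 1e-12)[1L]
  list(best_time = grid[best_k], best_criterion = crit[best_k],
       trace = data.frame(candidate = grid, criterion = crit,
                          ok = !is.na(crit)))
}

#' Singular transduction of a censored survival dataset
#'
#' Runs [transduce_instance()] independently for every censored record — each
#' search sees only the original dataset, never another record's selection,
#' which is what makes the cost linear in the number of censored cases — then
#' assembles the transduced targets `U_hat` (events keep `U_hat_i = U_i`;
#' censored records satisfy `U_i <= U_hat_i <= t_max` by construction) and
#' fits the final learner once on the transduced times with the original
#' event indicators.
#'
#' @param d a [survival_dataset()] with at least one event
#' @param cfg a [transduction_config()]
#' @return object of class `transduction_result`: `data` (the transduced
#'   dataset, a `survival_dataset` carrying the new times), `original` (the
#'   untouched input), `transduced_times`, `model` (final fit),
#'   `baseline_criterion` (criterion of a plain fit on the original data),
#'   `final_criterion` (criterion of the final model, original times), and
#'   `provenance` — per censored record, the full candidate trace
#' @export
transduce_dataset <- function(d, cfg) {
  stopifnot(inherits(d, "survival_dataset"), inherits(cfg, "transduction_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cens <- which(d$event == 0L)
  u_hat <- d$time
  provenance <- list()
  baseline <- search_criterion(d, d, cfg)
  for (i in cens) {
    res <- transduce_instance(d, i, cfg)
    u_hat[i] <- res$best_time
    provenance[[as.character(i)]] <- res$trace
    if (cfg$verbose) {
      message(sprintf("record %d: U = %.4g -> U_hat = %.4g (criterion %.4f)",
                      i, d$time[i], res$best_time, res$best_criterion))
    }
  }
  d_trans <- d
  d_trans$time <- u_hat
  d_trans$t_max <- max(u_hat)
  model <- if (length(cens)) fit_learner(cfg$learner, d_trans) else baseline$model
  final_eval <- evaluate_scores(d, predict(model, d), cfg$time_point)
  structure(
    list(data = d_trans, original = d, transduced_times = u_hat,
         model = model, config = cfg,
         baseline_criterion = baseline$criterion,
         final_criterion = final_eval$criterion,
         final_evaluation = final_eval,
         provenance = provenance),
    class = "transduction_result"
  )
}

#' @export
print.transduction_result <- function(x, ...) {
  moved <- sum(x$transduced_times != x$original$time)
  cat(sprintf("Transduction result: %d of %d censored targets moved\n",
              moved, sum(x$original$event == 0)))
  cat(sprintf("  training criterion (original times): baseline %.4f -> final %.4f\n",
              x$baseline_criterion, x$final_criterion))
  invisible(x)
}

#' Evaluate a fitted model on training and validation endpoints
#'
#' The standard report of the early-to-late endpoint design: metrics on the
#' training data, on an early-endpoint validation set, and optionally on a
#' late-endpoint validation set over the same patients. All metrics are
#' computed on ORIGINAL observed times (transduced targets are a training
#' device only), and the stratification threshold is selected on the training
#' scores once and frozen for both validation blocks.
#'
#' @param model a fitted model with a `predict` method returning
#'   survival-oriented scores
#' @param d_train training [survival_dataset()] (original times)
#' @param d_valid_early early-endpoint validation set
#' @param d_valid_late optional late-endpoint validation set (same feature
#'   schema)
#' @param time_point evaluation horizon for sensitivity/specificity
#' @return data frame with one row per block (`training`,
#'   `validation_early`, `validation_late`) and columns `ci`, `sensitivity`,
#'   `specificity`, `criterion`, `threshold`, `time_point`, `n`
#' @export
report_evaluation <- function(model, d_train, d_valid_early,
                              d_valid_late = NULL, time_point) {
  sets <- list(training = d_train, validation_early = d_valid_early)
  if (!is.null(d_valid_late)) sets$validation_late <- d_valid_late
  schema <- d_train$feature_names
  for (nm in names(sets)) {
    if (!identical(sets[[nm]]$feature_names, schema)) {
      stop(sprintf("feature schema mismatch between training data and %s", nm),
           call. = FALSE)
    }
  }
  train_scores <- predict(model, d_train)
  threshold <- select_threshold(d_train, train_scores, time_point)
  rows <- lapply(names(sets), function(nm) {
    dd <- sets[[nm]]
    ev <- evaluate_scores(dd, predict(model, dd), time_point, threshold = threshold)
    data.frame(block = nm, ci = ev$ci, sensitivity = ev$sensitivity,
               specificity = ev$specificity, criterion = ev$criterion,
               threshold = threshold, time_point = time_point,
               n = n_records(dd))
  })
  do.call(rbind, rows)
}
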