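#' Concordance index for right-censored data
#'
#' Harrell's concordance index: the probability that, of two comparable
#' patients, the one with the shorter survival time receives the smaller
#' predicted score. Scores are survival-time-oriented throughout the package
#' (larger score = longer predicted survival), so a perfect model scores 1 and
#' a perfectly reversed one scores 0; 0.5 is chance.
#'
#' Comparable pairs are (i, j) with `U_i < U_j` and `delta_i = 1`, plus tied
#' pairs `U_i = U_j` with `delta_i = 1, delta_j = 0` (the event is known to
#' precede the censored patient's latent time). A pair is concordant when
#' `s_i < s_j`; tied scores receive credit 0.5. Pairs of tied event times are
#' not comparable.
#'
#' @param d a [survival_dataset()]
#' @param scores numeric vector of model outputs, one per record, all finite.
#' @return concordance index in \[0, 1\]
#' @export
concordance_index <- function(d, scores) {
  stopifnot(inherits(d, "survival_dataset"))
  scores <- check_scores(d, scores)
  u <- d$time; ev <- d$event
  n <- length(u)
  # comparable[i, j]: i is the earlier patient of the pair
  du <- outer(u, u, "<")                    # U_i < U_j
  tie <- outer(u, u, "==")
  comp <- (du & (ev == 1)) | (tie & outer(ev == 1, ev == 0, "&"))
  npairs <- sum(comp)
  if (npairs == 0) {
    stop("concordance index undefined: no comparable pairs", call. = FALSE)
  }
  slt <- outer(scores, scores, "<")
  seq_ <- outer(scores, scores, "==")
  (sum(slt & comp) + 0.5 * sum(seq_ & comp)) / npairs
}

check_scores <- function(d, scores) {
  scores <- as.numeric(scores)
  if (length(scores) != n_records(d)) {
    stop("scores must have one entry per record", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  scores
}

#' Stratify a population at a time point
#'
#' Splits records into a positive (high-risk) class — events occurring at or
#' before the time point — a negative class — anyone still event-free beyond
#' it — and an excluded set: censored records whose follow-up ended at or
#' before the time point, about whom nothing is known at that horizon.
#' Predicted high-risk means score below the threshold, because scores are
#' survival-time-oriented.
#'
#' @param d a [survival_dataset()]
#' @param scores survival-oriented scores, one per record
#' @param time_point positive time horizon
#' @param threshold score cutoff; records with `score < threshold` are
#'   predicted positive (high risk)
#' @return an object of class `stratification_result`: labels per record
#'   (`"positive"`, `"negative"`, `"excluded"`), the threshold, time point,
#'   sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`, computed over
#'   non-excluded records only.
#' @export
stratify <- function(d, scores, time_point, threshold) {
  stopifnot(inherits(d, "survival_dataset"))
  scores <- check_scores(d, scores)
  if (!is.finite(time_point) || time_point <= 0) {
    stop("`time_point` must be a positive number", call. = FALSE)
  }
  pos <- d$event == 1 & d$time <= time_point
  neg <- d$time > time_point
  excl <- d$event == 0 & d$time <= time_point
  if (!any(pos)) {
    stop(sprintf("stratification undefined at t = %g: positive class empty (no events at or before the time point)",
                 time_point), call. = FALSE)
  }
  if (!any(neg)) {
    stop(sprintf("stratification undefined at t = %g: negative class empty (no records beyond the time point)",
                 time_point), call. = FALSE)
  }
  pred_pos <- scores < threshold
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(neg & !pred_pos); fp <- sum(neg & pred_pos)
  labels <- rep("negative", length(scores))
  labels[pos] <- "positive"
  labels[excl] <- "excluded"
  structure(
    list(time_point = time_point, threshold = threshold, labels = labels,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         counts = c(tp = tp, fn = fn, tn = tn, fp = fp, excluded = sum(excl))),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("Stratification at t = %g (threshold %.4g): sens %.3f, spec %.3f, %d excluded\n",
              x$time_point, x$threshold, x$sensitivity, x$specificity,
              x$counts[["excluded"]]))
  invisible(x)
}

#' Select a score threshold on training data
#'
#' Searches the midpoints of adjacent sorted unique scores and returns the
#' cutoff maximizing sensitivity x specificity at the given time point; ties
#' are broken toward the smaller cutoff. The threshold is meant to be frozen
#' on training data and reused unchanged on validation data.
#'
#' @inheritParams stratify
#' @return the selected threshold (numeric scalar)
#' @export
select_threshold <- function(d, scores, time_point) {
  stopifnot(inherits(d, "survival_dataset"))
  scores <- check_scores(d, scores)
  su <- sort(unique(scores))
  if (length(su) == 1L) {
    warning("all scores identical; threshold selection is vacuous", call. = FALSE)
    # single candidate: the score itself (classifies everything negative)
    cand <- su
  } else {
    cand <- (su[-1] + su[-length(su)]) / 2
  }
  best <- NULL; best_val <- -Inf
  for (th in cand) {
    st <- stratify(d, scores, time_point, th)   # errors propagate
    val <- st$sensitivity * st$specificity
    if (val > best_val + 1e-12) {
      best_val <- val; best <- th
    }
  }
  best
}

#' Combined concordance / classification criterion
#'
#' `criterion = CI + sensitivity * specificity`, the scalar objective used
#' both to compare fitted models and to drive the transduction search. Both
#' terms live on a 0-1 accuracy scale, so the criterion ranges over \[0, 2\].
#'
#' @param ci concordance index in \[0, 1\]
#' @param sensitivity,specificity classification accuracies in \[0, 1\]
#' @return `ci + sensitivity * specificity`
#' @export
criterion <- function(ci, sensitivity, specificity) {
  for (v in list(ci = ci, sensitivity = sensitivity, specificity = specificity)) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("criterion inputs must be numbers in [0, 1]", call. = FALSE)
    }
  }
  ci + sensitivity * specificity
}

#' Evaluate survival-oriented scores against a dataset
#'
#' The single evaluation entry point used by the transduction search and the
#' experiment pipeline: concordance index over comparable pairs, sensitivity
#' and specificity at a time point, and their combination
#' `CI + sens * spec`. When `threshold` is `NULL` it is chosen on `d` itself
#' with [select_threshold()]; pass a frozen training threshold when
#' evaluating validation data.
#'
#' @inheritParams stratify
#' @param threshold score cutoff, or `NULL` to select it on `d`
#' @return list with `ci`, `sensitivity`, `specificity`, `criterion`,
#'   `threshold`, `time_point`
#' @export
evaluate_scores <- function(d, scores, time_point, threshold = NULL) {
  scores <- check_scores(d, scores)
  ci <- concordance_index(d, scores)
  if (is.null(threshold)) {
    threshold <- select_threshold(d, scores, time_point)
  }
  st <- stratify(d, scores, time_point, threshold)
  list(ci = ci,
       sensitivity = st$sensitivity,
       specificity = st$specificity,
       criterion = criterion(ci, st$sensitivity, st$specificity),
       threshold = threshold,
       time_point = time_point)
}
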