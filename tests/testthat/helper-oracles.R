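# Independent oracles and fixture builders used across the suite.
# Each oracle is a direct, unoptimized transcription of the definition it
# checks, sharing no code with the implementation under test.

# Brute-force Harrell concordance: enumerate every ordered pair, apply the
# comparability rule, count concordance with 0.5 for score ties.
brute_force_ci <- function(time, event, scores) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] < scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# Direct confusion-matrix counting for time-point stratification.
brute_force_confusion <- function(time, event, scores, tp, thr) {
  tp_ <- fn <- tn <- fp <- 0
  for (i in seq_along(time)) {
    if (event[i] == 0 && time[i] <= tp) next        # excluded
    truth_pos <- event[i] == 1 && time[i] <= tp
    pred_pos <- scores[i] < thr
    if (truth_pos && pred_pos) tp_ <- tp_ + 1
    if (truth_pos && !pred_pos) fn <- fn + 1
    if (!truth_pos && !pred_pos) tn <- tn + 1
    if (!truth_pos && pred_pos) fp <- fp + 1
  }
  c(sensitivity = tp_ / (tp_ + fn), specificity = tn / (tn + fp))
}

# Primal SVRc objective (definition) and a derivative-free minimizer over
# (w, b) as an independent solution oracle for small linear-kernel problems.
svrc_primal_oracle_obj <- function(par, X, y, Ci, Cis, ei, eis) {
  d <- ncol(X)
  w <- par[seq_len(d)]; b <- par[d + 1]
  f <- drop(X %*% w) + b
  0.5 * sum(w^2) + sum(Ci * pmax(0, y - f - ei)) + sum(Cis * pmax(0, f - y - eis))
}

svrc_primal_oracle <- function(X, y, Ci, Cis, ei, eis, start = NULL) {
  d <- ncol(X)
  if (is.null(start)) start <- rep(0, d + 1)
  o <- optim(start, svrc_primal_oracle_obj, X = X, y = y,
             Ci = Ci, Cis = Cis, ei = ei, eis = eis,
             method = "Nelder-Mead", control = list(maxit = 50000, reltol = 1e-14))
  o <- optim(o$par, svrc_primal_oracle_obj, X = X, y = y,
             Ci = Ci, Cis = Cis, ei = ei, eis = eis,
             method = "Nelder-Mead", control = list(maxit = 50000, reltol = 1e-15))
  o
}

# Small random right-censored fixture.
random_fixture <- function(n, d = 2, event_prob = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    ev <- rbinom(n, 1, event_prob)
    if (sum(ev) >= 1) break
  }
  survival_dataset(matrix(rnorm(n * d), n, d),
                   round(rexp(n, 1 / 10), 3), ev)
}

# A learner whose fitted model ignores the targets entirely: it always
# scores by the first feature. Used to show transduction does not move
# targets when the criterion cannot respond to them.
frozen_scorer_learner <- function() {
  structure(list(
    name = "frozen",
    fit = function(d) structure(list(), class = "frozen_scorer")
  ), class = "survival_learner")
}
registerS3method("predict", "frozen_scorer",
                 function(object, d, ...) d$features[, 1L],
                 envir = asNamespace("stats"))
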