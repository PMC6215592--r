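#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Breslow handling of tied event
#' times by Newton-Raphson with step halving, iterating to a gradient norm of
#' `tol` (default 1e-8) or `max_iter` iterations. The model is the de facto
#' standard for right-censored regression: the hazard for patient i is
#' `h_i(t) = h0(t) * exp(b' x_i)`, and censored records contribute to risk
#' sets only up to their censoring time. The baseline hazard `h0` is not
#' estimated: it cancels from every ranking-based quantity this package
#' computes (concordance, threshold stratification).
#'
#' Monotone likelihood (perfect separation) is detected when a coefficient
#' exceeds `coef_cap` in absolute value; the coefficient vector is capped and
#' a warning is raised.
#'
#' @param d a [survival_dataset()] with at least one event
#' @param standardize center/scale features before fitting (default `FALSE`;
#'   Cox estimates are equivariant to scaling so this only affects the scale
#'   on which coefficients are reported)
#' @param ridge optional L2 penalty (default 0 = plain Cox); a small ridge is
#'   an escape hatch for separation pathologies, not a tuning device
#' @param max_iter,tol Newton iteration controls
#' @param coef_cap absolute bound beyond which monotone likelihood is declared
#' @return object of class `cox_model`: `coefficients` (hazard-oriented, one
#'   per feature), `feature_names`, `loglik`, `vcov` (inverse information),
#'   `iterations`, `grad_norm`, `converged`, `separation`, and the scaling
#'   applied (if any)
#' @export
fit_cox <- function(d, standardize = FALSE, ridge = 0,
                    max_iter = 100L, tol = 1e-8, coef_cap = 15) {
  stopifnot(inherits(d, "survival_dataset"))
  if (sum(d$event) == 0) stop("cannot fit Cox model: no events", call. = FALSE)
  scaling <- NULL
  if (standardize) {
    scaling <- feature_scaling(d)
    d <- apply_scaling(scaling, d)
  }
  X <- d$features
  p <- ncol(X)
  const <- apply(X, 2L, function(col) max(col) == min(col))
  if (any(const)) {
    stop(sprintf("feature(s) constant across all records: %s",
                 paste(d$feature_names[const], collapse = ", ")), call. = FALSE)
  }
  beta <- rep(0, p)
  ll_old <- cox_loglik(beta, d, ridge)$loglik
  separation <- FALSE
  iter <- 0L
  gnorm <- Inf
  for (iter in seq_len(max_iter)) {
    der <- cox_loglik(beta, d, ridge)
    gnorm <- sqrt(sum(der$gradient^2))
    if (gnorm <= tol) break
    step <- tryCatch(solve(der$hessian, der$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {
      stop("Cox fit failed: singular information matrix (collinear features?)",
           call. = FALSE)
    }
    # Newton direction is -H^{-1} g with H negative definite
    delta <- -step
    # step halving
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + delta / 2^h
      ll_new <- cox_loglik(cand, d, ridge)$loglik
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    beta <- cand; ll_old <- ll_new
    if (max(abs(beta)) > coef_cap) {
      separation <- TRUE
      beta <- pmin(pmax(beta, -coef_cap), coef_cap)
      warning("monotone partial likelihood detected (perfect separation); coefficients capped",
              call. = FALSE)
      break
    }
  }
  final <- cox_loglik(beta, d, ridge)
  gnorm <- sqrt(sum(final$gradient^2))
  converged <- gnorm <= tol || separation
  if (!converged) {
    stop(sprintf("Cox fit did not converge in %d iterations (gradient norm %.3g)",
                 max_iter, gnorm), call. = FALSE)
  }
  vcov <- tryCatch(solve(-final$hessian), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(d$feature_names, d$feature_names)
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), d$feature_names),
         feature_names = d$feature_names,
         loglik = final$loglik, vcov = vcov,
         iterations = iter, grad_norm = gnorm,
         converged = converged, separation = separation,
         ridge = ridge, scaling = scaling),
    class = "cox_model"
  )
}

# Breslow partial log-likelihood, gradient and Hessian.
# Records sorted by decreasing time; cumulative sums give, for each event
# time, S0 = sum_{U_j >= t} e^eta_j, S1 = sum x_j e^eta_j, S2 = sum x_j x_j' e^eta_j.
# Tied observed times share the same risk set, so cumulative positions are
# taken at the last index of each tie group.
cox_loglik <- function(beta, d, ridge = 0) {
  X <- d$features; u <- d$time; ev <- d$event
  n <- nrow(X); p <- ncol(X)
  ord <- order(u, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]; uo <- u[ord]; evo <- ev[ord]
  eta <- drop(Xo %*% beta)
  eta_c <- eta - max(eta)                  # guard exp overflow; constant cancels
  w <- exp(eta_c)
  S0 <- cumsum(w)
  S1 <- apply(Xo * w, 2L, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # S2 stored as n x p(p+1)/2 cumulative of upper-triangular products
  idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- Xo[, idx[, 1], drop = FALSE] * Xo[, idx[, 2], drop = FALSE]
  S2 <- apply(XX * w, 2L, cumsum)
  if (nrow(idx) == 1L) S2 <- matrix(S2, ncol = 1L)
  # position of risk-set boundary for each record: last index of its tie group
  pos <- ave(seq_len(n), match(uo, unique(uo)), FUN = max)
  events <- which(evo == 1)
  pe <- pos[events]
  ll <- sum(eta_c[events] - log(S0[pe]))
  mu <- S1[pe, , drop = FALSE] / S0[pe]
  grad <- colSums(Xo[events, , drop = FALSE]) - colSums(mu)
  Htri <- -(colSums(S2[pe, , drop = FALSE] / S0[pe]) -
            colSums(mu[, idx[, 1], drop = FALSE] * mu[, idx[, 2], drop = FALSE]))
  H <- matrix(0, p, p)
  H[upper.tri(H, diag = TRUE)] <- Htri
  H <- H + t(H) - diag(diag(H), p)
  if (ridge > 0) {
    ll <- ll - ridge * sum(beta^2) / 2
    grad <- grad - ridge * beta
    H <- H - ridge * diag(p)
  }
  list(loglik = ll, gradient = grad, hessian = H)
}

#' Predict survival-oriented scores from a Cox model
#'
#' Returns the negated linear predictor `-(b' x_i)` per record: higher hazard
#' means shorter predicted survival, so negation produces scores on the
#' survival-time orientation every metric in this package expects.
#'
#' @param object a fitted `cox_model`
#' @param d a [survival_dataset()] with matching feature dimension
#' @param ... unused
#' @return numeric score vector
#' @export
predict.cox_model <- function(object, d, ...) {
  stopifnot(inherits(d, "survival_dataset"))
  if (n_features(d) != length(object$coefficients)) {
    stop("feature dimension mismatch between model and dataset", call. = FALSE)
  }
  if (!is.null(object$scaling)) d <- apply_scaling(object$scaling, d)
  -drop(d$features %*% object$coefficients)
}

#' Per-feature weights of a fitted model
#'
#' Generic accessor for the per-feature weight vector of any base learner.
#' Cox weights are the raw coefficients, hazard-oriented (positive = higher
#' risk = shorter survival). Linear-kernel SVRc weights are
#' survival-time-oriented (negative = risk factor), i.e. the opposite sign
#' convention — compare magnitudes, or normalize, across learners.
#'
#' @param model a fitted model
#' @param ... unused
#' @return named numeric vector, one weight per feature
#' @export
feature_weights <- function(model, ...) UseMethod("feature_weights")

#' @rdname feature_weights
#' @export
feature_weights.cox_model <- function(model, ...) model$coefficients

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards model (%d features, loglik %.4f, %d Newton iterations)\n",
              length(x$coefficients), x$loglik, x$iterations))
  print(round(x$coefficients, 4))
  if (x$separation) cat("note: monotone likelihood detected; coefficients capped\n")
  invisible(x)
}
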