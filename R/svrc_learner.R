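#' Parameters for censoring-aware support vector regression
#'
#' SVRc adapts epsilon-insensitive support vector regression to right-censored
#' targets by letting the slack penalty `C` and tube half-width `epsilon`
#' depend on the record's censoring status and on which side of the tube the
#' residual falls. The starred quantities govern the upper side
#' (over-prediction, `f(x) > y`); the unstarred the lower side
#' (under-prediction). For a censored record the observed time is only a lower
#' bound on the true survival time, so predicting above it should be cheap:
#' the recommended regime is `eps_c_star >= eps_n_star` and
#' `C_c_star <= C_n_star` (a warning is raised otherwise).
#'
#' The epsilon defaults are data-adaptive: left `NULL`, they resolve at fit
#' time to `0.1 * sd(times)` on every side except the censored upper side,
#' which gets `0.5 * sd(times)`.
#'
#' @param C_n,C_n_star,C_c,C_c_star positive slack penalties for
#'   noncensored (`_n`) and censored (`_c`) records, lower and upper (`_star`)
#'   side
#' @param eps_n,eps_n_star,eps_c,eps_c_star nonnegative tube half-widths, or
#'   `NULL` for the data-adaptive defaults
#' @param kernel `"linear"` (default, yields one weight per feature) or
#'   `"rbf"`
#' @param gamma RBF bandwidth, used only when `kernel = "rbf"`
#' @return object of class `svrc_params`
#' @export
svrc_params <- function(C_n = 1, C_n_star = 1, C_c = 1, C_c_star = 0.2,
                        eps_n = NULL, eps_n_star = NULL,
                        eps_c = NULL, eps_c_star = NULL,
                        kernel = c("linear", "rbf"), gamma = 1) {
  kernel <- match.arg(kernel)
  cs <- c(C_n = C_n, C_n_star = C_n_star, C_c = C_c, C_c_star = C_c_star)
  if (any(!is.finite(cs)) || any(cs <= 0)) {
    stop("all C parameters must be positive and finite", call. = FALSE)
  }
  for (e in list(eps_n, eps_n_star, eps_c, eps_c_star)) {
    if (!is.null(e) && (!is.finite(e) || e < 0)) {
      stop("epsilon parameters must be nonnegative", call. = FALSE)
    }
  }
  p <- structure(
    list(C_n = C_n, C_n_star = C_n_star, C_c = C_c, C_c_star = C_c_star,
         eps_n = eps_n, eps_n_star = eps_n_star,
         eps_c = eps_c, eps_c_star = eps_c_star,
         kernel = kernel, gamma = gamma),
    class = "svrc_params"
  )
  check_svrc_regime(p)
  p
}

check_svrc_regime <- function(p) {
  if (p$C_c_star > p$C_n_star) {
    warning("C_c_star > C_n_star: over-prediction of censored targets is penalized more heavily than of events; the usual censoring-aware regime is the reverse",
            call. = FALSE)
  }
  if (!is.null(p$eps_c_star) && !is.null(p$eps_n_star) && p$eps_c_star < p$eps_n_star) {
    warning("eps_c_star < eps_n_star: the censored upper tube is narrower than the event tube; the usual censoring-aware regime is the reverse",
            call. = FALSE)
  }
  invisible(p)
}

# Fill NULL epsilons from the observed-time spread of the training data.
resolve_eps <- function(params, times) {
  s <- stats::sd(times)
  if (!is.finite(s) || s == 0) s <- 1
  if (is.null(params$eps_n)) params$eps_n <- 0.1 * s
  if (is.null(params$eps_n_star)) params$eps_n_star <- 0.1 * s
  if (is.null(params$eps_c)) params$eps_c <- 0.1 * s
  if (is.null(params$eps_c_star)) params$eps_c_star <- 0.5 * s
  params
}

#' Resolve per-sample SVRc penalties and tube widths
#'
#' With `s_i = 1` for a censored record and `s_i = 0` for an event, each
#' record's parameters are the censoring-status mixture
#' `C_i* = s_i C_c* + (1 - s_i) C_n*`, `eps_i* = s_i eps_c* + (1 - s_i)
#' eps_n*`, and symmetrically on the unstarred (lower) side.
#'
#' @param params an [svrc_params()] with all epsilons resolved (numeric)
#' @param event_indicator 0/1 vector (1 = event)
#' @return list of vectors `C`, `C_star`, `eps`, `eps_star`
#' @export
resolve_per_sample <- function(params, event_indicator) {
  stopifnot(inherits(params, "svrc_params"))
  if (is.null(params$eps_n) || is.null(params$eps_n_star) ||
      is.null(params$eps_c) || is.null(params$eps_c_star)) {
    stop("epsilon parameters unresolved; call resolve_eps via fit_svrc or supply numerics",
         call. = FALSE)
  }
  s <- 1 - as.numeric(event_indicator)     # 1 iff censored
  list(C        = s * params$C_c      + (1 - s) * params$C_n,
       C_star   = s * params$C_c_star + (1 - s) * params$C_n_star,
       eps      = s * params$eps_c      + (1 - s) * params$eps_n,
       eps_star = s * params$eps_c_star + (1 - s) * params$eps_n_star)
}

svrc_kernel <- function(params, X, Y = NULL) {
  if (params$kernel == "linear") {
    if (is.null(Y)) X %*% t(X) else X %*% t(Y)
  } else {
    if (is.null(Y)) Y <- X
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    exp(-params$gamma * pmax(d2, 0))
  }
}

#' Fit support vector regression for censored data
#'
#' Solves the convex program
#' `min 1/2 ||W||^2 + sum_i (C_i xi_i + C_i* xi_i*)` subject to
#' `y_i - f(x_i) <= eps_i + xi_i`, `f(x_i) - y_i <= eps_i* + xi_i*`,
#' `xi, xi* >= 0`, with `y_i` the observed (possibly transduced) time and the
#' per-sample parameters given by [resolve_per_sample()]. The problem is
#' solved in the dual as a quadratic program with box constraints
#' `alpha_i in [0, C_i]`, `alpha_i* in [0, C_i*]` and one equality
#' constraint; the intercept is then recovered by exact one-dimensional
#' minimization of the primal loss in `b`. A tiny diagonal jitter
#' regularizes the positive semidefinite dual Hessian; the relative duality
#' gap of the returned solution is recorded in the diagnostics and a warning
#' is raised if it exceeds `gap_tol`.
#'
#' @param d a [survival_dataset()] with at least 2 records
#' @param params an [svrc_params()]
#' @param standardize center/scale features on the training data (default
#'   `TRUE`; the C/epsilon parameters are scale-sensitive)
#' @param log_time fit on `log(1 + y)` instead of raw times (default `FALSE`)
#' @param jitter relative diagonal jitter for the dual Hessian
#' @param gap_tol warn when the relative duality gap exceeds this
#' @return object of class `svrc_model`: for the linear kernel a weight
#'   vector `w` (per feature, survival-time-oriented) and intercept `b`;
#'   dual coefficients `beta = alpha - alpha*`, support vectors, resolved
#'   params, and solver diagnostics (primal/dual objectives, relative gap)
#' @export
fit_svrc <- function(d, params = svrc_params(), standardize = TRUE,
                     log_time = FALSE, jitter = 1e-10, gap_tol = 1e-6) {
  stopifnot(inherits(d, "survival_dataset"), inherits(params, "svrc_params"))
  n <- n_records(d)
  if (n < 2L) stop("SVRc requires at least 2 records", call. = FALSE)
  scaling <- NULL
  if (standardize) {
    scaling <- feature_scaling(d)
    d <- apply_scaling(scaling, d)
  }
  y <- if (log_time) log1p(d$time) else d$time
  params <- resolve_eps(params, y)
  ps <- resolve_per_sample(params, d$event)
  X <- d$features
  K <- svrc_kernel(params, X)
  jit <- jitter * max(1, mean(diag(K)))
  z <- svrc_solve_dual(K, y, ps, jit)
  alpha <- pmin(pmax(z[1:n], 0), ps$C)
  alpha_star <- pmin(pmax(z[(n + 1):(2 * n)], 0), ps$C_star)
  beta <- alpha - alpha_star
  f0 <- drop(K %*% beta)                   # f(x) - b on training points
  b <- svrc_intercept(f0, y, ps)
  w <- if (params$kernel == "linear") {
    stats::setNames(drop(t(X) %*% beta), d$feature_names)
  } else NULL
  fitted <- f0 + b
  primal <- svrc_primal_objective(beta, K, fitted, y, ps)
  dual <- sum(y * beta) - sum(ps$eps * alpha) - sum(ps$eps_star * alpha_star) -
    0.5 * drop(t(beta) %*% K %*% beta)
  gap <- abs(primal - dual) / max(1, abs(primal))
  if (gap > gap_tol) {
    warning(sprintf("SVRc relative duality gap %.3g exceeds %.1g", gap, gap_tol),
            call. = FALSE)
  }
  sv <- which(abs(beta) > 1e-8 * max(ps$C, ps$C_star))
  structure(
    list(w = w, b = b, beta = beta,
         support = sv, X_train = X, params = params, per_sample = ps,
         feature_names = d$feature_names, scaling = scaling,
         log_time = log_time, fitted = fitted,
         diagnostics = list(primal_objective = primal, dual_objective = dual,
                            relative_gap = gap, n_support = length(sv),
                            jitter = jit)),
    class = "svrc_model"
  )
}

# Solve the SVRc dual QP
#   max q'z - 1/2 z' H z,  H = [[K, -K], [-K, K]] + jit*I,
#   s.t. sum(alpha) = sum(alpha*),  0 <= alpha <= C,  0 <= alpha* <= C*,
# with z = (alpha, alpha*). Primary solver is kernlab's interior-point QP
# (handles the positive-semidefinite H well); if it does not report
# convergence, fall back to quadprog with a heavier diagonal jitter, which
# the active-set method needs for conditioning.
svrc_solve_dual <- function(K, y, ps, jit) {
  n <- length(y)
  H0 <- rbind(cbind(K, -K), cbind(-K, K))
  qvec <- c(y - ps$eps, -y - ps$eps_star)
  upper <- c(ps$C, ps$C_star)
  # true (unjittered) dual objective, used to rank fallback candidates
  dual_value <- function(z) {
    beta <- z[1:n] - z[(n + 1):(2 * n)]
    sum(qvec * z) - 0.5 * drop(t(beta) %*% K %*% beta)
  }
  H <- H0
  diag(H) <- diag(H) + jit
  A <- matrix(c(rep(1, n), rep(-1, n)), 1L)
  ip <- tryCatch(
    kernlab::ipop(-qvec, H, A, 0, rep(0, 2 * n), upper, 0,
                  sigf = 9, maxiter = 200),
    error = function(e) NULL
  )
  if (!is.null(ip) && kernlab::how(ip) == "converged") {
    return(kernlab::primal(ip))
  }
  # interior-point solve failed: fall back to the active-set method, which
  # needs a heavier diagonal jitter for conditioning; escalate the jitter
  # and keep the candidate scoring best on the true dual objective
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), -upper)
  best <- NULL; best_val <- -Inf; errs <- character(0)
  for (jr in c(1e-6, 1e-4, 1e-3)) {
    H <- H0
    diag(H) <- diag(H) + jr * max(1, mean(diag(K)))
    sol <- tryCatch(quadprog::solve.QP(H, qvec, Amat, bvec, meq = 1L),
                    error = function(e) conditionMessage(e))
    if (is.character(sol)) { errs <- c(errs, sol); next }
    val <- dual_value(pmin(pmax(sol$solution, 0), upper))
    if (val > best_val) { best_val <- val; best <- sol$solution }
  }
  if (is.null(best)) {
    stop(sprintf("SVRc dual QP failed: %s", paste(unique(errs), collapse = "; ")),
         call. = FALSE)
  }
  best
}

# Exact minimizer over b of the piecewise-linear primal loss given f0 = f - b.
# Breakpoints where a hinge activates; the loss is convex, so scan them and
# take the midpoint of the flat optimal interval.
svrc_intercept <- function(f0, y, ps) {
  lower_bp <- y - ps$eps - f0        # loss accrues for b < lower_bp
  upper_bp <- y + ps$eps_star - f0   # loss accrues for b > upper_bp
  cand <- sort(unique(c(lower_bp, upper_bp)))
  loss <- function(b) {
    sum(ps$C * pmax(0, lower_bp - b)) + sum(ps$C_star * pmax(0, b - upper_bp))
  }
  vals <- vapply(cand, loss, numeric(1))
  i <- which.min(vals)
  b <- cand[i]
  # flat optimum interval: extend to the neighbour with (numerically) equal loss
  if (i < length(cand) && abs(vals[i + 1] - vals[i]) <= 1e-10 * (1 + abs(vals[i]))) {
    b <- (cand[i] + cand[i + 1]) / 2
  }
  b
}

svrc_primal_objective <- function(beta, K, fitted, y, ps) {
  0.5 * drop(t(beta) %*% K %*% beta) +
    sum(ps$C * pmax(0, y - fitted - ps$eps)) +
    sum(ps$C_star * pmax(0, fitted - y - ps$eps_star))
}

#' Predict survival times from a fitted SVRc model
#'
#' `f(x) = W . phi(x) + b`. SVRc regresses the survival time directly, so
#' predictions are already on the survival-time orientation the metrics
#' expect (no negation needed, unlike the Cox linear predictor).
#'
#' @param object a fitted `svrc_model`
#' @param d a [survival_dataset()] with matching feature dimension
#' @param ... unused
#' @return numeric score vector (predicted times; log scale if the model was
#'   fit with `log_time = TRUE`)
#' @export
predict.svrc_model <- function(object, d, ...) {
  stopifnot(inherits(d, "survival_dataset"))
  if (n_features(d) != ncol(object$X_train)) {
    stop("feature dimension mismatch between model and dataset", call. = FALSE)
  }
  if (!is.null(object$scaling)) d <- apply_scaling(object$scaling, d)
  Kx <- svrc_kernel(object$params, d$features, object$X_train)
  drop(Kx %*% object$beta) + object$b
}

#' @rdname feature_weights
#' @export
feature_weights.svrc_model <- function(model, ...) {
  if (model$params$kernel != "linear") {
    stop("per-feature weights are only defined for the linear kernel", call. = FALSE)
  }
  model$w
}

#' @export
print.svrc_model <- function(x, ...) {
  cat(sprintf("SVRc model (%s kernel, %d support vectors, relative duality gap %.2g)\n",
              x$params$kernel, x$diagnostics$n_support, x$diagnostics$relative_gap))
  if (!is.null(x$w)) print(round(x$w, 4))
  invisible(x)
}
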