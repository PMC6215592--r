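#' Configuration for the two-endpoint disease-progression simulator
#'
#' Generates right-censored cohorts with the structure of a prostatectomy
#' follow-up study: an early, noisier endpoint (biochemical recurrence) with
#' an event rate in the low teens, and a later, rarer clinical endpoint
#' reached only by a subset of the early-endpoint patients — so the late
#' endpoint is nested within the early one by construction, as both endpoints
#' share each patient's censoring time.
#'
#' The early event time is Weibull with shape `weibull_shape` and scale
#' `weibull_scale * exp(-beta' x / weibull_shape)`, which makes the hazard
#' exactly proportional — `h(t) = h0(t) exp(beta' x)` — so a Cox fit on
#' generated data is a clean parameter-recovery check. Censoring is
#' noninformative: `C = min(Uniform(0, c*), study_horizon)` with `c*`
#' calibrated by bisection so the realized event rate lands within
#' `calibration_tol` of `1 - censor_rate_target`. Among true early events,
#' progression to the late endpoint is Bernoulli with probability
#' `plogis(progression_intercept + progression_beta' x)` and the late event
#' time adds an independent Weibull gap.
#'
#' Default values emulate a cohort of ~340 patients with 9 exchangeable
#' standard-normal covariates, an early event rate near 13% and a late event
#' rate near 3.5%.
#'
#' @param n cohort size
#' @param d number of covariates (standard multivariate normal)
#' @param beta length-`d` log-hazard effects for the early endpoint
#' @param weibull_shape,weibull_scale baseline Weibull parameters of the
#'   early event time (time units, e.g. months)
#' @param censor_rate_target fraction of records to be censored, in (0, 1)
#' @param calibration_tol realized event rate must match `1 -
#'   censor_rate_target` within this (absolute) tolerance
#' @param progression_intercept,progression_beta logistic model of the
#'   probability that an early event progresses to the late endpoint
#' @param gap_shape,gap_scale Weibull parameters of the late-minus-early gap
#' @param study_horizon administrative censoring time
#' @param seed integer RNG seed
#' @return object of class `progression_config`
#' @export
progression_config <- function(n = 340, d = 9,
                               beta = c(0.5, -0.4, 0.3, 0.25, -0.2,
                                        rep(0, max(0, d - 5)))[seq_len(d)],
                               weibull_shape = 1.5, weibull_scale = 250,
                               censor_rate_target = 0.87,
                               calibration_tol = 0.02,
                               progression_intercept = 0.3,
                               progression_beta = c(0.6, rep(0, max(0, d - 1)))[seq_len(d)],
                               gap_shape = 1.3, gap_scale = 45,
                               study_horizon = 120, seed = 1L) {
  stopifnot(n >= 2, d >= 1,
            censor_rate_target > 0, censor_rate_target < 1,
            weibull_shape > 0, weibull_scale > 0,
            gap_shape > 0, gap_scale > 0, study_horizon > 0)
  beta <- rep_len(as.numeric(beta), d)
  progression_beta <- rep_len(as.numeric(progression_beta), d)
  structure(
    list(n = as.integer(n), d = as.integer(d), beta = beta,
         weibull_shape = weibull_shape, weibull_scale = weibull_scale,
         censor_rate_target = censor_rate_target,
         calibration_tol = calibration_tol,
         progression_intercept = progression_intercept,
         progression_beta = progression_beta,
         gap_shape = gap_shape, gap_scale = gap_scale,
         study_horizon = study_horizon, seed = as.integer(seed)),
    class = "progression_config"
  )
}

# Bisection on the uniform-censoring upper bound c*. Given fixed draws
# (true times tt, uniform quantiles v), the realized event rate
# mean(tt <= pmin(v * cstar, horizon)) is nondecreasing in c*, so bisection
# is exact up to grid resolution.
calibrate_censoring <- function(tt, v, horizon, target_event_rate, tol) {
  rate_at <- function(cstar) mean(tt <= pmin(v * cstar, horizon))
  hi <- horizon / min(v)             # beyond this, censoring is horizon-only
  max_rate <- rate_at(hi)
  if (max_rate < target_event_rate - tol) {
    stop(sprintf("censoring calibration failed: even with no random censoring the event rate under the study horizon is %.3f < target %.3f",
                 max_rate, target_event_rate), call. = FALSE)
  }
  lo <- 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_event_rate) lo <- mid else hi <- mid
  }
  # hi is (numerically) the smallest scale whose realized rate >= target;
  # with n records the realized rate moves in steps of 1/n, so allow that
  # granularity on top of the requested tolerance
  cstar <- hi
  tol <- tol + 0.5 / length(tt)
  if (abs(rate_at(cstar) - target_event_rate) > tol) {
    stop("censoring calibration did not reach the target event rate", call. = FALSE)
  }
  cstar
}

#' Generate a single-endpoint right-censored cohort
#'
#' Realizes the latent variables the observed data hide: true event times
#' `T`, censoring times `C`, observed `U = min(T, C)` and
#' `delta = 1[T <= C]`. The hidden truth is returned alongside the dataset
#' for oracle tests only; pipeline entry points never read it.
#'
#' @param cfg a [progression_config()]
#' @return list with `data` (a [survival_dataset()]) and `truth` (list of
#'   `true_time`, `censor_time`, `linear_predictor`)
#' @export
generate_single_endpoint <- function(cfg) {
  stopifnot(inherits(cfg, "progression_config"))
  set.seed(cfg$seed)
  sim_early(cfg)$as_result()
}

# Shared early-endpoint machinery; returns closures so the two-endpoint
# generator can continue from the same RNG stream.
sim_early <- function(cfg) {
  X <- matrix(stats::rnorm(cfg$n * cfg$d), cfg$n, cfg$d)
  colnames(X) <- paste0("x", seq_len(cfg$d))
  lp <- drop(X %*% cfg$beta)
  # scale acts through exp(-lp/shape): hazard proportional to exp(lp)
  tt <- stats::rweibull(cfg$n, shape = cfg$weibull_shape,
                        scale = cfg$weibull_scale * exp(-lp / cfg$weibull_shape))
  v <- stats::runif(cfg$n)
  cstar <- calibrate_censoring(tt, v, cfg$study_horizon,
                               target_event_rate = 1 - cfg$censor_rate_target,
                               tol = cfg$calibration_tol)
  cc <- pmin(v * cstar, cfg$study_horizon)
  u <- pmin(tt, cc)
  delta <- as.integer(tt <= cc)
  list(
    X = X, lp = lp, tt = tt, cc = cc, u = u, delta = delta, cstar = cstar,
    as_result = function() {
      list(data = survival_dataset(X, u, delta),
           truth = list(true_time = tt, censor_time = cc,
                        linear_predictor = lp, censor_scale = cstar))
    }
  )
}

#' Generate a nested two-endpoint cohort
#'
#' The early endpoint is generated as in [generate_single_endpoint()]. Each
#' TRUE early event then progresses to the late endpoint with probability
#' `plogis(progression_intercept + progression_beta' x)`; a progressing
#' patient's late event time is the early time plus an independent Weibull
#' gap, and non-progressing patients never reach the late endpoint. Both
#' endpoints are censored by the same follow-up time, so every observed late
#' event is necessarily an observed early event at an earlier or equal time
#' (nesting holds by construction).
#'
#' @param cfg a [progression_config()]
#' @return list with `early` and `late` (both [survival_dataset()]s sharing
#'   features and row order) and `truth` (true/censor times for both
#'   endpoints, the progression indicator, and the linear predictor)
#' @export
generate_two_endpoint <- function(cfg) {
  stopifnot(inherits(cfg, "progression_config"))
  set.seed(cfg$seed)
  e <- sim_early(cfg)
  p_prog <- stats::plogis(cfg$progression_intercept +
                          drop(e$X %*% cfg$progression_beta))
  progresses <- stats::rbinom(cfg$n, 1L, p_prog) == 1L
  gap <- stats::rweibull(cfg$n, shape = cfg$gap_shape, scale = cfg$gap_scale)
  tt_late <- ifelse(progresses, e$tt + gap, Inf)
  u_late <- pmin(tt_late, e$cc)
  delta_late <- as.integer(tt_late <= e$cc)
  early <- survival_dataset(e$X, e$u, e$delta)
  late <- survival_dataset(e$X, u_late, delta_late, require_events = FALSE)
  list(early = early, late = late,
       truth = list(true_time_early = e$tt, true_time_late = tt_late,
                    censor_time = e$cc, progresses = progresses,
                    progression_prob = p_prog,
                    linear_predictor = e$lp, censor_scale = e$cstar))
}
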