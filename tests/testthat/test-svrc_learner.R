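sym_params <- function(C = 2, eps = 0.1) {
  svrc_params(C_n = C, C_n_star = C, C_c = C, C_c_star = C,
              eps_n = eps, eps_n_star = eps, eps_c = eps, eps_c_star = eps)
}

asym_params <- function() {
  svrc_params(C_n = 1, C_n_star = 1, C_c = 1, C_c_star = 0.2,
              eps_n = 0.1, eps_n_star = 0.1, eps_c = 0.1, eps_c_star = 0.5)
}

test_that("per-sample parameters mix by censoring status", {
  p <- svrc_params(C_n = 1, C_n_star = 2, C_c = 3, C_c_star = 0.5,
                   eps_n = 0.1, eps_n_star = 0.2, eps_c = 0.3, eps_c_star = 0.4)
  # event record (delta = 1, s = 0) takes the noncensored parameters
  r_ev <- resolve_per_sample(p, 1)
  expect_equal(c(r_ev$C, r_ev$C_star, r_ev$eps, r_ev$eps_star),
               c(1, 2, 0.1, 0.2))
  # censored record (delta = 0, s = 1) takes the censored parameters
  r_c <- resolve_per_sample(p, 0)
  expect_equal(c(r_c$C, r_c$C_star, r_c$eps, r_c$eps_star),
               c(3, 0.5, 0.3, 0.4))
  # symmetric limit: every record gets the common values
  r <- resolve_per_sample(sym_params(2, 0.1), c(1, 0, 1))
  expect_equal(r$C, rep(2, 3))
  expect_equal(r$C_star, rep(2, 3))
  expect_equal(r$eps, rep(0.1, 3))
  expect_equal(r$eps_star, rep(0.1, 3))
})

test_that("parameter validation flags the non-censoring-aware regime", {
  expect_error(svrc_params(C_n = -1), "positive")
  expect_error(svrc_params(eps_n = -0.5), "nonnegative")
  expect_warning(svrc_params(C_c_star = 2, C_n_star = 1), "C_c_star")
  expect_warning(svrc_params(eps_c_star = 0.05, eps_n_star = 0.2), "eps_c_star")
})

test_that("symmetric limit coincides with reference epsilon-SVR", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (rep in 1:3) {
    n <- 5 + 5 * rep
    X <- matrix(rnorm(n * 2), n, 2)
    y <- drop(X %*% c(1.5, -1)) + rnorm(n, 0, 0.4)
    d <- survival_dataset(X, abs(y) + 1, rep(1, n))
    m <- fit_svrc(d, sym_params(2, 0.1), standardize = FALSE)
    ref <- e1071::svm(X, d$time, type = "eps-regression", kernel = "linear",
                      cost = 2, epsilon = 0.1, scale = FALSE, tolerance = 1e-10)
    w_ref <- unname(drop(t(ref$coefs) %*% ref$SV))
    expect_equal(unname(m$w), w_ref, tolerance = 1e-4)
    expect_equal(m$b, -ref$rho, tolerance = 1e-4)
  }
})

test_that("two points inside one tube are fit by a flat function", {
  d <- survival_dataset(matrix(c(0, 1)), c(5.0, 5.1), c(1, 1))
  m <- fit_svrc(d, sym_params(1, 0.5), standardize = FALSE)
  expect_equal(unname(m$w), 0, tolerance = 1e-6)
  expect_gte(m$b, 5.1 - 0.5 - 1e-8)
  expect_lte(m$b, 5.0 + 0.5 + 1e-8)
  # W = 0: all predictions equal the intercept
  expect_equal(predict(m, d), rep(m$b, 2), tolerance = 1e-6)
})

test_that("asymmetric solutions match a direct primal minimization", {
  set.seed(26)
  for (rep in 1:4) {
    n <- 6 + rep
    X <- matrix(rnorm(n * 2), n, 2)
    y <- drop(X %*% c(1, -0.5)) + 5 + rnorm(n, 0, 0.3)
    ev <- c(rep(0, 2), rep(1, n - 2))
    d <- survival_dataset(X, pmax(y, 0.1), ev)
    p <- asym_params()
    m <- fit_svrc(d, p, standardize = FALSE)
    ps <- resolve_per_sample(p, d$event)
    obj_fit <- svrc_primal_oracle_obj(c(m$w, m$b), X, d$time,
                                      ps$C, ps$C_star, ps$eps, ps$eps_star)
    oracle <- svrc_primal_oracle(X, d$time, ps$C, ps$C_star, ps$eps, ps$eps_star)
    # the QP solution must not be worse than the derivative-free oracle
    expect_lte(obj_fit, oracle$value * (1 + 1e-5) + 1e-8)
    expect_equal(obj_fit, min(obj_fit, oracle$value), tolerance = 1e-5)
  }
})

test_that("a wide censored upper tube zeroes censored over-prediction loss", {
  set.seed(33)
  n <- 6
  X <- matrix(rnorm(n), n, 1)
  ev <- c(0, 0, 1, 1, 1, 1)
  d <- survival_dataset(X, abs(rnorm(n, 5)), ev)
  p <- svrc_params(C_n = 1, C_n_star = 1, C_c = 1, C_c_star = 1,
                   eps_n = 0.1, eps_n_star = 0.1, eps_c = 0.1, eps_c_star = 100)
  m <- fit_svrc(d, p, standardize = FALSE)
  resid_up <- predict(m, d) - d$time
  cens <- d$event == 0
  # censored residuals above the target stay inside the tube: zero loss
  expect_true(all(pmax(0, resid_up[cens] - 100) == 0))
  # and the censored upper-side dual variables are inactive
  alpha_star <- pmax(-m$beta, 0)
  expect_equal(sum(alpha_star[cens]), 0, tolerance = 1e-8)
})

test_that("duality gap of returned solutions is certified small", {
  set.seed(41)
  sim <- generate_single_endpoint(progression_config(
    n = 40, d = 3, seed = 41, censor_rate_target = 0.5, weibull_scale = 70))
  m <- fit_svrc(sim$data, asym_params())
  expect_lt(m$diagnostics$relative_gap, 1e-6)
})

test_that("dual-to-primal weight identity holds", {
  set.seed(52)
  sim <- generate_single_endpoint(progression_config(
    n = 30, d = 3, seed = 52, censor_rate_target = 0.5, weibull_scale = 70))
  m <- fit_svrc(sim$data, asym_params(), standardize = FALSE)
  w_rebuilt <- unname(drop(t(m$X_train) %*% m$beta))
  expect_equal(unname(m$w), w_rebuilt, tolerance = 1e-6)
  expect_length(feature_weights(m), 3)
  # linear kernel: prediction is affine in the features
  d2 <- sim$data
  pred <- predict(m, d2)
  expect_equal(pred, drop(d2$features %*% m$w) + m$b, tolerance = 1e-8)
})

test_that("risk-increasing features get negative survival-oriented weights", {
  sim <- generate_single_endpoint(progression_config(
    n = 200, d = 2, beta = c(0.8, 0), seed = 61,
    censor_rate_target = 0.4, weibull_scale = 80))
  m <- fit_svrc(sim$data)
  # feature 1 raises the hazard, shortening survival: weight < 0
  expect_lt(feature_weights(m)[[1]], 0)
})

test_that("fits are invariant under record reordering", {
  set.seed(72)
  sim <- generate_single_endpoint(progression_config(
    n = 25, d = 2, seed = 72, censor_rate_target = 0.5, weibull_scale = 70))
  d <- sim$data
  m1 <- fit_svrc(d, asym_params(), standardize = FALSE)
  perm <- sample(25)
  d2 <- survival_dataset(d$features[perm, ], d$time[perm], d$event[perm])
  m2 <- fit_svrc(d2, asym_params(), standardize = FALSE)
  expect_equal(m2$w, m1$w, tolerance = 1e-5)
  expect_equal(m2$b, m1$b, tolerance = 1e-5)
})

test_that("widening the censored upper tube releases upper-side support vectors", {
  set.seed(83)
  sim <- generate_single_endpoint(progression_config(
    n = 40, d = 2, seed = 83, censor_rate_target = 0.6, weibull_scale = 60))
  d <- sim$data
  cens <- d$event == 0
  n_upper <- sapply(c(0.01, 0.5, 2, 10), function(ecs) {
    p <- suppressWarnings(
      svrc_params(eps_n = 0.1, eps_n_star = 0.1, eps_c = 0.1, eps_c_star = ecs))
    m <- fit_svrc(d, p, standardize = FALSE)
    sum(pmax(-m$beta, 0)[cens] > 1e-7)
  })
  expect_true(all(diff(n_upper) <= 0))
})

test_that("nonlinear kernels refuse per-feature weights but predict", {
  sim <- generate_single_endpoint(progression_config(
    n = 30, d = 2, seed = 91, censor_rate_target = 0.5, weibull_scale = 70))
  p <- svrc_params(kernel = "rbf", gamma = 0.5,
                   eps_n = 0.1, eps_n_star = 0.1, eps_c = 0.1, eps_c_star = 0.5)
  m <- fit_svrc(sim$data, p)
  expect_error(feature_weights(m), "linear kernel")
  expect_length(predict(m, sim$data), 30)
})
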