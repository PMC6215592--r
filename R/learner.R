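#' Base-learner factories
#'
#' A `survival_learner` is the contract the transduction wrapper and the
#' experiment pipeline train against: an object with a `fit(dataset)` function
#' returning a fitted model for which `predict(model, dataset)` yields
#' survival-time-oriented scores and [feature_weights()] yields a per-feature
#' weight vector. The two built-in learners are the Cox proportional-hazards
#' model and SVRc; any list with a `fit` element and a conforming model class
#' can stand in (e.g. frozen scorers in tests).
#'
#' @param ... arguments forwarded to [fit_cox()] / [fit_svrc()] at fit time
#'   (hyperparameters are fixed when the learner is constructed)
#' @return object of class `survival_learner` with elements `name` and `fit`
#' @export
cox_learner <- function(...) {
  args <- list(...)
  structure(
    list(name = "cox",
         fit = function(d) do.call(fit_cox, c(list(d), args))),
    class = "survival_learner"
  )
}

#' @param params an [svrc_params()] object
#' @rdname cox_learner
#' @export
svrc_learner <- function(params = svrc_params(), ...) {
  args <- list(...)
  structure(
    list(name = "svrc",
         fit = function(d) do.call(fit_svrc, c(list(d, params = params), args))),
    class = "survival_learner"
  )
}

#' Fit a survival learner to a dataset
#'
#' @param learner a `survival_learner`
#' @param d a [survival_dataset()]
#' @return the fitted model
#' @export
fit_learner <- function(learner, d) {
  stopifnot(is.list(learner), is.function(learner$fit))
  learner$fit(d)
}

#' @export
print.survival_learner <- function(x, ...) {
  cat(sprintf("survival learner: %s\n", x$name))
  invisible(x)
}
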