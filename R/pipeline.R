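#' Normalize per-feature weights for cross-model comparison
#'
#' Raw weights from different learners live on incomparable scales; dividing
#' by the dominant weight puts every model on a relative scale where the
#' most influential feature maps to +/-1. The default divides by the maximum
#' ABSOLUTE weight (sign preserved). Two alternatives are provided:
#' `"max"` divides by the largest signed weight, and `reference_feature`
#' divides by the named feature's absolute weight — published weight tables
#' are not always consistent about the denominator, so the convention is
#' explicit here.
#'
#' @param w named numeric weight vector, not all zero
#' @param method `"max_abs"` (default) or `"max"`
#' @param reference_feature optional feature name whose absolute weight is
#'   used as the denominator (overrides `method`)
#' @return normalized weight vector, same names and signs
#' @export
normalize_weights <- function(w, method = c("max_abs", "max"),
                              reference_feature = NULL) {
  method <- match.arg(method)
  nms <- names(w)
  w <- as.numeric(w)
  names(w) <- nms
  if (!length(w) || all(w == 0)) {
    stop("cannot normalize an empty or all-zero weight vector", call. = FALSE)
  }
  denom <- if (!is.null(reference_feature)) {
    if (!reference_feature %in% names(w)) {
      stop(sprintf("reference feature '%s' not found", reference_feature), call. = FALSE)
    }
    abs(w[[reference_feature]])
  } else if (method == "max_abs") {
    max(abs(w))
  } else {
    m <- max(w)
    if (m <= 0) stop("method 'max' requires at least one positive weight", call. = FALSE)
    m
  }
  if (denom == 0) stop("normalization denominator is zero", call. = FALSE)
  w / denom
}

#' Run the early-to-late endpoint experiment
#'
#' Reproduces the standard design end-to-end on user data or simulated
#' cohorts: for each requested variant (learner x with/without transduction),
#' fit on the training set's early endpoint — transducing censored targets
#' first when enabled — freeze the stratification threshold on training
#' scores, then evaluate concordance, sensitivity, specificity and the
#' combined criterion on (i) the training data, (ii) the early-endpoint
#' validation set and (iii) optionally the late-endpoint validation set, all
#' with original observed times. Feature weights, raw and normalized, are
#' collected per variant.
#'
#' @param d_train training [survival_dataset()] (early endpoint)
#' @param d_valid_early early-endpoint validation set (same feature schema)
#' @param d_valid_late optional late-endpoint validation set over the same
#'   validation patients
#' @param learners character subset of `c("cox", "svrc")`
#' @param transduction logical vector of transduction settings to run
#'   (default both off and on)
#' @param time_point evaluation horizon for the classification term
#' @param grid_size transduction grid increments (default 10)
#' @param svrc_params an [svrc_params()] for the SVRc variants
#' @param cox_args list of extra arguments for [fit_cox()]
#' @param weight_method normalization convention, see [normalize_weights()]
#' @param seed integer seed set once at the start of the run
#' @return object of class `experiment_result`: `metrics` (long data frame:
#'   variant x block x metric columns), `weights` (long data frame: variant
#'   x feature with original and normalized weight), `models`, and the echoed
#'   configuration
#' @export
run_experiment <- function(d_train, d_valid_early, d_valid_late = NULL,
                           learners = c("svrc", "cox"),
                           transduction = c(FALSE, TRUE),
                           time_point, grid_size = 10L,
                           svrc_params = transurv::svrc_params(),
                           cox_args = list(),
                           weight_method = "max_abs", seed = 1L) {
  stopifnot(inherits(d_train, "survival_dataset"),
            inherits(d_valid_early, "survival_dataset"))
  learners <- match.arg(learners, c("svrc", "cox"), several.ok = TRUE)
  set.seed(seed)
  variants <- expand.grid(learner = learners, transduced = transduction,
                          stringsAsFactors = FALSE)
  metrics <- list(); weights <- list(); models <- list()
  for (k in seq_len(nrow(variants))) {
    lname <- variants$learner[k]
    trans <- variants$transduced[k]
    vname <- paste0(lname, if (trans) "_transduction" else "")
    learner <- if (lname == "cox") do.call(cox_learner, cox_args)
               else svrc_learner(params = svrc_params)
    if (trans) {
      cfg <- transduction_config(learner, time_point = time_point,
                                 grid_size = grid_size)
      model <- transduce_dataset(d_train, cfg)$model
    } else {
      model <- fit_learner(learner, d_train)
    }
    rep_ <- report_evaluation(model, d_train, d_valid_early, d_valid_late,
                              time_point = time_point)
    rep_$variant <- vname
    metrics[[vname]] <- rep_
    w <- feature_weights(model)
    weights[[vname]] <- data.frame(
      variant = vname, feature = names(w), weight = as.numeric(w),
      normalized_weight = as.numeric(normalize_weights(w, method = weight_method)),
      row.names = NULL)
    models[[vname]] <- model
  }
  structure(
    list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
         weights = do.call(rbind, c(weights, list(make.row.names = FALSE))),
         models = models,
         config = list(learners = learners, transduction = transduction,
                       time_point = time_point, grid_size = grid_size,
                       weight_method = weight_method, seed = seed)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Early-to-late endpoint experiment\n")
  m <- x$metrics
  for (blk in unique(m$block)) {
    cat(sprintf("\n== %s ==\n", blk))
    sub <- m[m$block == blk, c("variant", "ci", "sensitivity", "specificity", "criterion")]
    sub[-1] <- lapply(sub[-1], round, 3)
    print(sub, row.names = FALSE)
  }
  invisible(x)
}

#' Write an experiment result to disk
#'
#' Emits `metrics.csv`, `metrics.json`, `weights.csv` and one serialized
#' model JSON per variant into `dir`.
#'
#' @param result an `experiment_result`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(result$metrics, file.path(dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  for (nm in names(result$models)) {
    write_model_json(result$models[[nm]], file.path(dir, paste0("model_", nm, ".json")))
  }
  invisible(dir)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `cox_model` or `svrc_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "cox_model")) {
    list(type = "cox", feature_names = model$feature_names,
         coefficients = as.list(model$coefficients),
         diagnostics = list(loglik = model$loglik, iterations = model$iterations,
                            grad_norm = model$grad_norm,
                            separation = model$separation))
  } else if (inherits(model, "svrc_model")) {
    list(type = "svrc", feature_names = model$feature_names,
         w = if (is.null(model$w)) NULL else as.list(model$w),
         b = model$b,
         params = model$params[c("C_n", "C_n_star", "C_c", "C_c_star",
                                 "eps_n", "eps_n_star", "eps_c", "eps_c_star",
                                 "kernel", "gamma")],
         diagnostics = model$diagnostics)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
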