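# Gradient-boosted tree regression of glucose on (I660, I940, SpO2), and
# the raw-count -> intensity calibration mapping.
#
# The boosting core (exact greedy squared-error trees, second-order leaf
# weights with L2 regularization lambda = 1, no subsampling) lives in
# src/gbt.cpp; it is deterministic for a given dataset and configuration.

#' Regressor configuration
#'
#' Defaults are the study's printed hyperparameters: learning rate 0.3,
#' maximum depth 6, 100 trees, squared-error objective.
#'
#' @param learning_rate shrinkage applied to each tree.
#' @param max_depth maximum tree depth.
#' @param n_estimators number of boosting rounds.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum samples per leaf.
#' @param seed recorded for provenance (the learner itself is deterministic).
#' @return list of class `gbt_config`.
#' @export
gbt_config <- function(learning_rate = 0.3, max_depth = 6,
                       n_estimators = 100, lambda = 1,
                       min_child_weight = 1, seed = 1) {
  stopifnot(learning_rate > 0, max_depth >= 1, n_estimators >= 1,
            lambda >= 0, min_child_weight >= 1)
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 n_estimators = n_estimators, lambda = lambda,
                 min_child_weight = min_child_weight, seed = seed),
            class = "gbt_config")
}

#' Train/test split specification
#'
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed RNG seed for the shuffle.
#' @param shuffle randomize row order before splitting.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, seed = 1, shuffle = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, seed = seed,
                 shuffle = shuffle), class = "split_spec")
}

gbt_fit <- function(X, y, config) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  booster <- .gbt_fit_cpp(X, y, config$n_estimators, config$learning_rate,
                          config$max_depth, config$lambda,
                          config$min_child_weight)
  structure(list(booster = booster, feature_names = colnames(X),
                 config = config), class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (any(!is.finite(X))) stop("features must be finite")
  as.numeric(.gbt_predict_cpp(object$booster, X))
}

dataset_md5 <- function(dataset) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(dataset, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Train the glucose regressor on a synthetic dataset
#'
#' Fits gradient-boosted trees mapping (intensity_660, intensity_940, spo2)
#' to glucose (mmol/L) on a shuffled train partition and returns the fitted
#' model together with held-out predictions. Reported metrics should always
#' be computed on the held-out pairs.
#'
#' @param dataset a [build_dataset()] result (or any data frame with the
#'   feature columns and `glucose_mmol`).
#' @param config a [gbt_config()].
#' @param split a [split_spec()].
#' @return object of class `glucose_model`: the fitted `model`, `train_idx`
#'   / `test_idx`, `holdout` (data frame of `reference_mmol`,
#'   `predicted_mmol`), and a `provenance` list (configs, seeds, dataset
#'   MD5).
#' @export
train_regressor <- function(dataset, config = gbt_config(),
                            split = split_spec()) {
  feats <- c("intensity_660", "intensity_940", "spo2")
  stopifnot(all(c(feats, "glucose_mmol") %in% names(dataset)))
  n <- nrow(dataset)
  if (n < 10) stop("need at least 10 rows to train")
  y <- dataset$glucose_mmol
  if (stats::var(y) == 0)
    warning("degenerate (constant) glucose target")

  idx <- seq_len(n)
  if (split$shuffle) {
    set.seed(split$seed)
    idx <- sample(idx)
  }
  n_test <- max(1, round(split$test_fraction * n))
  if (n_test >= n) stop("empty training partition")
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])

  X <- as.matrix(dataset[, feats])
  fit <- gbt_fit(X[train_idx, , drop = FALSE], y[train_idx], config)
  pred <- predict(fit, dataset[test_idx, feats, drop = FALSE])
  holdout <- data.frame(spo2 = dataset$spo2[test_idx],
                        reference_mmol = y[test_idx],
                        predicted_mmol = pred)
  structure(list(
    model = fit, train_idx = train_idx, test_idx = test_idx,
    holdout = holdout,
    provenance = list(config = unclass(config), split = unclass(split),
                      n_rows = n, dataset_md5 = dataset_md5(dataset),
                      n_launch = attr(dataset, "n_launch"),
                      optics_mode = attr(dataset, "mode"),
                      master_seed = attr(dataset, "master_seed"))),
    class = "glucose_model")
}

#' @export
predict.glucose_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && length(newdata) == 3)
    newdata <- data.frame(intensity_660 = newdata[1],
                          intensity_940 = newdata[2], spo2 = newdata[3])
  if (any(newdata$spo2 < 0 | newdata$spo2 > 100))
    stop("spo2 must lie in [0, 100]")
  predict(object$model, newdata)
}

#' @export
print.glucose_model <- function(x, ...) {
  cat("Glucose regressor: gradient-boosted trees (",
      x$provenance$config$n_estimators, " trees, depth ",
      x$provenance$config$max_depth, ", lr ",
      x$provenance$config$learning_rate, "), trained on ",
      length(x$train_idx), " rows, held out ", length(x$test_idx), "\n",
      sep = "")
  invisible(x)
}

#' Fit the raw-count to intensity calibration mapping
#'
#' Learns, per channel, a mapping from raw front-end counts into the
#' simulated-intensity domain so raw measurements can be fed to a regressor
#' trained on synthetic intensities. The default is a small boosted-tree
#' regressor per channel; an affine least-squares fallback is available and
#' is exact when the counts were generated by a noise-free affine transform.
#'
#' @param raw data frame with `counts_red` and `counts_ir`.
#' @param reference data frame with `intensity_660` and `intensity_940`
#'   aligned row-by-row with `raw`.
#' @param method `"boosted"` (default) or `"affine"`.
#' @param config a [gbt_config()] for the boosted method (default is a
#'   shallower 3-level booster; counts are univariate).
#' @return object of class `ppg_calibration`.
#' @export
fit_calibration <- function(raw, reference,
                            method = c("boosted", "affine"),
                            config = gbt_config(max_depth = 3)) {
  method <- match.arg(method)
  stopifnot(all(c("counts_red", "counts_ir") %in% names(raw)),
            all(c("intensity_660", "intensity_940") %in% names(reference)))
  if (nrow(raw) != nrow(reference)) stop("raw and reference lengths differ")
  if (nrow(raw) < 10) stop("need at least 10 paired rows")
  fit_channel <- function(x, y) {
    if (method == "affine") {
      co <- stats::coef(stats::lm(y ~ x))
      list(intercept = unname(co[1]), slope = unname(co[2]))
    } else {
      gbt_fit(matrix(x, ncol = 1, dimnames = list(NULL, "counts")), y, config)
    }
  }
  structure(list(
    method = method,
    red = fit_channel(raw$counts_red, reference$intensity_660),
    ir = fit_channel(raw$counts_ir, reference$intensity_940)),
    class = "ppg_calibration")
}

#' Map raw counts into the simulated-intensity domain
#'
#' @param calibration a [fit_calibration()] result.
#' @param raw data frame with `counts_red` and `counts_ir` (and optionally
#'   `spo2`, copied through).
#' @return data frame with `intensity_660`, `intensity_940` (and `spo2`).
#' @export
apply_calibration <- function(calibration, raw) {
  if (!inherits(calibration, "ppg_calibration"))
    stop("apply_calibration needs a fitted ppg_calibration object")
  apply_channel <- function(ch, x) {
    if (calibration$method == "affine") ch$intercept + ch$slope * x
    else predict(ch, data.frame(counts = x))
  }
  out <- data.frame(
    intensity_660 = apply_channel(calibration$red, raw$counts_red),
    intensity_940 = apply_channel(calibration$ir, raw$counts_ir))
  if ("spo2" %in% names(raw)) out$spo2 <- raw$spo2
  out
}
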