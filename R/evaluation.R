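# Clinical-accuracy evaluation: regression metrics, Clarke error-grid
# analysis, Bland-Altman statistics, and glucose unit conversions.
# All clinical metrics are computed on the mg/dL scale.

#' Glucose unit conversions
#'
#' Uses the conventional factor 1 mg/dL = 0.0555 mmol/L (from the molar
#' mass of glucose) in both directions.
#'
#' @param mmol glucose in mmol/L.
#' @param mgdl glucose in mg/dL.
#' @return converted value(s).
#' @examples
#' mgdl_from_mmol(5.55)  # 100 mg/dL
#' @export
mgdl_from_mmol <- function(mmol) mmol / 0.0555

#' @rdname mgdl_from_mmol
#' @export
mmol_from_mgdl <- function(mgdl) mgdl * 0.0555

#' Regression accuracy metrics
#'
#' MSE, MAE, RMSE, coefficient of determination (1 - SSres/SStot) and
#' Pearson correlation between reference and estimated glucose; intended to
#' be computed on the mg/dL scale. A zero-variance reference makes the
#' correlation-type metrics undefined (returned as NA with `undefined =
#' TRUE`).
#'
#' @param reference,estimated equal-length numeric vectors (mg/dL).
#' @return list of class `metrics_report`: `mse`, `mae`, `rmse`,
#'   `r_squared`, `pearson_r`, `n`, `undefined`.
#' @export
compute_metrics <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated))
  n <- length(reference)
  if (n < 2) stop("need at least 2 pairs")
  err <- estimated - reference
  mse <- mean(err^2)
  undefined <- stats::var(reference) == 0
  r2 <- if (undefined) NA_real_ else
    1 - sum(err^2) / sum((reference - mean(reference))^2)
  r <- if (undefined || stats::var(estimated) == 0) NA_real_ else
    stats::cor(reference, estimated)
  structure(list(mse = mse, mae = mean(abs(err)), rmse = sqrt(mse),
                 r_squared = r2, pearson_r = r, n = n,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "MSE %.4g  MAE %.4g  RMSE %.4g  R^2 %.4g  Pearson r %.4g  (n = %d)\n",
    x$mse, x$mae, x$rmse, x$r_squared, x$pearson_r, x$n))
  invisible(x)
}

#' Clarke error-grid zone of (reference, estimated) glucose pairs
#'
#' Classifies each pair (mg/dL) into the standard Clarke zones:
#' A (clinically accurate: within 20% of reference, or both in the
#' hypoglycemic range below 70), E (dangerous confusion of hypo- and
#' hyperglycemia), C (overcorrection), D (failure to detect), B (benign
#' otherwise). Boundary points resolve to the lower-risk zone
#' (A before B before C/D/E).
#'
#' @param reference,estimated glucose, mg/dL; both must be positive.
#' @return character vector of zones in `c("A","B","C","D","E")`.
#' @examples
#' clarke_zone(200, 200)  # "A"
#' clarke_zone(50, 250)   # "E"
#' @export
clarke_zone <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated))
  if (any(reference <= 0 | estimated <= 0))
    stop("glucose values must be positive")
  r <- reference
  e <- estimated
  zone <- rep("B", length(r))
  a <- (r <= 70 & e <= 70) | (e <= 1.2 * r & e >= 0.8 * r)
  ee <- !a & ((r >= 180 & e <= 70) | (r <= 70 & e >= 180))
  cc <- !a & !ee &
    ((r >= 70 & r <= 290 & e > r + 110) |
     (r >= 130 & r <= 180 & e < (7 / 5) * r - 182))
  dd <- !a & !ee & !cc &
    ((r >= 240 & e > 70 & e < 180) |
     (r < 175 / 3 & e < 180 & e > 70) |
     (r >= 175 / 3 & r <= 70 & e > (6 / 5) * r))
  zone[dd] <- "D"; zone[cc] <- "C"; zone[ee] <- "E"; zone[a] <- "A"
  zone
}

#' Clarke error-grid report
#'
#' Aggregates per-pair zones into counts and percentages.
#'
#' @inheritParams clarke_zone
#' @return list of class `ega_report` with `zone_counts`,
#'   `zone_percentages` (named A-E) and `n`.
#' @export
ega_report <- function(reference, estimated) {
  zones <- clarke_zone(reference, estimated)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(zone_counts = counts,
                 zone_percentages = 100 * counts / length(zones),
                 n = length(zones)),
            class = "ega_report")
}

#' @export
print.ega_report <- function(x, ...) {
  cat("Clarke EGA zones (% of", x$n, "pairs):\n")
  print(round(x$zone_percentages, 2))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are estimated minus reference; the limits of agreement are
#' bias +/- 1.96 times the sample (n - 1) standard deviation.
#'
#' @inheritParams clarke_zone
#' @return list of class `ba_report`: `bias`, `sd`, `loa_low`, `loa_high`,
#'   `n` (all on the input scale, conventionally mg/dL).
#' @export
bland_altman <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated))
  if (length(reference) < 2) stop("need at least 2 pairs")
  d <- estimated - reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "ba_report")
}

#' @export
print.ba_report <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g +/- %.3g, LoA [%.3g, %.3g] (n = %d)\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Diagnostic plots: Clarke grid and Bland-Altman
#'
#' Base-graphics renderings of the two standard clinical-agreement plots.
#'
#' @inheritParams clarke_zone
#' @param ... passed to [graphics::plot()].
#' @export
plot_clarke_grid <- function(reference, estimated, ...) {
  zones <- clarke_zone(reference, estimated)
  cols <- c(A = "forestgreen", B = "steelblue", C = "orange",
            D = "darkorange3", E = "red")
  lim <- c(0, max(400, reference, estimated))
  graphics::plot(reference, estimated, col = cols[zones], pch = 16,
                 xlim = lim, ylim = lim,
                 xlab = "Reference glucose (mg/dL)",
                 ylab = "Estimated glucose (mg/dL)", ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(0, 1.2, lty = 2, col = "grey60")
  graphics::abline(0, 0.8, lty = 2, col = "grey60")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(zones)
}

#' @rdname plot_clarke_grid
#' @export
plot_bland_altman <- function(reference, estimated, ...) {
  ba <- bland_altman(reference, estimated)
  m <- (reference + estimated) / 2
  graphics::plot(m, estimated - reference,
                 xlab = "Mean of reference and estimate (mg/dL)",
                 ylab = "Estimate - reference (mg/dL)", pch = 16, ...)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2), col = c("black", "red", "red"))
  invisible(ba)
}
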