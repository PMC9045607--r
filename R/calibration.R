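#' Squared-correlation R-squared
#'
#' The package-wide R-squared convention: the squared Pearson correlation
#' between predicted and actual values (so a correlation of 0.67 corresponds
#' to an R-squared of about 0.45). Note this is sign-blind: predictions
#' perfectly anti-correlated with the truth also score 1.
#'
#' @param predicted,actual numeric vectors of equal length (>= 3 pairs).
#' @return Fraction in `[0, 1]`.
#' @export
r_squared <- function(predicted, actual) {
  ok <- is.finite(predicted) & is.finite(actual)
  predicted <- predicted[ok]; actual <- actual[ok]
  if (length(actual) < 3L) stopf("need at least 3 pairs")
  if (sd(actual) < .Machine$double.eps^0.5)
    stopf("undefined correlation: actual values are constant")
  if (sd(predicted) < .Machine$double.eps^0.5) return(0)
  cor(predicted, actual)^2
}

#' Forward calibration model: composition to bending
#'
#' Ordinary least squares of the per-trial tip-angle change on the acetone
#' fraction, ethanol fraction and (optionally) the trial's initial angle,
#' with intercept. In-sample R-squared follows the squared-correlation
#' convention of [r_squared()].
#'
#' @param trials data.frame with columns `f_acetone`, `f_ethanol`,
#'   `initial_angle`, `delta_theta` (>= 5 rows).
#' @param include_initial_angle include the initial angle as a predictor.
#' @return Object of class `"calibration_model"` with `direction = "forward"`.
#' @export
fit_forward_model <- function(trials, include_initial_angle = TRUE) {
  need <- c("f_acetone", "f_ethanol", "delta_theta",
            if (include_initial_angle) "initial_angle")
  if (!all(need %in% names(trials)))
    stopf("trials table missing columns: %s",
          paste(setdiff(need, names(trials)), collapse = ", "))
  trials <- trials[stats::complete.cases(trials[, need]), , drop = FALSE]
  if (nrow(trials) < 5L) stopf("need at least 5 trials")
  feats <- c("f_acetone", "f_ethanol",
             if (include_initial_angle) "initial_angle")
  fml <- stats::reformulate(feats, response = "delta_theta")
  check_full_rank(trials, feats)
  fit <- lm(fml, data = trials)
  new_calibration_model(
    direction = "forward", feature_names = feats,
    fits = list(delta_theta = fit),
    r2 = c(delta_theta = r_squared(fitted(fit), trials$delta_theta)),
    n_trials = nrow(trials))
}

check_full_rank <- function(data, feats) {
  X <- cbind(1, as.matrix(data[, feats, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- c("(intercept)", feats)[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("collinear design: features %s are linearly dependent",
          paste(dropped, collapse = ", "))
  }
}

#' Inverse calibration model: transient-fit features to composition
#'
#' One ordinary-least-squares model per analyte (acetone and ethanol volume
#' fraction) regressed on the triple-exponential fit parameters of each
#' trial. The full feature set is (a0, a1, a2, a3, lambda1, lambda2, lambda3);
#' the reduced set (a0, lambda1, lambda2, lambda3) keeps only the constant
#' term and the exponents. Both are fitted so the report can state how much
#' predictive power the extra amplitude features add.
#'
#' @param fits data.frame with one row per converged trial fit: columns
#'   `a0..a3`, `lambda1..lambda3`, optionally `converged` (non-converged rows
#'   are dropped).
#' @param targets data.frame with columns `f_acetone`, `f_ethanol`, row-aligned
#'   with `fits`.
#' @param feature_subset `"full"` (default), `"reduced"`, or a character
#'   vector of feature column names.
#' @return Object of class `"calibration_model"` with `direction = "inverse"`,
#'   per-analyte `r2`, and `r2_full_minus_reduced` per analyte.
#' @export
fit_inverse_model <- function(fits, targets,
                              feature_subset = c("full", "reduced")) {
  full <- c("a0", "a1", "a2", "a3", "lambda1", "lambda2", "lambda3")
  reduced <- c("a0", "lambda1", "lambda2", "lambda3")
  feats <- if (is.character(feature_subset) && length(feature_subset) == 1L &&
               feature_subset %in% c("full", "reduced")) {
    if (feature_subset == "full") full else reduced
  } else if (identical(feature_subset, c("full", "reduced"))) {
    full
  } else as.character(feature_subset)

  if (nrow(fits) != nrow(targets))
    stopf("fits (%d rows) and targets (%d rows) must align", nrow(fits),
          nrow(targets))
  keep <- if ("converged" %in% names(fits)) fits$converged else
    rep(TRUE, nrow(fits))
  keep <- keep & stats::complete.cases(fits[, intersect(full, names(fits))])
  fits <- fits[keep, , drop = FALSE]
  targets <- targets[keep, , drop = FALSE]
  if (nrow(fits) < 8L) stopf("need at least 8 converged fits")
  if (nrow(fits) < length(feats) + 2L)
    stopf("under-determined: %d fits for %d features", nrow(fits),
          length(feats))

  d <- cbind(fits[, intersect(full, names(fits)), drop = FALSE], targets)
  one <- function(target, fset) {
    fit <- lm(stats::reformulate(fset, response = target), data = d)
    list(fit = fit, r2 = r_squared(fitted(fit), d[[target]]))
  }
  models <- lapply(c(f_acetone = "f_acetone", f_ethanol = "f_ethanol"),
                   one, fset = feats)
  r2_full <- vapply(c("f_acetone", "f_ethanol"),
                    function(tg) one(tg, full)$r2, numeric(1))
  r2_red <- vapply(c("f_acetone", "f_ethanol"),
                   function(tg) one(tg, reduced)$r2, numeric(1))

  new_calibration_model(
    direction = "inverse", feature_names = feats,
    fits = lapply(models, `[[`, "fit"),
    r2 = vapply(models, `[[`, numeric(1), "r2"),
    n_trials = nrow(fits),
    extra = list(r2_full_minus_reduced = r2_full - r2_red))
}

new_calibration_model <- function(direction, feature_names, fits, r2,
                                  n_trials, extra = list()) {
  structure(c(list(direction = direction, feature_names = feature_names,
                   fits = fits,
                   coefficients = lapply(fits, coef),
                   r2 = r2, n_trials = n_trials), extra),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("%s calibration model (%d trials)\n",
              if (x$direction == "forward") "Forward" else "Inverse",
              x$n_trials))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  for (tg in names(x$r2))
    cat(sprintf("  R^2 (%s): %.3f\n", tg, x$r2[[tg]]))
  if (!is.null(x$r2_full_minus_reduced))
    cat(sprintf("  R^2 gain of full over reduced features: %s\n",
                paste(sprintf("%s %+.3f", names(x$r2_full_minus_reduced),
                              x$r2_full_minus_reduced), collapse = ", ")))
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) object$coefficients

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  out <- lapply(object$fits, predict, newdata = newdata)
  if (length(out) == 1L) out[[1L]] else as.data.frame(out)
}

#' Hysteresis diagnostic on per-trial initial angles
#'
#' The angle a specimen has relaxed to when a new trial starts carries the
#' imprint of its exposure history. This diagnostic reports the series of
#' per-trial initial angles, its linear drift slope (degrees per trial) and
#' its lag-1 autocorrelation: a history-free film shows negligible drift and
#' no autocorrelation, while slow internal states produce both.
#'
#' @param initial_angles numeric vector of per-trial initial tip angles in
#'   temporal order (>= 10 trials), or a data.frame with an `initial_angle`
#'   column.
#' @return List of class `"hysteresis_diagnostic"`: `initial_angles`,
#'   `drift_slope_deg_per_trial`, `lag1_autocorrelation` (NA with
#'   `undefined = TRUE` if the series is constant).
#' @export
hysteresis_diagnostic <- function(initial_angles) {
  if (is.data.frame(initial_angles)) initial_angles <- initial_angles$initial_angle
  y <- as.numeric(initial_angles)
  y <- y[is.finite(y)]
  if (length(y) < 10L) stopf("need at least 10 trials in temporal order")
  trial <- seq_along(y)
  if (sd(y) < .Machine$double.eps^0.5) {
    out <- list(initial_angles = y, drift_slope_deg_per_trial = 0,
                lag1_autocorrelation = NA_real_, undefined = TRUE)
  } else {
    slope <- unname(coef(lm(y ~ trial))[2L])
    r1 <- unname(acf(y, lag.max = 1, plot = FALSE)$acf[2L])
    out <- list(initial_angles = y, drift_slope_deg_per_trial = slope,
                lag1_autocorrelation = r1, undefined = FALSE)
  }
  structure(out, class = "hysteresis_diagnostic")
}

#' @export
print.hysteresis_diagnostic <- function(x, ...) {
  cat(sprintf("Hysteresis diagnostic over %d trials\n",
              length(x$initial_angles)))
  cat(sprintf("  initial-angle drift: %.3f deg/trial\n",
              x$drift_slope_deg_per_trial))
  cat(sprintf("  lag-1 autocorrelation: %s\n",
              if (isTRUE(x$undefined)) "undefined (constant series)"
              else sprintf("%.3f", x$lag1_autocorrelation)))
  invisible(x)
}
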