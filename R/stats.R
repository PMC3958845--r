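#' Per-depth biovolume profile
#'
#' One observation per section: depth into the carrier compartment and
#' the biovolume fraction of a probe-targeted population at that depth.
#'
#' @param probe Probe name.
#' @param depth_um Numeric vector of section depths (>= 0).
#' @param fraction Numeric vector of biovolume fractions in \[0, 1\].
#'
#' @return Object of class `depth_profile` (a data.frame).
#' @export
depth_profile <- function(probe, depth_um, fraction) {
  stopifnot(length(depth_um) == length(fraction),
            all(depth_um >= 0), all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  structure(data.frame(probe = probe, depth_um = depth_um,
                       fraction = fraction, stringsAsFactors = FALSE),
            class = c("depth_profile", "data.frame"))
}

#' Fit a linear depth trend to a biovolume profile
#'
#' Ordinary least squares of biovolume fraction on section depth,
#' optionally restricted to a depth window (e.g. 180-400 um for a
#' population that only establishes below a certain depth). Significance
#' is the two-sided t-test on the slope, equivalent to the F-test for
#' simple regression. For perfectly constant responses R-squared is
#' reported as 0 with an undefined p-value.
#'
#' @param profile A [depth_profile()] (or data.frame with `depth_um` and
#'   `fraction`).
#' @param window Optional depth window `c(z_lo, z_hi)` in um (inclusive).
#' @param alpha Significance level used for the reported
#'   `significant` flag (default 0.01).
#'
#' @return Object of class `depth_trend`: list with `slope` (fraction per
#'   um), `intercept`, `r_squared`, `n`, `p_value`, `alpha`,
#'   `significant`, `window`, `probe`, and the underlying `lm` fit.
#' @export
fit_depth_regression <- function(profile, window = NULL, alpha = 0.01) {
  df <- as.data.frame(profile)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    df <- df[df$depth_um >= window[1] & df$depth_um <= window[2], ,
             drop = FALSE]
  } else {
    window <- c(min(df$depth_um), max(df$depth_um))
  }
  df <- df[!is.na(df$fraction), , drop = FALSE]
  n <- nrow(df)
  if (n < 3L)
    stop(sprintf("only %d observation(s) in depth window [%g, %g] um; need >= 3",
                 n, window[1], window[2]))
  fit <- stats::lm(fraction ~ depth_um, data = df)
  cf <- stats::coef(fit)
  ss_tot <- sum((df$fraction - mean(df$fraction))^2)
  if (ss_tot == 0) {
    r2 <- 0
    p <- NA_real_
  } else {
    # suppress summary.lm's note on noiseless fits; a perfect line is a
    # legitimate input here (synthetic truth)
    sfit <- suppressWarnings(summary(fit))
    r2 <- sfit$r.squared
    p <- sfit$coefficients["depth_um", "Pr(>|t|)"]
  }
  structure(list(slope = unname(cf["depth_um"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = r2, n = n, p_value = p, alpha = alpha,
                 significant = !is.na(p) && p < alpha,
                 window = window,
                 probe = if ("probe" %in% names(df)) df$probe[1] else NA_character_,
                 fit = fit),
            class = "depth_trend")
}

#' @export
print.depth_trend <- function(x, ...) {
  cat(sprintf(
    "<depth_trend>%s window [%g, %g] um\n  slope %.3e per um, R^2 = %.3f, n = %d, p = %.3g (alpha = %g%s)\n",
    if (is.na(x$probe)) "" else paste0(" ", x$probe),
    x$window[1], x$window[2], x$slope, x$r_squared, x$n,
    x$p_value, x$alpha,
    if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' @export
summary.depth_trend <- function(object, ...) summary(object$fit, ...)

#' @export
coef.depth_trend <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.depth_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  if (is.numeric(newdata)) newdata <- data.frame(depth_um = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.depth_trend <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.depth_trend <- function(x, ...) {
  df <- x$fit$model
  graphics::plot(df$depth_um, df$fraction,
                 xlab = "depth (um)", ylab = "biovolume fraction",
                 main = if (is.na(x$probe)) "depth trend" else x$probe, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Trend-recovery experiment on synthetic stacks
#'
#' Parameter-recovery harness: for each seed, generates a synthetic
#' compartment stack with known stratification, measures per-section
#' biovolume fractions, fits the AOB (full range) and anammox (windowed)
#' depth regressions, and summarizes recovered slope signs, significance
#' and R-squared. With `method = "imaging"` the full image pipeline
#' (render, threshold, noise-reduce, segment, artifact-reject, measure)
#' is run; with `method = "sampling"` fractions are drawn from the
#' generator's colony-sampling model without rendering images — the
#' appropriate (and much faster) route for large-replicate calibration of
#' the trend test itself, e.g. null rejection rates.
#'
#' @param config A [synthetic_config()].
#' @param seeds Integer vector of seeds, one stack per seed.
#' @param amx_window Depth window for the anammox regression (um).
#' @param alpha Significance level for both tests.
#' @param method `"imaging"` or `"sampling"` (see above).
#'
#' @return Object of class `trend_recovery`: list with `runs`
#'   (data.frame, one row per seed: slopes, R-squared, p-values,
#'   significance) and a `summary` list (counts of recovered signs,
#'   rejection rates, mean R-squared).
#' @export
trend_recovery_experiment <- function(config, seeds,
                                      amx_window = c(180, 400),
                                      alpha = 0.01,
                                      method = c("imaging", "sampling")) {
  method <- match.arg(method)
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    fr <- if (method == "imaging") {
      stack <- generate_compartment_stack(cfg)
      measure_stack_fractions(stack$sections)
    } else {
      sample_depth_fractions(cfg)
    }
    aob <- fit_depth_regression(
      depth_profile("Nse1472", fr$depth_um, fr$aob), alpha = alpha)
    amx <- fit_depth_regression(
      depth_profile("Bfu613", fr$depth_um, fr$amx),
      window = amx_window, alpha = alpha)
    data.frame(seed = s,
               aob_slope = aob$slope, aob_r2 = aob$r_squared,
               aob_p = aob$p_value, aob_sig = aob$significant,
               amx_slope = amx$slope, amx_r2 = amx$r_squared,
               amx_p = amx$p_value, amx_sig = amx$significant)
  })
  runs <- do.call(rbind, rows)
  summ <- list(
    n_seeds = length(seeds),
    aob_negative = sum(runs$aob_slope < 0),
    aob_negative_significant = sum(runs$aob_slope < 0 & runs$aob_sig),
    amx_positive = sum(runs$amx_slope > 0),
    amx_positive_significant = sum(runs$amx_slope > 0 & runs$amx_sig),
    mean_aob_r2 = mean(runs$aob_r2),
    mean_amx_r2 = mean(runs$amx_r2),
    aob_rejection_rate = mean(runs$aob_sig),
    amx_rejection_rate = mean(runs$amx_sig),
    alpha = alpha)
  structure(list(runs = runs, summary = summ), class = "trend_recovery")
}

#' @export
print.trend_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<trend_recovery> %d seeds, alpha = %g\n", s$n_seeds, s$alpha))
  cat(sprintf("  AOB slope < 0: %d/%d (significant: %d), mean R^2 = %.3f\n",
              s$aob_negative, s$n_seeds, s$aob_negative_significant,
              s$mean_aob_r2))
  cat(sprintf("  anammox slope > 0: %d/%d (significant: %d), mean R^2 = %.3f\n",
              s$amx_positive, s$n_seeds, s$amx_positive_significant,
              s$mean_amx_r2))
  invisible(x)
}
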