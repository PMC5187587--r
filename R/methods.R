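# S3 methods for the fitted-model classes.

#' @export
print.dipshift_fit <- function(x, ...) {
  cat("Dipolar order-parameter fit (DIPSHIFT)\n")
  unc <- if (is.na(x$uncertainty_s_ch)) "" else
    sprintf(" +/- %.3f", as.numeric(x$uncertainty_s_ch))
  cat(sprintf("  S_CH = %.3f%s\n", x$s_ch, unc))
  cat(sprintf("  amplitude = %.4f, baseline = %.4f\n", x$amplitude,
              x$baseline))
  cat(sprintf("  chi2 (SSR) = %.4g over %d points\n", x$chi2, x$n_points))
  invisible(x)
}

#' @export
summary.dipshift_fit <- function(object, ...) {
  res <- object$observed - object$fitted
  out <- list(fit = object,
              residual_sd = stats::sd(res),
              residual_range = range(res),
              flat = isTRUE(attr(object$uncertainty_s_ch, "flat")))
  class(out) <- "summary.dipshift_fit"
  out
}

#' @export
print.summary.dipshift_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.4g, range [%.4g, %.4g]\n",
              x$residual_sd, x$residual_range[1], x$residual_range[2]))
  if (x$flat)
    cat("  NOTE: flat chi-square landscape; uncertainty truncated at the [0, 1] domain\n")
  invisible(x)
}

#' @export
coef.dipshift_fit <- function(object, ...) {
  c(s_ch = object$s_ch, amplitude = object$amplitude,
    baseline = object$baseline)
}

#' @export
fitted.dipshift_fit <- function(object, ...) object$fitted

#' @export
residuals.dipshift_fit <- function(object, ...) object$observed - object$fitted

#' Model curve of a fitted order parameter at new evolution times
#'
#' @param object a [fit_dipshift()] result.
#' @param t1_us evolution times in microseconds (default: the fitted grid).
#' @param ... unused.
#' @return numeric vector of model intensities.
#' @export
predict.dipshift_fit <- function(object, t1_us = object$t1_us, ...) {
  same <- length(t1_us) == length(object$t1_us) &&
    all(abs(t1_us - object$t1_us) < 1e-9)
  shape <- if (same) {
    library_curve_at(object$library, object$s_ch)
  } else {
    curve <- simulate_dipshift(object$s_ch, object$config, t1_us = t1_us)
    curve$intensity
  }
  object$amplitude * shape + object$baseline
}

#' @export
plot.dipshift_fit <- function(x, ...) {
  graphics::plot(x$t1_us, x$observed, pch = 16,
                 xlab = expression(t[1] ~ "(" * mu * "s)"),
                 ylab = "normalized intensity",
                 main = sprintf("DIPSHIFT fit: S[CH] = %.3f", x$s_ch), ...)
  tt <- seq(min(x$t1_us), max(x$t1_us), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate noisy replicates of a fitted dephasing curve
#'
#' Draws `nsim` replicate curves from the fitted model with Gaussian noise at
#' the residual standard deviation.
#'
#' @param object a [fit_dipshift()] result.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with one column per replicate.
#' @export
simulate.dipshift_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  sdv <- stats::sd(object$observed - object$fitted)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), sd = sdv)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.t1_fit <- function(x, ...) {
  cat("Saturation-recovery T1 fit\n")
  se <- if (is.na(x$se_t1)) "" else sprintf(" +/- %.3g", x$se_t1)
  cat(sprintf("  T1 = %.4g s%s, M_eq = %.4g\n", x$t1_seconds, se, x$m_eq))
  cat(sprintf("  chi2 (SSR) = %.4g over %d points\n", x$chi2, x$n_points))
  invisible(x)
}

#' @export
summary.t1_fit <- function(object, ...) {
  res <- object$data$intensity - object$fitted
  cat("Saturation-recovery T1 fit\n")
  cat(sprintf("  T1 = %.5g s (se %.3g), M_eq = %.5g (se %.3g)\n",
              object$t1_seconds, object$se_t1, object$m_eq, object$se_m_eq))
  cat(sprintf("  residual sd = %.4g over %d points\n",
              stats::sd(res), object$n_points))
  invisible(object)
}

#' @export
coef.t1_fit <- function(object, ...) {
  c(t1_seconds = object$t1_seconds, m_eq = object$m_eq)
}

#' @export
fitted.t1_fit <- function(object, ...) object$fitted

#' @export
residuals.t1_fit <- function(object, ...) object$data$intensity - object$fitted

#' Recovery model at new delays
#'
#' @param object a [fit_t1()] result.
#' @param delay_s delays in seconds.
#' @param ... unused.
#' @return predicted intensities \eqn{M_{eq}(1 - e^{-t/T_1})}.
#' @export
predict.t1_fit <- function(object, delay_s = object$data$delay_s, ...) {
  object$m_eq * (1 - exp(-delay_s / object$t1_seconds))
}

#' @export
plot.t1_fit <- function(x, ...) {
  graphics::plot(x$data$delay_s, x$data$intensity, pch = 16,
                 xlab = "recovery delay (s)", ylab = "intensity",
                 main = sprintf("T1 = %.3g s", x$t1_seconds), ...)
  tt <- seq(0, max(x$data$delay_s), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}
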