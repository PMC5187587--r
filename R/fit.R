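# Order-parameter extraction. Fitting works against a precomputed library of
# simulated curves on an S_CH grid (step 0.005 by default): the phase is
# linear in S_CH, so a single unit-coupling phase matrix yields the whole
# family cheaply, and the grid search plus local refinement is deterministic.

.library_cache <- new.env(parent = emptyenv())

library_key <- function(config, geometry, powder, t1_us, sch_grid) {
  paste(
    format(c(config$spinning_freq_khz, config$kappa,
             vapply(geometry$ch_vectors, function(v) v$r, numeric(1))),
           digits = 15),
    n_protons(geometry), nrow(powder),
    format(sum(powder$beta) + 2 * sum(powder$gamma), digits = 15),
    format(range(t1_us), digits = 15), length(t1_us), length(sch_grid),
    collapse = "|")
}

#' Precomputed DIPSHIFT curve library over an S_CH grid
#'
#' Simulates the CH dephasing-curve family on a regular order-parameter grid
#' once and caches it; [fit_dipshift()] interpolates in this library instead
#' of re-simulating inside the optimizer.
#'
#' @inheritParams simulate_dipshift
#' @param sch_grid order-parameter grid (default 0 to 1, step 0.005).
#' @param d optional coupling (rad/s) overriding the geometry value, e.g. an
#'   effective CH2 coupling.
#' @return list with `sch_grid`, `t1_us` and matrix `curves`
#'   (length(sch_grid) x length(t1_us)).
#' @export
dipshift_curve_library <- function(config = experiment_config(),
                                   geometry = spin_geometry_ch(config$r_ch),
                                   powder = NULL,
                                   t1_us = config$t1_grid_us,
                                   sch_grid = seq(0, 1, by = 0.005),
                                   d = NULL) {
  if (is.null(powder)) powder <- default_powder(config)
  validate_powder(powder)
  if (is.null(d)) d <- dipolar_coupling_constant(geometry$ch_vectors[[1L]]$r)
  key <- paste(library_key(config, geometry, powder, t1_us, sch_grid),
               format(d, digits = 15))
  hit <- .library_cache[[key]]
  if (!is.null(hit)) return(hit)
  phi1 <- phase_matrix(config$kappa * d, powder$beta, powder$gamma,
                       config$spinning_freq_khz, t1_us)
  curves <- matrix(NA_real_, length(sch_grid), length(t1_us))
  w <- powder$weight
  for (k in seq_along(sch_grid))
    curves[k, ] <- as.vector(crossprod(w, cos(sch_grid[k] * phi1)))
  if (!is.null(config$t2_damping_us))
    curves <- sweep(curves, 2L, exp(-t1_us / config$t2_damping_us), `*`)
  lib <- list(sch_grid = sch_grid, t1_us = t1_us, curves = curves)
  .library_cache[[key]] <- lib
  lib
}

# model curve at arbitrary s by linear interpolation between library rows
library_curve_at <- function(lib, s) {
  g <- lib$sch_grid
  s <- max(g[1L], min(g[length(g)], s))
  k <- findInterval(s, g, all.inside = TRUE)
  w <- (s - g[k]) / (g[k + 1L] - g[k])
  (1 - w) * lib$curves[k, ] + w * lib$curves[k + 1L, ]
}

# best amplitude (and optional baseline) for a model shape m against data y;
# returns c(ssr, amplitude, baseline)
ols_amp <- function(y, m, baseline) {
  if (!baseline) {
    mm <- sum(m * m)
    a <- if (mm > 0) sum(m * y) / mm else 0
    c(sum((y - a * m)^2), a, 0)
  } else {
    n <- length(y)
    sm <- sum(m); smm <- sum(m * m); sy <- sum(y); smy <- sum(m * y)
    det <- smm * n - sm * sm
    if (abs(det) < 1e-12 * max(smm * n, 1)) {
      a <- 0; b <- sy / n
    } else {
      a <- (smy * n - sm * sy) / det
      b <- (smm * sy - sm * smy) / det
    }
    c(sum((y - a * m - b)^2), a, b)
  }
}

#' Fit the dipolar order parameter from a DIPSHIFT dephasing curve
#'
#' Least-squares fit of the simulated curve family to a measured (or
#' synthetic) dephasing curve. Free parameters are the order parameter S_CH
#' and an overall amplitude; an optional flat baseline absorbs overlapping
#' signal from species whose coupling has been averaged away (e.g. mobile
#' components under a rigid peak). The S_CH axis is searched exhaustively on
#' the library grid and refined locally, so the fit is deterministic.
#'
#' @param curve a [dephasing_curve()] (or data frame with `t1_us`,
#'   `intensity`) with at least 5 points within one rotor period.
#' @param config an [experiment_config()].
#' @param geometry CH [spin_geometry()] used to simulate the model family.
#' @param powder optional powder scheme (defaults from `config`).
#' @param baseline logical; float a flat baseline (default `FALSE`).
#' @param sch_grid order-parameter grid for the curve library.
#' @param d optional coupling override in rad/s (e.g. CH2 effective coupling).
#' @param uncertainty logical; run [estimate_uncertainty()] on the result
#'   (default `TRUE`).
#' @param chi2_threshold relative chi-square increase defining the
#'   uncertainty interval (default 0.15).
#' @return object of class `dipshift_fit` with fields `s_ch`, `amplitude`,
#'   `baseline`, `uncertainty_s_ch`, `chi2` (sum of squared residuals),
#'   `n_points`, `fitted`, and the inputs.
#' @examples
#' cfg <- experiment_config(n_powder = 512)
#' fit <- fit_dipshift(simulate_dipshift(0.8, cfg), cfg, uncertainty = FALSE)
#' coef(fit)
#' @export
fit_dipshift <- function(curve, config = experiment_config(),
                         geometry = spin_geometry_ch(config$r_ch),
                         powder = NULL, baseline = FALSE,
                         sch_grid = seq(0, 1, by = 0.005), d = NULL,
                         uncertainty = TRUE, chi2_threshold = 0.15) {
  if (!is.data.frame(curve) || !all(c("t1_us", "intensity") %in% names(curve)))
    stop("curve must have columns t1_us and intensity", call. = FALSE)
  keep <- curve$t1_us >= 0 & curve$t1_us <= config$tau_r_us * (1 + 1e-9)
  if (sum(keep) < 5L)
    stop("curve must contain at least 5 points within [0, tau_r]",
         call. = FALSE)
  t1 <- curve$t1_us[keep]
  y <- curve$intensity[keep]
  if (is.null(powder)) powder <- default_powder(config)
  lib <- dipshift_curve_library(config, geometry, powder, t1, sch_grid, d)

  if (stats::var(y) < .Machine$double.eps) {
    warning("flat zero-variance curve: no dephasing information; returning s_ch = 0")
    fitted <- rep(mean(y), length(y))
    out <- new_dipshift_fit(0, mean(y), 0, NA_real_, sum((y - fitted)^2),
                            length(y), t1, y, fitted, lib, baseline, config)
    return(out)
  }

  prof <- vapply(seq_along(lib$sch_grid),
                 function(k) ols_amp(y, lib$curves[k, ], baseline),
                 numeric(3))
  k0 <- which.min(prof[1L, ])
  lo <- lib$sch_grid[max(1L, k0 - 1L)]
  hi <- lib$sch_grid[min(length(lib$sch_grid), k0 + 1L)]
  objective <- function(s) ols_amp(y, library_curve_at(lib, s), baseline)[1L]
  opt <- if (hi > lo) stats::optimize(objective, c(lo, hi), tol = 1e-6)
         else list(minimum = lib$sch_grid[k0], objective = prof[1L, k0])
  s_hat <- opt$minimum
  pars <- ols_amp(y, library_curve_at(lib, s_hat), baseline)
  fitted <- pars[2L] * library_curve_at(lib, s_hat) + pars[3L]
  out <- new_dipshift_fit(s_hat, pars[2L], pars[3L], NA_real_, pars[1L],
                          length(y), t1, y, fitted, lib, baseline, config)
  if (uncertainty)
    out$uncertainty_s_ch <- estimate_uncertainty(out, threshold = chi2_threshold)
  out
}

new_dipshift_fit <- function(s_ch, amplitude, baseline_val, unc, chi2, n,
                             t1, y, fitted, lib, baseline_free, config) {
  structure(list(s_ch = s_ch, amplitude = amplitude, baseline = baseline_val,
                 uncertainty_s_ch = unc, chi2 = chi2, n_points = n,
                 t1_us = t1, observed = y, fitted = fitted,
                 library = lib, baseline_free = baseline_free,
                 config = config, call = sys.call(-1L)),
            class = "dipshift_fit")
}

#' Uncertainty of a fitted order parameter by chi-square scan
#'
#' Operationalizes "maximum parameter change before a clear deviation of the
#' simulated from the observed curve": scans S_CH away from the optimum,
#' refits the remaining free parameters at each fixed S_CH, and reports the
#' largest offset whose chi-square stays within `(1 + threshold)` times the
#' minimum. If the chi-square landscape is flat out to both domain bounds the
#' result is flagged (attribute `flat`) and truncated at the \[0, 1\] domain.
#'
#' @param fit a [fit_dipshift()] result.
#' @param threshold relative chi-square increase treated as a clear deviation
#'   (default 0.15).
#' @param step scan step in S_CH (default 0.001).
#' @return largest acceptable |delta S_CH| (one number).
#' @export
estimate_uncertainty <- function(fit, threshold = 0.15, step = 0.001) {
  stopifnot(inherits(fit, "dipshift_fit"))
  lib <- fit$library
  y <- fit$observed
  chi2_min <- max(fit$chi2, .Machine$double.eps * length(y))
  cutoff <- chi2_min * (1 + threshold)
  chi2_at <- function(s) ols_amp(y, library_curve_at(lib, s),
                                 fit$baseline_free)[1L]
  scan <- function(dir) {
    delta <- 0
    repeat {
      s_try <- fit$s_ch + dir * (delta + step)
      if (s_try < 0 || s_try > 1) return(list(delta = delta, open = TRUE))
      if (chi2_at(s_try) > cutoff) return(list(delta = delta, open = FALSE))
      delta <- delta + step
    }
  }
  up <- scan(+1)
  down <- scan(-1)
  out <- max(up$delta, down$delta)
  if (up$open && down$open) {
    out <- max(1 - fit$s_ch, fit$s_ch)
    attr(out, "flat") <- TRUE
  }
  out
}

#' Saturation-recovery curve container
#'
#' @param delays_s recovery delays in seconds (non-negative, strictly
#'   increasing after sorting; stored sorted).
#' @param intensity measured intensities (arbitrary units).
#' @return data frame of class `recovery_curve` with columns `delay_s`,
#'   `intensity`.
#' @export
recovery_curve <- function(delays_s, intensity) {
  if (length(delays_s) != length(intensity))
    stop("delays and intensities must have equal length", call. = FALSE)
  if (any(delays_s < 0))
    stop("range error: recovery delays must be non-negative", call. = FALSE)
  o <- order(delays_s)
  delays_s <- delays_s[o]; intensity <- intensity[o]
  if (any(diff(delays_s) <= 0))
    stop("recovery delays must be distinct", call. = FALSE)
  out <- data.frame(delay_s = as.numeric(delays_s),
                    intensity = as.numeric(intensity))
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Fit T1 from a saturation-recovery series
#'
#' Least-squares fit of the single-exponential recovery
#' \eqn{M(t) = M_{eq}\,(1 - e^{-t/T_1})} using Levenberg--Marquardt.
#'
#' @param curve a [recovery_curve()], or a data frame with columns `delay_s`
#'   and `intensity`.
#' @return object of class `t1_fit` with fields `t1_seconds`, `m_eq`, `chi2`
#'   (sum of squared residuals), standard errors, `fitted` and the data.
#' @examples
#' d <- seq(0.1, 20, length.out = 12)
#' fit_t1(recovery_curve(d, 1 - exp(-d / 2)))
#' @export
fit_t1 <- function(curve) {
  if (!is.data.frame(curve) || !all(c("delay_s", "intensity") %in% names(curve)))
    stop("curve must have columns delay_s and intensity", call. = FALSE)
  curve <- recovery_curve(curve$delay_s, curve$intensity)
  t <- curve$delay_s; y <- curve$intensity
  if (length(unique(t)) < 3L)
    stop("at least 3 distinct delays are required", call. = FALSE)
  m0 <- max(y)
  if (m0 <= 0) stop("non-convergence: recovery intensities are not positive",
                    call. = FALSE)
  # crude T1 start from log-linearized tail
  frac <- 1 - y / (1.05 * m0)
  ok <- frac > 1e-6 & t > 0
  t1_0 <- if (sum(ok) >= 2L) {
    sl <- unname(stats::coef(stats::lm(log(frac[ok]) ~ t[ok]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 3
  } else max(t) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ m_eq * (1 - exp(-t / t1)),
                      start = list(m_eq = m0, t1 = t1_0),
                      lower = c(m_eq = 0, t1 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "non-convergence: T1 fit failed (%s); residual range of raw data [%.3g, %.3g]",
        conditionMessage(e), min(y), max(y)), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(m_eq = NA_real_, t1 = NA_real_))
  res <- y - stats::fitted(fit)
  structure(list(t1_seconds = unname(cf["t1"]), m_eq = unname(cf["m_eq"]),
                 se_t1 = unname(se["t1"]), se_m_eq = unname(se["m_eq"]),
                 chi2 = sum(res^2), n_points = length(y),
                 fitted = as.numeric(stats::fitted(fit)), data = curve,
                 call = sys.call()),
            class = "t1_fit")
}
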