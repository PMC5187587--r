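#' DIPSHIFT experiment configuration
#'
#' Holds the acquisition parameters of the dipolar-dephasing simulation: MAS
#' spinning frequency, the homonuclear-decoupling scale factor kappa applied
#' to heteronuclear couplings (frequency-switched Lee--Goldburg gives the
#' theoretical 1/sqrt(3) ~ 0.577), the t1 sampling over one rotor period, the
#' powder scheme size, and the default C--H geometry.
#'
#' @param spinning_freq_khz MAS frequency nu_r in kHz (> 0); default 7.813.
#' @param kappa heteronuclear coupling scale in (0, 1]; default 1/sqrt(3).
#' @param n_t1_points number of evenly spaced t1 samples on \[0, tau_r\]
#'   (>= 2); default 33.
#' @param n_powder number of powder orientations; default 4096.
#' @param powder_method powder scheme (see [make_powder_scheme()]).
#' @param r_ch default C--H distance in Angstrom.
#' @param hch_angle default H--C--H angle in degrees for CH2 systems.
#' @param t2_damping_us optional T2' (microseconds) for a multiplicative
#'   exp(-t1/T2') damping of simulated curves; `NULL` (default) disables it.
#' @return object of class `experiment_config`; field `t1_grid_us` holds the
#'   t1 samples in microseconds and `tau_r_us` the rotor period 1/nu_r.
#' @examples
#' cfg <- experiment_config()
#' cfg$tau_r_us # 127.99 us at 7.813 kHz
#' @export
experiment_config <- function(spinning_freq_khz = 7.813,
                              kappa = 1 / sqrt(3),
                              n_t1_points = 33L,
                              n_powder = 4096L,
                              powder_method = "golden-spiral",
                              r_ch = 1.09,
                              hch_angle = 109.47,
                              t2_damping_us = NULL) {
  bad <- character()
  if (!is.numeric(spinning_freq_khz) || length(spinning_freq_khz) != 1L ||
      !is.finite(spinning_freq_khz) || spinning_freq_khz <= 0)
    bad <- c(bad, "spinning_freq_khz")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0 || kappa > 1)
    bad <- c(bad, "kappa")
  if (!is.numeric(n_t1_points) || length(n_t1_points) != 1L || n_t1_points < 2)
    bad <- c(bad, "n_t1_points")
  if (!is.numeric(n_powder) || length(n_powder) != 1L || n_powder < 1)
    bad <- c(bad, "n_powder")
  if (!is.numeric(r_ch) || length(r_ch) != 1L || r_ch <= 0)
    bad <- c(bad, "r_ch")
  if (!is.numeric(hch_angle) || length(hch_angle) != 1L ||
      hch_angle <= 0 || hch_angle >= 180)
    bad <- c(bad, "hch_angle")
  if (!is.null(t2_damping_us) &&
      (!is.numeric(t2_damping_us) || length(t2_damping_us) != 1L ||
       t2_damping_us <= 0))
    bad <- c(bad, "t2_damping_us")
  if (length(bad))
    stop("configuration error: out-of-range values for ",
         paste(bad, collapse = ", "), call. = FALSE)
  tau_r <- rotor_period_us(spinning_freq_khz)
  structure(list(
    spinning_freq_khz = spinning_freq_khz,
    kappa = kappa,
    n_t1_points = as.integer(n_t1_points),
    n_powder = as.integer(n_powder),
    powder_method = powder_method,
    r_ch = r_ch,
    hch_angle = hch_angle,
    t2_damping_us = t2_damping_us,
    tau_r_us = tau_r,
    t1_grid_us = seq(0, tau_r, length.out = as.integer(n_t1_points))
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  nu_r = %.3f kHz (tau_r = %.2f us), kappa = %.4f\n",
              x$spinning_freq_khz, x$tau_r_us, x$kappa))
  cat(sprintf("  t1 grid: %d points on [0, tau_r]; powder: %s, n = %d\n",
              x$n_t1_points, x$powder_method, x$n_powder))
  cat(sprintf("  geometry defaults: r_CH = %.3f A, H-C-H = %.2f deg\n",
              x$r_ch, x$hch_angle))
  if (!is.null(x$t2_damping_us))
    cat(sprintf("  T2' damping: %.1f us\n", x$t2_damping_us))
  invisible(x)
}

default_powder <- function(config) {
  make_powder_scheme(config$n_powder, config$powder_method)
}
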