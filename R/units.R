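# Physical constants (CODATA 2018) and unit conventions.
# External units: distances in Angstrom, times in microseconds (dephasing) or
# seconds (relaxation), spinning frequencies in kHz. Internal couplings are
# rad/s; all conversions are centralized here.

GAMMA_1H  <- 2.6752218744e8  # 1H gyromagnetic ratio, rad s^-1 T^-1
GAMMA_13C <- 6.728284e7      # 13C gyromagnetic ratio, rad s^-1 T^-1
HBAR      <- 1.054571817e-34 # reduced Planck constant, J s
MU0_4PI   <- 1e-7            # mu0 / 4pi, T m A^-1

#' Rigid-limit heteronuclear dipolar coupling constant
#'
#' Magnitude of the dipolar coupling constant
#' \eqn{d = (\mu_0/4\pi)\,\gamma_I \gamma_S \hbar / r^3} for a spin pair at
#' internuclear distance `r`. For a directly bonded C--H pair at 1.09 Angstrom
#' this is about \eqn{2\pi \times 23.3} kHz.
#'
#' @param r_angstrom internuclear distance in Angstrom (> 0).
#' @param gamma_i,gamma_s gyromagnetic ratios in rad s^-1 T^-1; defaults are
#'   1H and 13C.
#' @return coupling constant in rad/s (magnitude). Scales as \eqn{r^{-3}}.
#' @examples
#' dipolar_coupling_constant(1.09) / (2 * pi * 1e3) # ~23.3 kHz
#' @export
dipolar_coupling_constant <- function(r_angstrom, gamma_i = GAMMA_1H,
                                      gamma_s = GAMMA_13C) {
  if (!is.numeric(r_angstrom) || any(!is.finite(r_angstrom)) ||
      any(r_angstrom <= 0)) {
    stop("invalid geometry: internuclear distance must be positive and finite",
         call. = FALSE)
  }
  r_m <- r_angstrom * 1e-10
  MU0_4PI * abs(gamma_i * gamma_s) * HBAR / r_m^3
}

# rotor period in microseconds for a spinning frequency in kHz
rotor_period_us <- function(nu_r_khz) 1e3 / nu_r_khz

# rotor angular frequency in rad per microsecond
omega_r_rad_per_us <- function(nu_r_khz) 2 * pi * nu_r_khz * 1e-3

# rad/s -> rad/us
radps_to_rad_per_us <- function(x) x * 1e-6
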