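# Independent numerical oracles, deliberately separate from the package's
# closed-form / product-formula code paths.

# Adaptive quadrature of the instantaneous MAS-modulated dipolar frequency;
# checks the closed-form phase integral.
quadrature_phase <- function(d_eff, beta, gamma, nu_r_khz, t1_us) {
  wr <- 2 * pi * nu_r_khz * 1e-3
  d_us <- d_eff * 1e-6
  om <- function(t) {
    (d_us / 2) * (sin(beta)^2 * cos(2 * (wr * t + gamma)) -
                    sqrt(2) * sin(2 * beta) * cos(wr * t + gamma))
  }
  stats::integrate(om, 0, t1_us, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Density-matrix propagation of the 3-spin (C, Ha, Hb) secular Hamiltonian
# H(t) = omega_a(t) 2 IzC IzHa + omega_b(t) 2 IzC IzHb on a fine time grid
# (piecewise-constant midpoint rule), observing <Cx>. Checks the two-proton
# product formula.
propagator_ch2_signal <- function(d_eff_a, d_eff_b, angles_a, angles_b,
                                  nu_r_khz, t1_us, nsteps = 16384) {
  Iz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  Ix <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  I2 <- diag(2)
  kron3 <- function(a, b, c) kronecker(kronecker(a, b), c)
  Cx <- kron3(Ix, I2, I2)
  ha <- 2 * diag(kron3(Iz, Iz, I2))
  hb <- 2 * diag(kron3(Iz, I2, Iz))
  wr <- 2 * pi * nu_r_khz * 1e-3
  om <- function(d_us, beta, gamma, t) {
    (d_us / 2) * (sin(beta)^2 * cos(2 * (wr * t + gamma)) -
                    sqrt(2) * sin(2 * beta) * cos(wr * t + gamma))
  }
  ts <- seq(0, t1_us, length.out = nsteps + 1)
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  dt <- diff(ts)
  phi_a <- sum(om(d_eff_a * 1e-6, angles_a[1], angles_a[2], mid) * dt)
  phi_b <- sum(om(d_eff_b * 1e-6, angles_b[1], angles_b[2], mid) * dt)
  U <- diag(exp(-1i * (ha * phi_a + hb * phi_b)))
  rho <- U %*% Cx %*% Conj(t(U))
  Re(sum(diag(rho %*% Cx))) / Re(sum(diag(Cx %*% Cx)))
}

# small configs for fast tests
fast_config <- function(...) experiment_config(n_powder = 512, ...)
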