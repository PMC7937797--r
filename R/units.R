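#' @noRd
.kB <- 1.380649e-23  # Boltzmann constant, J/K (CODATA)

.check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop(sprintf("configuration error: '%s' must be a single positive number",
                 field), call. = FALSE)
  }
  invisible(value)
}

#' Physical unit system
#'
#' Defines the reference scales used to map between physical and
#' dimensionless quantities: a reference length `L0` (nm), a reference
#' diffusivity `D0` (um^2/s), and the temperature `T` (K). Derived
#' quantities follow: thermal energy `kBT` (J), reference time
#' `t0 = L0^2/D0` (s), reference force `f0 = kBT/L0` (N) and the friction
#' coefficient `gamma = kBT/D0` (kg/s, Einstein relation).
#'
#' Defaults are the scales of membrane-protein transport: `L0 = 10` nm
#' (transporter length), `D0 = 1e-2` um^2/s (substrate diffusivity inside
#' a crowded channel), `T = 300` K.
#'
#' @param L0 reference length in nm.
#' @param D0 reference diffusivity in um^2/s.
#' @param T temperature in K.
#' @return An object of class `unit_system` with fields `L0`, `D0`, `T`,
#'   `kBT`, `gamma`, `t0`, `f0` (`kBT`, `gamma`, `t0`, `f0` in SI units).
#' @examples
#' u <- unit_system()
#' u$t0               # 0.01 s: diffusion time across 10 nm
#' u$gamma * u$D0_SI  # equals kBT (Einstein relation)
#' @export
unit_system <- function(L0 = 10, D0 = 1e-2, T = 300) {
  .check_positive(L0, "L0")
  .check_positive(D0, "D0")
  .check_positive(T, "T")
  L0_SI <- L0 * 1e-9        # m
  D0_SI <- D0 * 1e-12       # m^2/s
  kBT <- .kB * T
  us <- list(
    L0 = L0, D0 = D0, T = T,
    L0_SI = L0_SI, D0_SI = D0_SI,
    kBT = kBT,
    gamma = kBT / D0_SI,
    t0 = L0_SI^2 / D0_SI,
    f0 = kBT / L0_SI
  )
  class(us) <- "unit_system"
  us
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  L0  = %g nm,  D0 = %g um^2/s,  T = %g K\n", x$L0, x$D0, x$T))
  cat(sprintf("  kBT = %.4g J,  t0 = %.4g s,  f0 = %.4g N,  gamma = %.4g kg/s\n",
              x$kBT, x$t0, x$f0, x$gamma))
  invisible(x)
}

#' Simulation configuration
#'
#' Builds and validates the full configuration of a translocation run.
#' Geometry and physics are given in physical units (nm, um^2/s, K,
#' 1/s); the chemical force `f_mu` is already dimensionless (force in
#' units of `kBT/L`, signed: positive pushes toward the exit). The
#' protocol and integrator settings are dimensionless.
#'
#' Default geometry: `h_min = 0.05 L`, `h_max = 0.55 L` (aspect ratio 11
#' with a cone cross-section `A = pi h^2`), a deliberate calibration that
#' puts the entropic force at the narrowest cross-section at maximal
#' opening at exactly 20 kBT/L — an order of magnitude above a typical
#' chemical-gradient force, the regime in which conformational breathing,
#' not the concentration gradient, drives transport.
#'
#' @param L channel length, nm.
#' @param h_max,h_min maximal/minimal channel radius, nm.
#' @param omega oscillation angular frequency, 1/s.
#' @param D substrate diffusivity, um^2/s.
#' @param T temperature, K.
#' @param f_mu dimensionless chemical-gradient force (units of kBT/L),
#'   signed; typically in `[0.1, 1]`.
#' @param area_exponent 2 for a cone (`A = pi h^2`), 1 for a slit
#'   (`A = 2 h`).
#' @param n_particles ensemble size.
#' @param max_time trajectory cutoff in diffusion times `L^2/D`.
#' @param boundary_mode `"reflecting-entrance"` (default; the exit at
#'   `x = L` is absorbing, re-entry is impossible) or `"absorbing-both"`.
#' @param dt_tilde integrator timestep in diffusion times.
#' @param m_tilde dimensionless particle mass; the velocity relaxation
#'   time is `m_tilde` diffusion times. The default `1e-5` keeps the
#'   velocity-persistence length `sqrt(m_tilde)` (the inertial boundary
#'   layer at the absorbing exit, which biases passage times as
#'   `sqrt(m_tilde)`) far below every geometric scale, so the dynamics is
#'   numerically overdamped while the Boltzmann-velocity protocol is
#'   retained.
#' @param backend `"gjf"` (Gronbech-Jensen--Farago) or `"em"` (overdamped
#'   Euler--Maruyama cross-check).
#' @param phase0 fixed oscillation phase in radians, or `NULL` (default)
#'   to draw each trajectory's phase uniformly on `[0, 2pi)`.
#' @param entrance_offset initial position as a fraction of `L`.
#' @param seed master RNG seed (integer).
#' @return A validated object of class `run_config`.
#' @examples
#' cfg <- run_config(omega = 3000, n_particles = 200)
#' to_dimensionless(cfg)$Omega  # 30
#' @export
run_config <- function(L = 10, h_max = 5.5, h_min = 0.5, omega = 3000,
                       D = 1e-2, T = 300, f_mu = 0.5, area_exponent = 2,
                       n_particles = 2000, max_time = 1000,
                       boundary_mode = c("reflecting-entrance",
                                         "absorbing-both"),
                       dt_tilde = 1e-4, m_tilde = 1e-5,
                       backend = c("gjf", "em"),
                       phase0 = NULL, entrance_offset = 1e-3, seed = 1L) {
  boundary_mode <- match.arg(boundary_mode)
  backend <- match.arg(backend)
  for (f in c("L", "h_max", "h_min", "D", "T", "max_time", "dt_tilde",
              "m_tilde", "entrance_offset")) {
    .check_positive(get(f), f)
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("configuration error: 'omega' must be a single number >= 0",
         call. = FALSE)
  if (!is.numeric(f_mu) || length(f_mu) != 1L || !is.finite(f_mu))
    stop("configuration error: 'f_mu' must be a single finite number",
         call. = FALSE)
  if (!area_exponent %in% c(1L, 2L))
    stop("configuration error: 'area_exponent' must be 1 or 2",
         call. = FALSE)
  if (n_particles < 1)
    stop("configuration error: 'n_particles' must be >= 1", call. = FALSE)
  if (h_min >= h_max)
    stop("configuration error: 'h_min' must be smaller than 'h_max'",
         call. = FALSE)
  if (h_max >= L)
    stop("configuration error: 'h_max' must be smaller than 'L'",
         call. = FALSE)
  if (!is.null(phase0) && (!is.numeric(phase0) || length(phase0) != 1L))
    stop("configuration error: 'phase0' must be NULL or one number",
         call. = FALSE)
  cfg <- list(L = L, h_max = h_max, h_min = h_min, omega = omega, D = D,
              T = T, f_mu = f_mu, area_exponent = as.integer(area_exponent),
              n_particles = as.integer(n_particles), max_time = max_time,
              boundary_mode = boundary_mode, dt_tilde = dt_tilde,
              m_tilde = m_tilde, backend = backend, phase0 = phase0,
              entrance_offset = entrance_offset, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  dl <- to_dimensionless(x)
  cat("<run_config>\n")
  cat(sprintf("  geometry : L = %g nm, h in [%g, %g] nm (aspect %.3g, A ~ h^%d)\n",
              x$L, x$h_min, x$h_max, dl$aspect, x$area_exponent))
  cat(sprintf("  physics  : omega = %g /s, D = %g um^2/s, T = %g K, f_mu = %g\n",
              x$omega, x$D, x$T, x$f_mu))
  cat(sprintf("  derived  : Omega = omega L^2/D = %.4g\n", dl$Omega))
  cat(sprintf("  protocol : n = %d, max_time = %g, %s, %s backend\n",
              x$n_particles, x$max_time, x$boundary_mode, x$backend))
  cat(sprintf("  numerics : dt = %g, m = %g, seed = %d\n",
              x$dt_tilde, x$m_tilde, x$seed))
  invisible(x)
}

#' Dimensionless groups of a configuration
#'
#' Reduces a physical configuration to the dimensionless parameters that
#' fully determine the dynamics: `Omega = omega L^2 / D` (ratio of the
#' diffusion time to the conformational-cycle time), the chemical force
#' `f_mu`, the aspect ratio `h_max/h_min`, the relative constriction
#' `h_min/L`, and the integrator settings. Two physical systems sharing
#' these groups have identical (dimensionless) transport rates.
#'
#' @param config a [run_config()].
#' @param units a [unit_system()] (only used for consistency of scales;
#'   the groups themselves depend on `config` alone).
#' @return An object of class `dimensionless_params`.
#' @export
to_dimensionless <- function(config, units = unit_system(T = config$T)) {
  stopifnot(inherits(config, "run_config"))
  L_SI <- config$L * 1e-9
  D_SI <- config$D * 1e-12
  dl <- list(
    Omega = config$omega * L_SI^2 / D_SI,
    f_mu = config$f_mu,
    aspect = config$h_max / config$h_min,
    h_min_rel = config$h_min / config$L,
    h_max_rel = config$h_max / config$L,
    area_exponent = config$area_exponent,
    m_tilde = config$m_tilde,
    dt_tilde = config$dt_tilde
  )
  class(dl) <- "dimensionless_params"
  dl
}

#' Convert a dimensionless rate to a physical turnover rate
#'
#' A dimensionless rate `Gamma_tilde` (events per diffusion time
#' `L^2/D`) maps to the physical rate `Gamma_tilde * D / L^2` in 1/s.
#' With transporter scales (`L = 10` nm, `D = 1e-2` um^2/s) one
#' dimensionless rate unit is 100/s; with ion-channel diffusivities
#' (`D = 1e3`--`1e4` um^2/s) it is `1e7`--`1e8`/s.
#'
#' @param gamma_dimless dimensionless transport rate(s).
#' @param D diffusivity in um^2/s.
#' @param L channel length in nm.
#' @param units optional [unit_system()] supplying defaults for `D`, `L`.
#' @return Physical rate(s) in 1/s.
#' @examples
#' to_physical_rate(1, D = 1e-2, L = 10)  # 100 /s
#' @export
to_physical_rate <- function(gamma_dimless, D = units$D0, L = units$L0,
                             units = unit_system()) {
  .check_positive(D, "D")
  .check_positive(L, "L")
  stopifnot(is.numeric(gamma_dimless))
  gamma_dimless * (D * 1e-12) / (L * 1e-9)^2
}
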