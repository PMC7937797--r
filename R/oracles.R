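# Independent validation oracles. None of these touch the integrator:
# the static-channel mean first-passage time comes from exact
# first-passage quadrature on the Fick-Jacobs effective potential, the
# free-diffusion diagnostics test the Einstein relation and
# equipartition, and the barrier bookkeeping is closed-form.

#' Effective potential of a frozen channel conformation
#'
#' Freezing the oscillation at a phase turns the problem into 1-D
#' diffusion in the Fick--Jacobs effective potential
#' `U(x) = -kBT ln A(x) - F_mu x`. At the mid phase (`sin = 0`) the
#' entropic part is flat; at `|sin| = 1` it spans
#' `area_exponent * kBT * ln(h_max/h_min)`.
#'
#' @param geom a [channel_geometry()].
#' @param f_mu dimensionless chemical force.
#' @param phase frozen phase in radians (the geometry is evaluated at
#'   `sin(phase)`).
#' @param kBT thermal energy.
#' @return An object of class `static_potential`: a list with the frozen
#'   `phase` and a vectorized function `U(x)`.
#' @export
static_potential <- function(geom, f_mu = 0, phase = 0, kBT = 1) {
  stopifnot(inherits(geom, "channel_geometry"))
  frozen <- channel_geometry(L = geom$L, h_max = geom$h_max,
                             h_min = geom$h_min, omega = 0,
                             area_exponent = geom$area_exponent,
                             phase0 = phase)
  U <- function(x) {
    -kBT * log(channel_area(frozen, x, 0)) - f_mu * kBT / geom$L * x
  }
  sp <- list(U = U, phase = phase, L = geom$L, kBT = kBT)
  class(sp) <- "static_potential"
  sp
}

#' Mean first-passage time by exact quadrature
#'
#' For overdamped diffusion in a potential `U(x)` on `[0, L]` with a
#' reflecting boundary at 0 and an absorbing boundary at `L`, the mean
#' first-passage time from `x0` is
#' \deqn{\langle\tau\rangle = \frac{1}{D}\int_{x_0}^{L} e^{U(y)/k_BT}
#'   \int_0^y e^{-U(z)/k_BT}\,dz\,dy,}
#' evaluated here by nested adaptive quadrature. Because the simulated
#' dynamics *is* this 1-D model, the quadrature is exact for the static
#' channel (up to the integrator's `dt` and the small mass), not an
#' approximation — which makes it a genuine cross-check.
#'
#' @param potential a [static_potential()] (or any list with fields `U`,
#'   `L`, `kBT`).
#' @param D diffusion coefficient.
#' @param x0 starting position.
#' @param rel_tol quadrature relative tolerance.
#' @return The mean first-passage time.
#' @examples
#' flat <- list(U = function(x) 0 * x, L = 1, kBT = 1)
#' mfpt_quadrature(flat)  # 1/2 = L^2/(2D)
#' @export
mfpt_quadrature <- function(potential, D = 1, x0 = 0, rel_tol = 1e-8) {
  U <- potential$U
  L <- potential$L
  kBT <- potential$kBT
  if (!all(is.finite(U(seq(0, L, length.out = 64)))))
    stop("oracle error: potential is not finite on [0, L]", call. = FALSE)
  inner <- function(y) {
    vapply(y, function(yy) {
      integrate(function(z) exp(-U(z) / kBT), 0, yy,
                rel.tol = rel_tol, abs.tol = 0)$value
    }, numeric(1))
  }
  outer_ig <- function(y) exp(U(y) / kBT) * inner(y)
  integrate(outer_ig, x0, L, rel.tol = rel_tol, abs.tol = 0)$value / D
}

#' Entropic barrier of a frozen conformation
#'
#' Range of the entropic part of the effective potential at a frozen
#' phase: `max U_ent - min U_ent`. Zero for a cylinder or at the mid
#' phase; `area_exponent * kBT * ln(h_max/h_min)` at maximal opening.
#'
#' @param geom a [channel_geometry()].
#' @param phase frozen phase in radians.
#' @param kBT thermal energy.
#' @return Barrier height (energy units of `kBT`).
#' @export
entropic_barrier <- function(geom, phase = pi / 2, kBT = 1) {
  stopifnot(inherits(geom, "channel_geometry"))
  # h is monotone in x at fixed phase, so the extremes sit at the ends
  s <- abs(sin(phase))
  h_lo <- (geom$h_max + geom$h_min) / 2 - s * (geom$h_max - geom$h_min) / 2
  h_hi <- (geom$h_max + geom$h_min) / 2 + s * (geom$h_max - geom$h_min) / 2
  geom$area_exponent * kBT * log(h_hi / h_lo)
}

#' Free-particle integrator diagnostics
#'
#' Runs the GJF kernel with forces and boundaries disabled and checks the
#' two exact stationary properties of the thermostat: the ensemble MSD
#' grows as `2 D t` (Einstein relation, `D = kBT/gamma`) and the velocity
#' variance equals `kBT/m` (equipartition).
#'
#' @param n ensemble size.
#' @param n_steps steps per particle.
#' @param m_tilde,dt_tilde mass and timestep (dimensionless).
#' @param gamma,kBT friction and thermal energy.
#' @param seed RNG seed.
#' @param msd_tol,v2_tol relative tolerances for the pass/fail flags.
#' @return A list: `msd_slope`, `msd_expected` (`2 kBT/gamma`),
#'   `msd_rel_err`, `v2`, `v2_expected` (`kBT/m`), `v2_rel_err`,
#'   `pass_msd`, `pass_v2`, `pass`.
#' @export
free_diffusion_diagnostics <- function(n = 20000, n_steps = 2000,
                                       m_tilde = 1e-3, dt_tilde = 1e-4,
                                       gamma = 1, kBT = 1, seed = 1,
                                       msd_tol = 0.03, v2_tol = 0.02) {
  set.seed(seed)
  res <- cpp_free_ensemble(as.integer(n), as.integer(n_steps),
                           stride = max(1L, as.integer(n_steps / 20)),
                           mass = m_tilde, gamma = gamma, kBT = kBT,
                           dt = dt_tilde)
  # discard the ballistic transient (t < 10 m/gamma) before fitting
  keep <- res$t > 10 * m_tilde / gamma
  fit <- lm(msd ~ t, data = data.frame(t = res$t[keep], msd = res$msd[keep]))
  slope <- unname(coef(fit)["t"])
  v2 <- mean(res$v2[keep])
  out <- list(
    msd_slope = slope, msd_expected = 2 * kBT / gamma,
    msd_rel_err = abs(slope - 2 * kBT / gamma) / (2 * kBT / gamma),
    v2 = v2, v2_expected = kBT / m_tilde,
    v2_rel_err = abs(v2 - kBT / m_tilde) / (kBT / m_tilde)
  )
  out$pass_msd <- out$msd_rel_err < msd_tol
  out$pass_v2 <- out$v2_rel_err < v2_tol
  out$pass <- out$pass_msd && out$pass_v2
  out
}

#' Run the full oracle validation suite
#'
#' Cross-validates the simulator against every reference with a known
#' answer: free-diffusion MSD and equipartition, Boltzmann sampling in a
#' static harmonic well (chi-square test), the flat-channel mean
#' first-passage time `L^2/(2D)`, and the static-cone quadrature at
#' several frozen phases and chemical forces.
#'
#' @param seed master seed.
#' @param n_mc trajectories per Monte-Carlo check.
#' @param phases frozen phases for the static-cone checks.
#' @param f_mu_values chemical forces for the static-cone checks.
#' @param config base [run_config()] (geometry and integrator settings).
#' @return A data.frame with one row per check: `check`, `observed`,
#'   `expected`, `tolerance`, `pass`.
#' @export
validate_simulator <- function(seed = 1, n_mc = 2000,
                               phases = c(0, pi / 4, pi / 2),
                               f_mu_values = c(0, 0.5, 1),
                               config = run_config(seed = seed)) {
  rows <- list()
  add <- function(check, observed, expected, tol, pass) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, observed = observed, expected = expected,
      tolerance = tol, pass = pass)
  }

  fd <- free_diffusion_diagnostics(seed = seed)
  add("free diffusion: MSD slope = 2D", fd$msd_slope, fd$msd_expected,
      "3% relative", fd$pass_msd)
  add("free diffusion: <v^2> = kBT/m", fd$v2, fd$v2_expected,
      "2% relative", fd$pass_v2)

  set.seed(seed)
  xs <- cpp_harmonic_track(n_samples = 20000L, stride = 500L,
                           burn_in = 10000L, k = 100, mass = config$m_tilde,
                           gamma = 1, kBT = 1, dt = config$dt_tilde)
  sigma <- sqrt(1 / 100)
  br <- qnorm(seq(0.1, 0.9, by = 0.1), sd = sigma)  # 10 equiprobable bins
  obs <- table(cut(xs, c(-Inf, br, Inf)))
  pch <- suppressWarnings(chisq.test(as.numeric(obs),
                                     p = rep(0.1, 10))$p.value)
  add("harmonic well: Boltzmann sampling (chi-square p)", pch, NA_real_,
      "p > 0.01", pch > 0.01)

  # flat channel (cylinder limit: mid phase), f_mu = 0
  cfg0 <- config
  cfg0$f_mu <- 0
  cfg0$phase0 <- 0
  cfg0$n_particles <- as.integer(n_mc)
  recs <- simulate_ensemble(cfg0, Omega = 0)
  ok <- recs$exit_side == "exit"
  mt <- mean(recs$tau[ok])
  se <- sd(recs$tau[ok]) / sqrt(sum(ok))
  add("flat channel: <tau> = L^2/(2D)", mt, 0.5, "3 standard errors",
      abs(mt - 0.5) < 3 * se)

  # static cone at frozen phases vs first-passage quadrature
  geom <- as_channel_geometry(config)
  for (ph in phases) {
    for (fm in f_mu_values) {
      cfg <- config
      cfg$f_mu <- fm
      cfg$phase0 <- ph
      cfg$n_particles <- as.integer(n_mc)
      recs <- simulate_ensemble(cfg, Omega = 0)
      ok <- recs$exit_side == "exit"
      mt <- mean(recs$tau[ok])
      se <- sd(recs$tau[ok]) / sqrt(sum(ok))
      ref <- mfpt_quadrature(static_potential(geom, f_mu = fm, phase = ph),
                             D = 1, x0 = cfg$entrance_offset)
      add(sprintf("static cone: phase %.3g, f_mu %.2g", ph, fm),
          mt, ref, "3 standard errors", abs(mt - ref) < 3 * se)
    }
  }
  do.call(rbind, rows)
}
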