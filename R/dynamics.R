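# Trajectory-level dynamics: Boltzmann initial conditions, the
# Gronbech-Jensen--Farago (GJF) step, boundary handling, and the ensemble
# driver around the compiled kernel. Everything here is dimensionless:
# L = 1, kBT = 1, gamma = 1 (so D = 1 and time is measured in L^2/D).

# Deterministic per-trajectory seed from (master seed, sweep cell, index).
# Order-independent and independent of f_mu, so sweeps over f_mu share
# noise streams (common random numbers). All arithmetic stays exact in
# doubles (< 2^53) and the result is a valid 32-bit seed.
.traj_seed <- function(master, cell, j) {
  s <- ((master %% 2147483647) * 1000003 + cell * 10007 + j) %% 2147483646
  as.integer(s + 1)
}

#' Draw the initial state of a substrate particle
#'
#' The particle starts just inside the entrance (`x = entrance_offset`,
#' default `1e-3 L`, off the reflecting wall), with a velocity drawn from
#' the one-dimensional Maxwell--Boltzmann law (variance `kBT/m`) and — for
#' an oscillating channel without a pinned phase — an oscillation phase
#' drawn uniformly on `[0, 2pi)`, realizing the ensemble average over
#' initial states.
#'
#' @param config a [run_config()].
#' @return An object of class `particle_state`: fields `x`, `v`, `t`,
#'   `phase0`.
#' @export
draw_initial_state <- function(config) {
  stopifnot(inherits(config, "run_config"))
  phase0 <- if (is.null(config$phase0)) runif(1, 0, 2 * pi) else config$phase0
  v <- rnorm(1) * sqrt(1 / config$m_tilde)  # kBT = 1
  st <- list(x = config$entrance_offset, v = v, t = 0, phase0 = phase0,
             x_prev = NA_real_)
  class(st) <- "particle_state"
  st
}

#' One Gronbech-Jensen--Farago integration step
#'
#' Advances `m dv/dt = -gamma v + F(x,t) + F_r` by one timestep of the
#' GJF stochastic Velocity-Verlet discretization. The thermal impulse
#' `beta` per step is Gaussian with zero mean and variance
#' `2 gamma kBT dt`; the scheme reproduces the exact configurational
#' Boltzmann statistics and the exact Einstein diffusion of the
#' continuous equation at any stable timestep. This pure-R step is the
#' reference the compiled kernel is tested against; ensembles run through
#' [simulate_ensemble()].
#'
#' @param state a `particle_state` (from [draw_initial_state()]).
#' @param dt timestep.
#' @param field a [force_field()].
#' @param m particle mass.
#' @param gamma friction coefficient.
#' @param noise optional fixed thermal impulse (for reproducing a known
#'   noise stream); drawn from the current RNG when `NULL`.
#' @return The advanced `particle_state` (boundaries not yet applied;
#'   `x_prev` holds the pre-step position).
#' @export
gjf_step <- function(state, dt, field, m, gamma = 1, noise = NULL) {
  stopifnot(inherits(state, "particle_state"), dt > 0)
  kBT <- field$kBT
  beta <- if (is.null(noise)) sqrt(2 * gamma * kBT * dt) * rnorm(1) else noise
  cc <- gamma * dt / (2 * m)
  b <- 1 / (1 + cc)
  a <- (1 - cc) / (1 + cc)
  # forces see the particle's own oscillation phase on top of the geometry's
  f <- .field_force(field, state$x, state$t, state$phase0)
  xn <- state$x + b * dt * state$v + b * dt^2 / (2 * m) * f +
    b * dt / (2 * m) * beta
  fn <- .field_force(field, xn, state$t + dt, state$phase0)
  vn <- a * state$v + dt / (2 * m) * (a * f + fn) + b / m * beta
  if (!is.finite(xn) || !is.finite(vn))
    stop(sprintf("integration error: non-finite state (x=%g, v=%g, t=%g)",
                 xn, vn, state$t + dt), call. = FALSE)
  st <- state
  st$x_prev <- state$x
  st$t_prev <- state$t
  st$x <- xn
  st$v <- vn
  st$t <- state$t + dt
  st
}

# Force at (x, t) with a per-particle phase offset added to the geometry's.
.field_force <- function(field, x, t, phase0) {
  g <- field$geom
  s <- sin(g$omega * t + g$phase0 + phase0)
  h <- (g$h_max - g$h_min) * (x / g$L - 0.5) * s + (g$h_max + g$h_min) / 2
  dh <- (g$h_max - g$h_min) * s / g$L
  field$kBT * (g$area_exponent * dh / h + field$f_mu / g$L)
}

#' Apply channel boundaries after one step
#'
#' The exit at `x = L` is always absorbing (a substrate that has left
#' into the far medium cannot re-enter); the entrance at `x = 0` is
#' either reflecting (`x -> -x`, `v -> -v`; the default, so every
#' trajectory eventually translocates) or absorbing. Crossing times are
#' interpolated linearly within the final step.
#'
#' @param state a `particle_state` just advanced by [gjf_step()] (its
#'   `x_prev` must be set).
#' @param config a [run_config()] (only `boundary_mode` is used).
#' @param L channel length (1 in internal units).
#' @return Either the (possibly reflected) `particle_state`, or a
#'   `boundary_event` list with fields `exit_side` (`"exit"` or
#'   `"entrance"`) and `tau`.
#' @export
apply_boundaries <- function(state, config, L = 1) {
  stopifnot(inherits(state, "particle_state"))
  x <- state$x
  if (x >= 0 && x < L) return(state)
  if (x >= L) {
    tau <- state$t
    if (!is.na(state$x_prev) && !is.null(state$t_prev)) {
      dt <- state$t - state$t_prev
      frac <- (L - state$x_prev) / (x - state$x_prev)
      tau <- state$t_prev + frac * dt
    }
    ev <- list(exit_side = "exit", tau = tau)
    class(ev) <- "boundary_event"
    return(ev)
  }
  # x < 0
  if (config$boundary_mode == "absorbing-both") {
    ev <- list(exit_side = "entrance", tau = state$t)
    class(ev) <- "boundary_event"
    return(ev)
  }
  st <- state
  st$x <- -x
  st$v <- -state$v
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one translocation trajectory
#'
#' Runs the full protocol for a single substrate: draw the initial state,
#' integrate the Langevin equation through the breathing channel, stop at
#' the first boundary event or at `max_time`. Uses the compiled GJF
#' kernel (or the overdamped Euler--Maruyama backend if configured).
#'
#' @param config a [run_config()].
#' @param Omega optional dimensionless frequency overriding the one
#'   implied by `config$omega`.
#' @param seed optional integer seed applied before the trajectory.
#' @param record_stride if `> 0`, keep every `record_stride`-th `(t, x)`
#'   sample of the path (debugging aid).
#' @return An object of class `translocation_record`: `tau`, `success`,
#'   `exit_side` (`"exit"`, `"entrance"` or `"timeout"`), `n_steps`,
#'   `phase0`, `mean_path_velocity` (net displacement over `tau`), and
#'   optionally `path` (data.frame `t`, `x`).
#' @export
simulate_translocation <- function(config, Omega = NULL, seed = NULL,
                                   record_stride = 0) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) set.seed(seed)
  dl <- to_dimensionless(config)
  if (is.null(Omega)) Omega <- dl$Omega
  res <- cpp_translocate(
    hmax = dl$h_max_rel, hmin = dl$h_min_rel, L = 1, omega = Omega,
    aexp = config$area_exponent, fmu = config$f_mu, mass = config$m_tilde,
    gamma = 1, kBT = 1, dt = config$dt_tilde, max_time = config$max_time,
    x0 = config$entrance_offset,
    draw_phase = is.null(config$phase0),
    phase0 = config$phase0 %||% 0,
    boundary = if (config$boundary_mode == "absorbing-both") 1L else 0L,
    backend = if (config$backend == "em") 1L else 0L,
    record_stride = as.integer(record_stride))
  exit_side <- c("entrance", "exit")[res$exit_side + 1]
  if (res$exit_side < 0) exit_side <- "timeout"
  success <- identical(exit_side, "exit")
  mpv <- if (exit_side == "timeout") NA_real_ else {
    end_x <- if (success) 1 else 0
    (end_x - config$entrance_offset) / res$tau
  }
  rec <- list(tau = res$tau, success = success, exit_side = exit_side,
              n_steps = res$n_steps, phase0 = res$phase0,
              mean_path_velocity = mpv)
  if (record_stride > 0)
    rec$path <- data.frame(t = res$path_t, x = res$path_x)
  class(rec) <- "translocation_record"
  rec
}

#' Simulate an ensemble of translocation trajectories
#'
#' Repeats [simulate_translocation()] for `config$n_particles` substrates,
#' each on its own reproducible RNG stream derived from the master seed
#' by a counter scheme (so results are independent of execution order and
#' identical across `f_mu` values for variance reduction in sweeps).
#'
#' @inheritParams simulate_translocation
#' @param cell_index integer tag of the sweep cell, mixed into the
#'   per-trajectory seeds so grid cells use distinct streams.
#' @return A data.frame with one row per trajectory: `tau`, `success`,
#'   `exit_side`, `n_steps`, `phase0`, `mean_path_velocity`.
#' @examples
#' cfg <- run_config(n_particles = 50, omega = 3000, seed = 7)
#' recs <- simulate_ensemble(cfg)
#' mean(1 / recs$tau[recs$success])  # dimensionless transport rate
#' @export
simulate_ensemble <- function(config, Omega = NULL, cell_index = 0) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_particles
  tau <- phase0 <- mpv <- numeric(n)
  steps <- numeric(n)
  side <- character(n)
  for (j in seq_len(n)) {
    rec <- simulate_translocation(
      config, Omega = Omega,
      seed = .traj_seed(config$seed, cell_index, j))
    tau[j] <- rec$tau
    side[j] <- rec$exit_side
    steps[j] <- rec$n_steps
    phase0[j] <- rec$phase0
    mpv[j] <- rec$mean_path_velocity
  }
  out <- data.frame(tau = tau, success = side == "exit", exit_side = side,
                    n_steps = steps, phase0 = phase0,
                    mean_path_velocity = mpv)
  timeouts <- mean(side == "timeout")
  if (timeouts > 0.001)
    warning(sprintf(
      "%.2f%% of trajectories hit max_time = %g; rate estimates exclude them",
      100 * timeouts, config$max_time), call. = FALSE)
  out
}
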