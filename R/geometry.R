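#' Oscillating conical channel
#'
#' The channel radius breathes linearly in `x` about a fixed midpoint:
#' \deqn{h(x,t) = (h_{max}-h_{min})\,(x/L - 1/2)\,\sin(\omega t + \phi_0)
#'   + (h_{max}+h_{min})/2.}
#' At phase `sin = +1` the entrance (`x = 0`) is at its narrowest
#' (`h_min`) and the exit at its widest (`h_max`); half a period later
#' the cone is mirrored. The cross-sectional area is `A = pi h^2`
#' (`area_exponent = 2`, a cone) or `A = 2 h` (`area_exponent = 1`, a
#' slit).
#'
#' Arguments are dimensionless by default (`L = 1`); the same object
#' serves at physical scales if all lengths share a unit.
#'
#' @param L channel length.
#' @param h_max,h_min maximal/minimal radius, `0 < h_min < h_max < L`.
#' @param omega angular frequency of the breathing (per unit time of
#'   whatever time unit `t` is in; dimensionless `Omega` internally).
#' @param area_exponent 1 or 2 (see above).
#' @param phase0 phase offset in radians.
#' @return An object of class `channel_geometry`.
#' @examples
#' geom <- channel_geometry(omega = 30)
#' channel_radius(geom, x = 0, t = pi / 60)    # h_min at maximal opening
#' @export
channel_geometry <- function(L = 1, h_max = 0.55 * L, h_min = 0.05 * L,
                             omega = 0, area_exponent = 2, phase0 = 0) {
  .check_positive(L, "L")
  .check_positive(h_max, "h_max")
  .check_positive(h_min, "h_min")
  if (omega < 0) stop("configuration error: 'omega' must be >= 0",
                      call. = FALSE)
  # equality is allowed: the degenerate cylinder is a useful null geometry
  if (h_min > h_max)
    stop("configuration error: 'h_min' must not exceed 'h_max'",
         call. = FALSE)
  if (h_max >= L)
    stop("configuration error: 'h_max' must be smaller than 'L'",
         call. = FALSE)
  if (!area_exponent %in% c(1L, 2L))
    stop("configuration error: 'area_exponent' must be 1 or 2",
         call. = FALSE)
  geom <- list(L = L, h_max = h_max, h_min = h_min, omega = omega,
               area_exponent = as.integer(area_exponent), phase0 = phase0)
  class(geom) <- "channel_geometry"
  geom
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> L = %g, h in [%g, %g] (aspect %.3g), omega = %g, A ~ h^%d\n",
    x$L, x$h_min, x$h_max, x$h_max / x$h_min, x$omega, x$area_exponent))
  invisible(x)
}

#' Extract the dimensionless channel geometry of a configuration
#'
#' @param config a [run_config()].
#' @param Omega optional dimensionless frequency overriding the one
#'   implied by `config$omega`.
#' @return A `channel_geometry` with `L = 1`.
#' @export
as_channel_geometry <- function(config, Omega = NULL) {
  dl <- to_dimensionless(config)
  channel_geometry(
    L = 1,
    h_max = dl$h_max_rel, h_min = dl$h_min_rel,
    omega = if (is.null(Omega)) dl$Omega else Omega,
    area_exponent = config$area_exponent,
    phase0 = if (is.null(config$phase0)) 0 else config$phase0
  )
}

.check_inside <- function(x, L) {
  if (any(x < 0 | x > L))
    stop("domain error: position x outside the channel [0, L]",
         call. = FALSE)
}

#' Channel radius h(x, t)
#'
#' @param geom a [channel_geometry()].
#' @param x position(s) in `[0, L]`.
#' @param t time(s).
#' @return Radius value(s); always within `[h_min, h_max]`.
#' @export
channel_radius <- function(geom, x, t = 0) {
  .check_inside(x, geom$L)
  (geom$h_max - geom$h_min) * (x / geom$L - 0.5) *
    sin(geom$omega * t + geom$phase0) + (geom$h_max + geom$h_min) / 2
}

#' Channel cross-sectional area A(x, t)
#'
#' `A = pi h^2` for a cone, `A = 2 h` for a slit.
#'
#' @inheritParams channel_radius
#' @export
channel_area <- function(geom, x, t = 0) {
  h <- channel_radius(geom, x, t)
  if (geom$area_exponent == 2L) pi * h^2 else 2 * h
}

#' Logarithmic area gradient d/dx ln A(x, t)
#'
#' The analytic derivative `area_exponent * h'(x,t) / h(x,t)` with
#' `h' = (h_max - h_min) sin(omega t + phase0) / L`; this is the entropic
#' force in units of `kBT` per unit length.
#'
#' @inheritParams channel_radius
#' @export
log_area_gradient <- function(geom, x, t = 0) {
  .check_inside(x, geom$L)
  s <- sin(geom$omega * t + geom$phase0)
  h <- (geom$h_max - geom$h_min) * (x / geom$L - 0.5) * s +
    (geom$h_max + geom$h_min) / 2
  dh <- (geom$h_max - geom$h_min) * s / geom$L
  geom$area_exponent * dh / h
}

#' Tabulate the channel profile on a regular grid
#'
#' @param geom a [channel_geometry()].
#' @param n_x,n_t grid sizes in position and time (one oscillation period,
#'   or `[0, 1]` for a static channel).
#' @return A data.frame with columns `x`, `t`, `h`, `area`.
#' @export
geometry_grid <- function(geom, n_x = 101, n_t = 25) {
  period <- if (geom$omega > 0) 2 * pi / geom$omega else 1
  g <- expand.grid(x = seq(0, geom$L, length.out = n_x),
                   t = seq(0, period, length.out = n_t))
  g$h <- channel_radius(geom, g$x, g$t)
  g$area <- channel_area(geom, g$x, g$t)
  g
}
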