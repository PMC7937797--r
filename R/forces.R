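#' Force field inside the channel
#'
#' Bundles the deterministic forces of the Langevin equation
#' `gamma v = F_ent + F_mu + F_r`: the entropic force
#' `F_ent = kBT d/dx ln A(x,t)` induced by the breathing cross-section,
#' and the constant chemical-gradient force `F_mu = f_mu kBT / L`
#' (positive toward the exit). The thermal force `F_r` lives in the
#' integrator's noise term, not here.
#'
#' @param geom a [channel_geometry()].
#' @param f_mu dimensionless chemical force (signed).
#' @param kBT thermal energy (1 in internal units).
#' @return An object of class `force_field`.
#' @export
force_field <- function(geom, f_mu = 0, kBT = 1) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (!is.finite(f_mu)) stop("'f_mu' must be finite", call. = FALSE)
  .check_positive(kBT, "kBT")
  ff <- list(geom = geom, f_mu = f_mu, kBT = kBT)
  class(ff) <- "force_field"
  ff
}

#' Entropic force kBT d/dx ln A
#'
#' Points toward the widening side of the channel: at the phase of
#' maximal opening it expels the substrate from the constriction, where
#' its magnitude peaks at
#' `area_exponent * (h_max - h_min) / h_min` in units of `kBT/L`
#' (20 for the default geometry).
#'
#' @param field a [force_field()].
#' @param x position(s) in `[0, L]`.
#' @param t time(s).
#' @return Force value(s) in energy/length units of the field.
#' @export
entropic_force <- function(field, x, t = 0) {
  field$kBT * log_area_gradient(field$geom, x, t)
}

#' Chemical-gradient force f_mu kBT / L
#'
#' Constant along the channel and in time; positive values push toward
#' the exit.
#'
#' @param field a [force_field()].
#' @export
chemical_force <- function(field) {
  field$f_mu * field$kBT / field$geom$L
}

#' Total deterministic force F_ent + F_mu
#'
#' @inheritParams entropic_force
#' @export
total_force <- function(field, x, t = 0) {
  entropic_force(field, x, t) + chemical_force(field)
}
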