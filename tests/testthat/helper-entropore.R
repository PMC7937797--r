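# Shared fixtures: small dimensionless configurations built in code.

# default breathing cone, dimensionless (L = 1)
default_geom <- function(omega = 0, ...) {
  channel_geometry(L = 1, h_max = 0.55, h_min = 0.05, omega = omega, ...)
}

# degenerate cylinder: zero entropic force everywhere
cylinder_geom <- function(h0 = 0.3, omega = 0) {
  channel_geometry(L = 1, h_max = h0, h_min = h0, omega = omega)
}

# a quick config for Monte-Carlo checks
quick_config <- function(n = 500, seed = 1, ...) {
  run_config(n_particles = n, seed = seed, ...)
}
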