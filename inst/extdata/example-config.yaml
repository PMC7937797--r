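# Example entropore run configuration.
# Any subset of sections/fields may be given; the rest take package
# defaults. Load with load_config() or pass to the CLI via --config.

geometry:
  L: 10          # nm
  h_max: 5.5     # nm
  h_min: 0.5     # nm
  omega: 3000    # 1/s  (Omega = omega L^2 / D = 30)
  area_exponent: 2

physics:
  D: 1.0e-2      # um^2/s
  T: 300         # K
  f_mu: 0.5      # kBT/L, signed (+ toward exit)

protocol:
  n_particles: 2000
  max_time: 1000           # L^2/D
  boundary_mode: reflecting-entrance

integrator:
  dt_tilde: 1.0e-4
  m_tilde: 1.0e-5
  backend: gjf

output:
  seed: 1
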