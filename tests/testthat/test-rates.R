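fake_records <- function(tau) {
  data.frame(tau = tau, success = TRUE, exit_side = "exit",
             n_steps = 1, phase0 = 0, mean_path_velocity = 1 / tau)
}

test_that("rate estimator is the ensemble mean of per-trajectory velocities", {
  cfg <- quick_config(entrance_offset = 1e-12)
  # degenerate ensemble: all tau equal
  est <- estimate_rate(fake_records(rep(2, 10)), cfg, n_boot = 50)
  expect_equal(est$gamma_dimless, 0.5)
  expect_equal(est$success_fraction, 1)
  # <1/tau>, not 1/<tau>
  est2 <- estimate_rate(fake_records(c(1, 1, 2, 2)), cfg, n_boot = 50)
  expect_equal(est2$gamma_dimless, 0.75)
  expect_equal(est2$gamma_inv_mean_tau, 1 / 1.5)
})

test_that("rate from a simulated ensemble equals the one-line reducer", {
  cfg <- quick_config(n = 800, omega = 0, phase0 = 0, f_mu = 0, seed = 2)
  recs <- simulate_ensemble(cfg)
  est <- estimate_rate(recs, cfg, n_boot = 200)
  ok <- recs$exit_side == "exit"
  expect_equal(est$gamma_dimless,
               mean((1 - cfg$entrance_offset) / recs$tau[ok]))
  expect_equal(est$n_success, sum(ok))
  # bootstrap stderr roughly matches the analytic standard error
  se <- sd(recs$mean_path_velocity[ok]) / sqrt(sum(ok))
  expect_lt(abs(est$stderr - se) / se, 0.25)
})

test_that("sweep rows are unique, sorted, and reproducible across seeds", {
  cfg <- quick_config(n = 300, seed = 21)
  grid <- c(5, 30, 80)
  sw <- sweep_frequency(grid, c(0.1, 1), cfg, n_boot = 200)
  expect_equal(nrow(sw), 6)
  expect_false(any(duplicated(sw[, c("omega_dimless", "f_mu")])))
  for (fm in c(0.1, 1)) {
    expect_equal(sw$omega_dimless[sw$f_mu == fm], sort(grid))
  }
  # a different master seed moves every estimate by < 3 combined stderr
  cfg2 <- quick_config(n = 300, seed = 1021)
  sw2 <- sweep_frequency(grid, c(0.1, 1), cfg2, n_boot = 200)
  d <- abs(sw$gamma_dimless - sw2$gamma_dimless)
  se <- sqrt(sw$stderr^2 + sw2$stderr^2)
  expect_true(all(d < 3 * se))
})

test_that("quadratic interpolation recovers a constructed log-domain peak", {
  grid <- default_omega_grid()
  g <- exp(-(log(grid) - log(30))^2)
  sw <- data.frame(omega_dimless = grid, f_mu = 1, gamma_dimless = g,
                   stderr = 0, n_success = 100, n_total = 100,
                   success_fraction = 1)
  class(sw) <- c("entropore_sweep", "data.frame")
  pk <- find_peak(sw, f_mu = 1)
  expect_true(pk$bracketed)
  expect_equal(pk$omega_peak, 30, tolerance = 0.02)
  expect_equal(pk$gamma_peak, 1, tolerance = 0.01)
  # uncertainty is half the log-grid spacing
  expect_equal(pk$uncertainty_log, 0.5 * log(300) / 23, tolerance = 1e-6)
})

test_that("a monotone series is flagged as non-bracketed", {
  grid <- default_omega_grid(10)
  sw <- data.frame(omega_dimless = grid, f_mu = 0.5,
                   gamma_dimless = log(grid), stderr = 0,
                   n_success = 100, n_total = 100, success_fraction = 1)
  class(sw) <- c("entropore_sweep", "data.frame")
  expect_warning(pk <- find_peak(sw, f_mu = 0.5), "edge")
  expect_false(pk$bracketed)
  expect_equal(pk$omega_peak, max(grid))
  expect_error(find_peak(sw[1:3, ], f_mu = 0.5), "5")
})

test_that("identical dimensionless groups collapse to one rate", {
  # same (Omega, f_mu, aspect, h_min/L) from two different physical systems
  cfg_a <- run_config(L = 10, D = 1e-2, omega = 3000, n_particles = 600,
                      seed = 31)
  cfg_b <- run_config(L = 20, D = 4e-2, omega = 3000, h_max = 11, h_min = 1,
                      n_particles = 600, seed = 32)
  expect_equal(to_dimensionless(cfg_a)$Omega, to_dimensionless(cfg_b)$Omega)
  ga <- estimate_rate(simulate_ensemble(cfg_a), cfg_a, n_boot = 300)
  gb <- estimate_rate(simulate_ensemble(cfg_b), cfg_b, n_boot = 300)
  se <- sqrt(ga$stderr^2 + gb$stderr^2)
  expect_lt(abs(ga$gamma_dimless - gb$gamma_dimless), 3 * se)
})
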