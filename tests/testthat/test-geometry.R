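test_that("radius law hits its closed-form values", {
  g <- default_geom(omega = 2)
  mid <- (0.55 + 0.05) / 2
  # sin = 0: uniform radius
  expect_equal(channel_radius(g, c(0, 0.3, 1), t = 0), rep(mid, 3))
  # midpoint is a node at any time
  for (t in c(0, 0.4, 1.7, 10)) expect_equal(channel_radius(g, 0.5, t), mid)
  # maximal opening (sin = +1): h_min at the entrance, h_max at the exit
  tq <- (pi / 2) / g$omega
  expect_equal(channel_radius(g, 0, tq), 0.05)
  expect_equal(channel_radius(g, 1, tq), 0.55)
})

test_that("radius is periodic, antisymmetric about the midpoint, and bounded", {
  g <- default_geom(omega = 7)
  set.seed(42)
  x <- runif(200)
  t <- runif(200, 0, 20)
  expect_equal(channel_radius(g, x, t),
               channel_radius(g, x, t + 2 * pi / g$omega))
  mid <- (g$h_max + g$h_min) / 2
  expect_equal(channel_radius(g, x, t) - mid,
               -(channel_radius(g, 1 - x, t) - mid))
  h <- channel_radius(g, x, t)
  expect_true(all(h >= g$h_min - 1e-12 & h <= g$h_max + 1e-12))
})

test_that("area follows the exponent convention", {
  g2 <- default_geom(omega = 3)
  expect_equal(channel_area(g2, 0.5, 0.77), pi * 0.3^2)
  g1 <- channel_geometry(h_max = 0.55, h_min = 0.05, omega = 3,
                         area_exponent = 1)
  expect_equal(channel_area(g1, 0.5, 0.77), 2 * 0.3)
  # degenerate cylinder: constant area
  cyl <- cylinder_geom(0.2, omega = 5)
  expect_equal(channel_area(cyl, c(0, 0.5, 1), 1.3), rep(pi * 0.04, 3))
  # area ratio across the channel at maximal opening = aspect^exponent
  tq <- (pi / 2) / 3
  expect_equal(channel_area(g2, 1, tq) / channel_area(g2, 0, tq), 11^2)
  expect_equal(channel_area(g1, 1, tq) / channel_area(g1, 0, tq), 11)
})

test_that("log-area gradient is the exact analytic derivative", {
  g <- default_geom(omega = 5)
  # zero at the mid phase and for a cylinder
  expect_equal(log_area_gradient(g, c(0.1, 0.9), t = 0), c(0, 0))
  cyl <- cylinder_geom(0.3, omega = 5)
  expect_equal(log_area_gradient(cyl, c(0.1, 0.9), t = 0.3), c(0, 0))
  # closed form at the narrowest end at maximal opening
  tq <- (pi / 2) / g$omega
  expect_equal(log_area_gradient(g, 0, tq), 2 * (0.55 - 0.05) / 0.05)
  # agrees with a central finite difference of ln(area) at random (x, t)
  set.seed(7)
  x <- runif(1000, 0.05, 0.95)
  t <- runif(1000, 0, 10)
  eps <- 1e-6
  fd <- (log(channel_area(g, x + eps, t)) -
           log(channel_area(g, x - eps, t))) / (2 * eps)
  an <- log_area_gradient(g, x, t)
  expect_true(all(abs(an - fd) <= 1e-6 * pmax(abs(fd), 1)))
})

test_that("geometry validates its invariants and domain", {
  expect_error(channel_geometry(h_min = 0.6, h_max = 0.55), "h_min")
  expect_error(channel_geometry(h_max = 1.2, h_min = 0.05), "h_max")
  expect_error(channel_geometry(h_min = -0.1), "h_min")
  g <- default_geom()
  expect_error(channel_radius(g, 1.2), "domain")
  expect_error(log_area_gradient(g, -0.1), "domain")
})

test_that("geometry_grid tabulates one period of the profile", {
  g <- default_geom(omega = 10)
  tab <- geometry_grid(g, n_x = 11, n_t = 5)
  expect_equal(nrow(tab), 55)
  expect_equal(max(tab$t), 2 * pi / 10)
  expect_equal(tab$h, channel_radius(g, tab$x, tab$t))
})
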