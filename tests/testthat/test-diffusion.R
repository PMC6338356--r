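test_that("scale function: closed form, neutral limit and continuity", {
  expect_identical(scale_function(0.7, 0), 0.7)
  expect_identical(scale_function(0, 2), 0)
  expect_identical(scale_function(0, -5), 0)
  expect_equal(scale_function(1, 2), (1 - exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(scale_function(1, 2), 0.432332, tolerance = 1e-6)
  # series branch is continuous across the neutral threshold
  x <- c(0.1, 0.5, 0.9)
  expect_equal(scale_function(x, 1e-9), scale_function(x, 2e-8),
               tolerance = 1e-7)
  # fixation probability s(x)/s(1) = x at gamma = 0, machine precision
  expect_equal(scale_function(x, 0) / scale_function(1, 0), x)
})

test_that("speed density: values, symmetry, domain, exponent variants", {
  expect_equal(speed_density(0.5, 0), 4)
  expect_equal(speed_density(0.25, 0), 16 / 3)
  x <- runif(20, 0.01, 0.99)
  expect_equal(speed_density(x, 0), speed_density(1 - x, 0))
  expect_error(speed_density(0, 0), "open interval")
  expect_error(speed_density(1, 1.5), "open interval")
  expect_equal(speed_density(0.3, 2), exp(2 * 0.3) / (0.3 * 0.7))
  ctrl_const <- prf_control(speed_exponent = "gamma_const")
  expect_equal(speed_density(0.3, 2, ctrl_const), exp(2) / (0.3 * 0.7))
})

test_that("diffusion grid invariants are enforced", {
  g <- diffusion_grid(50)
  expect_true(all(diff(g$x) > 0) && all(g$x > 0 & g$x < 1))
  bad <- g
  bad$x[3] <- bad$x[2]
  expect_error(solve_transition(0, 1, function(x) x, bad), "invalid grid")
  expect_error(diffusion_grid(2))
  expect_error(diffusion_grid(50, time_step = -1))
})

test_that("solve_transition: initial condition, zero map, nonnegativity", {
  ctrl <- test_ctrl()
  g <- diffusion_grid(ctrl$grid_points)
  f <- function(x) sin(pi * x)
  expect_identical(solve_transition(3, 0, f, g, ctrl), f(g$x))
  expect_equal(solve_transition(2, 0.7, function(x) 0 * x, g, ctrl),
               rep(0, length(g$x)))
  for (gamma in c(0, 3, -5)) {
    u <- solve_transition(gamma, 0.4, f, g, ctrl)
    expect_true(all(u > -1e-10))
  }
})

test_that("solve_transition matches the neutral leading eigenfunction decay", {
  # x(1-x) is an exact eigenfunction of x(1-x) d^2/dx^2 with eigenvalue -2
  ctrl <- prf_control(grid_points = 200, time_steps = 400)
  g <- diffusion_grid(200)
  f <- g$x * (1 - g$x)
  for (t in c(0.3, 1)) {
    u <- solve_transition(0, t, f, g, ctrl)
    expect_equal(u, f * exp(-2 * t), tolerance = 1e-4)
  }
})

test_that("Chapman-Kolmogorov self-consistency and grid refinement", {
  f <- function(x) x^2 * (1 - x)
  ck_gap <- function(n) {
    ctrl <- prf_control(grid_points = n, time_steps = n)
    g <- diffusion_grid(n)
    u12 <- solve_transition(1.5, 0.3, f, g, ctrl)
    u12 <- solve_transition(1.5, 0.5, u12, g, ctrl)
    u <- solve_transition(1.5, 0.8, f, g, ctrl)
    max(abs(u12 - u))
  }
  g1 <- ck_gap(100)
  g2 <- ck_gap(200)
  expect_lt(g1, 1e-4)                 # within grid tolerance
  expect_lt(g2, g1 / 2)               # halving h and dt at least halves it
})

test_that("transition mass is non-increasing in time (absorbing boundaries)", {
  ctrl <- test_ctrl()
  g <- diffusion_grid(ctrl$grid_points)
  for (gamma in c(0, 2, -6)) {
    masses <- sapply(c(0.05, 0.2, 0.5, 1, 2), function(t)
      solve_transition(gamma, t, function(x) rep(1, length(x)), g, ctrl))
    # each column is u(t, x) = total surviving mass from x; compare columns
    expect_true(all(diff(t(masses[c(30, 60, 90), ])) < 1e-10))
  }
})

test_that("fixation flux kernel: nonnegative, zero-time limit, refinement", {
  ctrl <- test_ctrl()
  set.seed(1)
  for (i in 1:5) {
    gamma <- runif(1, -6, 4)
    u <- runif(1, 0.1, 1.5)
    y <- runif(1, 0.15, 0.85)
    expect_gte(fixation_flux_kernel(gamma, u, y, ctrl = ctrl), 0)
  }
  expect_identical(fixation_flux_kernel(0, 0, 0.5), 0)
  # grid refinement: halving the spacing changes the extrapolated limit
  # within the stated tolerance
  k1 <- fixation_flux_kernel(0, 0.5, 0.4,
                             grid = diffusion_grid(150), ctrl = ctrl)
  k2 <- fixation_flux_kernel(0, 0.5, 0.4,
                             grid = diffusion_grid(300), ctrl = ctrl)
  expect_equal(k1, k2, tolerance = 2e-2)
})

test_that("unit-interval quadrature: exactness and stability", {
  expect_equal(integrate_unit_interval(function(x) rep(1, length(x))), 1)
  expect_equal(integrate_unit_interval(function(x) x^2), 1 / 3)
  expect_equal(integrate_unit_interval(function(x) x^10), 1 / 11)
  # cancellation identity x(1-x) * speed_density(x, 0) = 1
  expect_equal(integrate_unit_interval(function(x)
    x * (1 - x) * speed_density(x, 0)), 1)
  # doubling the order is stable for a model-type integrand
  g <- function(x) (1 - exp(-2 * (1 - x))) / (2 * x * (1 - x)) *
    (1 - x^8 - (1 - x)^8)
  expect_equal(integrate_unit_interval(g, 64), integrate_unit_interval(g, 128),
               tolerance = 1e-10)
  expect_error(integrate_unit_interval(function(x) 1 / (x - x)), "non-finite")
})

test_that("expect_over_gamma: degenerate, mean, second moment", {
  h <- function(g) g^2
  expect_identical(expect_over_gamma(h, 3, 0), 9)
  expect_equal(expect_over_gamma(identity, 3, 5), 3, tolerance = 1e-12)
  # second moment of N(0, 2^2); dense-trapezoid reference
  z <- seq(-30, 30, length.out = 20001)
  ref <- sum(z^2 * dnorm(z, 0, 2)) * (z[2] - z[1])
  expect_equal(expect_over_gamma(h, 0, 2), 4, tolerance = 1e-10)
  expect_equal(expect_over_gamma(h, 0, 2), ref, tolerance = 1e-6)
  expect_error(suppressWarnings(expect_over_gamma(function(g) log(g), 0, 1)),
               "non-finite")
})
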