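test_that("component values at the mid-surface match closed forms", {
  g <- default_geom()
  eps <- g$epsilon
  expect_equal(component_sB2(0, 20, g), -3 * 20 / (2 * sqrt(2) * eps^3))
  expect_equal(component_sB2(0, 20, g), -36.656, tolerance = 1e-4)
  expect_equal(component_sG(0, -14, g), -35 * (-14) / (16 * sqrt(2) * eps^3))
  expect_equal(component_sG(0, -14, g), 37.41, tolerance = 1e-3)
  # m- and gamma-carrying components vanish at z = 0
  expect_equal(component_sB0(0, 20, 0.1, g), 0)
  expect_equal(component_sT(0, 0.005, g), 0)
  expect_equal(component_sB1(0, 20, 0.1, g),
               -3 * sqrt(2) * 2 / eps^2 * (1 / sqrt(2)) * 0)
})

test_that("components have the stated parity and vanish with their constants", {
  g <- default_geom()
  z <- seq(0.05, 6, by = 0.23)
  expect_equal(component_sB2(-z, 20, g), component_sB2(z, 20, g))
  expect_equal(component_sB1(-z, 20, 0.1, g), -component_sB1(z, 20, 0.1, g))
  expect_equal(component_sB0(-z, 20, 0.1, g), component_sB0(z, 20, 0.1, g))
  expect_equal(component_sG(-z, -14, g), component_sG(z, -14, g))
  expect_equal(component_sT(-z, 0.005, g), component_sT(z, 0.005, g))
  expect_true(all(component_sB1(z, 20, 0.1, g) == 0) == FALSE)
  expect_identical(component_sB1(z, 20, 0, g), rep(0, length(z)))
  expect_identical(component_sB0(z, 20, 0, g), rep(0, length(z)))
  expect_identical(component_sT(z, 0, g), rep(0, length(z)))
  # m > 0: outer leaflet (z > 0) more repulsive
  expect_true(all(component_sB1(z, 20, 0.1, g) < 0))
})

test_that("quadrature moments of each component match the pinned constants", {
  g <- default_geom()
  k <- 20; m <- 0.1; kG0 <- -14; gamma <- 0.005
  eps <- g$epsilon
  zd2 <- (12 + pi^2) / 6 * eps^2
  cases <- list(
    list(g = function(z) component_sB2(z, k, g), P = c(0, 0, 2 * k)),
    list(g = function(z) component_sB1(z, k, m, g), P = c(0, -2 * k * m, 0)),
    list(g = function(z) component_sB0(z, k, m, g),
         P = c(2 * k * m^2, 0, 2 * k * m^2 * zd2)),
    list(g = function(z) component_sG(z, kG0, g), P = c(0, 0, kG0)),
    list(g = function(z) component_sT(z, gamma, g),
         P = c(gamma, 0, gamma * zd2)))
  for (cs in cases) {
    got <- vapply(0:2, function(i) moment_oracle(cs$g, i, eps), numeric(1))
    expect_equal(got, cs$P, tolerance = 1e-8)
  }
})

test_that("tension and spontaneous-tension components share one shape", {
  g <- default_geom()
  z <- seq(-8, 8, length.out = 301)
  lhs <- component_sT(z, 0.0123, g) / 0.0123
  rhs <- component_sB0(z, 20, 0.07, g) / (2 * 20 * 0.07^2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("components are linear in their own constants", {
  g <- default_geom()
  z <- seq(-5, 5, length.out = 41)
  expect_equal(component_sB2(z, 37, g), 37 / 20 * component_sB2(z, 20, g))
  expect_equal(component_sB1(z, 20, 0.2, g), 2 * component_sB1(z, 20, 0.1, g))
  expect_equal(component_sB0(z, 20, 0.2, g), 4 * component_sB0(z, 20, 0.1, g))
  expect_equal(component_sG(z, -7, g), 0.5 * component_sG(z, -14, g))
  expect_equal(component_sT(z, 0.02, g), 4 * component_sT(z, 0.005, g))
})

test_that("central stress and the zero-bump ratio", {
  g <- default_geom()
  expect_equal(central_stress(elastic_constants(k = 20, kG0 = -14), g),
               0.764, tolerance = 1e-3)
  # independent of m and gamma
  for (m in c(-0.1, 0, 0.1))
    expect_equal(central_stress(elastic_constants(20, -14, m = m, gamma = 0.01), g),
                 central_stress(elastic_constants(20, -14), g))
  # exact zero at kG0/k = -24/35
  expect_equal(central_stress(elastic_constants(20, -24 / 35 * 20), g), 0,
               tolerance = 1e-12)
  r <- zero_bump_ratio()
  expect_equal(r, -24 / 35, tolerance = 1e-10)
  expect_equal(r, -(3 / 2) * (16 / 35), tolerance = 1e-12)
  expect_equal(central_stress(elastic_constants(20, r * 20), g), 0,
               tolerance = 1e-10)
  # s(0) agrees with total_stress at z = 0
  p <- default_params()
  expect_equal(central_stress(p, g), total_stress(p, g, 0), tolerance = 1e-12)
})

test_that("sampled profiles are consistent, decaying, and shaped as expected", {
  g <- default_geom()
  p3 <- elastic_constants(k = 20, kG0 = -0.7 * 20)
  prof <- sample_profile(p3, g, -4, 4, 401)
  expect_equal(prof$total, rowSums(prof$components))
  # symmetric membrane: even total
  expect_equal(rev(prof$total), prof$total, tolerance = 1e-12)
  # positive in the headgroup regions, negative in the tail region
  head_idx <- abs(abs(prof$z) - 1.5) < 0.5
  tail_idx <- abs(abs(prof$z) - 0.5) < 0.2
  expect_true(all(prof$total[head_idx] > 0))
  expect_true(all(prof$total[tail_idx] < 0))
  # m > 0 tilts the profile: more negative on the outer side
  pm <- elastic_constants(k = 20, kG0 = -14, m = 0.1)
  tm <- total_stress(pm, g, prof$z)
  diff_ <- tm[prof$z > 0.2] - rev(tm)[prof$z > 0.2]
  expect_true(all(diff_ < 0))
  # decay invariant
  wide <- sample_profile(default_params(), g, -2 * g$lme, 2 * g$lme, 2001)
  far <- abs(wide$z) >= g$lme
  expect_lt(max(abs(wide$total[far])), 1e-3 * max(abs(wide$total)))
  expect_lt(abs(total_stress(default_params(), g, 10 * g$lme)),
            1e-10 * max(abs(wide$total)))
  # degenerate grids rejected; n = 2 allowed
  expect_error(sample_profile(p3, g, 4, -4), "degenerate")
  expect_error(sample_profile(p3, g, -4, 4, 1), "degenerate")
  two <- sample_profile(p3, g, -1, 1, 2)
  expect_equal(two$total, total_stress(p3, g, c(-1, 1)))
})

test_that("thinning under tension: smaller lme sharpens and narrows the profile", {
  p <- elastic_constants(k = 20, kG0 = -14)
  z <- seq(-4, 4, length.out = 2001)
  peak_stats <- function(lme) {
    g <- interface_geometry(lme = lme)
    s <- total_stress(p, g, z)
    pos <- which(z > 0)
    list(amp = max(abs(s)), peak = z[pos][which.max(s[pos])])
  }
  st <- lapply(c(5, 4.75, 4.5), peak_stats)
  amps <- vapply(st, `[[`, numeric(1), "amp")
  peaks <- vapply(st, `[[`, numeric(1), "peak")
  expect_true(all(diff(amps) > 0))   # thinner -> larger |s|
  expect_true(all(diff(peaks) < 0))  # thinner -> peaks move inward
})

test_that("constructors validate their inputs", {
  expect_error(elastic_constants(k = -1), "positive")
  expect_error(elastic_constants(k = 0), "positive")
  expect_error(interface_geometry(epsilon = -1), "positive")
  expect_error(interface_geometry(lme = 5, epsilon = 1.2), "range")
  g <- interface_geometry(epsilon = 5.73 / 6 * 6 / 5.73, ratio = 5.73)
  expect_equal(interface_geometry(lme = 5, ratio = 5.73)$epsilon, 5 / 5.73)
  p <- elastic_constants(k = 20, kG0 = -14, m = 0.1, gamma = 0.005)
  expect_equal(total_tension(p), 0.005 + 2 * 20 * 0.01)
})
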