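test_that("moment extraction inverts the invertible relations", {
  g <- default_geom()
  p <- elastic_constants(k = 20, kG0 = -14, m = 0.1, gamma = 0)
  prof <- sample_profile(p, g, -4 * g$lme, 4 * g$lme, 2001)
  ex <- extract_by_moments(prof)
  expect_equal(ex$Sigma, 0.4, tolerance = 1e-6)
  expect_equal(ex$km, 2, tolerance = 1e-6)
  expect_equal(ex$P2_combo, 26 + zD(g)^2 * 0.4, tolerance = 1e-6)
  # symmetric tensionless profile: (0, 0, 2k + kG0)
  prof_s <- sample_profile(elastic_constants(20, -14), g, -20, 20, 2001)
  ex_s <- extract_by_moments(prof_s)
  expect_lt(abs(ex_s$Sigma), 1e-10)
  expect_lt(abs(ex_s$km), 1e-10)
  expect_equal(ex_s$P2_combo, 26, tolerance = 1e-6)
})

test_that("moment extraction of a zero profile is all zero", {
  path <- tempfile(fileext = ".tsv")
  z <- seq(-20, 20, length.out = 401)
  writeLines(c("#units=kbt_nm3",
               sprintf("%.12g\t0", z)), path)
  ex <- extract_by_moments(read_profile(path))
  expect_equal(unlist(ex), c(Sigma = 0, km = 0, P2_combo = 0))
})

test_that("shape fit is the identity on noiseless self-generated profiles", {
  g <- default_geom()
  p <- default_params()
  prof <- sample_profile(p, g, -2 * g$lme, 2 * g$lme, 801)
  ex <- extract_by_shape_fit(prof, epsilon = g$epsilon)
  expect_equal(ex$params$k, 20, tolerance = 1e-6)
  expect_equal(ex$params$kG0, -14, tolerance = 1e-6)
  expect_equal(ex$params$m, 0.1, tolerance = 1e-6)
  expect_equal(ex$params$gamma, 0.005, tolerance = 1e-6)
  expect_equal(ex$Sigma, 0.405, tolerance = 1e-6)
  expect_lt(ex$rms_residual, 1e-8 * max(abs(prof$total)))
  expect_equal(ex$method, "shape_fit")
  # agrees with the moment route on (Sigma, k*m)
  em <- extract_by_moments(prof)
  expect_equal(em$Sigma, ex$Sigma, tolerance = 1e-5)
  expect_equal(em$km, ex$params$k * ex$params$m, tolerance = 1e-5)
})

test_that("epsilon can be recovered by the 1D residual search", {
  g <- interface_geometry(lme = 4.8)   # epsilon = 0.8, off the default
  p <- elastic_constants(k = 25, kG0 = -18, m = -0.05, gamma = 0.01)
  prof <- sample_profile(p, g, -12, 12, 801)
  prof$geom <- default_geom()          # pretend epsilon is unknown
  ex <- extract_by_shape_fit(prof, epsilon = "fit")
  expect_equal(ex$epsilon_used, 0.8, tolerance = 0.01)
  expect_equal(ex$params$k, 25, tolerance = 1e-3)
})

test_that("noisy synthesis is deterministic and correctly scaled", {
  g <- default_geom()
  p <- default_params()
  clean <- sample_profile(p, g, n = 801)
  a <- synthesize_noisy_profile(p, g, n = 801, noise_sd = 0.1, seed = 42)
  b <- synthesize_noisy_profile(p, g, n = 801, noise_sd = 0.1, seed = 42)
  expect_identical(a$total, b$total)
  c2 <- synthesize_noisy_profile(p, g, n = 801, noise_sd = 0.1, seed = 43)
  expect_false(identical(a$total, c2$total))
  # noise_sd = 0 reproduces the clean profile
  z0 <- synthesize_noisy_profile(p, g, n = 801, noise_sd = 0, seed = 1)
  expect_equal(z0$total, clean$total)
  # realized noise sd near the requested one (law of large numbers)
  big <- synthesize_noisy_profile(p, g, n = 20001L, noise_sd = 0.2, seed = 7)
  big_clean <- sample_profile(p, g, n = 20001L)
  expect_equal(sd(big$total - big_clean$total), 0.2, tolerance = 0.05)
  expect_error(synthesize_noisy_profile(p, g, noise_sd = -1), ">= 0")
})

test_that("m = 0 profiles yield an m estimate at the noise floor", {
  g <- default_geom()
  p <- elastic_constants(k = 20, kG0 = -14, m = 0, gamma = 0)
  prof <- synthesize_noisy_profile(p, g, n = 801, noise_sd = 0.1, seed = 5)
  ex <- extract_by_shape_fit(prof, epsilon = g$epsilon)
  expect_lt(abs(ex$params$m * ex$params$k), 3 * ex$coef_se[["mk"]])
})

test_that("recovery experiment: zero-noise exactness and monotone RMSE", {
  g <- default_geom()
  p <- default_params()
  tab <- recovery_experiment(p, g, noise_levels = c(0, 0.05, 0.15),
                             reps = 10L, seed = 3, n = 401L)
  z <- tab[tab$noise_sd == 0, ]
  expect_lt(max(abs(z$bias) / pmax(abs(z$truth), 1e-3)), 1e-6)
  expect_lt(max(z$rmse / pmax(abs(z$truth), 1e-3)), 1e-6)
  for (cn in unique(tab$constant)) {
    r <- tab$rmse[tab$constant == cn]
    expect_true(all(diff(r) >= 0), label = sprintf("RMSE monotone for %s", cn))
  }
  # determinism under the seed
  tab2 <- recovery_experiment(p, g, noise_levels = c(0, 0.05, 0.15),
                              reps = 10L, seed = 3, n = 401L)
  expect_identical(tab, tab2)
  expect_error(recovery_experiment(p, g, reps = 5L), ">= 10")
})

test_that("extraction input validation", {
  g <- default_geom()
  p <- default_params()
  expect_error(extract_by_shape_fit(sample_profile(p, g, -12, 12, 30)),
               "50")
  expect_error(extract_by_shape_fit(sample_profile(p, g, -6, 6, 301)),
               "narrow")
  expect_error(extract_by_moments(sample_profile(p, g, -6, 6, 301)),
               "at least")
})
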