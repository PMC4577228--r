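test_that("normalisation maps the plateau to one and is scale-invariant", {
  geom <- default_geom
  prof <- point_source_profile(geom, field_config(15, 0))
  n1 <- normalize_profile(prof)
  expect_equal(max(n1$value), 1, tolerance = 1e-9)
  expect_equal(min(n1$value), exp(-0.96 * 8), tolerance = 0.01)
  # idempotent
  expect_equal(normalize_profile(n1)$value, n1$value)
  # invariant under positive rescaling
  scaled <- prof
  scaled$value <- prof$value * 37.5
  expect_equal(normalize_profile(scaled)$value, n1$value)
  # a flat profile has no edge to normalise against
  flat <- fluence_profile(1:10, rep(2, 10))
  expect_error(normalize_profile(flat), "no discernible edge")
})

test_that("mixture evaluation matches the explicit sum of Gaussians", {
  gm <- gaussian_mixture(c(0.5, 1.2), c(-1, 2), c(0.3, 0.8))
  xs <- seq(-3, 4, 0.37)
  manual <- 0.5 * exp(-((xs + 1) / 0.3)^2) + 1.2 * exp(-((xs - 2) / 0.8)^2)
  expect_equal(evaluate_mixture(gm, xs), manual)
  # a single peak evaluated at its center returns the amplitude
  expect_equal(evaluate_mixture(gaussian_mixture(0.7, 1, 2), 1), 0.7)
  expect_error(gaussian_mixture(1, 0, -1), "positive")
})

test_that("a noiseless single Gaussian is recovered exactly", {
  true <- gaussian_mixture(0.9, 0.2, 0.45)
  xs <- seq(-1.3, 1.7, 0.01)
  prof <- fluence_profile(xs, evaluate_mixture(true, xs),
                          meta = list(normalized = TRUE))
  fit <- fit_edge_mixture(prof, n = 1, window = c(-1.3, 1.7))
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-6)
  expect_equal(fit$center, 0.2, tolerance = 1e-6)
  expect_equal(fit$width, 0.45, tolerance = 1e-6)
  expect_lt(attr(fit, "rmse"), 1e-8)
})

test_that("crossings are located by interpolation and bisection", {
  # straight line through (0,1) and (1,0) crosses 0.5 at 0.5
  line <- fluence_profile(c(0, 1), c(1, 0), meta = list(normalized = TRUE))
  expect_equal(find_crossing(line, 0.5, c(0, 1)), 0.5)
  # erf edge: crossings sit at the Gaussian quantiles
  sigma_cm <- 0.1
  f <- generate_fixture("erf_edge", list(sigma_mm = 1, noise_sd = 0))
  for (level in c(0.2, 0.5, 0.8)) {
    # linear interpolation on the 0.01 cm grid carries a small curvature error
    expect_lt(abs(find_crossing(f, level, c(-1, 1)) -
                    (-stats::qnorm(level) * sigma_cm)), 2e-4)
  }
  expect_error(find_crossing(line, 0.5, c(0.8, 1)), "not crossed")
})

test_that("penumbra width matches closed forms and degenerates for a step", {
  f <- generate_fixture("erf_edge", list(sigma_mm = 1, noise_sd = 0))
  expect_lt(abs(penumbra_width(f, c(-1, 1)) - 2 * stats::qnorm(0.8) * 1),
            0.005)
  expect_lt(abs(penumbra_width(f, c(-1, 1)) - f$meta$penumbra_mm), 0.005)
  step <- generate_fixture("step")
  expect_lt(penumbra_width(step, c(-1, 1)), 0.01 * 10 + 1e-9)
})

test_that("penumbra width is translation-invariant and scales under dilation", {
  f <- generate_fixture("erf_edge", list(sigma_mm = 1.5, noise_sd = 0))
  w0 <- penumbra_width(f, c(-1.5, 1.5))
  shifted <- fluence_profile(f$x + 2.4, f$value, f$meta)
  expect_equal(penumbra_width(shifted, c(-1.5, 1.5) + 2.4), w0,
               tolerance = 1e-9)
  dilated <- fluence_profile(f$x * 2, f$value, f$meta)
  expect_equal(penumbra_width(dilated, c(-3, 3)), 2 * w0, tolerance = 1e-9)
})

test_that("fitted and interpolated edges agree on smooth simulated profiles", {
  geom <- default_geom
  prof <- simulate_profile(geom, field_config(15, 5), source_model(1))
  e_int <- analyze_edge(prof, method = "interpolation")
  e_fit <- analyze_edge(prof, method = "fit")
  expect_lt(abs(e_int$field_edge - e_fit$field_edge) * 10, 0.05)
  expect_s3_class(e_fit$fit, "gaussian_mixture")
  expect_true(is.finite(e_fit$fit_rmse))
})

test_that("profile offsets follow the sign convention and additive identity", {
  o <- profile_offsets(edge = 9.932, nominal = 10, geometric = 9.99)
  expect_equal(o$pno, -0.68, tolerance = 1e-9)
  expect_equal(o$lpo, -0.1, tolerance = 1e-9)
  expect_identical(o$pno, o$lpo + o$rfo)
  expect_equal(profile_offsets(5, 5, 5)$pno, 0)
})

test_that("edge analysis serialises to the documented JSON record", {
  geom <- default_geom
  prof <- simulate_profile(geom, field_config(15, 0), source_model(1))
  ea <- analyze_edge(prof, method = "fit")
  path <- withr::local_tempfile(fileext = ".json")
  write_edge_analysis(ea, path)
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(rec$field_edge_cm[[1]], ea$field_edge, tolerance = 1e-9)
  expect_equal(rec$penumbra_width_mm[[1]], ea$penumbra_width, tolerance = 1e-9)
  expect_equal(rec$n_peaks[[1]], 3)
  expect_equal(length(rec$coefficients), 3)
})
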