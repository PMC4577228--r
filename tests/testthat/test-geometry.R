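test_that("treatment geometry validates its invariants", {
  geom <- default_geom
  expect_s3_class(geom, "treatment_geometry")
  expect_equal(geom$sad - geom$scd, 54)
  expect_error(treatment_geometry(sad = 40, scd = 46), "sad > scd")
  expect_error(treatment_geometry(mu = 0), "mu")
  expect_error(treatment_geometry(leaf_height = -1), "leaf_height")
})

test_that("geometry config files round-trip through YAML and JSON", {
  geom <- treatment_geometry(sad = 90, scd = 40, mu = 1.1)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_geometry(geom, path)
    back <- read_geometry(path)
    expect_equal(back$sad, 90)
    expect_equal(back$scd, 40)
    expect_equal(back$mu, 1.1)
  }
  # missing keys fall back to defaults
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sad_cm": 95}', path)
  expect_equal(read_geometry(path)$scd, 46)
})

test_that("leaf cross-section places the tip and arc center correctly", {
  cs <- leaf_cross_section(default_geom, 10, 15)
  expect_equal(cs$x_mechanical, 4.6)
  expect_equal(unname(cs$center), c(19.6, 54))
  expect_equal(cs$z_top - cs$z_bottom, default_geom$leaf_height)

  cs0 <- leaf_cross_section(default_geom, 0, 15)
  expect_equal(unname(cs0$center), c(15, 54))
  expect_equal(left_boundary(cs0, 54), 0)

  cs_n <- leaf_cross_section(default_geom, -20, 25)
  expect_equal(unname(cs_n$center), c(15.8, 54))

  expect_error(leaf_cross_section(default_geom, 0, 3), "unsupported geometry")
})

test_that("the field-facing boundary follows the arc and is minimal at the apex", {
  cs <- leaf_cross_section(default_geom, 0, 15)
  expect_equal(left_boundary(cs, 58), 15 - sqrt(225 - 16))
  # symmetric about the arc center height
  expect_equal(left_boundary(cs, 54 + 2.5), left_boundary(cs, 54 - 2.5))
  expect_error(left_boundary(cs, 70), "outside leaf slab")
  # apex minimality over random cross-sections
  set.seed(11)
  for (i in 1:20) {
    csr <- leaf_cross_section(default_geom, runif(1, -20, 20), runif(1, 4, 25))
    zz <- seq(csr$z_bottom, csr$z_top, length.out = 201)
    lb <- left_boundary(csr, zz)
    expect_equal(min(lb), left_boundary(csr, csr$center[["z"]]))
    expect_equal(min(lb), csr$center[["x"]] - csr$radius)
  }
})

test_that("path_length handles misses, full-slab rays and interior chords", {
  cs <- leaf_cross_section(default_geom, 0, 15)
  expect_equal(path_length(cs, ray(0, -5)), 0)
  # vertical ray through the deep body crosses the full slab
  expect_equal(path_length(cs, ray(18, 18)), default_geom$leaf_height)
  # a short chord near the arc apex lies fully inside the slab and must
  # match the circle-chord formula 2*sqrt(R^2 - d^2)
  r <- ray(0, 0.05)
  A <- c(0, 100); B <- c(0.05, 0)
  d <- B - A
  Cc <- c(15, 54)
  dist <- abs(d[1] * (Cc[2] - A[2]) - d[2] * (Cc[1] - A[1])) / sqrt(sum(d^2))
  expect_lt(dist, 15)
  chord <- 2 * sqrt(15^2 - dist^2)
  expect_lt(chord / 2, 4)  # chord z-extent inside the slab
  expect_equal(path_length(cs, r), chord, tolerance = 1e-10)
})

test_that("path_length matches the indicator-scan oracle on random rays", {
  set.seed(101)
  n_rays <- 1000
  for (i in seq_len(n_rays / 50)) {
    cs <- leaf_cross_section(default_geom, runif(1, -20, 20), runif(1, 4, 25))
    src <- runif(50, -0.5, 0.5)
    tgt <- cs$nominal_x + runif(50, -4, 4)
    got <- path_length(cs, ray(src, tgt))
    want <- vapply(1:50, function(j) oracle_path_scan(cs, src[j], tgt[j]), 0)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("path_length is continuous in the scoring position", {
  # near grazing tangency the path grows like sqrt(x - edge), so steps shrink
  # roughly with sqrt of the grid spacing rather than linearly; refining the
  # grid around the largest step must shrink it (no true discontinuity)
  cs <- leaf_cross_section(default_geom, 5, 15)
  xs <- seq(2, 8, by = 1e-3)
  p <- path_length(cs, ray(0, xs))
  jumps <- abs(diff(p))
  expect_lt(max(jumps), 0.5)
  i <- which.max(jumps)
  zoom <- seq(xs[i] - 2e-3, xs[i] + 2e-3, by = 1e-6)
  pz <- path_length(cs, ray(0, zoom))
  expect_lt(max(abs(diff(pz))), max(jumps) / 5)
})

test_that("mirroring is an involution and negates positions and offsets", {
  cs <- leaf_cross_section(default_geom, 10, 15)
  back <- mirror(mirror(cs))
  expect_equal(back, cs)
  expect_equal(mirror(3.2), -3.2)

  m <- mirror(cs)
  expect_equal(m$bank, "left")
  expect_equal(geometric_position(default_geom, m),
               -geometric_position(default_geom, cs))

  o_r <- compute_offsets(leaf_positions(default_geom, 10, 15))
  o_l <- compute_offsets(leaf_positions(default_geom, -10, 15, bank = "left"))
  expect_equal(o_l$lpo, -o_r$lpo, tolerance = 1e-9)
  expect_equal(o_l$rfo, -o_r$rfo, tolerance = 1e-9)
  expect_equal(o_l$pno, -o_r$pno, tolerance = 1e-9)

  # mirrored path lengths agree with mirrored rays
  expect_equal(path_length(m, ray(-0.2, -9.8)),
               path_length(cs, ray(0.2, 9.8)))
})
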