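test_that("half-value layer follows the closed form and scales with mu", {
  expect_equal(half_value_layer(0.96), -log(0.5) / 0.96)
  expect_equal(half_value_layer(0.96), 0.72203, tolerance = 1e-5)
  expect_equal(half_value_layer(log(2)), 1)
  expect_equal(half_value_layer(2 * 0.7), half_value_layer(0.7) / 2)
  expect_error(half_value_layer(0), "positive")
  expect_error(half_value_layer(-1), "positive")
})

test_that("tangent point satisfies perpendicularity or clamps to a corner", {
  geom <- default_geom
  # central leaf: the grazing ray is vertical through the tip
  tp <- tangent_point(geom, leaf_cross_section(geom, 0, 15))
  expect_equal(unname(tp), c(0, 54), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(tp, "clamped"), "none")
  # perpendicularity of CT and ST at an off-axis arc tangency
  cs <- leaf_cross_section(geom, 10, 15)
  tp <- tangent_point(geom, cs)
  ct <- tp - c(cs$center[["x"]], cs$center[["z"]])
  st <- tp - c(0, geom$sad)
  expect_equal(sum(ct * st), 0, tolerance = 1e-9)
  # far off-axis large radius: clamped to the proximal corner U
  cs2 <- leaf_cross_section(geom, -20, 25)
  tp2 <- tangent_point(geom, cs2)
  expect_identical(attr(tp2, "clamped"), "proximal")
  expect_equal(unname(tp2), c(15.8 - sqrt(625 - 16), 58),
               ignore_attr = TRUE)
  # source inside the arc circle also clamps to U (compact toy head)
  geom_toy <- treatment_geometry(sad = 30, scd = 10, leaf_height = 8,
                                 max_half_field = 10)
  cs3 <- leaf_cross_section(geom_toy, -18, 12)  # arc center (6, 20), D < R
  D <- sqrt(sum((c(cs3$center[["x"]], cs3$center[["z"]]) - c(0, 30))^2))
  expect_lt(D, 12)
  tp3 <- tangent_point(geom_toy, cs3)
  expect_identical(attr(tp3, "clamped"), "proximal")
  expect_equal(unname(tp3), unname(cs3$corner_u), ignore_attr = TRUE)
})

test_that("geometric position equals the dense outline-projection minimum", {
  geom <- default_geom
  expect_equal(geometric_position(geom, leaf_cross_section(geom, 0, 15)), 0,
               tolerance = 1e-9)
  # corner-clamped case has the closed corner projection
  cs <- leaf_cross_section(geom, -20, 25)
  expect_equal(geometric_position(geom, cs),
               (15.8 - sqrt(625 - 16)) * 100 / 42, ignore_attr = TRUE)
  for (R in c(4, 15, 25)) {
    for (xn in c(-20, 0, 20)) {
      csg <- leaf_cross_section(geom, xn, R)
      expect_equal(geometric_position(geom, csg),
                   oracle_min_projection(geom, csg), tolerance = 1e-5,
                   label = sprintf("geometric edge R=%g xn=%g", R, xn))
    }
  }
})

test_that("physical position matches the chord-distance closed form and the
           50% transmission crossing", {
  geom <- default_geom
  cs0 <- leaf_cross_section(geom, 0, 15)
  xp0 <- physical_position(geom, cs0)
  expect_equal(as.numeric(xp0), 0.009446, tolerance = 1e-4)
  expect_equal(as.numeric(xp0), oracle_chord_distance(geom, cs0),
               tolerance = 1e-9)
  expect_identical(attr(xp0, "case"), "arc-arc")
  # the secant chord has length L and both ends on the arc
  sec <- attr(xp0, "secant")
  L <- half_value_layer(geom$mu)
  expect_equal(sqrt(sum((sec$A - sec$B)^2)), L, tolerance = 1e-9)
  expect_equal(sum((sec$A - c(15, 54))^2), 225, tolerance = 1e-8)

  # vanishing half-value layer degenerates to the light-field edge
  geom_hi <- treatment_geometry(mu = 5000)
  cs_hi <- leaf_cross_section(geom_hi, 5, 15)
  expect_equal(as.numeric(physical_position(geom_hi, cs_hi)),
               geometric_position(geom_hi, cs_hi), tolerance = 1e-3)

  # full grid against the independent transmission oracle
  for (R in grid_radii) {
    for (xn in grid_nominals) {
      csg <- leaf_cross_section(geom, xn, R)
      expect_equal(as.numeric(physical_position(geom, csg)),
                   oracle_halfway_transmission(geom, csg), tolerance = 1e-4,
                   label = sprintf("physical edge R=%g xn=%g", R, xn))
    }
  }
})

test_that("flat-face secant branches are used where the arc chord leaves the slab", {
  geom <- default_geom
  expect_identical(attr(physical_position(geom, leaf_cross_section(geom, -20, 25)),
                        "case"), "proximal-flat")
  expect_identical(attr(physical_position(geom, leaf_cross_section(geom, 20, 25)),
                        "case"), "distal-flat")
})

test_that("offsets satisfy the additive identity and the study's shape claims", {
  geom <- default_geom
  pos <- leaf_positions(geom, 10, 15)
  o <- compute_offsets(pos)
  expect_identical(o$pno, o$lpo + o$rfo)
  expect_equal(o$lpo, (pos$x_geometric - pos$x_nominal) * 10)
  expect_equal(o$rfo, (pos$x_physical - pos$x_geometric) * 10)

  # central-axis leaf: zero LPO, RFO ~ 0.094 mm
  o0 <- compute_offsets(leaf_positions(geom, 0, 15))
  expect_equal(o0$lpo, 0, tolerance = 1e-8)
  expect_equal(o0$rfo, 0.094, tolerance = 0.01)

  # RFO is positive over the radius x nominal grid
  tabs <- lapply(grid_radii, function(R) analytic_offset_table(geom, R, grid_nominals))
  rfos <- unlist(lapply(tabs, `[[`, "rfo_mm"))
  expect_true(all(rfos > 0))

  # for R = 15 the RFO curve is nearly flat in the nominal position
  tab15 <- analytic_offset_table(geom, 15, -20:20)
  expect_lt(diff(range(tab15$rfo_mm)), 0.05)
  expect_identical(names(tab15),
                   c("radius_cm", "source_fwhm_mm", "nominal_cm", "x_mech_cm",
                     "x_geom_cm", "x_phys_cm", "lpo_mm", "rfo_mm", "pno_mm"))
})
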