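# Shared fixtures and independent oracles used across the test files.

default_geom <- treatment_geometry()

grid_radii <- c(4, 6, 8, 10, 15, 20, 25)
grid_nominals <- c(-20, -10, 0, 10, 20)

# Light-field edge oracle: project a dense sampling of the whole leaf outline
# (field-facing arc plus top/bottom flat faces) from the point source onto
# the scoring plane and take the minimum. Independent of the tangent-line
# construction.
oracle_min_projection <- function(geom, cs, n = 1e5) {
  stopifnot(cs$bank == "right")
  z_arc <- seq(cs$z_bottom, cs$z_top, length.out = n)
  x_arc <- cs$center[["x"]] - sqrt(cs$radius^2 - (z_arc - cs$center[["z"]])^2)
  x_flat <- seq(cs$corner_u[["x"]], cs$corner_u[["x"]] + cs$body_extent,
                length.out = 200)
  xs <- c(x_arc, x_flat, x_flat)
  zs <- c(z_arc, rep(cs$z_top, 200), rep(cs$z_bottom, 200))
  min(xs * geom$sad / (geom$sad - zs))
}

# Radiation-field edge oracle: the scoring position where a single ray from
# the on-axis point source is attenuated to exactly 50%, found by root
# finding on the exact transmission exp(-mu * path). Independent of the
# secant (half-value-layer chord) construction.
oracle_halfway_transmission <- function(geom, cs) {
  g <- geometric_position(geom, cs)
  f <- function(x0) exp(-geom$mu * path_length(cs, ray(0, x0))) - 0.5
  stats::uniroot(f, c(g - 1e-6, g + 3), tol = 1e-12)$root
}

# Closed-form chord-distance oracle for the pure arc-arc case: the secant is
# the line through the source at perpendicular distance sqrt(R^2 - (L/2)^2)
# from the arc center, on the field side; solve for its scoring intercept
# directly from the point-line distance formula.
oracle_chord_distance <- function(geom, cs) {
  L <- half_value_layer(geom$mu)
  h <- sqrt(cs$radius^2 - (L / 2)^2)
  S <- c(0, geom$sad)
  C <- c(cs$center[["x"]], cs$center[["z"]])
  dist_to_line <- function(x0) {
    d <- c(x0, 0) - S
    abs(d[1] * (C[2] - S[2]) - d[2] * (C[1] - S[1])) / sqrt(sum(d^2))
  }
  g <- geometric_position(geom, cs)
  stats::uniroot(function(x0) dist_to_line(x0) - h, c(g - 1e-9, g + 3),
                 tol = 1e-12)$root
}

# Path-length oracle: locate the ray's entry/exit points using only the
# pointwise inside-the-leaf indicator (scan + bisection refinement), then sum
# the inside-interval lengths. Independent of the interval arithmetic in
# path_length().
oracle_path_scan <- function(cs, source_x, scoring_x, n_scan = 4000) {
  stopifnot(cs$bank == "right")
  sad <- cs$source_z
  inside <- function(t) {
    x <- source_x + t * (scoring_x - source_x)
    z <- sad * (1 - t)
    in_slab <- z >= cs$z_bottom & z <= cs$z_top
    behind <- x <= cs$center[["x"]] + cs$body_extent
    in_disk <- (x - cs$center[["x"]])^2 + (z - cs$center[["z"]])^2 <= cs$radius^2
    in_slab & behind & (in_disk | x >= cs$center[["x"]])
  }
  t_lo <- (sad - cs$z_top) / sad
  t_hi <- (sad - cs$z_bottom) / sad
  tg <- seq(t_lo - 1e-9, t_hi + 1e-9, length.out = n_scan)
  ind <- inside(tg)
  flips <- which(ind[-1] != ind[-n_scan])
  refine <- function(a, b) {  # bisect an indicator transition
    for (i in 1:60) {
      m <- (a + b) / 2
      if (inside(m) == inside(a)) a <- m else b <- m
    }
    (a + b) / 2
  }
  cuts <- vapply(flips, function(i) refine(tg[i], tg[i + 1]), 0)
  bounds <- sort(c(if (ind[1]) tg[1], cuts, if (ind[n_scan]) tg[n_scan]))
  seglen <- sqrt((scoring_x - source_x)^2 + sad^2)
  if (length(bounds) == 0) return(0)
  sum(bounds[seq(2, length(bounds), by = 2)] -
        bounds[seq(1, length(bounds), by = 2)]) * seglen
}
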