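# Analytical leaf-edge constructions: the tangent (light-field) edge and the
# half-value-layer (radiation-field) edge, both for a point source on the
# axis, plus the LPO / RFO / PNO offset bookkeeping.

#' Half-value layer of the leaf material
#'
#' The material thickness that halves the primary beam intensity,
#' `L = -ln(0.5) / mu`.
#'
#' @param mu linear attenuation coefficient, 1/cm.
#' @return Thickness, cm.
#' @examples
#' half_value_layer(0.96)   # 0.7220 cm
#' half_value_layer(log(2)) # exactly 1
#' @export
half_value_layer <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("mu must be positive and finite", call. = FALSE)
  }
  -log(0.5) / mu
}

#' Grazing-ray tangent point on the leaf outline
#'
#' Finds the field-side point of the leaf outline whose ray from the point
#' source grazes the outline: the arc tangency satisfying the perpendicularity
#' condition (the source-to-tangent direction is orthogonal to the arc radius)
#' when its height falls inside the leaf slab, otherwise the proximal corner U
#' (if the unclamped tangency lies above the slab, or the source is inside the
#' arc circle) or the distal corner V (if it lies below).
#'
#' @param geom a [treatment_geometry()].
#' @param cs a [leaf_cross_section()].
#' @return Named numeric `c(x, z)` with attribute `clamped` equal to
#'   `"none"`, `"proximal"` or `"distal"`.
#' @export
tangent_point <- function(geom, cs) {
  stopifnot(inherits(geom, "treatment_geometry"),
            inherits(cs, "leaf_cross_section"))
  can <- as_canonical(cs)
  res <- tangent_point_canonical(geom, can)
  if (cs$bank == "left") res$point[["x"]] <- -res$point[["x"]]
  structure(res$point, clamped = res$clamped)
}

tangent_point_canonical <- function(geom, can) {
  S <- c(0, geom$sad)
  C <- c(can$center[["x"]], can$center[["z"]])
  R <- can$radius
  w <- C - S
  D <- sqrt(sum(w^2))
  corner <- function(z, how) list(point = c(x = can$corner_u[["x"]], z = z),
                                  clamped = how)
  if (D <= R) return(corner(can$z_top, "proximal"))
  # tangency points of the two tangent lines from S to the arc circle
  f <- D^2 - R^2
  perp <- c(-w[2], w[1])
  k1 <- S + (f / D^2) * w + (R * sqrt(f) / D^2) * perp
  k2 <- S + (f / D^2) * w - (R * sqrt(f) / D^2) * perp
  cand <- Filter(function(p) p[1] < C[1], list(k1, k2))
  if (length(cand) == 0L) {
    stop("numerical failure: no field-side tangency found", call. = FALSE)
  }
  proj <- vapply(cand, function(p) p[1] * geom$sad / (geom$sad - p[2]), 0)
  K <- cand[[which.min(proj)]]
  if (K[2] > can$z_top) corner(can$z_top, "proximal")
  else if (K[2] < can$z_bottom) corner(can$z_bottom, "distal")
  else list(point = c(x = K[1], z = K[2]), clamped = "none")
}

#' Geometric leaf position (light-field edge)
#'
#' Projects the grazing-ray tangent point from the source onto the scoring
#' plane, `x_G = x_T * sad / (sad - z_T)`. This equals the minimum over the
#' whole leaf outline of the source projection onto the scoring plane, i.e.
#' the light-field edge.
#'
#' @inheritParams tangent_point
#' @return Position on the scoring plane, cm.
#' @export
geometric_position <- function(geom, cs) {
  tp <- tangent_point(geom, cs)
  tp[["x"]] * geom$sad / (geom$sad - tp[["z"]])
}

# intersections of the line through S with direction d and the circle (C, R);
# returns the two points ordered by decreasing z, or NULL
line_circle_points <- function(S, d, C, R) {
  e <- S - C
  a <- sum(d^2)
  b <- 2 * sum(d * e)
  cc <- sum(e^2) - R^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  p1 <- S + t1 * d
  p2 <- S + t2 * d
  if (p1[2] >= p2[2]) list(A = p1, B = p2) else list(A = p2, B = p1)
}

# closed-form arc-arc secant: the line through S at perpendicular distance
# h = sqrt(R^2 - (L/2)^2) from C cuts a chord of length L out of the arc
# circle; of the two such lines take the field-side one (smaller scoring
# intercept). Returns list(A, B) or NULL when the source is inside the circle.
chord_distance_secant <- function(geom, can, L) {
  S <- c(0, geom$sad)
  C <- c(can$center[["x"]], can$center[["z"]])
  R <- can$radius
  if (L / 2 >= R) stop("half-value layer exceeds the arc diameter", call. = FALSE)
  h <- sqrt(R^2 - (L / 2)^2)
  w <- C - S
  D <- sqrt(sum(w^2))
  if (D <= h) return(NULL)
  f <- D^2 - h^2
  perp <- c(-w[2], w[1])
  k1 <- S + (f / D^2) * w + (h * sqrt(f) / D^2) * perp
  k2 <- S + (f / D^2) * w - (h * sqrt(f) / D^2) * perp
  intercept <- function(K) S[1] + (K[1] - S[1]) * S[2] / (S[2] - K[2])
  K <- if (intercept(k1) < intercept(k2)) k1 else k2
  line_circle_points(S, K - S, C, R)
}

# damped Newton iteration on a square system
newton_solve <- function(fun, jac, x0, tol = 1e-12, max_iter = 100L) {
  x <- x0
  fx <- fun(x)
  for (i in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) {
      return(list(x = x, residual = max(abs(fx)), converged = TRUE, iter = i - 1L))
    }
    step <- tryCatch(solve(jac(x), fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- fun(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
    x <- xn
    fx <- fn
  }
  list(x = x, residual = max(abs(fx)), converged = max(abs(fx)) < tol, iter = NA)
}

#' Physical leaf position (radiation-field edge, half-value-layer rule)
#'
#' Finds the scoring-plane intercept of the secant line through the point
#' source whose in-leaf path equals the half-value layer `L`, so the primary
#' transmission along it is exactly 50%. The secant endpoints A (proximal) and
#' B (distal) are first sought on the arc; if the arc solution leaves the leaf
#' slab, A moves onto the proximal flat face (`z_A = z_top`) or B onto the
#' distal flat face (`z_B = z_bottom`) and the system is re-solved. The
#' stacked nonlinear system (circle memberships, collinearity with the source,
#' chord length `L`) is solved by damped Newton iteration initialised from the
#' closed-form chord-distance construction, and the result is verified against
#' the exact [path_length()] of the secant ray.
#'
#' @inheritParams tangent_point
#' @return Position on the scoring plane, cm, with attributes `case`
#'   (`"arc-arc"`, `"proximal-flat"` or `"distal-flat"`), `secant` (the A and
#'   B endpoints) and `path_residual` (|path - L|, cm).
#' @examples
#' geom <- treatment_geometry()
#' physical_position(geom, leaf_cross_section(geom, 0, 15))  # ~0.0094 cm
#' @export
physical_position <- function(geom, cs) {
  stopifnot(inherits(geom, "treatment_geometry"),
            inherits(cs, "leaf_cross_section"))
  can <- as_canonical(cs)
  L <- half_value_layer(geom$mu)
  sol <- physical_secant_canonical(geom, can, L)
  x_p <- sol$B[1] * geom$sad / (geom$sad - sol$B[2])
  # post-hoc check against the exact ray path through the full outline
  resid <- abs(path_length(can, ray(0, x_p)) - L)
  if (resid > 1e-6) {
    stop(sprintf(paste0("numerical failure in physical_position: secant path ",
                        "differs from the half-value layer by %.3g cm ",
                        "(case %s, nominal %.4g, R %.4g)"),
                 resid, sol$case, can$nominal_x, can$radius), call. = FALSE)
  }
  if (cs$bank == "left") {
    x_p <- -x_p
    sol$A[1] <- -sol$A[1]
    sol$B[1] <- -sol$B[1]
  }
  structure(x_p, case = sol$case, secant = list(A = sol$A, B = sol$B),
            path_residual = resid)
}

physical_secant_canonical <- function(geom, can, L) {
  S <- c(0, geom$sad)
  C <- c(can$center[["x"]], can$center[["z"]])
  R <- can$radius
  D <- sqrt(sum((C - S)^2))
  tol_z <- 1e-9

  arc_arc <- function() {
    init <- chord_distance_secant(geom, can, L)
    if (is.null(init)) return(NULL)
    u0 <- c(init$A, init$B)
    fun <- function(u) {
      A <- u[1:2]; B <- u[3:4]
      c(sum((A - C)^2) - R^2,
        sum((B - C)^2) - R^2,
        (A[2] - S[2]) * (B[1] - S[1]) - (B[2] - S[2]) * (A[1] - S[1]),
        sum((A - B)^2) - L^2)
    }
    jac <- function(u) {
      A <- u[1:2]; B <- u[3:4]
      rbind(c(2 * (A - C), 0, 0),
            c(0, 0, 2 * (B - C)),
            c(-(B[2] - S[2]), B[1] - S[1], A[2] - S[2], -(A[1] - S[1])),
            c(2 * (A - B), -2 * (A - B)))
    }
    ns <- newton_solve(fun, jac, u0)
    if (!ns$converged) return(NULL)
    list(A = ns$x[1:2], B = ns$x[3:4], case = "arc-arc")
  }

  # A on the proximal flat face, B on the arc: unknowns (x_A, x_B, z_B)
  flat_proximal <- function(init_B) {
    zA <- can$z_top
    fun <- function(u) {
      A <- c(u[1], zA); B <- u[2:3]
      c(sum((B - C)^2) - R^2,
        (A[2] - S[2]) * (B[1] - S[1]) - (B[2] - S[2]) * (A[1] - S[1]),
        sum((A - B)^2) - L^2)
    }
    jac <- function(u) {
      A <- c(u[1], zA); B <- u[2:3]
      rbind(c(0, 2 * (B - C)),
            c(-(B[2] - S[2]), A[2] - S[2], -(A[1] - S[1])),
            c(2 * (A[1] - B[1]), -2 * (A - B)))
    }
    xA0 <- S[1] + (init_B[1] - S[1]) * (S[2] - zA) / (S[2] - init_B[2])
    ns <- newton_solve(fun, jac, c(xA0, init_B))
    if (!ns$converged) return(NULL)
    B <- ns$x[2:3]
    # reject spurious branches: B must sit on the field-facing arc inside the slab
    if (B[2] > can$z_top + tol_z || B[2] < can$z_bottom - tol_z ||
        B[1] >= C[1]) return(NULL)
    list(A = c(ns$x[1], zA), B = B, case = "proximal-flat")
  }

  # B on the distal flat face, A on the arc: unknowns (x_A, z_A, x_B)
  flat_distal <- function(init_A) {
    zB <- can$z_bottom
    fun <- function(u) {
      A <- u[1:2]; B <- c(u[3], zB)
      c(sum((A - C)^2) - R^2,
        (A[2] - S[2]) * (B[1] - S[1]) - (B[2] - S[2]) * (A[1] - S[1]),
        sum((A - B)^2) - L^2)
    }
    jac <- function(u) {
      A <- u[1:2]; B <- c(u[3], zB)
      rbind(c(2 * (A - C), 0),
            c(-(B[2] - S[2]), B[1] - S[1], A[2] - S[2]),
            c(2 * (A - B), -2 * (A[1] - B[1])))
    }
    xB0 <- S[1] + (init_A[1] - S[1]) * (S[2] - zB) / (S[2] - init_A[2])
    ns <- newton_solve(fun, jac, c(init_A, xB0))
    if (!ns$converged) return(NULL)
    A <- ns$x[1:2]
    if (A[2] > can$z_top + tol_z || A[2] < can$z_bottom - tol_z ||
        A[1] >= C[1]) return(NULL)
    list(A = A, B = c(ns$x[3], zB), case = "distal-flat")
  }

  sol <- if (D > R) arc_arc() else NULL
  if (!is.null(sol) && sol$A[2] <= can$z_top + tol_z &&
      sol$B[2] >= can$z_bottom - tol_z) {
    return(sol)
  }
  # seed the flat-face solvers from a field-facing arc point inside the slab,
  # half a chord below/above the corner
  arc_point <- function(z) c(C[1] - sqrt(R^2 - (z - C[2])^2), z)
  if (is.null(sol) || sol$A[2] > can$z_top + tol_z) {
    init_B <- arc_point(max(can$z_top - L / 2, can$center[["z"]]))
    sol2 <- flat_proximal(init_B)
    if (!is.null(sol2)) return(sol2)
  } else if (sol$B[2] < can$z_bottom - tol_z) {
    init_A <- arc_point(min(can$z_bottom + L / 2, can$center[["z"]]))
    sol2 <- flat_distal(init_A)
    if (!is.null(sol2)) return(sol2)
  }
  stop("numerical failure: half-value-layer secant solver did not converge",
       call. = FALSE)
}

#' All four leaf positions for one configuration
#'
#' Computes the mechanical tip position E on the leaf middle plane, and the
#' nominal N, geometric G and physical P positions on the scoring plane, for
#' one leaf.
#'
#' @inheritParams tangent_point
#' @param nominal_x nominal leaf position, cm.
#' @param radius leaf-end arc radius, cm.
#' @param bank `"right"` or `"left"`.
#' @return An object of class `leaf_positions` with fields `x_nominal`,
#'   `x_mechanical`, `x_geometric`, `x_physical`, `tangent_point` and
#'   `secant_points`.
#' @export
leaf_positions <- function(geom, nominal_x, radius, bank = "right") {
  cs <- leaf_cross_section(geom, nominal_x, radius, bank = bank)
  tp <- tangent_point(geom, cs)
  xg <- geometric_position(geom, cs)
  xp <- physical_position(geom, cs)
  structure(list(
    x_nominal = nominal_x,
    x_mechanical = cs$x_mechanical,
    x_geometric = xg,
    x_physical = as.numeric(xp),
    tangent_point = tp,
    secant_points = attr(xp, "secant"),
    radius = radius,
    bank = cs$bank
  ), class = "leaf_positions")
}

#' @export
print.leaf_positions <- function(x, ...) {
  cat(sprintf("Leaf positions (%s bank, R = %.4g cm), cm:\n", x$bank, x$radius))
  cat(sprintf("  N = %.5g  E = %.5g  G = %.5g  P = %.5g\n",
              x$x_nominal, x$x_mechanical, x$x_geometric, x$x_physical))
  o <- compute_offsets(x)
  cat(sprintf("  LPO = %.4g mm  RFO = %.4g mm  PNO = %.4g mm\n",
              o$lpo, o$rfo, o$pno))
  invisible(x)
}

#' Leaf-position, radiation-field and physical-nominal offsets
#'
#' The three calibration offsets in millimetres: leaf position offset
#' `LPO = x_G - x_N`, radiation field offset `RFO = x_P - x_G`, and
#' physical-nominal offset `PNO = x_P - x_N = LPO + RFO`. The identity
#' `pno = lpo + rfo` holds exactly by construction.
#'
#' @param positions a [leaf_positions()] object.
#' @return An object of class `mlc_offsets` with fields `lpo`, `rfo`, `pno`
#'   (mm).
#' @export
compute_offsets <- function(positions) {
  stopifnot(inherits(positions, "leaf_positions"))
  lpo <- (positions$x_geometric - positions$x_nominal) * 10
  rfo <- (positions$x_physical - positions$x_geometric) * 10
  structure(list(lpo = lpo, rfo = rfo, pno = lpo + rfo),
            class = "mlc_offsets")
}

new_offsets <- function(lpo, rfo) {
  structure(list(lpo = lpo, rfo = rfo, pno = lpo + rfo), class = "mlc_offsets")
}

#' @export
print.mlc_offsets <- function(x, ...) {
  cat(sprintf("Offsets (mm): LPO = %.4g  RFO = %.4g  PNO = %.4g\n",
              x$lpo, x$rfo, x$pno))
  invisible(x)
}

#' @export
mirror.mlc_offsets <- function(x) {
  new_offsets(-x$lpo, -x$rfo)
}

#' Analytic leaf-position table over a range of nominal positions
#'
#' Runs the tangent and half-value-layer constructions for one leaf-end radius
#' across a sequence of nominal positions and tabulates positions (cm) and
#' offsets (mm).
#'
#' @inheritParams tangent_point
#' @param radius leaf-end arc radius, cm.
#' @param nominals nominal positions, cm.
#' @return A data.frame with columns `radius_cm`, `source_fwhm_mm` (NA for
#'   the analytic point-source method), `nominal_cm`, `x_mech_cm`,
#'   `x_geom_cm`, `x_phys_cm`, `lpo_mm`, `rfo_mm`, `pno_mm`.
#' @examples
#' tab <- analytic_offset_table(treatment_geometry(), 15, c(-10, 0, 10))
#' mean(tab$rfo_mm)
#' @export
analytic_offset_table <- function(geom, radius, nominals = -20:20) {
  rows <- lapply(nominals, function(xn) {
    pos <- leaf_positions(geom, xn, radius)
    o <- compute_offsets(pos)
    data.frame(radius_cm = radius, source_fwhm_mm = NA_real_, nominal_cm = xn,
               x_mech_cm = pos$x_mechanical, x_geom_cm = pos$x_geometric,
               x_phys_cm = pos$x_physical,
               lpo_mm = o$lpo, rfo_mm = o$rfo, pno_mm = o$pno)
  })
  do.call(rbind, rows)
}
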