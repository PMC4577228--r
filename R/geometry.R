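# Coordinate frame: origin at the isocenter, z increasing toward the source,
# source on the axis at (0, sad); the scoring plane is z = 0 and the leaf
# (collimator) middle plane is z = sad - scd. All internal lengths are cm.

#' Treatment-head geometry
#'
#' Bundles the machine constants of a single-focused MLC treatment head:
#' source-to-axis distance (SAD), source-to-collimator distance (SCD, measured
#' to the leaf middle plane), source-to-diaphragm distance (SDD, informational
#' only), leaf height, the linear attenuation coefficient of the leaf material,
#' and the maximum half field size on the scoring plane. Defaults describe a
#' conventional linac head with 8 cm tungsten leaves and a monoenergetic
#' attenuation coefficient of 0.96 per cm.
#'
#' @param sad source-to-axis distance, cm.
#' @param scd source-to-collimator (leaf middle plane) distance, cm.
#' @param sdd source-to-diaphragm distance, cm (not used in calculations).
#' @param leaf_height leaf height along z, cm.
#' @param mu linear attenuation coefficient of the leaf material, 1/cm.
#' @param max_half_field maximum half field size on the scoring plane, cm.
#' @return An object of class `treatment_geometry`.
#' @examples
#' geom <- treatment_geometry()
#' geom$sad - geom$scd  # z of the leaf middle plane
#' @export
treatment_geometry <- function(sad = 100, scd = 46, sdd = 33.9,
                               leaf_height = 8, mu = 0.96,
                               max_half_field = 20) {
  stopifnot(is.numeric(sad), is.numeric(scd), is.numeric(sdd),
            is.numeric(leaf_height), is.numeric(mu), is.numeric(max_half_field))
  if (!(sad > scd && scd > 0)) {
    stop("invalid geometry: need sad > scd > 0", call. = FALSE)
  }
  if (leaf_height <= 0) stop("leaf_height must be positive", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  z_mid <- sad - scd
  if (!(z_mid > 0 && z_mid < sad)) {
    stop("leaf middle plane must lie strictly between scoring plane and source",
         call. = FALSE)
  }
  if (z_mid - leaf_height / 2 <= 0 || z_mid + leaf_height / 2 >= sad) {
    stop("leaf slab must lie strictly between scoring plane and source",
         call. = FALSE)
  }
  structure(list(sad = sad, scd = scd, sdd = sdd,
                 leaf_height = leaf_height, mu = mu,
                 max_half_field = max_half_field,
                 source_z = sad),
            class = "treatment_geometry")
}

#' @export
print.treatment_geometry <- function(x, ...) {
  cat("Treatment-head geometry (cm, 1/cm):\n")
  cat(sprintf("  SAD %.4g  SCD %.4g  SDD %.4g\n", x$sad, x$scd, x$sdd))
  cat(sprintf("  leaf height %.4g  mu %.4g  max half field %.4g\n",
              x$leaf_height, x$mu, x$max_half_field))
  cat(sprintf("  leaf middle plane z = %.4g, slab z in [%.4g, %.4g]\n",
              x$sad - x$scd,
              x$sad - x$scd - x$leaf_height / 2,
              x$sad - x$scd + x$leaf_height / 2))
  invisible(x)
}

# short id string used as profile provenance metadata
geometry_signature <- function(geom) {
  paste0("sad", geom$sad, "_scd", geom$scd, "_lh", geom$leaf_height,
         "_mu", geom$mu)
}

#' Read or write a treatment-geometry configuration file
#'
#' Geometry files are YAML or JSON (chosen by file extension) with keys
#' `sad_cm`, `scd_cm`, `sdd_cm`, `leaf_height_cm`, `mu_per_cm`,
#' `max_half_field_cm`. Missing keys fall back to the defaults of
#' [treatment_geometry()].
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_geometry` returns a `treatment_geometry`; `write_geometry`
#'   invisibly returns `path`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported geometry file extension: .", ext, call. = FALSE))
  defaults <- formals(treatment_geometry)
  val <- function(key, default) if (!is.null(cfg[[key]])) as.numeric(cfg[[key]]) else default
  treatment_geometry(
    sad = val("sad_cm", defaults$sad),
    scd = val("scd_cm", defaults$scd),
    sdd = val("sdd_cm", defaults$sdd),
    leaf_height = val("leaf_height_cm", defaults$leaf_height),
    mu = val("mu_per_cm", defaults$mu),
    max_half_field = val("max_half_field_cm", defaults$max_half_field)
  )
}

#' @rdname read_geometry
#' @param geom a `treatment_geometry`.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "treatment_geometry"))
  cfg <- list(sad_cm = geom$sad, scd_cm = geom$scd, sdd_cm = geom$sdd,
              leaf_height_cm = geom$leaf_height, mu_per_cm = geom$mu,
              max_half_field_cm = geom$max_half_field)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(cfg, path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA),
         stop("unsupported geometry file extension: .", ext, call. = FALSE))
  invisible(path)
}

#' Construct a rounded-end leaf cross-section
#'
#' Builds the 2-D outline of one leaf in the x-z plane: a circular-arc tip of
#' radius `radius` spanning the full leaf height, flat proximal (top) and
#' distal (bottom) faces, and a finite body extending behind the tip. The
#' mechanical tip position on the leaf middle plane is the back-projection of
#' the nominal position, `x_E = nominal_x * scd / sad`, and the arc center sits
#' one radius behind it, `x_C = x_E + radius` (right bank; the left bank is the
#' mirror image).
#'
#' @param geom a [treatment_geometry()].
#' @param nominal_x nominal leaf position on the scoring plane, cm.
#' @param radius leaf-end arc radius, cm; must be at least half the leaf
#'   height so the arc spans the full leaf height.
#' @param bank `"right"` (body toward +x, canonical) or `"left"`.
#' @param body_extent x-extent of the leaf body behind the tip, cm. The
#'   transmission floor through the full leaf height makes the exact value
#'   irrelevant beyond a few cm.
#' @return An object of class `leaf_cross_section` with the arc `center`
#'   (named x, z), `radius`, `z_top`, `z_bottom`, corner points `corner_u`
#'   (proximal) and `corner_v` (distal), `bank` and `nominal_x`.
#' @examples
#' cs <- leaf_cross_section(treatment_geometry(), nominal_x = 10, radius = 15)
#' cs$center  # (19.6, 54)
#' @export
leaf_cross_section <- function(geom, nominal_x, radius,
                               bank = c("right", "left"), body_extent = 20) {
  stopifnot(inherits(geom, "treatment_geometry"),
            is.numeric(nominal_x), length(nominal_x) == 1L,
            is.numeric(radius), length(radius) == 1L)
  bank <- match.arg(bank)
  lh <- geom$leaf_height
  if (radius < lh / 2) {
    stop(sprintf(paste0("unsupported geometry: radius %.4g cm is smaller than ",
                        "half the leaf height (%.4g cm); the arc does not span ",
                        "the leaf height"), radius, lh / 2), call. = FALSE)
  }
  if (body_extent <= 0) stop("body_extent must be positive", call. = FALSE)
  # canonical right-bank construction; the left bank mirrors it
  n_can <- if (bank == "right") nominal_x else -nominal_x
  x_e <- n_can * geom$scd / geom$sad
  z_c <- geom$sad - geom$scd
  x_c <- x_e + radius
  x_corner <- x_c - sqrt(radius^2 - (lh / 2)^2)
  sgn <- if (bank == "right") 1 else -1
  structure(list(
    center = c(x = sgn * x_c, z = z_c),
    radius = radius,
    z_top = z_c + lh / 2,
    z_bottom = z_c - lh / 2,
    body_extent = body_extent,
    bank = bank,
    nominal_x = nominal_x,
    x_mechanical = sgn * x_e,
    corner_u = c(x = sgn * x_corner, z = z_c + lh / 2),
    corner_v = c(x = sgn * x_corner, z = z_c - lh / 2),
    source_z = geom$sad
  ), class = "leaf_cross_section")
}

#' @export
print.leaf_cross_section <- function(x, ...) {
  cat(sprintf("Leaf cross-section (%s bank): nominal %.4g cm, R = %.4g cm\n",
              x$bank, x$nominal_x, x$radius))
  cat(sprintf("  arc center (%.4g, %.4g), slab z in [%.4g, %.4g]\n",
              x$center[["x"]], x$center[["z"]], x$z_bottom, x$z_top))
  cat(sprintf("  mechanical tip x = %.4g cm on the middle plane\n",
              x$x_mechanical))
  invisible(x)
}

# canonical (right-bank) view of a cross-section
as_canonical <- function(cs) if (cs$bank == "right") cs else mirror(cs)

#' Field-facing leaf boundary at height z
#'
#' Returns the x-coordinate of the field-facing arc boundary of the leaf
#' outline at height `z`: `x_C - sqrt(R^2 - (z - z_C)^2)` for a right-bank
#' leaf (the mirrored value for the left bank). Vectorised over `z`.
#'
#' @param cs a [leaf_cross_section()].
#' @param z height(s) within the leaf slab, cm.
#' @return Boundary x-position(s), cm.
#' @export
left_boundary <- function(cs, z) {
  stopifnot(inherits(cs, "leaf_cross_section"))
  can <- as_canonical(cs)
  if (any(z < can$z_bottom - 1e-12 | z > can$z_top + 1e-12)) {
    stop(sprintf("z outside leaf slab [%.4g, %.4g]", can$z_bottom, can$z_top),
         call. = FALSE)
  }
  x <- can$center[["x"]] - sqrt(can$radius^2 - (z - can$center[["z"]])^2)
  if (cs$bank == "left") -x else x
}

#' Mirror a leaf configuration about the beam axis
#'
#' Applies the x -> -x symmetry: cross-sections swap bank, numeric positions
#' and offsets change sign. `mirror(mirror(x))` is the identity.
#'
#' @param x a `leaf_cross_section`, `mlc_offsets`, or numeric vector.
#' @return The mirrored object of the same type.
#' @export
mirror <- function(x) UseMethod("mirror")

#' @export
mirror.default <- function(x) {
  if (!is.numeric(x)) stop("cannot mirror object of class ", class(x)[1L],
                           call. = FALSE)
  -x
}

#' @export
mirror.leaf_cross_section <- function(x) {
  x$center[["x"]] <- -x$center[["x"]]
  x$nominal_x <- -x$nominal_x
  x$x_mechanical <- -x$x_mechanical
  x$corner_u[["x"]] <- -x$corner_u[["x"]]
  x$corner_v[["x"]] <- -x$corner_v[["x"]]
  x$bank <- if (x$bank == "right") "left" else "right"
  x
}

#' Beam rays from the source plane to the scoring plane
#'
#' A ray runs from `(source_x, sad)` on the source plane to `(scoring_x, 0)`
#' on the scoring plane. Both arguments are recycled to a common length, so a
#' single `ray()` call can describe a whole fan of rays.
#'
#' @param source_x x-position(s) of the ray origin on the source plane, cm.
#' @param scoring_x x-position(s) targeted on the scoring plane, cm.
#' @return An object of class `beam_ray`.
#' @export
ray <- function(source_x, scoring_x) {
  stopifnot(is.numeric(source_x), is.numeric(scoring_x))
  n <- max(length(source_x), length(scoring_x))
  structure(list(source_x = rep_len(source_x, n),
                 scoring_x = rep_len(scoring_x, n)),
            class = "beam_ray")
}

# intersect two interval sets given as (lo, hi) vectors
interval_cap <- function(a, b) list(lo = pmax(a$lo, b$lo), hi = pmin(a$hi, b$hi))
interval_len <- function(a) pmax(0, a$hi - a$lo)

# half-plane constraint x >= bound (ge = TRUE) or x <= bound along the ray,
# expressed as a t-interval; x(t) = xs + t * dx
halfplane_interval <- function(xs, dx, bound, ge) {
  n <- length(xs)
  lo <- rep(-Inf, n)
  hi <- rep(Inf, n)
  tb <- (bound - xs) / dx
  pos <- dx > 0
  neg <- dx < 0
  if (ge) {
    lo[pos] <- tb[pos]
    hi[neg] <- tb[neg]
    bad <- dx == 0 & xs < bound
  } else {
    hi[pos] <- tb[pos]
    lo[neg] <- tb[neg]
    bad <- dx == 0 & xs > bound
  }
  lo[bad] <- Inf
  hi[bad] <- -Inf
  list(lo = lo, hi = hi)
}

#' Exact ray path length through a leaf cross-section
#'
#' Computes the length of the ray segment inside the leaf outline (arc tip,
#' flat top/bottom faces, finite body) analytically from the circle-line
#' intersection clipped to the leaf slab and body extent. This is the argument
#' of the exponential attenuation law used by the fluence simulator.
#' Vectorised over the rays; rays that miss the leaf return 0.
#'
#' @param cs a [leaf_cross_section()].
#' @param r a [ray()] (or fan of rays).
#' @return Numeric vector of in-leaf path lengths, cm.
#' @examples
#' geom <- treatment_geometry()
#' cs <- leaf_cross_section(geom, 0, 15)
#' path_length(cs, ray(0, -5))    # misses the leaf: 0
#' path_length(cs, ray(18, 18))   # vertical ray through the deep body: 8
#' @export
path_length <- function(cs, r) {
  stopifnot(inherits(cs, "leaf_cross_section"), inherits(r, "beam_ray"))
  can <- as_canonical(cs)
  sgn <- if (cs$bank == "left") -1 else 1
  xs <- sgn * r$source_x
  xt <- sgn * r$scoring_x
  n <- length(xs)
  sad <- can$source_z
  dx <- xt - xs
  seglen <- sqrt(dx^2 + sad^2)
  # P(t) = (xs + t*dx, sad*(1 - t)); t = 0 at the source, 1 at the scoring plane
  slab <- list(lo = rep((sad - can$z_top) / sad, n),
               hi = rep((sad - can$z_bottom) / sad, n))
  behind <- halfplane_interval(xs, dx, can$center[["x"]] + can$body_extent, FALSE)
  right <- halfplane_interval(xs, dx, can$center[["x"]], TRUE)
  # disk |P(t) - C|^2 <= R^2: quadratic in t
  ex <- xs - can$center[["x"]]
  ez <- sad - can$center[["z"]]
  a <- dx^2 + sad^2
  b <- 2 * (dx * ex - sad * ez)
  cc <- ex^2 + ez^2 - can$radius^2
  disc <- b^2 - 4 * a * cc
  has <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  disk <- list(lo = ifelse(has, (-b - sq) / (2 * a), Inf),
               hi = ifelse(has, (-b + sq) / (2 * a), -Inf))
  # region = slab & behind-limit & (disk | right half-plane); inclusion-exclusion
  base <- interval_cap(slab, behind)
  t_disk <- interval_len(interval_cap(base, disk))
  t_right <- interval_len(interval_cap(base, right))
  t_both <- interval_len(interval_cap(interval_cap(base, disk), right))
  (t_disk + t_right - t_both) * seglen
}
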