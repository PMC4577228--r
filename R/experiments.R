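# Sweep orchestration over leaf-end radii, focal-spot sizes and nominal
# positions, plus the synthetic fixture generator used throughout the tests.

#' Sweep configuration
#'
#' Defaults mirror the study conditions: radii 4-25 cm, focal spots 0.5-3 mm
#' FWHM, nominal positions -20 to 20 cm in 1 cm steps.
#'
#' @param radii leaf-end radii, cm.
#' @param fwhms focal-spot FWHM values, mm.
#' @param nominals nominal leaf positions, cm.
#' @param geometry a [treatment_geometry()].
#' @param grid_step profile grid spacing, cm.
#' @param edge_method `"interpolation"` (deterministic profiles) or `"fit"`.
#' @param n_peaks peaks for the mixture fit when `edge_method = "fit"`.
#' @param mode `"quadrature"` or `"montecarlo"` source integration.
#' @param histories montecarlo histories per profile.
#' @param seed base seed (montecarlo mode and fit restarts).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(radii = c(4, 6, 8, 10, 15, 20, 25),
                         fwhms = c(0.5, 1, 2, 3),
                         nominals = -20:20,
                         geometry = treatment_geometry(),
                         grid_step = 0.01,
                         edge_method = c("interpolation", "fit"),
                         n_peaks = 3,
                         mode = c("quadrature", "montecarlo"),
                         histories = 1e5, seed = 1) {
  stopifnot(length(radii) >= 1L, length(fwhms) >= 1L, length(nominals) >= 1L,
            inherits(geometry, "treatment_geometry"))
  if (any(abs(nominals) > geometry$max_half_field)) {
    stop("nominal positions must lie within the maximum half field",
         call. = FALSE)
  }
  structure(list(radii = radii, fwhms = fwhms, nominals = nominals,
                 geometry = geometry, grid_step = grid_step,
                 edge_method = match.arg(edge_method), n_peaks = n_peaks,
                 mode = match.arg(mode), histories = histories, seed = seed),
            class = "sweep_config")
}

#' Run a penumbra / offset sweep
#'
#' For every combination of radius, focal-spot FWHM and nominal position:
#' simulate the primary-fluence profile, extract the 50% edge and the 20-80%
#' penumbra width, compute the analytic geometric and physical edges, and
#' emit one record. Per-record failures are caught, flagged in the `ok`
#' column and reported as a warning; the sweep continues.
#'
#' @param config a [sweep_config()].
#' @return A data.frame with one row per configuration: `radius`, `fwhm`,
#'   `nominal`, `penumbra_width_mm`, `field_edge_cm`, `lpo_mm`,
#'   `rfo_analytic_mm`, `rfo_sim_mm`, `pno_analytic_mm`, `pno_sim_mm`,
#'   `fit_rmse`, `ok`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  geom <- config$geometry
  grid <- expand.grid(nominal = config$nominals, fwhm = config$fwhms,
                      radius = config$radii)
  rows <- vector("list", nrow(grid))
  n_fail <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rows[[i]] <- tryCatch({
      pos <- leaf_positions(geom, g$nominal, g$radius)
      src <- if (config$mode == "quadrature") {
        source_model(g$fwhm)
      } else {
        source_model(g$fwhm, mode = "montecarlo",
                     n_points = config$histories,
                     seed = config$seed + i)
      }
      prof <- simulate_profile(geom, field_config(g$radius, g$nominal), src,
                               grid_step = config$grid_step)
      ea <- analyze_edge(prof, method = config$edge_method,
                         n_peaks = config$n_peaks, seed = config$seed)
      o_sim <- profile_offsets(ea$field_edge, g$nominal, pos$x_geometric)
      o_an <- compute_offsets(pos)
      data.frame(radius = g$radius, fwhm = g$fwhm, nominal = g$nominal,
                 penumbra_width_mm = ea$penumbra_width,
                 field_edge_cm = ea$field_edge,
                 lpo_mm = o_an$lpo,
                 rfo_analytic_mm = o_an$rfo, rfo_sim_mm = o_sim$rfo,
                 pno_analytic_mm = o_an$pno, pno_sim_mm = o_sim$pno,
                 fit_rmse = ea$fit_rmse, ok = TRUE)
    }, error = function(e) {
      n_fail <<- n_fail + 1L
      data.frame(radius = g$radius, fwhm = g$fwhm, nominal = g$nominal,
                 penumbra_width_mm = NA_real_, field_edge_cm = NA_real_,
                 lpo_mm = NA_real_, rfo_analytic_mm = NA_real_,
                 rfo_sim_mm = NA_real_, pno_analytic_mm = NA_real_,
                 pno_sim_mm = NA_real_, fit_rmse = NA_real_, ok = FALSE)
    })
  }
  if (n_fail > 0L) {
    warning(sprintf("%d of %d sweep records failed; see the ok column",
                    n_fail, nrow(grid)), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarise analytic vs simulated offsets per radius
#'
#' Groups sweep records by radius and focal-spot size and summarises the gap
#' between simulated and analytic offsets: mean and maximum
#' `|pno_sim - pno_analytic|` and the mean RFO for each method.
#'
#' @param records output of [run_sweep()].
#' @return A data.frame with one row per (radius, fwhm).
#' @export
compare_analytic_numeric <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("radius", "fwhm", "pno_sim_mm", "pno_analytic_mm") %in%
                  names(records)))
  recs <- records[records$ok %||% TRUE, , drop = FALSE]
  keys <- unique(recs[, c("radius", "fwhm")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- recs$radius == keys$radius[i] & recs$fwhm == keys$fwhm[i]
    r <- recs[sel, ]
    gap <- r$pno_sim_mm - r$pno_analytic_mm
    data.frame(radius = keys$radius[i], fwhm = keys$fwhm[i],
               n = nrow(r),
               mean_abs_pno_gap_mm = mean(abs(gap)),
               max_abs_pno_gap_mm = max(abs(gap)),
               mean_rfo_analytic_mm = mean(r$rfo_analytic_mm),
               mean_rfo_sim_mm = mean(r$rfo_sim_mm),
               mean_rfo_gap_mm = mean(r$rfo_sim_mm - r$rfo_analytic_mm))
  })
  do.call(rbind, rows)
}

# coefficients of the bundled three-peak reference edge fit (published fit of
# a simulated edge profile: R = 10 cm leaf at nominal 10 cm, 2 mm source)
reference_mixture_coefficients <- function() {
  list(amplitude = c(0.406, 0.397, 0.996),
       center = c(9.813, 9.586, 9.054),
       width = c(0.169, 0.269, 0.668))
}

#' Bundled reference edge mixture
#'
#' The three-peak Gaussian mixture whose nine coefficients reproduce a
#' published fit of a simulated field-edge profile (10 cm leaf-end radius,
#' nominal position 10 cm, 2 mm FWHM source). Its 50% crossing sits near
#' 9.932 cm with a 20-80% penumbra width near 1.98 mm; it serves as a fixed,
#' fully specified worked example for the edge-analysis operations.
#'
#' @return A [gaussian_mixture()] with a default search window attribute of
#'   `c(9, 10.5)` cm.
#' @examples
#' gm <- reference_mixture()
#' find_crossing(gm, 0.5)
#' @export
reference_mixture <- function() {
  co <- reference_mixture_coefficients()
  gm <- gaussian_mixture(co$amplitude, co$center, co$width)
  attr(gm, "window") <- c(9, 10.5)
  gm
}

#' Generate a synthetic profile fixture
#'
#' Deterministic (seeded) synthetic profiles with known ground truth, used
#' for testing the analysis stage:
#' \describe{
#'   \item{`erf_edge`}{a Gaussian-blurred step (complementary error function
#'     shape) with edge position `edge` (cm) and blur `sigma_mm`, plus
#'     additive Gaussian noise `noise_sd`; the true 50% edge and 20-80% width
#'     are stored in the metadata.}
#'   \item{`step`}{an ideal step at `edge`.}
#'   \item{`reference_mixture`}{the bundled [reference_mixture()] rendered on
#'     its window.}
#' }
#'
#' @param kind fixture kind.
#' @param params named list of overrides: `edge`, `sigma_mm`, `noise_sd`,
#'   `window` (half-width, cm), `step` (grid spacing, cm).
#' @param seed seed for the noise.
#' @return A [fluence_profile()] with ground truth in `meta`.
#' @export
generate_fixture <- function(kind = c("erf_edge", "step", "reference_mixture"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(edge = 0, sigma_mm = 1, noise_sd = 0.005,
                              window = 3, step = 0.01), params)
  if (kind == "reference_mixture") {
    gm <- reference_mixture()
    xs <- seq(9, 10.5, by = 0.001)
    return(fluence_profile(xs, evaluate_mixture(gm, xs),
                           meta = list(kind = kind, normalized = TRUE,
                                       nominal_edge = 10)))
  }
  xs <- seq(p$edge - p$window, p$edge + p$window, by = p$step)
  if (kind == "step") {
    v <- as.numeric(xs < p$edge)
    meta <- list(kind = kind, edge_cm = p$edge, penumbra_mm = 0,
                 normalized = FALSE, seed = seed)
    return(fluence_profile(xs, v, meta))
  }
  sigma_cm <- p$sigma_mm / 10
  v <- stats::pnorm(-(xs - p$edge) / sigma_cm)
  v <- v + with_local_seed(seed, stats::rnorm(length(xs), 0, p$noise_sd))
  meta <- list(kind = kind, edge_cm = p$edge, sigma_mm = p$sigma_mm,
               penumbra_mm = 2 * stats::qnorm(0.8) * p$sigma_mm,
               noise_sd = p$noise_sd, seed = seed, normalized = FALSE)
  fluence_profile(xs, pmax(v, 0), meta)
}
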