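#' Gamma-index analysis of two dose grids
#'
#' For every evaluated point above the low-dose threshold, the gamma index
#' is the minimum over the reference search neighbourhood of
#' `sqrt((dose difference / dose criterion)^2 + (distance / distance
#' criterion)^2)`, with sub-pixel interpolation of the reference; the gamma
#' passing rate (GPR) is the percentage of evaluated points with gamma <= 1.
#' Both grids are planar matrices or 3D arrays that share the physical
#' position of their first pixel centre.
#'
#' Defaults follow portal-dosimetry convention: global normalization to the
#' reference maximum and a 10% low-dose threshold; the search radius is 3x
#' the distance criterion with a search step of `dist_mm / 10` in 2D
#' (`dist_mm / 2` in 3D, where the exhaustive search grows cubically).
#'
#' @param reference Reference dose, matrix or 3D array.
#' @param evaluated Evaluated dose, same dimensionality.
#' @param dose_pct Dose-difference criterion, percent (e.g. 3).
#' @param dist_mm Distance-to-agreement criterion, mm (e.g. 2).
#' @param ref_spacing_mm,eval_spacing_mm Grid spacings (length 2 or 3), mm.
#' @param threshold_pct Low-dose threshold as a percentage of the reference
#'   maximum; points below it are excluded (default 10).
#' @param mode `"global"` (criterion anchored to the reference maximum) or
#'   `"local"`.
#' @param search_factor Search radius as a multiple of `dist_mm` (default 3).
#' @param step_mm Search step; default `dist_mm / 10` (2D) or `dist_mm / 2`
#'   (3D).
#' @return Object of class `gamma_result`: list with `gamma` (array of gamma
#'   values, `NA` below threshold), `gpr_pct`, `criteria`, `threshold_pct`,
#'   `mode`, `n_evaluated`.
#' @export
gamma_index <- function(reference, evaluated, dose_pct = 3, dist_mm = 2,
                        ref_spacing_mm = c(2.5, 2.5),
                        eval_spacing_mm = ref_spacing_mm,
                        threshold_pct = 10, mode = c("global", "local"),
                        search_factor = 3, step_mm = NULL) {
  mode <- match.arg(mode)
  stopifnot(dose_pct > 0, dist_mm > 0)
  rdim <- dim(reference)
  edim <- dim(evaluated)
  if (is.null(rdim) || is.null(edim))
    stop("reference and evaluated must be matrices or 3D arrays")
  nd <- length(rdim)
  if (nd != length(edim)) stop("reference and evaluated dimensionality differ")
  if (length(ref_spacing_mm) != nd || length(eval_spacing_mm) != nd)
    stop("spacing length must match grid dimensionality")
  if (any(ref_spacing_mm <= 0) || any(eval_spacing_mm <= 0))
    stop("spacings must be positive")
  rmax <- max(reference)
  if (rmax <= 0) stop("reference dose is not positive")
  thresh_abs <- threshold_pct / 100 * rmax
  if (all(evaluated < thresh_abs))
    stop("all evaluated points fall below the low-dose threshold")
  crit_abs <- dose_pct / 100 * rmax
  search_mm <- search_factor * dist_mm
  if (is.null(step_mm)) step_mm <- if (nd == 2) dist_mm / 10 else dist_mm / 2
  args <- list(as.numeric(reference), as.integer(rdim),
               as.numeric(ref_spacing_mm), as.numeric(evaluated),
               as.integer(edim), as.numeric(eval_spacing_mm), crit_abs,
               dist_mm, search_mm, step_mm, mode == "local", dose_pct / 100,
               thresh_abs)
  g <- if (nd == 2) do.call(.gamma2d_cpp, args) else do.call(.gamma3d_cpp, args)
  g <- array(g, dim = edim)
  n_eval <- sum(!is.na(g))
  # gamma = 1 passes; tolerance absorbs float rounding at the boundary
  gpr <- 100 * sum(g <= 1 + 1e-9, na.rm = TRUE) / n_eval
  structure(list(gamma = g, gpr_pct = gpr,
                 criteria = c(dose_pct = dose_pct, dist_mm = dist_mm),
                 threshold_pct = threshold_pct, mode = mode,
                 n_evaluated = n_eval),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (%s), GPR %.2f%% over %d points\n",
              x$criteria["dose_pct"], x$criteria["dist_mm"], x$mode,
              x$gpr_pct, x$n_evaluated))
  invisible(x)
}

#' Two-tier per-field gamma pass report
#'
#' Applies the primary criteria to every field; fields failing the pass-rate
#' threshold are re-evaluated at the fallback criteria (the two-tier
#' commissioning workflow). Summarizes mean and SD of the primary GPR.
#'
#' @param fields Named list of `list(reference =, evaluated =)` planar dose
#'   pairs, or precomputed [gamma_index()] results.
#' @param dose_pct,dist_mm Primary criteria (default 3%/2 mm).
#' @param fallback_dose_pct,fallback_dist_mm Fallback criteria (default
#'   2%/4 mm).
#' @param pass_pct GPR required to pass a field, percent (default 95).
#' @param ... Passed on to [gamma_index()] (spacings, threshold, mode).
#' @return Object of class `field_pass_report`: list with `fields` (tibble:
#'   field, gpr_pct, pass, fallback_gpr_pct, fallback_pass), `mean_gpr`,
#'   `sd_gpr`, `pass_pct`, criteria.
#' @export
field_pass_report <- function(fields, dose_pct = 3, dist_mm = 2,
                              fallback_dose_pct = 2, fallback_dist_mm = 4,
                              pass_pct = 95, ...) {
  stopifnot(length(fields) >= 1)
  nms <- names(fields)
  if (is.null(nms)) nms <- paste0("field", seq_along(fields))
  rows <- purrr::map2(fields, nms, function(fd, nm) {
    g1 <- if (inherits(fd, "gamma_result")) fd else
      gamma_index(fd$reference, fd$evaluated, dose_pct, dist_mm, ...)
    pass <- g1$gpr_pct >= pass_pct
    fb_gpr <- NA_real_
    fb_pass <- NA
    if (!pass && !inherits(fd, "gamma_result")) {
      g2 <- gamma_index(fd$reference, fd$evaluated, fallback_dose_pct,
                        fallback_dist_mm, ...)
      fb_gpr <- g2$gpr_pct
      fb_pass <- fb_gpr >= pass_pct
    }
    tibble::tibble(field = nm, gpr_pct = g1$gpr_pct, pass = pass,
                   fallback_gpr_pct = fb_gpr, fallback_pass = fb_pass)
  })
  tab <- dplyr::bind_rows(rows)
  structure(list(fields = tab, mean_gpr = mean(tab$gpr_pct),
                 sd_gpr = stats::sd(tab$gpr_pct), pass_pct = pass_pct,
                 criteria = c(dose_pct = dose_pct, dist_mm = dist_mm),
                 fallback = c(dose_pct = fallback_dose_pct,
                              dist_mm = fallback_dist_mm)),
            class = "field_pass_report")
}

#' @export
print.field_pass_report <- function(x, ...) {
  n_fail <- sum(!x$fields$pass)
  cat(sprintf(
    "<field_pass_report> %d fields at %g%%/%g mm: GPR %.1f +/- %.1f%%, %d failing (fallback %g%%/%g mm)\n",
    nrow(x$fields), x$criteria["dose_pct"], x$criteria["dist_mm"],
    x$mean_gpr, if (is.na(x$sd_gpr)) 0 else x$sd_gpr, n_fail,
    x$fallback["dose_pct"], x$fallback["dist_mm"]))
  invisible(x)
}

#' @export
tidy.field_pass_report <- function(x, ...) x$fields

#' @export
glance.field_pass_report <- function(x, ...) {
  tibble::tibble(n_fields = nrow(x$fields), mean_gpr = x$mean_gpr,
                 sd_gpr = x$sd_gpr, n_fail = sum(!x$fields$pass),
                 n_fallback_pass = sum(x$fields$fallback_pass, na.rm = TRUE),
                 pass_pct = x$pass_pct)
}

#' Synthesize a planar portal dose from the dose engine
#'
#' Runs one beam's fluence through the dose engine on a homogeneous
#' water-slab phantom and extracts the dose plane through the isocenter
#' perpendicular to the beam — a stand-in for a portal-imager measurement
#' used to exercise the QA chain.
#'
#' @param fm A [fluence_map()].
#' @param slab_mm Slab thickness along the beam, mm (default 200).
#' @param extent_mm Lateral slab extent, mm (default 340).
#' @param spacing_mm Isotropic voxel size of the slab grid, mm (default 2.5).
#' @param sad_mm Source-axis distance, mm.
#' @param engine_params Passed to [compute_dose()].
#' @return List with `plane` (matrix, fluence-grid shape) and `spacing_mm`.
#' @export
portal_plane <- function(fm, slab_mm = 200, extent_mm = 340,
                         spacing_mm = 2.5, sad_mm = 1000,
                         engine_params = list()) {
  stopifnot(inherits(fm, "fluence_map"))
  n_xy <- ceiling(extent_mm / spacing_mm)
  n_z <- ceiling(slab_mm / spacing_mm)
  d <- c(n_xy, n_z, n_xy)  # beam along +y (gantry 0)
  hu <- array(0, dim = d)  # water
  origin <- -(d - 1) * spacing_mm / 2
  ct <- voxel_volume(hu, rep(spacing_mm, 3), origin, unit = "HU")
  body <- array(TRUE, dim = d)
  ss <- structure_set(ct, list(BODY = body), c(BODY = "BODY"))
  tpl <- beam_template(c(0, 0, 0), 0, sad_mm = sad_mm)
  fm1 <- fluence_map(fm$values, fm$grid, beam = 1L, clipped = fm$clipped)
  dose <- compute_dose(ct, ss, tpl, list(fm1), engine_params)
  iy <- which.min(abs(axis_coords(ct)[[2]]))
  plane_x <- axis_coords(ct)[[1]]
  plane_z <- axis_coords(ct)[[3]]
  # resample onto the fluence grid (u maps to +x, v to +z at gantry 0)
  plane <- matrix(0, fm$grid$n_pixels, fm$grid$n_pixels)
  for (j in seq_along(fm$grid$v))
    for (i in seq_along(fm$grid$u))
      plane[i, j] <- plane_val(dose$values[, iy, ], plane_x, plane_z,
                               fm$grid$u[i], fm$grid$v[j])
  list(plane = plane, spacing_mm = rep(fm$grid$pixel_mm, 2))
}

plane_val <- function(m, xs, zs, x, z) {
  i <- findInterval(x, xs, all.inside = TRUE)
  j <- findInterval(z, zs, all.inside = TRUE)
  ax <- (x - xs[i]) / (xs[i + 1] - xs[i])
  az <- (z - zs[j]) / (zs[j + 1] - zs[j])
  ax <- min(max(ax, 0), 1)
  az <- min(max(az, 0), 1)
  m[i, j] * (1 - ax) * (1 - az) + m[i + 1, j] * ax * (1 - az) +
    m[i, j + 1] * (1 - ax) * az + m[i + 1, j + 1] * ax * az
}
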