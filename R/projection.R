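#' Fluence-map grid geometry
#'
#' The standard fluence/projection grid: 128 x 128 pixels of 2.5 x 2.5 mm in
#' the isocenter plane, centred on the beam axis. Pixel (i, j) sits at
#' in-plane coordinates `u = (i - (n+1)/2) * px`, `v = (j - (n+1)/2) * px`.
#'
#' @param n_pixels Pixels per side (default 128).
#' @param pixel_mm Pixel size, mm (default 2.5).
#' @return List with `n_pixels`, `pixel_mm`, and the `u`/`v` pixel-centre
#'   coordinate vectors (mm).
#' @export
fluence_grid <- function(n_pixels = 128, pixel_mm = 2.5) {
  stopifnot(n_pixels >= 1, pixel_mm > 0)
  cc <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_mm
  list(n_pixels = as.integer(n_pixels), pixel_mm = pixel_mm, u = cc, v = cc)
}

# world positions (n^2 x 3) of all pixel centres for one beam
pixel_positions <- function(grid, isocenter_mm, gantry_deg, sad_mm) {
  fr <- beam_frame(isocenter_mm, gantry_deg, sad_mm)
  uu <- rep(grid$u, times = grid$n_pixels)
  vv <- rep(grid$v, each = grid$n_pixels)
  t(isocenter_mm + outer(fr$u, uu) + outer(fr$v, vv))
}

#' Convert HU to relative electron density
#'
#' Piecewise-linear two-segment table: density 0 at -1000 HU rising to 1 at
#' 0 HU (air to water), then 1 + HU/1950 above (soft tissue to bone),
#' clamped at 0.
#'
#' @param hu Numeric HU values.
#' @return Relative electron densities (water = 1).
#' @export
hu_to_density <- function(hu) {
  d <- ifelse(hu <= 0, 1 + hu / 1000, 1 + hu / 1950)
  pmax(d, 0)
}

#' Trace a ray through a voxel grid
#'
#' Exact incremental (Siddon-style) voxel traversal of the ray from `source`
#' through `target`, extended through the whole volume. Segment lengths sum
#' to the in-volume chord length.
#'
#' @param volume A [voxel_volume()].
#' @param source_mm Ray origin (outside the volume), mm.
#' @param target_mm A point the ray passes through (e.g. a fluence pixel), mm.
#' @return Tibble with `voxel` (1-based linear index), `length_mm`,
#'   `t_start_mm`, `t_end_mm`, ordered from the source; zero rows if the ray
#'   misses the volume.
#' @export
trace_ray <- function(volume, source_mm, target_mm) {
  stopifnot(inherits(volume, "voxel_volume"))
  df <- .trace_ray_cpp(dim(volume$values), volume$spacing_mm,
                       volume$origin_mm, as.numeric(source_mm),
                       as.numeric(target_mm))
  tibble::as_tibble(df)
}

project_channel <- function(ct, mask, body, template, beam, grid, mode,
                            density = NULL) {
  if (is.null(density)) density <- hu_to_density(ct$values)
  fr <- beam_frame(template$isocenter_mm, template$gantry_deg[beam],
                   template$sad_mm)
  pix <- pixel_positions(grid, template$isocenter_mm,
                         template$gantry_deg[beam], template$sad_mm)
  vals <- .bev_project_cpp(as.numeric(density), dim(ct$values),
                           ct$spacing_mm, ct$origin_mm, fr$source, pix,
                           as.logical(mask), as.logical(body),
                           if (mode == "intra") 0L else 1L)
  matrix(vals, grid$n_pixels, grid$n_pixels)
}

#' Intra-structure BEV projection
#'
#' Line integral of CT-derived density along each pixel's divergent ray,
#' restricted to voxels inside the structure mask; zero where the ray misses
#' the mask.
#'
#' @param ct CT [voxel_volume()] (HU).
#' @param mask Logical structure mask on the CT grid.
#' @param template A [beam_template()].
#' @param beam Beam index (1-based).
#' @param grid A [fluence_grid()].
#' @return `n_pixels` x `n_pixels` numeric matrix (u along rows, v along
#'   columns).
#' @export
intra_projection <- function(ct, mask, template, beam,
                             grid = fluence_grid()) {
  stopifnot(identical(dim(mask), dim(ct$values)))
  project_channel(ct, mask, mask, template, beam, grid, "intra")
}

#' Interface BEV projection
#'
#' Line integral of CT-derived density along each pixel's ray from the first
#' body-entry point to the last exit point of the structure; zero if the ray
#' misses the structure.
#'
#' @inheritParams intra_projection
#' @param structure_mask Logical structure mask.
#' @param body_mask Logical BODY mask.
#' @return Numeric matrix as in [intra_projection()].
#' @export
interface_projection <- function(ct, structure_mask, body_mask, template,
                                 beam, grid = fluence_grid()) {
  stopifnot(identical(dim(structure_mask), dim(ct$values)),
            identical(dim(body_mask), dim(ct$values)))
  project_channel(ct, structure_mask, body_mask, template, beam, grid,
                  "interface")
}

#' Build the 12-channel anatomical projection stack for one beam
#'
#' Interface projections for the ten standard structures plus intra-structure
#' projections for PTV and CTV, on the fluence grid, each channel
#' max-normalized to `[0, 1]` (all-zero channels stay zero).
#'
#' @param ct CT [voxel_volume()].
#' @param structures A [structure_set()] carrying the standard ten structures
#'   and BODY.
#' @param template A [beam_template()].
#' @param beam Beam index (1-based).
#' @param grid A [fluence_grid()] (default 128 x 128 at 2.5 mm).
#' @param normalize Max-normalize each channel (default `TRUE`).
#' @return Object of class `projection_stack`: list with `channels` (named
#'   list of matrices), `grid`, `beam`, `gantry_deg`.
#' @export
build_stack <- function(ct, structures, template, beam,
                        grid = fluence_grid(), normalize = TRUE) {
  check_standard_set(structures)
  body <- structures$masks[["BODY"]]
  density <- hu_to_density(ct$values)
  channels <- list()
  for (nm in hn_standard_structures()) {
    channels[[paste0("interface:", nm)]] <-
      project_channel(ct, structures$masks[[nm]], body, template, beam, grid,
                      "interface", density = density)
  }
  for (nm in c("PTV", "CTV")) {
    channels[[paste0("intra:", nm)]] <-
      project_channel(ct, structures$masks[[nm]], body, template, beam, grid,
                      "intra", density = density)
  }
  if (normalize) {
    channels <- lapply(channels, function(ch) {
      m <- max(ch)
      if (m > 0) ch / m else ch
    })
  }
  structure(list(channels = channels, grid = grid, beam = beam,
                 gantry_deg = template$gantry_deg[beam]),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> beam %d (gantry %g), %d channels, %dx%d @ %g mm\n",
              x$beam, x$gantry_deg, length(x$channels), x$grid$n_pixels,
              x$grid$n_pixels, x$grid$pixel_mm))
  invisible(x)
}

#' Build projection stacks for every beam of a template
#'
#' @inheritParams build_stack
#' @return List of [build_stack()] results, one per beam.
#' @export
build_stacks <- function(ct, structures, template, grid = fluence_grid(),
                         normalize = TRUE) {
  lapply(seq_along(template$gantry_deg), function(b)
    build_stack(ct, structures, template, b, grid, normalize))
}
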