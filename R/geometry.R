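#' Beam template: isocenter, gantry angles, per-beam jaws
#'
#' @param isocenter_mm Length-3 isocenter in patient coordinates, mm.
#' @param gantry_deg Ordered gantry angles on the IEC scale, `[0, 360)`.
#' @param jaws_mm Matrix with one row per beam and columns `x1, x2, y1, y2`
#'   (mm in the isocenter plane, BEV frame), or `NULL` for an unset template.
#' @param sad_mm Source-axis distance, mm (default 1000, a standard linac).
#' @return Object of class `beam_template`.
#' @export
beam_template <- function(isocenter_mm, gantry_deg, jaws_mm = NULL,
                          sad_mm = 1000) {
  isocenter_mm <- as.numeric(isocenter_mm)
  stopifnot(length(isocenter_mm) == 3L, sad_mm > 0)
  gantry_deg <- as.numeric(gantry_deg) %% 360
  if (anyDuplicated(gantry_deg)) stop("gantry angles must be unique")
  if (!is.null(jaws_mm)) {
    jaws_mm <- as.matrix(jaws_mm)
    if (nrow(jaws_mm) != length(gantry_deg) || ncol(jaws_mm) != 4L)
      stop("`jaws_mm` must be a (n_beams x 4) matrix")
    colnames(jaws_mm) <- c("x1", "x2", "y1", "y2")
    if (any(jaws_mm[, 1] >= jaws_mm[, 2]) || any(jaws_mm[, 3] >= jaws_mm[, 4]))
      stop("jaws require x1 < x2 and y1 < y2")
  }
  structure(list(isocenter_mm = isocenter_mm, gantry_deg = gantry_deg,
                 jaws_mm = jaws_mm, sad_mm = sad_mm),
            class = "beam_template")
}

#' @export
print.beam_template <- function(x, ...) {
  cat(sprintf("<beam_template> %d beams, SAD %g mm, isocenter (%s) mm\n",
              length(x$gantry_deg), x$sad_mm,
              paste(format(x$isocenter_mm), collapse = ", ")))
  cat("  gantry:", paste(x$gantry_deg, collapse = ", "), "\n")
  if (!is.null(x$jaws_mm)) {
    cat("  jaws (x1, x2, y1, y2) mm:\n")
    for (b in seq_len(nrow(x$jaws_mm)))
      cat(sprintf("   %5.1f: %s\n", x$gantry_deg[b],
                  paste(sprintf("%7.1f", x$jaws_mm[b, ]), collapse = " ")))
  }
  invisible(x)
}

#' Beam coordinate frame for a gantry angle
#'
#' IEC gantry scale: at 0 deg the source is anterior of the patient and the
#' beam travels anterior-to-posterior; at 90 deg the source is at the
#' patient's left. Returns the source position, the unit beam direction, and
#' the in-plane BEV axes (u transverse, v = superior).
#'
#' @param isocenter_mm Isocenter, mm.
#' @param gantry_deg Gantry angle, degrees.
#' @param sad_mm Source-axis distance, mm.
#' @return List with `source`, `dir`, `u`, `v`.
#' @export
beam_frame <- function(isocenter_mm, gantry_deg, sad_mm = 1000) {
  g <- gantry_deg * pi / 180
  src_dir <- c(sin(g), -cos(g), 0)
  list(source = isocenter_mm + sad_mm * src_dir,
       dir = -src_dir,
       u = c(cos(g), sin(g), 0),
       v = c(0, 0, 1))
}

#' Divergent BEV projection of mask voxel centres onto the isocenter plane
#'
#' @param volume Reference [voxel_volume()].
#' @param mask Logical array on the volume grid.
#' @param isocenter_mm Isocenter, mm.
#' @param gantry_deg Gantry angle, degrees.
#' @param sad_mm Source-axis distance, mm.
#' @return Matrix with columns `u`, `v` (mm in the isocenter plane).
#' @export
bev_points <- function(volume, mask, isocenter_mm, gantry_deg, sad_mm = 1000) {
  fr <- beam_frame(isocenter_mm, gantry_deg, sad_mm)
  p <- mask_coords(volume, mask)
  r <- sweep(p, 2, isocenter_mm, `-`)
  depth <- as.numeric(r %*% fr$dir)
  scale <- sad_mm / (sad_mm + depth)
  cbind(u = as.numeric(r %*% fr$u) * scale, v = r[, 3] * scale)
}

#' Automatic isocenter placement
#'
#' Places the isocenter at the centroid of the PTV with the highest
#' prescription (the boost when present). If that point lies more than
#' `max_shift_mm` from the primary PTV's centroid, the primary centroid is
#' used instead, so the beam divergence stays close to template conditions.
#' Each coordinate, expressed relative to the CT origin, is rounded to the
#' nearest `round_mm` for patient-setup convenience.
#'
#' @param structures A [structure_set()] with at least one prescribed PTV.
#' @param max_shift_mm Fallback distance threshold, mm (default 25).
#' @param round_mm Rounding step per coordinate, mm (default 5).
#' @return Length-3 isocenter, mm.
#' @export
place_isocenter <- function(structures, max_shift_mm = 25, round_mm = 5) {
  ptvs <- structures_with_role(structures, "PTV")
  if (!length(ptvs)) stop("no PTV-role structure present")
  rx <- structures$rx_gy[ptvs]
  if (length(ptvs) > 1L) {
    if (any(is.na(rx))) stop("multiple PTVs but prescriptions missing")
    top <- ptvs[rx == max(rx)]
    if (length(top) > 1L)
      stop("tie in highest prescription across PTVs: ",
           paste(top, collapse = ", "), " (disambiguate manually)")
  }
  highest <- if (length(ptvs) == 1L) ptvs else ptvs[which.max(rx)]
  vol <- structures$volume
  c_high <- mask_centroid(vol, structures$masks[[highest]])
  prim <- primary_ptv(structures)
  c_prim <- mask_centroid(vol, structures$masks[[prim]])
  target <- if (sqrt(sum((c_high - c_prim)^2)) > max_shift_mm) c_prim else c_high
  o <- vol$origin_mm
  o + round((target - o) / round_mm) * round_mm
}

#' Standard gantry layout
#'
#' Evenly spaced gantry angles starting at `start_deg` and advancing
#' counterclockwise (decreasing IEC angle, the conventional evenly spaced
#' head-and-neck layout); set `direction = "cw"` for the opposite sense.
#'
#' @param n_beams Number of beams (default 9).
#' @param start_deg First gantry angle (default 180).
#' @param step_deg Angular spacing, degrees (default 40).
#' @param direction `"ccw"` (decreasing IEC angle) or `"cw"`.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
place_beams <- function(n_beams = 9, start_deg = 180, step_deg = 40,
                        direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  stopifnot(n_beams >= 1, step_deg > 0)
  if (n_beams * step_deg > 360)
    stop("beam layout exceeds a full rotation")
  sgn <- if (direction == "ccw") -1 else 1
  (start_deg + sgn * step_deg * (seq_len(n_beams) - 1)) %% 360
}

#' Per-beam collimator jaw fitting
#'
#' For each beam the jaws are the bounding box of the PTV's divergent BEV
#' projection expanded by `margin_mm`. For beams whose field intersects a
#' shoulder landmark's BEV projection, the inferior jaw edge is raised to the
#' most-superior extent of that projection plus `shoulder_clearance_mm` —
#' mimicking a planner balancing beam entrance through the shoulders against
#' PTV coverage — but never so far that less than `min_coverage` of the PTV's
#' projected points remain in the field.
#'
#' @param structures A [structure_set()] with PTV, BODY and landmark masks.
#' @param template A [beam_template()] (jaws may be unset).
#' @param margin_mm Margin added around the PTV BEV bounding box (default 7).
#' @param shoulder_clearance_mm Clearance above the shoulder-top projection
#'   (default 5).
#' @param min_coverage Minimum retained fraction of projected PTV points
#'   (default 0.98).
#' @param max_field_mm Maximum allowed jaw opening per axis (default 400).
#' @return The template with `jaws_mm` filled in.
#' @export
fit_jaws <- function(structures, template, margin_mm = 7,
                     shoulder_clearance_mm = 5, min_coverage = 0.98,
                     max_field_mm = 400) {
  stopifnot(inherits(template, "beam_template"))
  vol <- structures$volume
  ptvs <- structures_with_role(structures, "PTV")
  if (!length(ptvs)) stop("no PTV-role structure present")
  ptv_mask <- Reduce(`|`, structures$masks[ptvs])
  shoulder_names <- intersect(structures_with_role(structures, "LANDMARK"),
                              grep("^Shoulder", names(structures$masks),
                                   value = TRUE))
  half_vox <- max(vol$spacing_mm) / 2
  jaws <- matrix(NA_real_, length(template$gantry_deg), 4,
                 dimnames = list(NULL, c("x1", "x2", "y1", "y2")))
  for (b in seq_along(template$gantry_deg)) {
    g <- template$gantry_deg[b]
    pts <- bev_points(vol, ptv_mask, template$isocenter_mm, g, template$sad_mm)
    x1 <- min(pts[, "u"]) - half_vox - margin_mm
    x2 <- max(pts[, "u"]) + half_vox + margin_mm
    y1 <- min(pts[, "v"]) - half_vox - margin_mm
    y2 <- max(pts[, "v"]) + half_vox + margin_mm
    if ((x2 - x1) > max_field_mm || (y2 - y1) > max_field_mm)
      stop(sprintf("beam %g: PTV BEV projection exceeds maximum field size", g))
    for (sn in shoulder_names) {
      if (!any(structures$masks[[sn]])) next
      sh <- bev_points(vol, structures$masks[[sn]], template$isocenter_mm, g,
                       template$sad_mm)
      in_field <- sh[, "u"] >= x1 & sh[, "u"] <= x2 &
        sh[, "v"] >= y1 & sh[, "v"] <= y2
      if (!any(in_field)) next
      candidate <- max(sh[in_field, "v"]) + half_vox + shoulder_clearance_mm
      # cap: keep at least min_coverage of the projected PTV points
      floor_v <- unname(quantile(pts[, "v"], 1 - min_coverage, type = 7))
      candidate <- min(candidate, floor_v)
      y1 <- max(y1, candidate)  # shoulder rule only ever raises the edge
    }
    jaws[b, ] <- c(x1, x2, y1, y2)
  }
  beam_template(template$isocenter_mm, template$gantry_deg, jaws,
                template$sad_mm)
}

#' Build the standard 9-beam template for a structure set
#'
#' Convenience wrapper: [place_isocenter()], [place_beams()], [fit_jaws()].
#'
#' @inheritParams fit_jaws
#' @param n_beams,start_deg,step_deg Gantry layout, see [place_beams()].
#' @param sad_mm Source-axis distance, mm.
#' @return A [beam_template()] with jaws fitted.
#' @export
auto_template <- function(structures, n_beams = 9, start_deg = 180,
                          step_deg = 40, sad_mm = 1000, margin_mm = 7,
                          shoulder_clearance_mm = 5) {
  iso <- place_isocenter(structures)
  tpl <- beam_template(iso, place_beams(n_beams, start_deg, step_deg),
                       sad_mm = sad_mm)
  fit_jaws(structures, tpl, margin_mm = margin_mm,
           shoulder_clearance_mm = shoulder_clearance_mm)
}

#' Serialize a beam template to / from JSON
#'
#' @param template A [beam_template()].
#' @param path JSON file path.
#' @return `read_plan()` returns a [beam_template()].
#' @export
write_plan <- function(template, path) {
  stopifnot(inherits(template, "beam_template"))
  obj <- list(isocenter_mm = template$isocenter_mm,
              gantry_deg = template$gantry_deg,
              sad_mm = template$sad_mm,
              jaws_mm = if (is.null(template$jaws_mm)) NULL else
                apply(template$jaws_mm, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  jaws <- NULL
  if (!is.null(obj$jaws_mm)) {
    jaws <- if (is.data.frame(obj$jaws_mm)) t(as.matrix(obj$jaws_mm)) else
      do.call(rbind, lapply(obj$jaws_mm, unlist))
    if (nrow(jaws) != length(obj$gantry_deg)) jaws <- t(jaws)
  }
  beam_template(obj$isocenter_mm, obj$gantry_deg, jaws, obj$sad_mm)
}
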