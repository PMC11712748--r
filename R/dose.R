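#' Simplified forward dose engine
#'
#' Maps per-beam fluence maps to a 3D dose grid. Each fluence pixel deposits
#' primary dose along its divergent ray as
#' `fluence * exp(-mu * radiological depth) * (SAD / r)^2`, where the
#' radiological depth is the density line integral reusing the projection ray
#' tracer, followed by a 3D Gaussian lateral-scatter convolution and
#' restriction to the BODY mask (dilated by a small buildup margin). This is
#' a deliberately simple, clearly labelled stand-in for a clinical dose
#' algorithm: linear in fluence, additive over beams, and reproducible, but
#' with no claim to clinical accuracy.
#'
#' Engine parameters (`engine_params`): `mu` attenuation coefficient per mm
#' water-equivalent (default 0.005), `scatter_sigma_mm` Gaussian scatter
#' sigma (default 4; 0 disables), `min_density` deposition gate (default
#' 0.1), `body_dilate_vox` buildup margin in voxels (default 2),
#' `output_factor` global calibration scalar (default 1).
#'
#' @param ct CT [voxel_volume()] (HU).
#' @param structures A [structure_set()] with a BODY mask.
#' @param template A [beam_template()].
#' @param fluences List of [fluence_map()], one per template beam.
#' @param engine_params Named list of overrides, see above.
#' @return A [voxel_volume()] with unit `"Gy"` and attribute `"engine"`
#'   recording the parameters used.
#' @export
compute_dose <- function(ct, structures, template, fluences,
                         engine_params = list()) {
  p <- modifyList(list(mu = 0.005, scatter_sigma_mm = 4, min_density = 0.1,
                       body_dilate_vox = 2, output_factor = 1),
                  engine_params)
  if (length(fluences) != length(template$gantry_deg))
    stop("need one fluence map per template beam")
  body <- structures$masks[["BODY"]]
  if (is.null(body)) stop("structure set has no BODY mask")
  if (!identical(dim(body), dim(ct$values)))
    stop("CT and structure grids do not match")
  density <- hu_to_density(ct$values)
  dims <- dim(ct$values)
  dose <- numeric(prod(dims))
  for (b in seq_along(fluences)) {
    fm <- fluences[[b]]
    stopifnot(inherits(fm, "fluence_map"))
    if (all(fm$values == 0)) next
    fr <- beam_frame(template$isocenter_mm, template$gantry_deg[b],
                     template$sad_mm)
    pix <- pixel_positions(fm$grid, template$isocenter_mm,
                           template$gantry_deg[b], template$sad_mm)
    dose <- dose + .deposit_dose_cpp(as.numeric(density), dims,
                                     ct$spacing_mm, ct$origin_mm, fr$source,
                                     pix, as.numeric(fm$values), p$mu,
                                     template$sad_mm, p$min_density)
  }
  if (p$scatter_sigma_mm > 0)
    dose <- .gauss_blur3_cpp(dose, dims, p$scatter_sigma_mm / ct$spacing_mm)
  dose <- array(p$output_factor * dose, dim = dims)
  keep <- dilate_mask(body, p$body_dilate_vox)
  dose[!keep] <- 0
  out <- voxel_volume(dose, ct$spacing_mm, ct$origin_mm, unit = "Gy")
  attr(out, "engine") <- p
  out
}

# box dilation by k voxels along each axis
dilate_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) {
    acc <- out
    for (s in seq_len(k)) {
      lo <- shift_arr(out, ax, s)
      hi <- shift_arr(out, ax, -s)
      acc <- acc | lo | hi
    }
    out <- acc
  }
  out
}

shift_arr <- function(a, ax, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[ax]
  if (by > 0) {
    src[[ax]] <- c(rep(1L, by), seq_len(n - by))
  } else {
    src[[ax]] <- c(seq_len(n)[-seq_len(-by)], rep(n, -by))
  }
  out <- do.call(`[`, c(list(a), src))
  pad <- abs(by)
  blank <- if (by > 0) seq_len(pad) else n - pad + seq_len(pad)
  sel <- idx
  sel[[ax]] <- blank
  do.call(`[<-`, c(list(out), sel, list(FALSE)))
}

#' Normalize a dose grid to the prescription
#'
#' Scales the dose by a single scalar so that the PTV's D95% equals the
#' prescription exactly: 95% of the PTV volume receives at least `rx_gy`.
#' D95% is found by linear interpolation on the sorted voxel doses
#' (equivalently, inversion of the cumulative DVH).
#'
#' @param dose Dose [voxel_volume()] (Gy).
#' @param ptv_mask Logical PTV mask.
#' @param rx_gy Prescription dose, Gy (default 44).
#' @return The scaled dose volume, with attribute `"norm_scale"`.
#' @export
normalize_to_prescription <- function(dose, ptv_mask, rx_gy = 44) {
  stopifnot(inherits(dose, "voxel_volume"))
  dv <- dose$values[ptv_mask]
  if (!length(dv)) stop("PTV mask is empty")
  if (all(dv == 0)) stop("dose is zero everywhere in the PTV")
  d95 <- unname(quantile(dv, 0.05, type = 7))
  s <- rx_gy / d95
  out <- voxel_volume(dose$values * s, dose$spacing_mm, dose$origin_mm,
                      unit = "Gy")
  attr(out, "engine") <- attr(dose, "engine")
  attr(out, "norm_scale") <- s
  out
}

#' Rescale a plan's prescription
#'
#' Linear rescaling used to pool plans prescribed at different dose levels:
#' every voxel is multiplied by `to_gy / from_gy` (50 Gy plans scaled down
#' to 44 Gy for pooled statistics).
#'
#' @param dose Dose [voxel_volume()] (Gy).
#' @param from_gy Original prescription (default 50).
#' @param to_gy Target prescription (default 44).
#' @return Rescaled dose volume.
#' @export
rescale_prescription <- function(dose, from_gy = 50, to_gy = 44) {
  stopifnot(inherits(dose, "voxel_volume"), from_gy > 0, to_gy > 0)
  out <- voxel_volume(dose$values * (to_gy / from_gy), dose$spacing_mm,
                      dose$origin_mm, unit = "Gy")
  attr(out, "engine") <- attr(dose, "engine")
  out
}

#' Relative monitor-unit proxy
#'
#' `calibration * sum over beams of max(fluence)`: a relative proxy for the
#' total monitor units of a plan (peak fluence per beam drives beam-on time),
#' not a clinical MU calculation.
#'
#' @param fluences List of [fluence_map()].
#' @param calibration Scalar calibration factor (default 1).
#' @return Scalar proxy value.
#' @export
total_mu_proxy <- function(fluences, calibration = 1) {
  calibration * sum(vapply(fluences, function(f) max(f$values), numeric(1)))
}
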