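#' Cumulative dose-volume histogram
#'
#' Voxel-counted cumulative DVH on a uniform dose axis: for each dose grid
#' point, the percentage of the structure's volume receiving at least that
#' dose. The curve starts at 100% at 0 Gy and is non-increasing.
#'
#' @param dose Dose [voxel_volume()] (Gy).
#' @param mask Logical structure mask (non-empty).
#' @param bin_gy Dose bin width, Gy (default 0.1).
#' @param max_gy Upper end of the dose axis; defaults to the structure
#'   maximum plus one bin.
#' @param structure Optional structure name carried into the output.
#' @return Tibble of class `dvh_curve` with columns `structure`, `dose_gy`,
#'   `volume_pct`.
#' @export
dvh <- function(dose, mask, bin_gy = 0.1, max_gy = NULL,
                structure = NA_character_) {
  stopifnot(inherits(dose, "voxel_volume"))
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask shape does not match the dose grid")
  dv <- dose$values[mask]
  if (!length(dv)) stop("mask is empty")
  if (is.null(max_gy)) max_gy <- max(dv) + bin_gy
  axis <- seq(0, max_gy, by = bin_gy)
  n <- length(dv)
  vol <- vapply(axis, function(d) 100 * sum(dv >= d) / n, numeric(1))
  out <- tibble::tibble(structure = structure, dose_gy = axis,
                        volume_pct = vol)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' DVHs for every structure of a set
#'
#' @inheritParams dvh
#' @param structures A [structure_set()]; landmarks and BODY are skipped
#'   unless `include` names them.
#' @param include Structure names to evaluate (default: all PTV/CTV/OAR-role
#'   structures).
#' @return Tibble with one [dvh()] block per structure, on a shared axis.
#' @export
dvh_all <- function(dose, structures, bin_gy = 0.1, include = NULL) {
  if (is.null(include))
    include <- names(structures$roles)[structures$roles %in%
                                         c("PTV", "CTV", "OAR")]
  max_gy <- max(dose$values) + bin_gy
  out <- dplyr::bind_rows(lapply(include, function(nm)
    dvh(dose, structures$masks[[nm]], bin_gy, max_gy, structure = nm)))
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Conformity index
#'
#' Ratio of the prescription isodose volume to the PTV volume. By
#' convention the isodose volume is measured over the BODY (or the whole
#' grid when no body mask is given); set `within` to a PTV mask for the
#' target-only variant.
#'
#' @param dose Dose [voxel_volume()] (Gy).
#' @param ptv_mask Logical PTV mask.
#' @param rx_gy Prescription dose, Gy.
#' @param within Logical mask over which the isodose volume is counted
#'   (default: everywhere).
#' @return Scalar CI (> 0 for any plan with prescription coverage).
#' @export
conformity_index <- function(dose, ptv_mask, rx_gy, within = NULL) {
  stopifnot(inherits(dose, "voxel_volume"))
  v <- dose$values
  sel <- v >= rx_gy
  if (!is.null(within)) sel <- sel & within
  n_ptv <- sum(ptv_mask)
  if (n_ptv == 0) stop("PTV mask is empty")
  sum(sel) / n_ptv
}

#' Heterogeneity index
#'
#' `(D2% - D98%) / rx`: the spread between near-maximum and near-minimum
#' target dose relative to the prescription. Reported on the x100 scale
#' (a perfectly uniform target scores 0, a plan with D2% = 46.2 Gy and
#' D98% = 42.0 Gy at 44 Gy scores 9.55); the raw fraction is attached as
#' attribute `"fraction"`.
#'
#' @inheritParams conformity_index
#' @return Scalar HI on the x100 scale.
#' @export
heterogeneity_index <- function(dose, ptv_mask, rx_gy) {
  d2 <- dose_at_volume(dose, ptv_mask, pct = 2)
  d98 <- dose_at_volume(dose, ptv_mask, pct = 98)
  frac <- (d2 - d98) / rx_gy
  structure(100 * frac, fraction = frac)
}

#' Dose-at-volume endpoints
#'
#' `D_x%` is the minimum dose received by the hottest x% of the structure,
#' computed by linear interpolation on the sorted voxel doses (inverse
#' cumulative DVH). `D_cc` endpoints convert the absolute volume to a
#' percentage of the structure volume first; asking for more cc than the
#' structure holds is an error.
#'
#' @param dose Dose [voxel_volume()] (Gy).
#' @param mask Logical structure mask.
#' @param pct Volume percentage in (0, 100], or `NULL` when `cc` is given.
#' @param cc Absolute volume in cm^3, or `NULL` when `pct` is given.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, pct = NULL, cc = NULL) {
  stopifnot(inherits(dose, "voxel_volume"))
  dv <- dose$values[mask]
  if (!length(dv)) stop("mask is empty")
  if (is.null(pct) == is.null(cc))
    stop("give exactly one of `pct` or `cc`")
  if (!is.null(cc)) {
    vol_cc <- length(dv) * voxel_cc(dose)
    if (cc > vol_cc)
      stop(sprintf("requested %g cc exceeds structure volume %.2f cc", cc,
                   vol_cc))
    pct <- 100 * cc / vol_cc
  }
  if (pct <= 0 || pct > 100) stop("`pct` must be in (0, 100]")
  # hottest pct percent -> (1 - pct/100) quantile of the voxel doses
  unname(quantile(dv, 1 - pct / 100, type = 7))
}

#' @rdname dose_at_volume
#' @export
median_dose <- function(dose, mask) dose_at_volume(dose, mask, pct = 50)

#' Standard endpoint table for one plan
#'
#' The commissioning endpoint set: CI and HI of the PTV, BODY D1cc,
#' brainstem and cord+5 mm D0.1cc, median doses of both parotids, oral
#' cavity, larynx and pharynx, mandible D1cc, and the total-MU proxy (when
#' fluence maps are supplied).
#'
#' @param dose Dose [voxel_volume()] (Gy), normally already normalized.
#' @param structures A standard [structure_set()].
#' @param rx_gy Prescription dose, Gy (default 44).
#' @param fluences Optional list of [fluence_map()] for the MU proxy.
#' @param label Plan label stored in the output (e.g. `"Clinical"`, `"BP"`).
#' @return Tibble with columns `plan`, `endpoint`, `structure`, `value`.
#' @export
endpoint_table <- function(dose, structures, rx_gy = 44, fluences = NULL,
                           label = "plan") {
  check_standard_set(structures)
  m <- structures$masks
  body <- m[["BODY"]]
  rows <- list(
    list("CI", "PTV", conformity_index(dose, m$PTV, rx_gy, within = body)),
    list("HI", "PTV", as.numeric(heterogeneity_index(dose, m$PTV, rx_gy))),
    list("D1cc_Gy", "BODY", dose_at_volume(dose, body, cc = 1)),
    list("D0.1cc_Gy", "Brainstem", dose_at_volume(dose, m$Brainstem, cc = 0.1)),
    list("D0.1cc_Gy", "Cord+5mm", dose_at_volume(dose, m[["Cord+5mm"]], cc = 0.1)),
    list("Dmedian_Gy", "Parotid_L", median_dose(dose, m$Parotid_L)),
    list("Dmedian_Gy", "Parotid_R", median_dose(dose, m$Parotid_R)),
    list("Dmedian_Gy", "OralCavity", median_dose(dose, m$OralCavity)),
    list("Dmedian_Gy", "Larynx", median_dose(dose, m$Larynx)),
    list("Dmedian_Gy", "Pharynx", median_dose(dose, m$Pharynx)),
    list("D1cc_Gy", "Mandible", dose_at_volume(dose, m$Mandible, cc = 1))
  )
  if (!is.null(fluences))
    rows <- c(rows, list(list("TotalMU", "plan", total_mu_proxy(fluences))))
  tibble::tibble(
    plan = label,
    endpoint = vapply(rows, function(r) paste(r[[2]], r[[1]], sep = " "),
                      character(1)),
    structure = vapply(rows, `[[`, character(1), 2),
    value = vapply(rows, `[[`, numeric(1), 3)
  )
}
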