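#' Standard structure names of the bilateral head-and-neck model
#'
#' The ten structures used throughout the pipeline: the primary planning and
#' clinical target volumes, and eight organs at risk of the head-and-neck
#' region. Landmark structures (lungs, shoulders) and BODY come on top.
#'
#' @return Character vector of the ten canonical names.
#' @export
hn_standard_structures <- function() {
  c("PTV", "CTV", "Brainstem", "Cord+5mm", "Parotid_L", "Parotid_R",
    "OralCavity", "Larynx", "Pharynx", "Mandible")
}

#' Structure set: named binary masks on a shared voxel grid
#'
#' @param volume Reference [voxel_volume()] defining the grid.
#' @param masks Named list of logical arrays, all with the grid's dimensions.
#' @param roles Named character vector mapping structure name to one of
#'   `"PTV"`, `"CTV"`, `"OAR"`, `"BODY"`, `"LANDMARK"`.
#' @param rx_gy Named numeric vector of prescriptions (Gy) for PTV-role
#'   structures.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(volume, masks, roles, rx_gy = numeric()) {
  stopifnot(inherits(volume, "voxel_volume"), is.list(masks))
  d <- dim(volume$values)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m)) storage.mode(masks[[nm]]) <- "logical"
    if (!identical(dim(masks[[nm]]), d))
      stop(sprintf("mask '%s' shape does not match the reference volume", nm))
  }
  ok_roles <- c("PTV", "CTV", "OAR", "BODY", "LANDMARK")
  if (is.null(names(roles)) || !all(names(roles) %in% names(masks)))
    stop("`roles` must be named after entries of `masks`")
  if (!all(roles %in% ok_roles))
    stop("roles must be among ", paste(ok_roles, collapse = ", "))
  missing_role <- setdiff(names(masks), names(roles))
  if (length(missing_role))
    stop("missing role for: ", paste(missing_role, collapse = ", "))
  if (length(rx_gy)) {
    bad <- names(rx_gy)[roles[names(rx_gy)] != "PTV"]
    if (length(bad)) stop("rx_gy given for non-PTV structure: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(volume = volume, masks = masks,
                 roles = roles[names(masks)], rx_gy = rx_gy),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %s grid\n", length(x$masks),
              paste(dim(x$volume$values), collapse = "x")))
  for (nm in names(x$masks)) {
    rx <- if (nm %in% names(x$rx_gy)) sprintf(" rx=%g Gy", x$rx_gy[[nm]]) else ""
    cat(sprintf("  %-12s %-8s %8.1f cc%s\n", nm, x$roles[[nm]],
                mask_volume_cc(x$volume, x$masks[[nm]]), rx))
  }
  invisible(x)
}

#' Names of structures having a given role
#' @param structures A [structure_set()].
#' @param role Role string.
#' @return Character vector.
#' @export
structures_with_role <- function(structures, role) {
  names(structures$roles)[structures$roles == role]
}

#' Summarize a structure set as a tibble
#'
#' @param x A [structure_set()].
#' @param ... Unused.
#' @return Tibble with name, role, prescription and voxel-counted volume.
#' @export
tidy.structure_set <- function(x, ...) {
  tibble::tibble(
    structure = names(x$masks),
    role = unname(x$roles[names(x$masks)]),
    rx_gy = vapply(names(x$masks), function(nm)
      if (nm %in% names(x$rx_gy)) x$rx_gy[[nm]] else NA_real_, numeric(1)),
    volume_cc = vapply(x$masks, function(m) mask_volume_cc(x$volume, m),
                       numeric(1))
  )
}

#' Check that a structure set carries the ten standard structures
#'
#' @param structures A [structure_set()].
#' @param require_body Also require a BODY mask.
#' @return Invisibly `TRUE`; errors naming any missing structure.
#' @export
check_standard_set <- function(structures, require_body = TRUE) {
  need <- hn_standard_structures()
  if (require_body) need <- c(need, "BODY")
  miss <- setdiff(need, names(structures$masks))
  if (length(miss))
    stop("missing required structure(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Primary PTV of a structure set
#'
#' With several PTV-role structures the primary target is the one with the
#' lowest prescription (the large elective volume, as opposed to a boost).
#' @param structures A [structure_set()].
#' @return Structure name.
#' @export
primary_ptv <- function(structures) {
  ptvs <- structures_with_role(structures, "PTV")
  if (!length(ptvs)) stop("no PTV-role structure present")
  if (length(ptvs) == 1L) return(ptvs)
  rx <- structures$rx_gy[ptvs]
  if (any(is.na(rx))) stop("multiple PTVs but prescriptions missing")
  ptvs[which.min(rx)]
}
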