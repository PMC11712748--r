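#' Specification of a synthetic bilateral head-and-neck phantom
#'
#' Describes the geometry of a fully synthetic head-and-neck phantom: a
#' CT-like volume plus the ten standard planning structures (see
#' [hn_standard_structures()]) and lung/shoulder landmarks. All solids are
#' ellipsoids, elliptic cylinders or slabs with analytic volumes, so the
#' voxelized masks can be verified against closed-form references.
#'
#' @param grid_shape Voxels per axis (x, y, z).
#' @param spacing_mm Voxel size per axis, mm.
#' @param ptv_extent_mm Named vector `c(cc = , lateral = )`: craniocaudal and
#'   lateral extent of the primary PTV in mm.
#' @param boost_present Add a boost PTV (`PTV_boost`).
#' @param boost_offset_mm Offset of the boost centre from the primary PTV
#'   centre, mm.
#' @param boost_rx_gy Boost prescription, Gy.
#' @param parotid_offset_mm Named vector `c(left = , right = )`: baseline
#'   lateral distance of each parotid centre from the midline, mm. When
#'   `overlap_fraction > 0` the lateral position is solved by bisection so
#'   that the requested PTV overlap is met, overriding the baseline.
#' @param overlap_fraction Target fraction of each parotid's volume inside
#'   the PTV, in `[0, 0.5]`.
#' @param asymmetry Left/right scale factor applied to the left parotid's
#'   semi-axes (1 = symmetric).
#' @param jitter_mm Standard deviation of Gaussian boundary jitter applied to
#'   solid surfaces (0 disables; nonzero breaks the analytic-volume check by
#'   design).
#' @param hu_noise_sd Standard deviation of Gaussian HU noise within tissue
#'   classes.
#' @param seed RNG seed; identical spec + seed gives a bit-identical phantom.
#' @param rx_gy Primary prescription dose, Gy.
#' @param rx_levels Optional named vector of prescriptions per PTV name;
#'   defaults to `c(PTV = rx_gy)` plus the boost when present.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80, 80, 96),
                         spacing_mm = c(2.5, 2.5, 2.5),
                         ptv_extent_mm = c(cc = 90, lateral = 110),
                         boost_present = FALSE,
                         boost_offset_mm = c(25, 0, 0),
                         boost_rx_gy = 70,
                         parotid_offset_mm = c(left = 70, right = 70),
                         overlap_fraction = 0,
                         asymmetry = 1,
                         jitter_mm = 0,
                         hu_noise_sd = 8,
                         seed = 1L,
                         rx_gy = 44,
                         rx_levels = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 4L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            all(ptv_extent_mm > 0), all(parotid_offset_mm > 0),
            asymmetry > 0, jitter_mm >= 0, hu_noise_sd >= 0, rx_gy > 0)
  if (overlap_fraction < 0 || overlap_fraction > 0.5)
    stop("`overlap_fraction` must be in [0, 0.5]")
  if (is.null(names(ptv_extent_mm))) names(ptv_extent_mm) <- c("cc", "lateral")
  if (is.null(names(parotid_offset_mm)))
    names(parotid_offset_mm) <- c("left", "right")
  if (is.null(rx_levels)) {
    rx_levels <- c(PTV = rx_gy)
    if (boost_present) rx_levels <- c(rx_levels, PTV_boost = boost_rx_gy)
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 ptv_extent_mm = ptv_extent_mm, boost_present = boost_present,
                 boost_offset_mm = as.numeric(boost_offset_mm),
                 boost_rx_gy = boost_rx_gy,
                 parotid_offset_mm = parotid_offset_mm,
                 overlap_fraction = overlap_fraction, asymmetry = asymmetry,
                 jitter_mm = jitter_mm, hu_noise_sd = hu_noise_sd,
                 seed = as.integer(seed), rx_gy = rx_gy,
                 rx_levels = rx_levels),
            class = "phantom_spec")
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# quadratic-form mask of an ellipsoid, optionally restricted in z and jittered
ellipsoid_mask <- function(ax, center, semi, z_range = NULL, jitter = NULL) {
  qx <- ((ax[[1]] - center[1]) / semi[1])^2
  qy <- ((ax[[2]] - center[2]) / semi[2])^2
  qz <- if (length(semi) >= 3 && is.finite(semi[3]))
    ((ax[[3]] - center[3]) / semi[3])^2 else rep(0, length(ax[[3]]))
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  thr <- 1
  if (!is.null(jitter)) thr <- (1 + jitter)^2
  m <- q <= thr
  if (!is.null(z_range)) {
    zok <- ax[[3]] >= z_range[1] & ax[[3]] <= z_range[2]
    m <- m & rep(zok, each = length(ax[[1]]) * length(ax[[2]]))
  }
  m
}

ellipsoid_cc <- function(semi) 4 / 3 * pi * prod(semi) / 1000

cylinder_cc <- function(semi_xy, z_range) {
  pi * prod(semi_xy) * diff(z_range) / 1000
}

#' Generate a synthetic head-and-neck phantom
#'
#' Builds the CT-like HU volume and the standard structure set (ten planning
#' structures, BODY, and lung/shoulder landmarks) described by a
#' [phantom_spec()]. HU values are assigned per tissue class (air -1000,
#' soft tissue around 40, lung around -700, bone around 700) with seeded
#' Gaussian noise; all structure masks are clipped to BODY and the CTV is
#' contained in the PTV by construction.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `hn_phantom` with elements `ct` (a
#'   [voxel_volume()]), `structures` (a [structure_set()] carrying an
#'   `analytic_cc` attribute with closed-form solid volumes), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  rx <- spec$rx_levels
  if (anyDuplicated(rx))
    stop("two PTVs share the same prescription: the highest-dose PTV is ambiguous")

  d <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- -(d - 1) * sp / 2
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * sp[a])
  nvox <- prod(d)

  with_preserved_rng(spec$seed, {
    jit <- function() {
      if (spec$jitter_mm > 0)
        array(rnorm(nvox, 0, spec$jitter_mm / 30), dim = d) else NULL
    }

    # BODY: neck ellipse above the shoulder line, wider torso ellipse below
    z_shoulder <- -70
    zl <- length(ax[[3]])
    neck <- ellipsoid_mask(ax, c(0, 0, 0), c(90, 85, Inf))
    torso <- ellipsoid_mask(ax, c(0, 0, 0), c(98, 90, Inf))
    above <- rep(ax[[3]] > z_shoulder, each = d[1] * d[2])
    body <- (neck & above) | (torso & !above)

    ptv_center <- c(0, 10, 30)
    ptv_semi <- c(spec$ptv_extent_mm[["lateral"]] / 2, 42,
                  spec$ptv_extent_mm[["cc"]] / 2)
    ptv <- ellipsoid_mask(ax, ptv_center, ptv_semi, jitter = jit()) & body
    ctv_semi <- 0.8 * ptv_semi
    ctv <- ellipsoid_mask(ax, ptv_center, ctv_semi, jitter = NULL) & ptv

    analytic <- c(PTV = ellipsoid_cc(ptv_semi), CTV = ellipsoid_cc(ctv_semi))

    solids <- list(
      Brainstem = list(center = c(0, 30, 85), semi = c(10, 12, 25)),
      OralCavity = list(center = c(0, -45, 40), semi = c(25, 22, 25)),
      Larynx = list(center = c(0, -38, -20), semi = c(14, 14, 24)),
      Mandible = list(center = c(0, -55, 30), semi = c(34, 14, 18))
    )
    masks <- list(BODY = body, PTV = ptv, CTV = ctv)
    for (nm in names(solids)) {
      s <- solids[[nm]]
      masks[[nm]] <- ellipsoid_mask(ax, s$center, s$semi, jitter = jit()) & body
      analytic[nm] <- ellipsoid_cc(s$semi)
    }

    cord_z <- c(-60, 90)
    masks[["Cord+5mm"]] <- ellipsoid_mask(ax, c(0, 55, 0), c(10, 10, Inf),
                                          z_range = cord_z) & body
    analytic["Cord+5mm"] <- cylinder_cc(c(10, 10), cord_z)

    phar_z <- c(-45, 70)
    masks[["Pharynx"]] <- ellipsoid_mask(ax, c(0, 12, 0), c(13, 9, Inf),
                                         z_range = phar_z) & body
    analytic["Pharynx"] <- cylinder_cc(c(13, 9), phar_z)

    # parotids: lateral position solved for the requested PTV overlap
    parotid_semi_base <- c(11, 16, 20)
    parotid_center_yz <- c(10, 40)
    place_parotid <- function(side) {
      sgn <- if (side == "left") 1 else -1
      semi <- parotid_semi_base * if (side == "left") spec$asymmetry else 1
      x0 <- spec$parotid_offset_mm[[side]]
      make <- function(xc)
        ellipsoid_mask(ax, c(sgn * xc, parotid_center_yz[1],
                             parotid_center_yz[2]), semi) & body
      if (spec$overlap_fraction > 0) {
        f_of <- function(xc) {
          m <- make(xc)
          sum(m & ptv) / max(1L, sum(m))
        }
        lo <- 15; hi <- x0
        if (f_of(hi) < spec$overlap_fraction) {
          for (it in 1:30) {
            mid <- (lo + hi) / 2
            if (f_of(mid) >= spec$overlap_fraction) lo <- mid else hi <- mid
          }
          x0 <- (lo + hi) / 2
        }
      }
      list(mask = make(x0), semi = semi)
    }
    pl <- place_parotid("left")
    pr <- place_parotid("right")
    masks[["Parotid_L"]] <- pl$mask
    masks[["Parotid_R"]] <- pr$mask
    analytic["Parotid_L"] <- ellipsoid_cc(pl$semi)
    analytic["Parotid_R"] <- ellipsoid_cc(pr$semi)

    if (spec$boost_present) {
      bc <- ptv_center + spec$boost_offset_mm
      bsemi <- c(20, 18, 18)
      masks[["PTV_boost"]] <- ellipsoid_mask(ax, bc, bsemi) & body
      analytic["PTV_boost"] <- ellipsoid_cc(bsemi)
    }

    # landmarks
    masks[["Lungs"]] <-
      (ellipsoid_mask(ax, c(45, 15, -98), c(26, 35, 20)) |
         ellipsoid_mask(ax, c(-45, 15, -98), c(26, 35, 20))) & body
    masks[["Shoulder_L"]] <- ellipsoid_mask(ax, c(72, 0, -95),
                                            c(25, 45, 24)) & body
    masks[["Shoulder_R"]] <- ellipsoid_mask(ax, c(-72, 0, -95),
                                            c(25, 45, 24)) & body

    # HU assignment
    hu <- array(-1000, dim = d)
    hu[body] <- 40 + rnorm(sum(body), 0, spec$hu_noise_sd)
    spine <- ellipsoid_mask(ax, c(0, 72, 0), c(12, 12, Inf),
                            z_range = c(-60, 95)) & body
    bone <- spine | masks[["Mandible"]]
    hu[bone] <- 700 + rnorm(sum(bone), 0, 5 * spec$hu_noise_sd)
    hu[masks[["Lungs"]]] <- -700 + rnorm(sum(masks[["Lungs"]]), 0,
                                         spec$hu_noise_sd)

    ct <- voxel_volume(hu, spacing_mm = sp, origin_mm = origin, unit = "HU")
    roles <- c(BODY = "BODY", PTV = "PTV", CTV = "CTV", Brainstem = "OAR",
               OralCavity = "OAR", Larynx = "OAR", Mandible = "OAR",
               `Cord+5mm` = "OAR", Pharynx = "OAR", Parotid_L = "OAR",
               Parotid_R = "OAR", Lungs = "LANDMARK", Shoulder_L = "LANDMARK",
               Shoulder_R = "LANDMARK")
    if (spec$boost_present) roles <- c(roles, PTV_boost = "PTV")
    ss <- structure_set(ct, masks, roles[names(masks)], rx_gy = rx)
    attr(ss, "analytic_cc") <- analytic
    structure(list(ct = ct, structures = ss, spec = spec),
              class = "hn_phantom")
  })
}

#' @export
print.hn_phantom <- function(x, ...) {
  cat("<hn_phantom>\n")
  print(x$ct)
  print(x$structures)
  invisible(x)
}
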