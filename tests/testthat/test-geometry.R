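make_ptv_set <- function(vol, ptv_idx, extra = list(), rx = c(PTV = 44)) {
  d <- dim(vol$values)
  masks <- list(PTV = array(FALSE, d))
  masks$PTV[ptv_idx] <- TRUE
  roles <- c(PTV = "PTV")
  for (nm in names(extra)) {
    masks[[nm]] <- extra[[nm]]$mask
    roles[nm] <- extra[[nm]]$role
  }
  structure_set(vol, masks, roles, rx_gy = rx)
}

test_that("isocenter is the PTV centroid rounded per coordinate to 5 mm", {
  # voxel centres chosen so the centroid is exactly (12.4, -3.1, 7.6) mm
  vol <- voxel_volume(array(0, c(20, 15, 12)), c(0.8, 0.2, 0.8),
                      c(0, -5, 0))
  idx <- as.matrix(expand.grid(16:17, 10:11, 10:11))
  ss <- make_ptv_set(vol, idx)
  ctr <- mask_centroid(vol, ss$masks$PTV)
  expect_equal(ctr, c(12.4, -3.1, 7.6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(place_isocenter(ss), c(10, -5, 10), ignore_attr = TRUE)
})

test_that("boost isocenter falls back to the primary PTV centroid beyond 25 mm", {
  vol <- voxel_volume(array(0, c(60, 30, 30)), c(1, 1, 1), c(0, 0, 0))
  d <- dim(vol$values)
  prim <- array(FALSE, d); prim[9:13, 9:13, 9:13] <- TRUE     # centroid (10,10,10)
  far <- array(FALSE, d); far[41, 11, 11] <- TRUE             # (40,10,10): 30 mm away
  near <- array(FALSE, d); near[21, 11, 11] <- TRUE           # (20,10,10): 10 mm away
  ss_far <- structure_set(vol, list(PTV = prim, PTV_boost = far),
                          c(PTV = "PTV", PTV_boost = "PTV"),
                          rx_gy = c(PTV = 44, PTV_boost = 70))
  expect_equal(place_isocenter(ss_far), c(10, 10, 10), ignore_attr = TRUE)
  ss_near <- structure_set(vol, list(PTV = prim, PTV_boost = near),
                           c(PTV = "PTV", PTV_boost = "PTV"),
                           rx_gy = c(PTV = 44, PTV_boost = 70))
  expect_equal(place_isocenter(ss_near), c(20, 10, 10), ignore_attr = TRUE)
})

test_that("isocenter placement rejects missing PTVs and prescription ties", {
  vol <- voxel_volume(array(0, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  oar <- array(FALSE, dim(vol$values)); oar[3, 3, 3] <- TRUE
  ss <- structure_set(vol, list(X = oar), c(X = "OAR"))
  expect_error(place_isocenter(ss), "no PTV")
  a <- array(FALSE, dim(vol$values)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, dim(vol$values)); b[8, 8, 8] <- TRUE
  tie <- structure_set(vol, list(P1 = a, P2 = b), c(P1 = "PTV", P2 = "PTV"),
                       rx_gy = c(P1 = 44, P2 = 44))
  expect_error(place_isocenter(tie), "tie")
})

test_that("isocenter placement is idempotent and translation-equivariant", {
  vol <- voxel_volume(array(0, c(40, 40, 40)), c(1, 1, 1), c(0, 0, 0))
  d <- dim(vol$values)
  m <- array(FALSE, d); m[5:11, 7:13, 9:15] <- TRUE
  ss <- make_ptv_set(vol, which(m, arr.ind = TRUE))
  iso1 <- place_isocenter(ss)
  expect_identical(place_isocenter(ss), iso1)
  # shift by a multiple of the rounding step: isocenter shifts exactly along
  shift <- c(15, 10, 5)
  m2 <- array(FALSE, d)
  m2[5:11 + shift[1], 7:13 + shift[2], 9:15 + shift[3]] <- TRUE
  ss2 <- make_ptv_set(vol, which(m2, arr.ind = TRUE))
  expect_equal(place_isocenter(ss2), iso1 + shift, ignore_attr = TRUE)
})

test_that("standard gantry layout starts at 180 and advances counterclockwise in 40-degree steps", {
  expect_equal(place_beams(),
               c(180, 140, 100, 60, 20, 340, 300, 260, 220))
  expect_equal(place_beams(1), 180)
  ang <- sort(place_beams())
  gaps <- diff(c(ang, ang[1] + 360))
  expect_true(all(gaps == 40))
  expect_equal(place_beams(9, direction = "cw"),
               c(180, 220, 260, 300, 340, 20, 60, 100, 140))
  expect_error(place_beams(10, step_deg = 40), "rotation")
  expect_false(anyDuplicated(place_beams()) > 0)
})

sphere_case <- function(r = 20, d = c(40, 40, 40), sp = c(2, 2, 2),
                        slab_z = NULL) {
  vol <- voxel_volume(array(0, d), sp, -(d - 1) * sp / 2, "HU")
  axc <- axis_coords(vol)
  q <- outer(outer(axc[[1]]^2, axc[[2]]^2, `+`), axc[[3]]^2, `+`)
  ptv <- q <= r^2
  masks <- list(PTV = ptv, BODY = array(TRUE, d))
  roles <- c(PTV = "PTV", BODY = "BODY")
  if (!is.null(slab_z)) {
    sh <- array(FALSE, d)
    zk <- axc[[3]] >= slab_z[1] & axc[[3]] <= slab_z[2]
    sh[abs(axc[[1]]) <= 30, , zk] <- TRUE
    masks$Shoulder_L <- sh
    roles["Shoulder_L"] <- "LANDMARK"
  }
  structure_set(vol, masks, roles, rx_gy = c(PTV = 44))
}

test_that("jaws fit a centred sphere to its radius in the isocenter plane", {
  ss <- sphere_case(r = 20)
  tpl <- beam_template(c(0, 0, 0), c(0, 90, 180, 260), sad_mm = 1000)
  fitted <- fit_jaws(ss, tpl, margin_mm = 0)
  for (b in 1:4) {
    expect_equal(unname(fitted$jaws_mm[b, c("x2", "y2")]), c(20, 20),
                 tolerance = 0.1)  # half a voxel + divergence
    expect_equal(unname(fitted$jaws_mm[b, c("x1", "y1")]), c(-20, -20),
                 tolerance = 0.1)
  }
  # margin moves every edge outward by exactly the margin
  with_m <- fit_jaws(ss, tpl, margin_mm = 7)
  expect_equal(with_m$jaws_mm[, c("x1", "y1")],
               fitted$jaws_mm[, c("x1", "y1")] - 7, tolerance = 1e-9)
  expect_equal(with_m$jaws_mm[, c("x2", "y2")],
               fitted$jaws_mm[, c("x2", "y2")] + 7, tolerance = 1e-9)
})

test_that("shoulder rule raises only the inferior jaw edge, bounded by coverage", {
  ss_plain <- sphere_case(r = 25)
  ss_slab <- sphere_case(r = 25, slab_z = c(-35, -22))
  tpl <- beam_template(c(0, 0, 0), 180, sad_mm = 1000)
  j0 <- fit_jaws(ss_plain, tpl, margin_mm = 0)$jaws_mm[1, ]
  # permissive coverage floor: the edge clears the slab-top projection
  j1 <- fit_jaws(ss_slab, tpl, margin_mm = 0, min_coverage = 0.5)$jaws_mm[1, ]
  slab_top <- max(bev_points(ss_slab$volume, ss_slab$masks$Shoulder_L,
                             c(0, 0, 0), 180, 1000)[, "v"])
  expect_gte(j1[["y1"]], slab_top)
  expect_gt(j1[["y1"]], j0[["y1"]])
  expect_equal(j1[c("x1", "x2", "y2")], j0[c("x1", "x2", "y2")],
               tolerance = 1e-9)
  # default coverage floor: at least min_coverage of PTV BEV points retained
  j2 <- fit_jaws(ss_slab, tpl, margin_mm = 0, min_coverage = 0.98)$jaws_mm[1, ]
  pts <- bev_points(ss_slab$volume, ss_slab$masks$PTV, c(0, 0, 0), 180, 1000)
  inside <- pts[, "u"] >= j2[["x1"]] & pts[, "u"] <= j2[["x2"]] &
    pts[, "v"] >= j2[["y1"]] & pts[, "v"] <= j2[["y2"]]
  expect_gte(mean(inside), 0.98)
})

test_that("oversized PTV projections are rejected", {
  ss <- sphere_case(r = 25)
  tpl <- beam_template(c(0, 0, 0), 180, sad_mm = 1000)
  expect_error(fit_jaws(ss, tpl, max_field_mm = 30), "field size")
})

test_that("beam templates serialize losslessly to JSON", {
  ph <- test_phantom()
  tpl <- auto_template(ph$structures)
  td <- withr::local_tempdir()
  p <- file.path(td, "plan.json")
  write_plan(tpl, p)
  tpl2 <- read_plan(p)
  expect_equal(tpl2$isocenter_mm, tpl$isocenter_mm)
  expect_equal(tpl2$gantry_deg, tpl$gantry_deg)
  expect_equal(unname(tpl2$jaws_mm), unname(tpl$jaws_mm))
  expect_equal(tpl2$sad_mm, tpl$sad_mm)
})
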