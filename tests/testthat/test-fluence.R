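test_that("the six tradeoff profiles map labels to weighting and preference", {
  expect_setequal(tradeoff_labels(), c("BP", "BO", "LP", "LO", "RP", "RO"))
  mapping <- list(
    BP = c("both", "PTV"), BO = c("both", "OAR"),
    LP = c("left", "PTV"), LO = c("left", "OAR"),
    RP = c("right", "PTV"), RO = c("right", "OAR"))
  for (lbl in names(mapping)) {
    p <- tradeoff_profile(lbl)
    expect_identical(p$parotid_weighting, mapping[[lbl]][1], label = lbl)
    expect_identical(p$ptv_oar_preference, mapping[[lbl]][2], label = lbl)
  }
  expect_error(tradeoff_profile("XX"), "unknown")
})

test_that("fluence maps enforce nonnegativity, finiteness and grid shape", {
  g <- fluence_grid(16, 2.5)
  expect_error(fluence_map(matrix(-1, 16, 16), g), "nonnegative")
  expect_error(fluence_map(matrix(Inf, 16, 16), g), "finite")
  expect_error(fluence_map(matrix(0, 8, 8), g), "16 x 16")
})

test_that("predictor contract holds for the registered baseline", {
  ph <- test_phantom(overlap = 0.2)
  tpl <- cached("tpl_ov", function() auto_template(ph$structures))
  stacks <- cached("stacks_ov", function()
    build_stacks(ph$ct, ph$structures, tpl))
  expect_true("baseline" %in% list_predictors())
  maps <- predict_fluence(stacks, "BP", tpl)
  expect_length(maps, length(stacks))
  for (fm in maps) {
    expect_true(all(fm$values >= 0) && all(is.finite(fm$values)))
    expect_identical(dim(fm$values), c(128L, 128L))
    expect_true(fm$clipped)
  }
  # jaw-clip compliance
  for (b in seq_along(maps)) {
    fm <- maps[[b]]
    out_u <- fm$grid$u < tpl$jaws_mm[b, "x1"] | fm$grid$u > tpl$jaws_mm[b, "x2"]
    out_v <- fm$grid$v < tpl$jaws_mm[b, "y1"] | fm$grid$v > tpl$jaws_mm[b, "y2"]
    expect_true(all(fm$values[out_u, ] == 0))
    expect_true(all(fm$values[, out_v] == 0))
  }
  # determinism
  maps2 <- predict_fluence(stacks, "BP", tpl)
  expect_identical(lapply(maps, `[[`, "values"), lapply(maps2, `[[`, "values"))
  expect_error(predict_fluence(stacks, "BP", tpl, predictor = "nope"),
               "unknown predictor")
})

test_that("all-zero stacks predict all-zero fluence", {
  ph <- test_phantom()
  tpl <- cached("tpl_default", function() auto_template(ph$structures))
  air <- voxel_volume(array(-1000, dim(ph$ct$values)), ph$ct$spacing_mm,
                      ph$ct$origin_mm, "HU")
  st <- build_stack(air, ph$structures, tpl, 1)
  maps <- baseline_conformal(list(st), "BP", tpl)
  expect_true(all(maps[[1]]$values == 0))
})

test_that("profile changes modulate parotid shadows in the expected direction", {
  ph <- test_phantom(overlap = 0.2)
  tpl <- cached("tpl_ov", function() auto_template(ph$structures))
  stacks <- cached("stacks_ov", function()
    build_stacks(ph$ct, ph$structures, tpl))
  bp <- baseline_conformal(stacks, "BP", tpl)
  lp <- baseline_conformal(stacks, "LP", tpl)
  bo <- baseline_conformal(stacks, "BO", tpl)
  shadow_sum <- function(maps, ch) {
    s <- 0
    for (b in seq_along(maps)) {
      sh <- stacks[[b]]$channels[[ch]] > 0.05
      s <- s + sum(maps[[b]]$values[sh])
    }
    s
  }
  # LP spares the left parotid harder than BP
  expect_lt(shadow_sum(lp, "interface:Parotid_L"),
            shadow_sum(bp, "interface:Parotid_L"))
  # OAR-priority attenuates at least as much as PTV-priority everywhere
  for (b in seq_along(bp))
    expect_true(all(bo[[b]]$values <= bp[[b]]$values + 1e-12))
  # total fluence non-increasing as the attenuation weight decreases
  sums <- vapply(c(0.9, 0.6, 0.3), function(w) {
    maps <- baseline_conformal(stacks, "BP", tpl, params = list(w_ptv = w))
    sum(vapply(maps, function(m) sum(m$values), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sums) < 0))
})

test_that("threshold zero opens the aperture over the whole PTV channel", {
  ph <- test_phantom()
  tpl <- cached("tpl_default", function() auto_template(ph$structures))
  st <- cached("stack_b1", function() build_stack(ph$ct, ph$structures, tpl, 1))
  maps <- baseline_conformal(list(st), "BP", template = NULL,
                             params = list(threshold = 0, feather_px = 0))
  ptv_ch <- st$channels[["interface:PTV"]]
  expect_true(all(maps[[1]]$values[ptv_ch > 0] > 0))
  expect_true(all(maps[[1]]$values[ptv_ch == 0] == 0))
})

test_that("fluence text files round trip and reject malformed headers", {
  set.seed(9)
  fm <- fluence_map(matrix(runif(128^2), 128, 128), beam = 3L)
  td <- withr::local_tempdir()
  p <- file.path(td, "beam_03.txt")
  write_fluence(fm, p)
  fm2 <- read_fluence(p)
  expect_identical(fm2$values, fm$values)
  expect_identical(fm2$beam, 3L)
  expect_equal(fm2$grid$pixel_mm, 2.5)
  # grid-size enforcement
  small <- fluence_map(matrix(1, 16, 16), fluence_grid(16, 2.5))
  p2 <- file.path(td, "small.txt")
  write_fluence(small, p2)
  expect_error(read_fluence(p2), "expected 128")
  expect_s3_class(read_fluence(p2, expect_pixels = 16), "fluence_map")
  # header mismatch
  lines <- readLines(p)
  writeLines(lines[!grepl("^pixels:", lines)], p)
  expect_error(read_fluence(p), "pixels")
})
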