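test_that("ray tracing reproduces axis-aligned, diagonal and reversed traversals", {
  v <- water_volume(c(8, 8, 8), c(2, 2, 2))
  # axis-aligned ray along +y through the grid centre column
  tr <- trace_ray(v, c(1, -100, 1), c(1, 0, 1))
  expect_identical(nrow(tr), 8L)
  expect_true(all(abs(tr$length_mm - 2) < 1e-9))
  expect_equal(sum(tr$length_mm), 16, tolerance = 1e-12)
  # diagonal through a 2x2x2 unit-voxel cube: chord = body diagonal
  cube <- voxel_volume(array(1, c(2, 2, 2)), c(1, 1, 1), c(0.5, 0.5, 0.5))
  tr2 <- trace_ray(cube, c(-5, -5, -5), c(0.5, 0.5, 0.5))
  expect_equal(sum(tr2$length_mm), 2 * sqrt(3), tolerance = 1e-9)
  # reversed ray: same voxels in reverse order, same lengths
  tr3 <- trace_ray(cube, c(7, 7, 7), c(0.5, 0.5, 0.5))
  expect_equal(rev(tr3$voxel), tr2$voxel)
  expect_equal(rev(tr3$length_mm), tr2$length_mm, tolerance = 1e-9)
  # miss
  expect_identical(nrow(trace_ray(v, c(100, -100, 100), c(100, 0, 100))), 0L)
})

test_that("projections match the brute-force voxel-sum oracle on axis-aligned beams", {
  set.seed(42)
  d <- c(16, 16, 16)
  hu <- array(runif(prod(d), -500, 800), dim = d)
  ct <- voxel_volume(hu, c(1, 1, 1), -(d - 1) / 2, "HU")
  mask <- array(FALSE, d); mask[5:12, 4:10, 6:13] <- TRUE
  body <- array(FALSE, d); body[2:15, 2:15, 2:15] <- TRUE
  grid <- fluence_grid(16, 1)  # pixel centres coincide with voxel columns
  for (g in c(0, 90, 180, 270)) {
    tpl <- beam_template(c(0, 0, 0), g, sad_mm = 1e7)  # effectively parallel
    P <- intra_projection(ct, mask, tpl, 1, grid)
    O <- oracle_projection(ct, mask, body, g, "intra")
    expect_lt(max(abs(P - O)) / max(O), 1e-6, label = paste("intra", g))
    IF <- interface_projection(ct, mask, body, tpl, 1, grid)
    OI <- oracle_projection(ct, mask, body, g, "interface")
    expect_lt(max(abs(IF - OI)) / max(OI), 1e-6,
              label = paste("interface", g))
  }
})

test_that("intra projection is monotone in the mask and zero for empty masks", {
  set.seed(7)
  d <- c(12, 12, 12)
  hu <- array(runif(prod(d), 0, 500), dim = d)
  ct <- voxel_volume(hu, c(2, 2, 2), -(d - 1), "HU")
  tpl <- beam_template(c(0, 0, 0), 40, sad_mm = 1000)
  grid <- fluence_grid(12, 2)
  empty <- array(FALSE, d)
  expect_true(all(intra_projection(ct, empty, tpl, 1, grid) == 0))
  small <- array(FALSE, d); small[4:7, 4:7, 4:7] <- TRUE
  big <- small; big[3:9, 3:9, 3:9] <- TRUE
  p_small <- intra_projection(ct, small, tpl, 1, grid)
  p_big <- intra_projection(ct, big, tpl, 1, grid)
  expect_true(all(p_big - p_small > -1e-12))
})

test_that("interface of BODY equals the full body-chord integral (intra limit)", {
  d <- c(14, 14, 14)
  hu <- array(100, dim = d)
  ct <- voxel_volume(hu, c(2, 2, 2), -(d - 1), "HU")
  body <- array(FALSE, d); body[3:12, 3:12, 3:12] <- TRUE  # convex block
  tpl <- beam_template(c(0, 0, 0), 0, sad_mm = 1000)
  grid <- fluence_grid(14, 2)
  a <- interface_projection(ct, body, body, tpl, 1, grid)
  b <- intra_projection(ct, body, tpl, 1, grid)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("interface spans body entry to structure exit, exceeding the intra integral", {
  # anterior structure, posterior beam: interface covers the air-gap-free
  # stretch from the posterior body surface through the structure
  d <- c(14, 20, 14)
  hu <- array(0, dim = d)  # water body
  ct <- voxel_volume(hu, c(2, 2, 2), -(d - 1) * c(1, 1, 1) * 2 / 2, "HU")
  body <- array(TRUE, d)
  struct <- array(FALSE, d)
  struct[5:10, 3:6, 5:10] <- TRUE  # anterior block (low y)
  tpl <- beam_template(c(0, 0, 0), 180, sad_mm = 1000)  # posterior beam
  grid <- fluence_grid(14, 2)
  iface <- interface_projection(ct, struct, body, tpl, 1, grid)
  intra <- intra_projection(ct, struct, tpl, 1, grid)
  hit <- intra > 0
  expect_true(any(hit))
  expect_true(all(iface[hit] > intra[hit]))
  # rays missing the structure but crossing the body read zero
  expect_true(all(iface[!hit] == 0))
})

test_that("12-channel stacks conform to the 128x128 @ 2.5 mm contract", {
  ph <- test_phantom()
  tpl <- cached("tpl_default", function() auto_template(ph$structures))
  st <- cached("stack_b1", function()
    build_stack(ph$ct, ph$structures, tpl, 1))
  expect_length(st$channels, 12L)
  expect_setequal(names(st$channels),
                  c(paste0("interface:", hn_standard_structures()),
                    paste0("intra:", c("PTV", "CTV"))))
  for (ch in st$channels) {
    expect_identical(dim(ch), c(128L, 128L))
    expect_true(all(is.finite(ch)) && all(ch >= 0))
  }
  expect_equal(st$grid$pixel_mm, 2.5)
  # per-channel max after normalization is 0 or 1
  mx <- vapply(st$channels, max, numeric(1))
  expect_true(all(abs(mx - 1) < 1e-12 | mx == 0))
})

test_that("all-air CT yields an all-zero stack; missing structures are named", {
  ph <- test_phantom()
  air <- voxel_volume(array(-1000, dim(ph$ct$values)), ph$ct$spacing_mm,
                      ph$ct$origin_mm, "HU")
  tpl <- cached("tpl_default", function() auto_template(ph$structures))
  st <- build_stack(air, ph$structures, tpl, 1)
  expect_true(all(vapply(st$channels, function(ch) all(ch == 0),
                         logical(1))))
  broken <- ph$structures
  broken$masks$Larynx <- NULL
  broken$roles <- broken$roles[names(broken$roles) != "Larynx"]
  expect_error(build_stack(ph$ct, broken, tpl, 1), "Larynx")
})

test_that("divergent projections converge to the parallel oracle as SAD grows", {
  set.seed(11)
  d <- c(12, 12, 12)
  hu <- array(runif(prod(d), 0, 400), dim = d)
  ct <- voxel_volume(hu, c(1, 1, 1), -(d - 1) / 2, "HU")
  mask <- array(FALSE, d); mask[4:9, 4:9, 4:9] <- TRUE
  grid <- fluence_grid(12, 1)
  oracle <- oracle_projection(ct, mask, mask, 0, "intra")
  err <- vapply(c(500, 1000, 4000, 64000), function(sad) {
    tpl <- beam_template(c(0, 0, 0), 0, sad_mm = sad)
    max(abs(intra_projection(ct, mask, tpl, 1, grid) - oracle))
  }, numeric(1))
  expect_true(all(diff(err) < 1e-12))  # monotone convergence
  expect_lt(err[4] / max(oracle), 1e-3)
})
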