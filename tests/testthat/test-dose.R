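water_case <- function(d = c(31, 60, 31), sp = c(2, 2, 2)) {
  ct <- water_volume(d, sp)
  body <- array(TRUE, d)
  list(ct = ct,
       ss = structure_set(ct, list(BODY = body), c(BODY = "BODY")))
}

test_that("zero fluence gives zero dose; engine is linear and additive over beams", {
  wc <- water_case(c(21, 30, 21))
  tpl <- beam_template(c(0, 0, 0), c(0, 180), sad_mm = 1000)
  g <- fluence_grid(32, 2.5)
  zero <- fluence_map(matrix(0, 32, 32), g, 1)
  d0 <- compute_dose(wc$ct, wc$ss, tpl, list(zero, zero))
  expect_true(all(d0$values == 0))
  set.seed(5)
  f1 <- fluence_map(matrix(runif(32^2), 32, 32), g, 1)
  f2 <- fluence_map(matrix(runif(32^2), 32, 32), g, 2)
  d12 <- compute_dose(wc$ct, wc$ss, tpl, list(f1, f2))
  d1 <- compute_dose(wc$ct, wc$ss, tpl, list(f1, zero))
  d2 <- compute_dose(wc$ct, wc$ss, tpl, list(zero, f2))
  expect_equal(d12$values, d1$values + d2$values, tolerance = 1e-12)
  # linearity in fluence
  f1s <- fluence_map(2.5 * f1$values, g, 1)
  d1s <- compute_dose(wc$ct, wc$ss, tpl, list(f1s, zero))
  expect_equal(d1s$values, 2.5 * d1$values, tolerance = 1e-12)
  # reproducibility: bit-identical reruns
  expect_identical(compute_dose(wc$ct, wc$ss, tpl, list(f1, f2))$values,
                   d12$values)
})

test_that("central pencil beam follows the attenuated inverse-square closed form", {
  wc <- water_case(c(31, 60, 31), c(2, 2, 2))
  tpl <- beam_template(c(0, 0, 0), 0, sad_mm = 1000)
  g <- fluence_grid(128, 2.5)
  vals <- matrix(0, 128, 128); vals[64:65, 64:65] <- 1
  fm <- fluence_map(vals, g, 1)
  dose <- compute_dose(wc$ct, wc$ss, tpl, list(fm),
                       list(scatter_sigma_mm = 0, body_dilate_vox = 0))
  prof <- dose$values[17, , 17]  # column adjacent to the pencil
  ys <- axis_coords(wc$ct)[[2]]
  entry <- ys[1] - wc$ct$spacing_mm[2] / 2  # upstream surface of the slab
  mu <- 0.005; sad <- 1000
  closed <- exp(-mu * (ys - entry)) * (sad / (sad + ys))^2
  w <- which(prof > 0)
  expect_gt(length(w), 30)
  ratio <- (prof[w] / max(prof)) / (closed[w] / max(closed[w]))
  expect_lt(max(abs(ratio - 1)), 0.02)
})

test_that("opposed beams on a symmetric phantom give a symmetric dose", {
  # odd y-count puts the central plane on-grid; x/z spacings are chosen
  # incommensurate so no ray crosses an x- and z-face at the same parameter
  # (a corner degeneracy that float rounding would resolve arbitrarily)
  wc <- water_case(c(25, 41, 21), c(2, 2, 2.5))
  tpl <- beam_template(c(0, 0, 0), c(0, 180), sad_mm = 1000)
  g <- fluence_grid(32, 2.5)
  vals <- matrix(0, 32, 32); vals[12:21, 12:21] <- 1
  d <- compute_dose(wc$ct, wc$ss, tpl,
                    list(fluence_map(vals, g, 1), fluence_map(vals, g, 2)))
  flipped <- d$values[, rev(seq_len(dim(d$values)[2])), ]
  expect_lt(max(abs(d$values - flipped)) / max(d$values), 1e-3)
})

test_that("normalization pins D95 to the prescription and is idempotent", {
  ph <- test_phantom()
  res <- cached("plan_bp", function() plan_case(ph, "BP"))
  dv <- res$dose$values[ph$structures$masks$PTV]
  expect_equal(unname(quantile(dv, 0.05, type = 7)), 44, tolerance = 1e-9)
  again <- normalize_to_prescription(res$dose, ph$structures$masks$PTV, 44)
  expect_equal(again$values, res$dose$values, tolerance = 1e-12)
  expect_equal(attr(again, "norm_scale"), 1, tolerance = 1e-9)
  # uniform dose scales exactly
  u <- voxel_volume(array(22, dim(ph$ct$values)), ph$ct$spacing_mm,
                    ph$ct$origin_mm, "Gy")
  un <- normalize_to_prescription(u, ph$structures$masks$PTV, 44)
  expect_true(all(un$values == 44))
  expect_equal(attr(un, "norm_scale"), 2)
  # degenerate input
  z <- voxel_volume(array(0, dim(ph$ct$values)), ph$ct$spacing_mm,
                    ph$ct$origin_mm, "Gy")
  expect_error(normalize_to_prescription(z, ph$structures$masks$PTV), "zero")
})

test_that("prescription rescaling is a pure scalar on dose and DVH abscissa", {
  ph <- test_phantom()
  res <- cached("plan_bp", function() plan_case(ph, "BP"))
  r <- rescale_prescription(res$dose, from_gy = 50, to_gy = 44)
  expect_equal(r$values, res$dose$values * 0.88, tolerance = 1e-12)
  same <- rescale_prescription(res$dose, 44, 44)
  expect_identical(same$values, res$dose$values)
  # DVH abscissa scales linearly: volume at dose d before = volume at 0.88 d after
  m <- ph$structures$masks$Parotid_L
  v_before <- dvh(res$dose, m, bin_gy = 0.5)
  v_after <- dvh(r, m, bin_gy = 0.44)
  expect_equal(v_after$volume_pct, v_before$volume_pct[seq_len(nrow(v_after))],
               tolerance = 1e-9)
})

test_that("the MU proxy is linear and additive in the fluence set", {
  g <- fluence_grid(16, 2.5)
  zero <- list(fluence_map(matrix(0, 16, 16), g))
  expect_identical(total_mu_proxy(zero), 0)
  set.seed(1)
  f <- fluence_map(matrix(runif(256), 16, 16), g)
  nine <- rep(list(f), 9)
  expect_equal(total_mu_proxy(nine), 9 * total_mu_proxy(list(f)))
  doubled <- lapply(nine, function(x) fluence_map(2 * x$values, g))
  expect_equal(total_mu_proxy(doubled), 2 * total_mu_proxy(nine))
})
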