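# Shared fixtures and independent oracles. Phantoms are cached per spec so
# expensive volumes are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# anatomically complete phantom on a coarse 5 mm grid (fast); the default
# 2.5 mm phantom is exercised where resolution matters
test_phantom <- function(overlap = 0, seed = 1L, ...) {
  key <- paste("ph", overlap, seed, ..., sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_phantom(phantom_spec(
      grid_shape = c(40, 40, 48), spacing_mm = c(5, 5, 5),
      overlap_fraction = overlap, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# uniform water volume centred on the origin
water_volume <- function(d = c(16, 16, 16), sp = c(2, 2, 2), hu = 0) {
  voxel_volume(array(hu, dim = d), sp, -(d - 1) * sp / 2, unit = "HU")
}

# brute-force parallel projection oracle for axis-aligned beams.
# gantry 0: rays along +y; gantry 180: along -y; 90: along -x; 270: along +x.
# Returns the oracle value for fluence pixel (u, v) mapped onto the grid.
oracle_projection <- function(ct, mask, body, gantry, mode = "intra") {
  dens <- hu_to_density(ct$values)
  d <- dim(ct$values)
  stopifnot(gantry %in% c(0, 90, 180, 270))
  sp <- ct$spacing_mm
  # march order along the ray for each (u, v) pixel column
  res <- switch(as.character(gantry),
    "0"   = list(ax = 2, dir = +1, umap = 1, usgn = +1),
    "180" = list(ax = 2, dir = -1, umap = 1, usgn = -1),
    "90"  = list(ax = 1, dir = -1, umap = 2, usgn = +1),
    "270" = list(ax = 1, dir = +1, umap = 2, usgn = -1))
  n_u <- d[res$umap]
  n_v <- d[3]
  out <- matrix(0, n_u, n_v)
  for (iu in seq_len(n_u)) {
    for (iv in seq_len(n_v)) {
      march <- seq_len(d[res$ax])
      if (res$dir < 0) march <- rev(march)
      dcol <- numeric(length(march))
      mcol <- logical(length(march))
      bcol <- logical(length(march))
      for (k in seq_along(march)) {
        idx <- if (res$ax == 2) c(iu, march[k], iv) else c(march[k], iu, iv)
        dcol[k] <- dens[idx[1], idx[2], idx[3]]
        mcol[k] <- mask[idx[1], idx[2], idx[3]]
        bcol[k] <- body[idx[1], idx[2], idx[3]]
      }
      if (mode == "intra") {
        out[iu, iv] <- sum(dcol[mcol]) * sp[res$ax]
      } else {
        if (any(mcol) && any(bcol)) {
          a <- which(bcol)[1]
          b <- max(which(mcol))
          if (b >= a) out[iu, iv] <- sum(dcol[a:b]) * sp[res$ax]
        }
      }
    }
  }
  # the BEV u axis maps to -x (gantry 180) or -y (gantry 270): flip rows
  if (res$usgn < 0) out <- out[rev(seq_len(n_u)), , drop = FALSE]
  out
}

# exhaustive gamma search oracle on toy grids (R implementation,
# independent of the compiled search)
oracle_gamma <- function(ref, ev, dose_pct, dist_mm, spacing,
                         step = 0.1, search_factor = 3) {
  crit <- dose_pct / 100 * max(ref)
  nr <- nrow(ref); nc <- ncol(ref)
  xs <- (seq_len(nr) - 1) * spacing[1]
  ys <- (seq_len(nc) - 1) * spacing[2]
  interp <- function(x, y) {
    i <- min(max(floor(x / spacing[1]), 0), nr - 2)
    j <- min(max(floor(y / spacing[2]), 0), nc - 2)
    ax <- x / spacing[1] - i
    ay <- y / spacing[2] - j
    ref[i + 1, j + 1] * (1 - ax) * (1 - ay) +
      ref[i + 2, j + 1] * ax * (1 - ay) +
      ref[i + 1, j + 2] * (1 - ax) * ay +
      ref[i + 2, j + 2] * ax * ay
  }
  rad <- search_factor * dist_mm
  offs <- seq(-rad, rad, by = step)
  g <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- Inf
      for (dx in offs) {
        for (dy in offs) {
          if (dx^2 + dy^2 > rad^2) next
          x <- xs[i] + dx; y <- ys[j] + dy
          if (x < 0 || y < 0 || x > xs[nr] || y > ys[nc]) next
          gg <- ((ev[i, j] - interp(x, y)) / crit)^2 +
            (dx^2 + dy^2) / dist_mm^2
          if (gg < best) best <- gg
        }
      }
      g[i, j] <- sqrt(best)
    }
  }
  g
}

# type-7 quantile written out longhand (independent of stats::quantile)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
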