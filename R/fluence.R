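#' Fluence map for one beam
#'
#' @param values Nonnegative numeric matrix on the fluence grid.
#' @param grid A [fluence_grid()].
#' @param beam Beam index (1-based).
#' @param clipped Logical: have values outside the jaw rectangle been zeroed?
#' @return Object of class `fluence_map`.
#' @export
fluence_map <- function(values, grid = fluence_grid(), beam = 1L,
                        clipped = FALSE) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("fluence values must be finite")
  if (any(values < 0)) stop("fluence values must be nonnegative")
  if (!all(dim(values) == grid$n_pixels))
    stop(sprintf("fluence must be %d x %d", grid$n_pixels, grid$n_pixels))
  structure(list(values = values, grid = grid, beam = as.integer(beam),
                 clipped = isTRUE(clipped)),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> beam %d, %dx%d @ %g mm, max %.4g%s\n", x$beam,
              nrow(x$values), ncol(x$values), x$grid$pixel_mm,
              max(x$values), if (x$clipped) ", jaw-clipped" else ""))
  invisible(x)
}

#' The six parotid/target tradeoff profiles
#'
#' Each profile pairs a parotid sparing preference (both, left only, right
#' only) with a PTV-vs-OAR priority: BP, BO, LP, LO, RP, RO.
#'
#' @param label One of `"BP"`, `"BO"`, `"LP"`, `"LO"`, `"RP"`, `"RO"`.
#' @return Object of class `tradeoff_profile` with fields `label`,
#'   `parotid_weighting` (`"both"`, `"left"`, `"right"`) and
#'   `ptv_oar_preference` (`"PTV"` or `"OAR"`).
#' @export
tradeoff_profile <- function(label) {
  labels <- tradeoff_labels()
  if (!is.character(label) || length(label) != 1L || !label %in% labels)
    stop("unknown tradeoff profile: ", paste(label, collapse = ", "))
  weighting <- switch(substr(label, 1, 1),
                      B = "both", L = "left", R = "right")
  preference <- if (substr(label, 2, 2) == "P") "PTV" else "OAR"
  structure(list(label = label, parotid_weighting = weighting,
                 ptv_oar_preference = preference),
            class = "tradeoff_profile")
}

#' @rdname tradeoff_profile
#' @export
tradeoff_labels <- function() c("BP", "BO", "LP", "LO", "RP", "RO")

#' @export
print.tradeoff_profile <- function(x, ...) {
  cat(sprintf("<tradeoff_profile> %s: parotid weighting '%s', prioritize %s\n",
              x$label, x$parotid_weighting, x$ptv_oar_preference))
  invisible(x)
}

# --- predictor registry ----------------------------------------------------

predictor_registry <- new.env(parent = emptyenv())

#' Register or look up a fluence predictor
#'
#' A predictor is a function `(stacks, profile, template, params) -> list of
#' fluence_map`, one per beam. The built-in `"baseline"` predictor is
#' registered at load time; trained models can be plugged in under new names
#' without touching the rest of the pipeline.
#'
#' @param name Predictor name.
#' @param fn Predictor function.
#' @return `register_predictor()` returns `name` invisibly;
#'   `get_predictor()` the function; `list_predictors()` the names.
#' @export
register_predictor <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = predictor_registry)
  invisible(name)
}

#' @rdname register_predictor
#' @export
get_predictor <- function(name) {
  if (!exists(name, envir = predictor_registry))
    stop("unknown predictor: ", name)
  get(name, envir = predictor_registry)
}

#' @rdname register_predictor
#' @export
list_predictors <- function() ls(predictor_registry)

#' Predict fluence maps for all beams of a template
#'
#' Dispatches to a registered predictor. The contract: one nonnegative
#' fluence map per stack on the stack's grid, deterministic given identical
#' inputs, with the tradeoff profile modulating the output wherever parotid
#' channels are nonzero.
#'
#' @param stacks List of [build_stack()] results, one per beam.
#' @param profile A [tradeoff_profile()] or its label.
#' @param template The [beam_template()] the stacks came from (used for jaw
#'   clipping).
#' @param predictor Registered predictor name (default `"baseline"`).
#' @param params Optional list of predictor parameters.
#' @return List of [fluence_map()], one per beam.
#' @export
predict_fluence <- function(stacks, profile, template,
                            predictor = "baseline", params = list()) {
  if (is.character(profile)) profile <- tradeoff_profile(profile)
  stopifnot(inherits(profile, "tradeoff_profile"))
  fn <- get_predictor(predictor)
  maps <- fn(stacks, profile, template, params)
  if (length(maps) != length(stacks))
    stop("predictor returned ", length(maps), " maps for ", length(stacks),
         " stacks")
  maps
}

#' Deterministic conformal baseline predictor
#'
#' A stand-in for a trained fluence model that makes the pipeline exercisable
#' end to end: a uniform aperture over the PTV's interface projection, with
#' multiplicative attenuation over each spared parotid's BEV shadow (stronger
#' for OAR-priority profiles, and stronger still when a single parotid
#' carries the whole sparing preference), Gaussian edge feathering, and jaw
#' clipping. Parameters (all in `params`): `threshold` (aperture threshold on
#' the normalized PTV channel, default 0.05), `feather_px` (Gaussian sigma in
#' pixels, default 1), `w_ptv` (parotid attenuation for *P profiles, default
#' 0.7), `w_oar` (for *O profiles, default 0.4). These are package defaults
#' chosen for plausible tradeoff behaviour, not fitted values.
#'
#' @param stacks List of projection stacks.
#' @param profile A [tradeoff_profile()].
#' @param template A [beam_template()] (for jaw clipping; `NULL` to skip).
#' @param params Parameter overrides, see above.
#' @return List of [fluence_map()].
#' @export
baseline_conformal <- function(stacks, profile, template = NULL,
                               params = list()) {
  if (is.character(profile)) profile <- tradeoff_profile(profile)
  p <- modifyList(list(threshold = 0.05, feather_px = 1, w_ptv = 0.7,
                       w_oar = 0.4), params)
  w <- if (profile$ptv_oar_preference == "PTV") p$w_ptv else p$w_oar
  spared <- switch(profile$parotid_weighting,
                   both = c(Parotid_L = w, Parotid_R = w),
                   left = c(Parotid_L = w^2),
                   right = c(Parotid_R = w^2))
  lapply(stacks, function(st) {
    ptv <- st$channels[["interface:PTV"]]
    m <- max(ptv)
    ptvn <- if (m > 0) ptv / m else ptv
    f <- (ptvn > p$threshold) * 1.0
    for (nm in names(spared)) {
      shadow <- st$channels[[paste0("interface:", nm)]]
      ms <- max(shadow)
      if (ms > 0) f[shadow / ms > p$threshold] <-
          f[shadow / ms > p$threshold] * spared[[nm]]
    }
    if (p$feather_px > 0) f <- blur2d(f, p$feather_px)
    fm <- fluence_map(f, st$grid, st$beam, clipped = FALSE)
    if (!is.null(template) && !is.null(template$jaws_mm))
      fm <- clip_to_jaws(fm, template$jaws_mm[st$beam, ])
    fm
  })
}

blur2d <- function(m, sigma_px) {
  arr <- array(m, dim = c(nrow(m), ncol(m), 1L))
  out <- .gauss_blur3_cpp(as.numeric(arr), dim(arr), c(sigma_px, sigma_px, 0))
  matrix(out, nrow(m), ncol(m))
}

#' Zero fluence outside a jaw rectangle
#'
#' @param fm A [fluence_map()].
#' @param jaws Length-4 vector `(x1, x2, y1, y2)` in mm (isocenter plane).
#' @return The clipped [fluence_map()] with `clipped = TRUE`.
#' @export
clip_to_jaws <- function(fm, jaws) {
  stopifnot(inherits(fm, "fluence_map"), length(jaws) == 4L)
  keep_u <- fm$grid$u >= jaws[1] & fm$grid$u <= jaws[2]
  keep_v <- fm$grid$v >= jaws[3] & fm$grid$v <= jaws[4]
  v <- fm$values * outer(keep_u, keep_v)
  fluence_map(v, fm$grid, fm$beam, clipped = TRUE)
}

# --- plain-text fluence exchange format ------------------------------------

#' Read and write fluence maps as plain text
#'
#' TPS-style exchange dialect: a small key/value header (`beam`, `pixels`,
#' `pixel_mm`) followed by the matrix, whitespace-separated, one v-row per
#' line. The round trip is lossless at full double precision.
#'
#' @param fm A [fluence_map()].
#' @param path File path.
#' @param expect_pixels Grid size enforced on read (default 128; `NULL` to
#'   accept any).
#' @return `read_fluence()` returns a [fluence_map()].
#' @export
write_fluence <- function(fm, path) {
  stopifnot(inherits(fm, "fluence_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# hnplanr fluence"),
               sprintf("beam: %d", fm$beam),
               sprintf("pixels: %d", fm$grid$n_pixels),
               sprintf("pixel_mm: %.17g", fm$grid$pixel_mm),
               sprintf("clipped: %d", as.integer(fm$clipped))), con)
  write.table(format(t(fm$values), digits = 17, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path, expect_pixels = 128L) {
  lines <- readLines(path)
  hdr <- grep("^[a-z_]+:", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("fluence file missing header field '", key, "'")
    sub(paste0("^", key, ":\\s*"), "", ln[1])
  }
  n <- as.integer(getv("pixels"))
  px <- as.numeric(getv("pixel_mm"))
  beam <- as.integer(getv("beam"))
  clipped <- as.integer(getv("clipped")) == 1L
  if (!is.null(expect_pixels) && n != expect_pixels)
    stop(sprintf("fluence grid is %d pixels, expected %d", n, expect_pixels))
  body <- lines[!grepl("^#", lines) & !grepl("^[a-z_]+:", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) stop("fluence body has wrong number of rows")
  vals <- t(vapply(strsplit(trimws(body), "\\s+"), function(x) {
    v <- as.numeric(x)
    if (length(v) != n) stop("fluence body has wrong number of columns")
    v
  }, numeric(n)))
  fluence_map(t(vals), fluence_grid(n, px), beam, clipped)
}
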