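#' Read and write voxel volumes
#'
#' Volumes are exchanged as NIfTI (via RNifti) or raw-encoded NRRD. The
#' package's patient-axis convention is written to file verbatim (the affine
#' is `diag(spacing)` with the first-voxel-centre origin in the last column),
#' so a write/read round trip reproduces values, spacing and origin.
#'
#' @param volume A [voxel_volume()].
#' @param path File path; format inferred from extension (`.nii`, `.nii.gz`,
#'   `.nrrd`) unless `format` is given.
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @param unit Unit to attach on read (`"HU"`, `"Gy"`, `"unitless"`).
#' @return `read_volume()` returns a [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(inherits(volume, "voxel_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- volume$spacing_mm
    aff <- diag(c(volume$spacing_mm, 1))
    aff[1:3, 4] <- volume$origin_mm
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    write_nrrd(volume, path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd"),
                        unit = c("HU", "Gy", "unitless")) {
  unit <- match.arg(unit)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    spacing <- apply(aff[1:3, 1:3], 2, function(v) sqrt(sum(v^2)))
    origin <- aff[1:3, 4]
    voxel_volume(array(as.numeric(img), dim = dim(img)),
                 spacing_mm = spacing, origin_mm = origin, unit = unit)
  } else {
    read_nrrd(path, unit = unit)
  }
}

guess_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("cannot infer volume format from extension of ", path)
}

# Minimal NRRD writer: raw little-endian doubles, diagonal space directions.
write_nrrd <- function(volume, path) {
  d <- dim(volume$values)
  sp <- volume$spacing_mm
  o <- volume$origin_mm
  hdr <- c(
    "NRRD0004",
    "# generated by hnplanr",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path, unit = "unitless") {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated NRRD header in ", path)
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  fields <- lines[grepl(":", lines, fixed = TRUE) & !grepl("^#", lines)]
  kv <- do.call(rbind, lapply(strsplit(fields, ":\\s*"), function(x)
    c(tolower(x[1]), paste(x[-1], collapse = ":"))))
  get_field <- function(key) {
    i <- match(key, kv[, 1])
    if (is.na(i)) NA_character_ else kv[i, 2]
  }
  type <- get_field("type")
  if (!type %in% c("double", "float")) stop("unsupported NRRD type: ", type)
  enc <- get_field("encoding")
  if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  sizes <- as.integer(strsplit(trimws(get_field("sizes")), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD supported")
  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(m, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  sd_field <- get_field("space directions")
  spacing <- c(1, 1, 1)
  if (!is.na(sd_field)) {
    vecs <- parse_vecs(sd_field)
    spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), numeric(1))
  }
  origin <- c(0, 0, 0)
  so_field <- get_field("space origin")
  if (!is.na(so_field)) origin <- parse_vecs(so_field)[[1]]
  n <- prod(sizes)
  sz <- if (type == "double") 8L else 4L
  vals <- readBin(con, "numeric", n = n, size = sz, endian = "little")
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  voxel_volume(array(vals, dim = sizes), spacing_mm = spacing,
               origin_mm = origin, unit = unit)
}

#' Read and write structure sets
#'
#' A structure set is stored as one binary-mask volume file per structure
#' plus a `structures.json` manifest holding names, roles, prescriptions and
#' the file format. Masks may overlap (the CTV lies inside the PTV), which a
#' single labelmap cannot represent losslessly.
#'
#' @param structures A [structure_set()].
#' @param dir Directory to write into / read from.
#' @param format `"nifti"` or `"nrrd"`.
#' @param volume Reference [voxel_volume()] the masks must match; when `NULL`
#'   (the default) the reference grid is taken from the stored BODY mask.
#' @return `read_structures()` returns a [structure_set()];
#'   `write_structures()` returns `dir` invisibly.
#' @export
write_structures <- function(structures, dir, format = c("nifti", "nrrd")) {
  stopifnot(inherits(structures, "structure_set"))
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (nm in names(structures$masks)) {
    fname <- paste0(gsub("[^A-Za-z0-9_+-]", "_", nm), ext)
    v <- voxel_volume(array(as.numeric(structures$masks[[nm]]),
                            dim = dim(structures$volume$values)),
                      spacing_mm = structures$volume$spacing_mm,
                      origin_mm = structures$volume$origin_mm,
                      unit = "unitless")
    write_volume(v, file.path(dir, fname), format = format)
    files[[nm]] <- fname
  }
  manifest <- list(format = format, files = files,
                   roles = as.list(structures$roles),
                   rx_gy = as.list(structures$rx_gy))
  jsonlite::write_json(manifest, file.path(dir, "structures.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_structures
#' @export
read_structures <- function(dir, volume = NULL) {
  mpath <- file.path(dir, "structures.json")
  if (!file.exists(mpath)) stop("no structures.json manifest in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  masks <- list()
  ref <- volume
  for (nm in names(manifest$files)) {
    v <- read_volume(file.path(dir, manifest$files[[nm]]),
                     format = manifest$format, unit = "unitless")
    if (is.null(ref) && identical(manifest$roles[[nm]], "BODY")) ref <- v
    masks[[nm]] <- array(v$values > 0.5, dim = dim(v$values))
    attr(masks[[nm]], "grid") <- list(spacing = v$spacing_mm,
                                      origin = v$origin_mm)
  }
  if (is.null(ref)) stop("no reference volume given and no BODY mask stored")
  for (nm in names(masks)) {
    g <- attr(masks[[nm]], "grid")
    if (!identical(dim(masks[[nm]]), dim(ref$values)) ||
        any(abs(g$spacing - ref$spacing_mm) > 1e-6) ||
        any(abs(g$origin - ref$origin_mm) > 1e-6))
      stop(sprintf("mask '%s' grid does not match the reference volume", nm))
    attr(masks[[nm]], "grid") <- NULL
  }
  rx <- unlist(manifest$rx_gy)
  rx <- if (is.null(rx)) numeric() else
    setNames(as.numeric(rx), names(rx))
  structure_set(ref, masks, unlist(manifest$roles), rx_gy = rx)
}
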