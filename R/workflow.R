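#' Write a phantom as an on-disk planning case
#'
#' Lays out a case directory the three-step workflow operates on:
#' `ct.nii.gz` plus a `structures/` directory (one mask per structure and a
#' role manifest).
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Case directory (created if needed).
#' @param format Volume format, `"nifti"` or `"nrrd"`.
#' @return `dir`, invisibly.
#' @export
write_case <- function(phantom, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  stopifnot(inherits(phantom, "hn_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  write_volume(phantom$ct, file.path(dir, paste0("ct", ext)), format)
  write_structures(phantom$structures, file.path(dir, "structures"), format)
  invisible(dir)
}

read_case <- function(dir) {
  ct_path <- c(Sys.glob(file.path(dir, "ct.nii.gz")),
               Sys.glob(file.path(dir, "ct.nii")),
               Sys.glob(file.path(dir, "ct.nrrd")))
  if (!length(ct_path)) stop("no CT volume found in ", dir)
  ct <- read_volume(ct_path[1], unit = "HU")
  structures <- read_structures(file.path(dir, "structures"), volume = ct)
  list(ct = ct, structures = structures)
}

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (!file.exists(p)) list(steps = list()) else
    jsonlite::read_json(p, simplifyVector = TRUE)
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(dir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Workflow step 1: structure checks and template preparation
#'
#' Mirrors the first pause-review-continue stage of the planning workflow:
#' validates the structure-name mapping against the standard set (listing
#' candidates when something is unmapped), places the isocenter, lays out
#' the 9-beam template, fits the jaws, applies any user overrides, and
#' writes `plan.json` plus the run manifest.
#'
#' @param dir Case directory (see [write_case()]).
#' @param mapping Named character vector `standard name -> stored name`;
#'   `NULL` when the stored names are already standard.
#' @param overrides Optional list with `isocenter_mm` and/or `jaws_mm`,
#'   honoured verbatim and recorded in the manifest.
#' @param n_beams,start_deg,step_deg,sad_mm,margin_mm Template settings.
#' @return The fitted [beam_template()], invisibly.
#' @export
step1_prepare <- function(dir, mapping = NULL, overrides = list(),
                          n_beams = 9, start_deg = 180, step_deg = 40,
                          sad_mm = 1000, margin_mm = 7) {
  case <- read_case(dir)
  structures <- case$structures
  if (!is.null(mapping)) {
    missing_target <- setdiff(mapping, names(structures$masks))
    if (length(missing_target))
      stop("mapping refers to absent structures: ",
           paste(missing_target, collapse = ", "))
    renamed <- structures$masks[mapping]
    names(renamed) <- names(mapping)
    keep <- setdiff(names(structures$masks), mapping)
    masks <- c(renamed, structures$masks[keep])
    roles <- structures$roles[c(mapping, keep)]
    names(roles) <- names(masks)
    rx <- structures$rx_gy
    hit <- match(names(rx), mapping)
    names(rx)[!is.na(hit)] <- names(mapping)[hit[!is.na(hit)]]
    structures <- structure_set(structures$volume, masks, roles, rx)
  }
  need <- c(hn_standard_structures(), "BODY")
  miss <- setdiff(need, names(structures$masks))
  if (length(miss))
    stop("unmapped required structure(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(structures$masks), collapse = ", "))
  iso <- if (!is.null(overrides$isocenter_mm))
    as.numeric(overrides$isocenter_mm) else place_isocenter(structures)
  tpl <- beam_template(iso, place_beams(n_beams, start_deg, step_deg),
                       sad_mm = sad_mm)
  tpl <- fit_jaws(structures, tpl, margin_mm = margin_mm)
  if (!is.null(overrides$jaws_mm))
    tpl <- beam_template(iso, tpl$gantry_deg, as.matrix(overrides$jaws_mm),
                         sad_mm)
  write_plan(tpl, file.path(dir, "plan.json"))
  manifest <- read_manifest(dir)
  manifest$steps$step1 <- list(
    done = TRUE,
    mapping = if (is.null(mapping)) NULL else as.list(mapping),
    overrides = lapply(overrides, function(x)
      if (is.matrix(x)) apply(x, 1, as.list) else x),
    config = list(n_beams = n_beams, start_deg = start_deg,
                  step_deg = step_deg, sad_mm = sad_mm,
                  margin_mm = margin_mm))
  write_manifest(dir, manifest)
  invisible(tpl)
}

#' Workflow step 2: projection and fluence prediction
#'
#' Builds the 12-channel projection stacks for every beam and runs the
#' requested predictor for each tradeoff profile, storing per-profile
#' fluence directories in the TPS-style text format.
#'
#' @param dir Case directory; step 1 must have been run.
#' @param profiles Profile labels (default: all six).
#' @param predictor Registered predictor name.
#' @param params Predictor parameters.
#' @return Invisibly, a named list of fluence-map lists per profile.
#' @export
step2_predict <- function(dir, profiles = tradeoff_labels(),
                          predictor = "baseline", params = list()) {
  if (!file.exists(file.path(dir, "plan.json")))
    stop("step 1 has not produced plan.json in ", dir)
  case <- read_case(dir)
  tpl <- read_plan(file.path(dir, "plan.json"))
  stacks <- build_stacks(case$ct, case$structures, tpl)
  out <- list()
  for (prof in profiles) {
    maps <- predict_fluence(stacks, prof, tpl, predictor, params)
    pdir <- file.path(dir, "fluence", prof)
    if (!dir.exists(pdir)) dir.create(pdir, recursive = TRUE)
    for (b in seq_along(maps))
      write_fluence(maps[[b]], file.path(pdir, sprintf("beam_%02d.txt", b)))
    out[[prof]] <- maps
  }
  manifest <- read_manifest(dir)
  manifest$steps$step2 <- list(done = TRUE, profiles = profiles,
                               predictor = predictor)
  write_manifest(dir, manifest)
  invisible(out)
}

#' Workflow step 3: dose, normalization and evaluation
#'
#' Runs the dose engine on a profile's predicted fluence, normalizes to the
#' prescription covering 95% of the PTV, and writes the endpoint table and
#' DVHs for planner review; optionally gamma-compares a beam's portal plane
#' against a provided reference.
#'
#' @param dir Case directory; steps 1 and 2 must have been run.
#' @param profile Profile label to finalize.
#' @param rx_gy Prescription, Gy (default 44).
#' @param engine_params Passed to [compute_dose()].
#' @param reference_portal Optional list per beam of reference planar doses
#'   for gamma QA; `NULL` skips QA.
#' @return List with `dose`, `endpoints`, `dvh`, and `qa` (or `NULL`).
#' @export
step3_finalize <- function(dir, profile, rx_gy = 44, engine_params = list(),
                           reference_portal = NULL) {
  pdir <- file.path(dir, "fluence", profile)
  if (!dir.exists(pdir))
    stop("step 2 has not produced fluence maps for profile ", profile)
  case <- read_case(dir)
  tpl <- read_plan(file.path(dir, "plan.json"))
  files <- sort(Sys.glob(file.path(pdir, "beam_*.txt")))
  fluences <- lapply(files, read_fluence)
  dose <- compute_dose(case$ct, case$structures, tpl, fluences,
                       engine_params)
  dose <- normalize_to_prescription(dose, case$structures$masks$PTV, rx_gy)
  endpoints <- endpoint_table(dose, case$structures, rx_gy, fluences,
                              label = profile)
  curves <- dvh_all(dose, case$structures)
  edir <- file.path(dir, "eval", profile)
  if (!dir.exists(edir)) dir.create(edir, recursive = TRUE)
  utils::write.csv(endpoints, file.path(edir, "endpoints.csv"),
                   row.names = FALSE)
  utils::write.csv(curves, file.path(edir, "dvh.csv"), row.names = FALSE)
  qa <- NULL
  if (!is.null(reference_portal)) {
    qa <- field_pass_report(purrr::imap(reference_portal, function(ref, b) {
      pp <- portal_plane(fluences[[as.integer(b)]])
      list(reference = ref, evaluated = pp$plane)
    }))
  }
  manifest <- read_manifest(dir)
  manifest$steps$step3 <- c(manifest$steps$step3,
                            setNames(list(list(done = TRUE, rx_gy = rx_gy,
                                               qa = !is.null(qa))), profile))
  write_manifest(dir, manifest)
  list(dose = dose, endpoints = endpoints, dvh = curves, qa = qa)
}

#' End-to-end plan generation in memory
#'
#' Convenience wrapper running template automation, projection, prediction,
#' dose and evaluation for one phantom and one tradeoff profile without
#' touching disk.
#'
#' @param phantom A [generate_phantom()] result.
#' @param profile Tradeoff profile label (default `"BP"`).
#' @param predictor Registered predictor name.
#' @param rx_gy Prescription, Gy.
#' @param engine_params Passed to [compute_dose()].
#' @param params Predictor parameters.
#' @return List with `template`, `stacks`, `fluences`, `dose` (normalized),
#'   `endpoints`, `dvh`.
#' @export
plan_case <- function(phantom, profile = "BP", predictor = "baseline",
                      rx_gy = 44, engine_params = list(), params = list()) {
  stopifnot(inherits(phantom, "hn_phantom"))
  tpl <- auto_template(phantom$structures)
  stacks <- build_stacks(phantom$ct, phantom$structures, tpl)
  fluences <- predict_fluence(stacks, profile, tpl, predictor, params)
  dose <- compute_dose(phantom$ct, phantom$structures, tpl, fluences,
                       engine_params)
  dose <- normalize_to_prescription(dose, phantom$structures$masks$PTV,
                                    rx_gy)
  endpoints <- endpoint_table(dose, phantom$structures, rx_gy, fluences,
                              label = profile)
  list(template = tpl, stacks = stacks, fluences = fluences, dose = dose,
       endpoints = endpoints, dvh = dvh_all(dose, phantom$structures))
}
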