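#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; ties
#' among the absolute differences receive midranks. For n <= 12 remaining
#' pairs the p-value is exact, by enumeration of all 2^n sign assignments of
#' the (mid)ranks; for larger n the normal approximation with tie correction
#' and a 0.5 continuity correction is used. If every difference is zero the
#' test is degenerate and returns p = 1 with a warning.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param exact_max Largest n for which exact enumeration is used
#'   (default 12).
#' @return List of class `paired_wilcoxon`: `statistic` (V, sum of positive
#'   ranks), `p_value`, `n` (pairs after dropping zeros), `method`.
#' @export
paired_wilcoxon <- function(x, y, exact_max = 12) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; test is degenerate")
    return(structure(list(statistic = 0, p_value = 1, n = 0L,
                          method = "degenerate"),
                     class = "paired_wilcoxon"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign assignments of the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    p <- 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9))
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    ev <- n * (n + 1) / 4
    ties <- table(r)
    varv <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - ev
    z <- (z - sign(z) * 0.5) / sqrt(varv)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  structure(list(statistic = v, p_value = p, n = as.integer(n),
                 method = method),
            class = "paired_wilcoxon")
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat(sprintf("<paired_wilcoxon> V = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' @export
tidy.paired_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, n = x$n,
                 method = x$method)
}

#' Bonferroni significance flags
#'
#' A p-value is flagged significant iff `p <= alpha / m`, with `m` the
#' number of comparisons in the family (equivalently `min(1, p * m) <=
#' alpha`).
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Family size (default `length(p)`).
#' @return Logical vector of flags.
#' @export
bonferroni_flags <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), alpha > 0, m >= 1)
  p <= alpha / m
}

#' Assign a case to a parotid-tradeoff group
#'
#' Commissioning cases are grouped by the dosimetric tradeoff between the
#' parotids of their clinical plan: `bilateral` when left and right parotid
#' median doses are within `tau_gy` of each other, otherwise the group of the
#' lower-dose (spared) side.
#'
#' @param parotid_l_gy,parotid_r_gy Clinical parotid median doses, Gy.
#' @param tau_gy Similarity threshold, Gy (default 3).
#' @return `"bilateral"`, `"left"` or `"right"`.
#' @export
assign_group <- function(parotid_l_gy, parotid_r_gy, tau_gy = 3) {
  if (is.na(parotid_l_gy) || is.na(parotid_r_gy))
    stop("both parotid median doses are required")
  delta <- parotid_l_gy - parotid_r_gy
  if (abs(delta) <= tau_gy) "bilateral" else if (delta < 0) "left" else "right"
}

group_profiles <- function(group) {
  switch(group,
         bilateral = c(P = "BP", O = "BO"),
         left = c(P = "LP", O = "LO"),
         right = c(P = "RP", O = "RO"),
         stop("unknown group: ", group))
}

#' DVH band aggregation across cases
#'
#' Pointwise median and 25-75 percentile envelope of percentage volume over
#' cases, per structure and plan type, on a common dose axis (curves are
#' linearly resampled first).
#'
#' @param dvhs Tibble with columns `case`, `structure`, `dose_gy`,
#'   `volume_pct` and optionally `plan`.
#' @param structure Structure to aggregate (default: all present).
#' @param axis_gy Common dose axis; defaults to a 0.5 Gy grid spanning the
#'   input.
#' @return Tibble of class `dvh_bands` with columns `structure`, `plan`,
#'   `dose_gy`, `median_pct`, `q25_pct`, `q75_pct`, `n_cases`.
#' @export
dvh_bands <- function(dvhs, structure = NULL, axis_gy = NULL) {
  stopifnot(all(c("case", "structure", "dose_gy", "volume_pct") %in%
                  names(dvhs)))
  if (!"plan" %in% names(dvhs)) dvhs$plan <- "plan"
  if (!is.null(structure)) {
    keep <- structure
    dvhs <- dplyr::filter(dvhs, .data$structure %in% keep)
  }
  if (is.null(axis_gy))
    axis_gy <- seq(0, max(dvhs$dose_gy), by = 0.5)
  resampled <- dvhs |>
    dplyr::group_by(.data$case, .data$structure, .data$plan) |>
    dplyr::reframe(dose_gy = axis_gy,
                   volume_pct = resample_dvh(.data$dose_gy, .data$volume_pct,
                                             axis_gy))
  out <- resampled |>
    dplyr::group_by(.data$structure, .data$plan, .data$dose_gy) |>
    dplyr::summarise(median_pct = median(.data$volume_pct),
                     q25_pct = unname(quantile(.data$volume_pct, 0.25,
                                               type = 7)),
                     q75_pct = unname(quantile(.data$volume_pct, 0.75,
                                               type = 7)),
                     n_cases = dplyr::n(), .groups = "drop")
  class(out) <- c("dvh_bands", class(out))
  out
}

resample_dvh <- function(dose, vol, axis) {
  o <- order(dose)
  stats::approx(dose[o], vol[o], xout = axis, yleft = 100, yright = 0,
                rule = 2)$y
}

#' Synthetic commissioning cohort generator
#'
#' Generates per-case endpoint tables for a clinical plan and the six
#' tradeoff plans, emulating a commissioning cohort without any clinical
#' data. Clinical endpoint values are drawn around typical bilateral
#' head-and-neck magnitudes; cases are spread over the three parotid-tradeoff
#' groups by construction. The six per-profile values are the clinical value
#' plus a deterministic profile effect (matching the designed tradeoff
#' directions: *O profiles trade target homogeneity for OAR sparing), plus
#' `ai_shift` for endpoints listed there, plus paired noise.
#'
#' @param n_cases Number of cases (default 50).
#' @param seed RNG seed.
#' @param tau_gy Grouping threshold passed to [assign_group()].
#' @param ai_shift Named numeric vector of additional constant shifts applied
#'   to the AI plans for specific endpoints (names as in [endpoint_table()]);
#'   used for power/recovery checks.
#' @param noise_frac Paired noise per endpoint, as a fraction of that
#'   endpoint's population spread (default 0.5).
#' @param profile_effects Override the built-in per-endpoint profile effects;
#'   a tibble with columns `endpoint`, `effect_P`, `effect_O`.
#' @return Tibble with columns `case`, `group`, `plan`, `endpoint`, `value`.
#' @export
simulate_commissioning_cohort <- function(n_cases = 50, seed = 1L,
                                          tau_gy = 3, ai_shift = NULL,
                                          noise_frac = 0.5,
                                          profile_effects = NULL) {
  base <- clinical_endpoint_baseline()
  if (is.null(profile_effects)) profile_effects <- default_profile_effects()
  with_preserved_rng(seed, {
    cases <- lapply(seq_len(n_cases), function(i) {
      lat <- sample(c("bilateral", "left", "right"), 1,
                    prob = c(0.36, 0.32, 0.32))
      clin <- base$center + rnorm(nrow(base), 0, base$spread)
      names(clin) <- base$endpoint
      # impose the case's parotid laterality on the clinical plan
      gap <- tau_gy + abs(rnorm(1, 4, 1.5))
      if (lat == "left") {
        clin["Parotid_L Dmedian_Gy"] <- clin["Parotid_R Dmedian_Gy"] - gap
      } else if (lat == "right") {
        clin["Parotid_R Dmedian_Gy"] <- clin["Parotid_L Dmedian_Gy"] - gap
      } else {
        clin["Parotid_R Dmedian_Gy"] <- clin["Parotid_L Dmedian_Gy"] +
          rnorm(1, 0, tau_gy / 4)
      }
      clin <- pmax(clin, 0.1)
      grp <- assign_group(clin[["Parotid_L Dmedian_Gy"]],
                          clin[["Parotid_R Dmedian_Gy"]], tau_gy)
      rows <- list(tibble::tibble(case = i, group = grp, plan = "Clinical",
                                  endpoint = base$endpoint,
                                  value = unname(clin)))
      for (pref in c("P", "O")) {
        lbl <- group_profiles(grp)[[pref]]
        eff <- profile_effects[[paste0("effect_", pref)]]
        val <- clin + eff + rnorm(nrow(base), 0, noise_frac * base$spread)
        if (!is.null(ai_shift)) {
          hit <- intersect(names(ai_shift), base$endpoint)
          val[hit] <- val[hit] + ai_shift[hit]
        }
        rows <- c(rows, list(tibble::tibble(case = i, group = grp,
                                            plan = lbl,
                                            endpoint = base$endpoint,
                                            value = pmax(unname(val), 0))))
      }
      dplyr::bind_rows(rows)
    })
    dplyr::bind_rows(cases)
  })
}

clinical_endpoint_baseline <- function() {
  tibble::tibble(
    endpoint = c("PTV CI", "PTV HI", "BODY D1cc_Gy", "Brainstem D0.1cc_Gy",
                 "Cord+5mm D0.1cc_Gy", "Parotid_L Dmedian_Gy",
                 "Parotid_R Dmedian_Gy", "OralCavity Dmedian_Gy",
                 "Larynx Dmedian_Gy", "Pharynx Dmedian_Gy",
                 "Mandible D1cc_Gy", "plan TotalMU"),
    center = c(1.20, 9.3, 47.8, 15.7, 31.0, 13.6, 13.0, 19.3, 17.8, 34.1,
               44.1, 1841),
    spread = c(0.08, 1.5, 0.7, 7, 2.7, 2.4, 2.1, 6.4, 4.4, 4.1, 2.9, 250)
  )
}

default_profile_effects <- function() {
  ep <- clinical_endpoint_baseline()$endpoint
  effP <- setNames(numeric(length(ep)), ep)
  effO <- effP
  # *P: tighter conformity, slightly higher parotid dose, fewer MU
  effP["PTV CI"] <- -0.10
  effP[c("Parotid_L Dmedian_Gy", "Parotid_R Dmedian_Gy")] <- 3.5
  effP["plan TotalMU"] <- -350
  # *O: OAR sparing at the cost of target homogeneity and hot spots
  effO["PTV HI"] <- 6.0
  effO["BODY D1cc_Gy"] <- 1.8
  effO[c("Parotid_L Dmedian_Gy", "Parotid_R Dmedian_Gy")] <- -0.8
  effO["Cord+5mm D0.1cc_Gy"] <- -4.5
  effO["Pharynx Dmedian_Gy"] <- -2.0
  tibble::tibble(endpoint = ep, effect_P = unname(effP),
                 effect_O = unname(effO))
}

#' Commissioning comparison report
#'
#' The full commissioning analysis over a cohort of paired endpoint tables:
#' cases are grouped by parotid tradeoff, and within each group every
#' endpoint is summarized as median (IQR) per plan type and compared with
#' paired Wilcoxon signed-rank tests — clinical vs the group's *P plan (p1),
#' clinical vs *O (p2), *P vs *O (p3) — with Bonferroni correction over the
#' endpoint family within each comparison column.
#'
#' @param dataset Tibble as produced by [simulate_commissioning_cohort()]
#'   (columns `case`, `plan`, `endpoint`, `value`, and optionally `group`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param tau_gy Grouping threshold when `group` is absent (default 3).
#' @param m Bonferroni family size; defaults to the number of endpoints.
#' @return Object of class `commission_report` with elements `table` (tidy
#'   per-group statistics), `alpha`, `m`, `tau_gy`, `n_cases`, `groups`.
#' @export
build_report <- function(dataset, alpha = 0.05, tau_gy = 3, m = NULL) {
  need <- c("case", "plan", "endpoint", "value")
  stopifnot(all(need %in% names(dataset)))
  if (!"group" %in% names(dataset)) {
    grp_tbl <- dataset |>
      dplyr::filter(.data$plan == "Clinical",
                    .data$endpoint %in% c("Parotid_L Dmedian_Gy",
                                          "Parotid_R Dmedian_Gy")) |>
      tidyr::pivot_wider(id_cols = "case", names_from = "endpoint",
                         values_from = "value") |>
      dplyr::rowwise() |>
      dplyr::mutate(group = assign_group(.data$`Parotid_L Dmedian_Gy`,
                                         .data$`Parotid_R Dmedian_Gy`,
                                         tau_gy)) |>
      dplyr::ungroup() |>
      dplyr::select("case", "group")
    dataset <- dplyr::left_join(dataset, grp_tbl, by = "case")
  }
  endpoints <- unique(dataset$endpoint)
  if (is.null(m)) m <- length(endpoints)
  iqr_fmt <- function(v) sprintf("%.4g (%.4g)", median(v),
                                 unname(quantile(v, 0.75, type = 7)) -
                                   unname(quantile(v, 0.25, type = 7)))
  rows <- list()
  for (grp in intersect(c("bilateral", "left", "right"),
                        unique(dataset$group))) {
    dd <- dplyr::filter(dataset, .data$group == grp)
    prof <- group_profiles(grp)
    wide <- tidyr::pivot_wider(dd, id_cols = c("case", "endpoint"),
                               names_from = "plan", values_from = "value")
    for (ep in endpoints) {
      w <- dplyr::filter(wide, .data$endpoint == ep)
      clin <- w$Clinical
      vp <- w[[prof[["P"]]]]
      vo <- w[[prof[["O"]]]]
      suppress_degenerate <- function(a, b) {
        withCallingHandlers(paired_wilcoxon(a, b)$p_value,
                            warning = function(w) invokeRestart("muffleWarning"))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = grp, endpoint = ep, n = nrow(w),
        clinical = iqr_fmt(clin),
        plan_P = prof[["P"]], summary_P = iqr_fmt(vp),
        plan_O = prof[["O"]], summary_O = iqr_fmt(vo),
        p1 = suppress_degenerate(clin, vp),
        p2 = suppress_degenerate(clin, vo),
        p3 = suppress_degenerate(vp, vo)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(sig1 = bonferroni_flags(.data$p1, alpha, m),
                  sig2 = bonferroni_flags(.data$p2, alpha, m),
                  sig3 = bonferroni_flags(.data$p3, alpha, m)) |>
    dplyr::ungroup()
  structure(list(table = tab, alpha = alpha, m = m, tau_gy = tau_gy,
                 n_cases = length(unique(dataset$case)),
                 groups = table(dplyr::distinct(dataset, .data$case,
                                                .data$group)$group)),
            class = "commission_report")
}

#' @export
print.commission_report <- function(x, ...) {
  cat(sprintf(
    "<commission_report> %d cases (%s); alpha = %g, Bonferroni m = %d\n",
    x$n_cases,
    paste(sprintf("%s: %d", names(x$groups), x$groups), collapse = ", "),
    x$alpha, x$m))
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' @describeIn build_report Tidy per-comparison rows: one row per group,
#'   endpoint and comparison with p-value and Bonferroni flag.
#' @param x A `commission_report`.
#' @param ... Unused.
#' @export
tidy.commission_report <- function(x, ...) {
  x$table |>
    tidyr::pivot_longer(cols = c("p1", "p2", "p3"),
                        names_to = "comparison", values_to = "p_value") |>
    dplyr::mutate(significant = dplyr::case_when(
      comparison == "p1" ~ .data$sig1,
      comparison == "p2" ~ .data$sig2,
      TRUE ~ .data$sig3)) |>
    dplyr::select("group", "endpoint", "n", "comparison", "p_value",
                  "significant")
}

#' @describeIn build_report One-row summary of the analysis settings.
#' @export
glance.commission_report <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, n_groups = length(x$groups),
                 n_endpoints = length(unique(x$table$endpoint)),
                 alpha = x$alpha, m = x$m, tau_gy = x$tau_gy,
                 n_significant = sum(x$table$sig1, x$table$sig2,
                                     x$table$sig3, na.rm = TRUE))
}

#' Write a commissioning report to disk
#'
#' Writes `table2.csv` (the per-group endpoint statistics) and a markdown
#' summary; timestamps are suppressed so reruns are byte-identical.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "commission_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  md <- c("# Commissioning report", "",
          sprintf("Cases: %d; alpha = %g; Bonferroni family size m = %d; grouping threshold tau = %g Gy",
                  report$n_cases, report$alpha, report$m, report$tau_gy),
          "",
          knit_simple_table(report$table))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

knit_simple_table <- function(tab) {
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  hdr <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  body <- apply(df, 1, function(r) paste(r, collapse = " | "))
  c(hdr, sep, body)
}
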