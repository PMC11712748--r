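test_that("signed-rank p-values match the exact reference for n <= 12", {
  # frozen hand case: 6 strictly positive differences -> 2 * (1/2^6)
  pw <- paired_wilcoxon(11:16, rep(10, 6))
  expect_equal(pw$p_value, 0.03125, tolerance = 1e-12)
  expect_identical(pw$method, "exact enumeration")
  expect_equal(pw$statistic, 21)
  # identical samples are degenerate
  expect_warning(p1 <- paired_wilcoxon(1:8, 1:8), "degenerate")
  expect_equal(p1$p_value, 1)
  # exact agreement with the reference implementation for every n <= 12
  set.seed(41)
  for (n in 5:12) {
    for (k in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      ours <- paired_wilcoxon(x, y)$p_value
      ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12,
                   label = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("large-sample approximation matches the tie-corrected reference", {
  set.seed(42)
  for (k in 1:3) {
    x <- rnorm(30); y <- rnorm(30, 0.25)
    expect_equal(paired_wilcoxon(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # ties: rounded data force midranks
  x <- round(rnorm(25, 0, 2)); y <- round(rnorm(25, 0.8, 2))
  expect_equal(paired_wilcoxon(x, y)$p_value,
               suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("Bonferroni flags implement the alpha/m threshold", {
  expect_identical(bonferroni_flags(c(0.04, 0.06), 0.05, m = 1),
                   c(TRUE, FALSE))
  # 0.004 is not significant in a family of 13 at alpha 0.05
  expect_false(bonferroni_flags(0.004, 0.05, m = 13))
  expect_true(bonferroni_flags(0.003, 0.05, m = 13))
  set.seed(43)
  p <- runif(20)
  expect_identical(bonferroni_flags(p, 0.05, 20),
                   pmin(1, p * 20) <= 0.05)
})

test_that("parotid tradeoff grouping follows the lower-dose side with threshold tau", {
  expect_identical(assign_group(15, 15), "bilateral")
  expect_identical(assign_group(10, 20, tau_gy = 3), "left")
  expect_identical(assign_group(20, 10, tau_gy = 3), "right")
  expect_identical(assign_group(12, 14, tau_gy = 3), "bilateral")
  # tau sweep flips only boundary cases
  expect_identical(assign_group(12, 14, tau_gy = 1), "left")
  expect_error(assign_group(NA, 10), "required")
})

test_that("group assignment partitions the simulated cohort", {
  co <- simulate_commissioning_cohort(30, seed = 44)
  per_case <- dplyr::distinct(co, case, group)
  expect_identical(nrow(per_case), 30L)
  expect_true(all(per_case$group %in% c("bilateral", "left", "right")))
  # every case has a clinical plan and its two group profiles
  plans <- co |> dplyr::distinct(case, group, plan) |>
    dplyr::count(case, group)
  expect_true(all(plans$n == 3))
})

test_that("DVH bands are pointwise quartiles and collapse for identical cases", {
  ax <- seq(0, 50, by = 1)
  mk <- function(case, scale) tibble::tibble(
    case = case, structure = "PTV", plan = "X", dose_gy = ax,
    volume_pct = 100 * exp(-(ax / (30 * scale))^6))
  d3 <- dplyr::bind_rows(mk(1, 0.9), mk(2, 1.0), mk(3, 1.1))
  b <- dvh_bands(d3, axis_gy = ax)
  # median of three curves is the middle curve pointwise
  mid <- mk(2, 1.0)
  expect_equal(b$median_pct, mid$volume_pct, tolerance = 1e-9)
  expect_true(all(b$q25_pct <= b$median_pct & b$median_pct <= b$q75_pct))
  # monotone non-increasing in dose
  expect_true(all(diff(b$median_pct) <= 1e-9))
  same <- dplyr::bind_rows(mk(1, 1), mk(2, 1), mk(3, 1))
  b0 <- dvh_bands(same, axis_gy = ax)
  expect_equal(b0$q75_pct - b0$q25_pct, rep(0, nrow(b0)), tolerance = 1e-12)
})

test_that("a cohort with identical plans yields p = 1 and no flags", {
  eff0 <- hnplanr:::default_profile_effects()
  eff0$effect_P <- 0
  eff0$effect_O <- 0
  co <- simulate_commissioning_cohort(24, seed = 45, noise_frac = 0,
                                      profile_effects = eff0)
  rep <- build_report(co)
  expect_true(all(rep$table$p1 == 1 & rep$table$p2 == 1 & rep$table$p3 == 1))
  expect_false(any(rep$table$sig1 | rep$table$sig2 | rep$table$sig3))
  # identical medians
  expect_identical(rep$table$clinical, rep$table$summary_P)
})

test_that("an injected endpoint shift is flagged exactly where it was planted", {
  eff0 <- hnplanr:::default_profile_effects()
  eff0$effect_P <- 0
  eff0$effect_O <- 0
  co <- simulate_commissioning_cohort(30, seed = 46, noise_frac = 0.3,
                                      profile_effects = eff0,
                                      ai_shift = c("PTV HI" = 4))
  rep <- build_report(co)
  td <- tidy(rep)
  flagged <- td |> dplyr::filter(.data$significant)
  # the shifted endpoint is flagged in both AI-vs-clinical columns...
  expect_true(all(flagged$endpoint == "PTV HI"))
  expect_setequal(unique(flagged$comparison), c("p1", "p2"))
  # ...and in every group with enough pairs
  expect_gt(nrow(flagged), 0)
  # the *P-vs-*O comparison is clean (the shift hits both equally)
  expect_false(any(td$comparison == "p3" & td$significant))
})

test_that("reports with the designed tradeoffs recover the expected pattern", {
  rep <- cached("commission_rep", function()
    build_report(simulate_commissioning_cohort(50, seed = 47)))
  tab <- rep$table
  expect_identical(sum(rep$groups), 50L)
  bil <- tab[tab$group == "bilateral", ]
  # *P improves conformity vs clinical; *O trades HI for OAR sparing
  ci <- bil[bil$endpoint == "PTV CI", ]
  expect_true(ci$sig1)
  hi <- bil[bil$endpoint == "PTV HI", ]
  expect_true(hi$sig3)
  gl <- glance(rep)
  expect_identical(gl$n_cases, 50L)
  expect_identical(gl$m, nrow(hnplanr:::clinical_endpoint_baseline()))
})

test_that("written reports are byte-stable across reruns", {
  rep <- cached("commission_rep", function()
    build_report(simulate_commissioning_cohort(50, seed = 47)))
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  write_report(rep, td1)
  write_report(rep, td2)
  expect_identical(readLines(file.path(td1, "table2.csv")),
                   readLines(file.path(td2, "table2.csv")))
  expect_identical(readLines(file.path(td1, "report.md")),
                   readLines(file.path(td2, "report.md")))
})
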