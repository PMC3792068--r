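test_that("the pooled-variance t-test matches the closed form", {
  res <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # pooled sd 1, se = sqrt(2/3), t = -3/se
  res2 <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res2$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res2$t, -3.674, tolerance = 1e-3)
  expect_equal(res2$p, 2 * pt(-abs(res2$t), df = 4))
  expect_equal(res2$p, 0.0213, tolerance = 1e-2)

  # symmetry: swapping groups negates t, keeps p
  res3 <- student_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res3$t, -res2$t)
  expect_equal(res3$p, res2$p)

  expect_error(student_t_test(c(1, 1), c(2, 2)), "Degenerate")
  expect_error(student_t_test(1, c(1, 2)), "two")
})

test_that("AUROC equals brute-force pairwise counting", {
  vals <- c(2, 3, 4, 1, 1.5, 2.5)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auroc(vals, grp), 8 / 9)
  expect_equal(auroc(rep(1, 6), grp), 0.5)
  expect_equal(auroc(c(5, 6, 7, 1, 2, 3), grp), 1)

  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
    v <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1) # rounding forces ties
    g <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(auroc(v, g), oracle_auroc(v, g))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "control")
})

test_that("AUROC complements under sign flip for tie-free data", {
  set.seed(7)
  for (i in 1:10) {
    v <- rnorm(30)
    g <- rep(c(TRUE, FALSE), 15)
    expect_equal(auroc(v, g) + auroc(-v, g), 1)
  }
})

test_that("the differential screen uses the Bonferroni threshold alpha/G", {
  cohort <- simulate_cohort(cohort_config(n_uc = 10, n_hlt = 10, seed = 4))
  res <- differential_expression(cohort$abundance, cohort$metadata$group)
  expect_equal(nrow(res), 61L)
  expect_equal(unique(res$p_threshold), 0.05 / 61)
  expect_equal(res$significant, res$p < 0.05 / 61)
  expect_equal(res$direction, ifelse(res$mean_case > res$mean_control,
                                     "up", "down"))
})

test_that("the vectorized screen matches student_t_test and auroc per column", {
  cohort <- simulate_cohort(cohort_config(n_uc = 8, n_hlt = 9, seed = 3))
  res <- differential_expression(cohort$abundance, cohort$metadata$group)
  is_case <- cohort$metadata$group == "UC"
  for (code in sample(res$code, 8)) {
    v <- cohort$abundance[[code]]
    tt <- student_t_test(v[is_case], v[!is_case])
    i <- match(code, res$code)
    expect_equal(res$t[i], tt$t, tolerance = 1e-12)
    expect_equal(res$p[i], tt$p, tolerance = 1e-12)
    expect_equal(res$auroc[i], auroc(v, is_case), tolerance = 1e-12)
  }
})

test_that("a hugely shifted glycan is flagged significant and up", {
  cohort <- simulate_cohort(cohort_config(n_uc = 10, n_hlt = 10, seed = 9))
  ab <- cohort$abundance
  ab[["6200"]] <- ifelse(cohort$metadata$group == "UC",
                         ab[["6200"]] * 50, ab[["6200"]])
  res <- differential_expression(ab, cohort$metadata$group)
  row <- res[res$code == "6200", ]
  expect_true(row$significant)
  expect_equal(row$direction, "up")
  expect_equal(row$auroc, 1)
})

test_that("ratio marker selection takes best up over best down AUROC", {
  # toy construction: A perfectly up, B perfectly down
  ab <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    A = c(10, 11, 12, 13, 1, 2, 3, 4),
    B = c(1, 2, 1.5, 1.2, 8, 9, 10, 11),
    C = c(5, 5.2, 4.9, 5.1, 5.05, 4.95, 5.0, 5.1)
  )
  groups <- rep(c("UC", "HLT"), each = 4)
  res <- differential_expression(ab, groups, panel = NULL)
  marker <- select_ratio_marker(res, ab, groups, panel = NULL)
  expect_equal(marker$numerator$code, "A")
  expect_equal(marker$denominator$code, "B")
  expect_equal(marker$auroc, 1)

  # no significant down glycan: explicit refusal
  res_up_only <- res[res$code != "B", ]
  expect_error(select_ratio_marker(res_up_only, ab, groups, panel = NULL),
               "No marker selectable")
})

test_that("the default cohort yields the planted 5402/5410 marker", {
  cohort <- default_cohort()
  res <- differential_expression(cohort$abundance, cohort$metadata$group)
  marker <- select_ratio_marker(res, cohort$abundance, cohort$metadata$group)
  expect_equal(marker$numerator$code, "5402")
  expect_equal(marker$denominator$code, "5410")
  expect_equal(glance(marker)$numerator_label, 2378L)
  expect_equal(glance(marker)$denominator_label, 1914L)
})

test_that("marker AUROC is invariant to rescaling a glycan column", {
  cohort <- simulate_cohort(cohort_config(n_uc = 40, n_hlt = 40, seed = 6))
  res <- differential_expression(cohort$abundance, cohort$metadata$group)
  m1 <- select_ratio_marker(res, cohort$abundance, cohort$metadata$group)
  ab2 <- cohort$abundance
  ab2[[m1$denominator$code]] <- ab2[[m1$denominator$code]] * 2
  res2 <- differential_expression(ab2, cohort$metadata$group)
  m2 <- select_ratio_marker(res2, ab2, cohort$metadata$group)
  expect_equal(m2$numerator$code, m1$numerator$code)
  expect_equal(m2$denominator$code, m1$denominator$code)
  expect_equal(m2$auroc, m1$auroc)
})

test_that("samples with non-positive denominator are excluded with a warning", {
  ab <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    A = c(10, 11, 12, 13, 1, 2, 3, 4),
    B = c(1, 2, 1.5, 1.2, 8, 9, 10, 11)
  )
  ab$B[1] <- 0
  groups <- rep(c("UC", "HLT"), each = 4)
  res <- differential_expression(ab, groups, panel = NULL)
  expect_warning(
    marker <- select_ratio_marker(res, ab, groups, panel = NULL),
    "s1"
  )
  expect_equal(nrow(marker$ratios), 7L)
})

test_that("bootstrap group means are exact for constant values", {
  # both groups constant at the same value: estimates exact, p capped at 1
  res <- bootstrap_group_means(rep(3, 8), rep(c("a", "b"), each = 4),
                               B = 200, seed = 1)
  expect_equal(res$estimates$boot_estimate, c(3, 3))
  expect_equal(res$estimates$boot_se, c(0, 0))
  expect_equal(res$p, 1)
})

test_that("bootstrap point estimates stay within 2 SE of the plain mean", {
  set.seed(11)
  v <- c(rnorm(30, 10), rnorm(25, 12))
  g <- rep(c("x", "y"), c(30, 25))
  for (s in c(1, 2, 3)) {
    res <- bootstrap_group_means(v, g, B = 2000, seed = s)
    est <- res$estimates
    expect_true(all(abs(est$boot_estimate - est$observed_mean) <=
                      2 * est$boot_se))
  }
})

test_that("bootstrap p is reproducible for a fixed seed and detects separation", {
  v <- c(rnorm(20, 0), rnorm(20, 5))
  g <- rep(c("lo", "hi"), each = 20)
  r1 <- bootstrap_group_means(v, g, B = 1000, seed = 42)
  r2 <- bootstrap_group_means(v, g, B = 1000, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$p, 2 / 1001) # minimal attainable two-sided value
  expect_error(bootstrap_group_means(v, g, B = 10), "100")
})

test_that("strata comparisons report the built-in clinical contrasts", {
  cohort <- default_cohort()
  uc <- cohort$metadata$group == "UC"
  md <- cohort$metadata[uc, ]
  ratio <- cohort$abundance[["5402"]][uc] / cohort$abundance[["5410"]][uc]
  res <- compare_strata(ratio, md, B = 500, seed = 1)
  expect_setequal(res$stratum,
                  c("extent", "cai", "mayo", "steroid_refractory"))
  # severity-linked marker: higher in every severe stratum
  expect_true(all(res$mean_high > res$mean_low))
  # Mayo comparison excludes score-0 patients
  mayo_row <- res[res$stratum == "mayo", ]
  expect_equal(mayo_row$n_high + mayo_row$n_low, sum(md$mayo %in% 1:3))
  expect_lt(mayo_row$n_high + mayo_row$n_low, nrow(md))
})

test_that("identical strata distributions give p near 1", {
  md <- tibble::tibble(
    cai = rep(c(5, 15), 40),
    extent = rep(c("total", "left-sided"), 40),
    mayo = rep(c(1, 3), 40),
    steroid_refractory = rep(c(TRUE, FALSE), 40)
  )
  values <- rep(c(7, 3, 3, 7), 20) # identical multisets in both strata
  res <- compare_strata(values, md, B = 500, seed = 2)
  expect_true(all(res$p_t > 0.5))

  md_empty <- md
  md_empty$extent <- "total"
  expect_error(compare_strata(values, md_empty, strata = "extent",
                              B = 500, seed = 1),
               "extent")
})
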