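test_that("the product-limit estimator handles events and censoring", {
  km <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                   event = c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  km2 <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                    event = c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 2], 2 / 3) # censoring leaves S unchanged
  expect_equal(km2$surv[km2$time == 3], 0)

  km3 <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                    event = c(0, 0, 0)))
  expect_true(all(km3$surv == 1))

  expect_error(km_estimate(tibble::tibble(time_months = -1, event = 1)),
               "non-negative")
})

test_that("without censoring the KM curve is the empirical survivor function", {
  set.seed(20)
  times <- round(rexp(80, 0.1), 1)
  km <- km_estimate(tibble::tibble(time_months = times,
                                   event = rep(1, 80)))
  expect_equal(km$surv, oracle_ecdf_surv(times, km$time))
})

test_that("the log-rank statistic matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    d <- tibble::tibble(
      time_months = round(rexp(n, 0.1), 2),
      event = rbinom(n, 1, 0.7),
      group = sample(c("a", "b"), n, replace = TRUE)
    )
    if (sum(d$event) == 0 || length(unique(d$group)) < 2) next
    mine <- logrank_test(d)
    ref <- survival::survdiff(
      survival::Surv(time_months, event) ~ group, data = d
    )
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
})

test_that("the log-rank test has power against strong separation", {
  set.seed(5)
  reject <- vapply(1:20, function(i) {
    d <- tibble::tibble(
      time_months = c(rexp(100, 0.05), rexp(100, 0.25)),
      event = 1,
      group = rep(c("lo", "hi"), each = 100)
    )
    logrank_test(d)$p < 0.001
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("a single event still yields a valid log-rank p", {
  d <- tibble::tibble(time_months = c(1, 2, 3, 4),
                      event = c(1, 0, 0, 0),
                      group = c("a", "a", "b", "b"))
  res <- logrank_test(d)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("cox_fit agrees with survival::coxph on random small datasets", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    d <- tibble::tibble(
      time_months = round(rexp(n, 0.1), 1), # rounding creates ties
      event = rbinom(n, 1, 0.7),
      x1 = rnorm(n),
      x2 = rbinom(n, 1, 0.5)
    )
    if (sum(d$event) < 5 || length(unique(d$x2)) < 2) next
    mine <- cox_fit(d, c("x1", "x2"))
    ref <- survival::coxph(
      survival::Surv(time_months, event) ~ x1 + x2,
      data = d, ties = "breslow"
    )
    expect_equal(unname(mine$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-4)
    expect_equal(unname(mine$se),
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
    # Efron flag too
    mine_e <- cox_fit(d, c("x1", "x2"), ties = "efron")
    ref_e <- survival::coxph(
      survival::Surv(time_months, event) ~ x1 + x2,
      data = d, ties = "efron"
    )
    expect_equal(unname(mine_e$coefficients), unname(stats::coef(ref_e)),
                 tolerance = 1e-4)
  }
})

test_that("cox_fit recovers a true hazard ratio of 2", {
  set.seed(12)
  n <- 500
  arm <- rep(0:1, n / 2)
  d <- tibble::tibble(
    time_months = rexp(n, 0.05 * 2^arm),
    event = 1,
    arm = arm
  )
  fit <- cox_fit(d, "arm")
  expect_true(fit$converged)
  expect_gt(fit$hr[["arm"]], 1.7)
  expect_lt(fit$hr[["arm"]], 2.35)
  td <- tidy(fit)
  expect_equal(td$hr, exp(td$estimate))
  expect_true(td$conf.low < td$hr && td$hr < td$conf.high)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  d <- tibble::tibble(time_months = 1:6, event = rep(1, 6),
                      x = rep(2, 6))
  expect_error(cox_fit(d, "x"), "Constant")
  expect_error(cox_fit(tibble::tibble(time_months = 1:3, event = rep(0, 3),
                                      x = 1:3), "x"),
               "event")
  # perfect separation: monotone likelihood must be flagged
  sep <- tibble::tibble(time_months = c(1, 2, 3, 10, 11, 12),
                        event = rep(1, 6),
                        x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- cox_fit(sep, "x"), "separation|converge")
  expect_false(fit$converged)
})

test_that("the univariate screen applies the entry rule in input order", {
  cohort <- default_cohort()
  md <- cohort$metadata[cohort$metadata$group == "UC", ]
  d <- tibble::tibble(
    time_months = md$time_months, event = md$event,
    marker_high = as.numeric(md$marker_high),
    noise = withr::with_seed(1, rnorm(nrow(md)))
  )
  scr <- univariate_screen(d, c("marker_high", "noise"))
  expect_equal(scr$term, c("marker_high", "noise"))
  expect_true(scr$selected[scr$term == "marker_high"])
  scr_all <- univariate_screen(d, c("marker_high", "noise"), entry_p = 1)
  expect_true(all(scr_all$selected))
})

test_that("multivariate fit drops the more weakly prognostic collinear twin", {
  cohort <- default_cohort()
  md <- cohort$metadata[cohort$metadata$group == "UC", ]
  d <- tibble::tibble(
    time_months = md$time_months, event = md$event,
    a = as.numeric(md$marker_high),
    b = as.numeric(md$marker_high) # identical twin
  )
  expect_message(fit <- multivariate_cox(d, c("a", "b")), "collinearity")
  expect_length(fit$coefficients, 1L)
  expect_equal(fit$dropped, "b") # equal p: the later one is dropped

  # uncorrelated covariates are all retained
  d$b <- withr::with_seed(2, rnorm(nrow(d)))
  fit2 <- multivariate_cox(d, c("a", "b"))
  expect_length(fit2$coefficients, 2L)
  expect_equal(fit2$dropped, character(0))
})

test_that("a single surviving covariate reduces to the univariate fit", {
  cohort <- default_cohort()
  md <- cohort$metadata[cohort$metadata$group == "UC", ]
  d <- tibble::tibble(
    time_months = md$time_months, event = md$event,
    a = as.numeric(md$marker_high), b = as.numeric(md$marker_high)
  )
  multi <- suppressMessages(multivariate_cox(d, c("a", "b")))
  uni <- cox_fit(d, "a")
  expect_equal(multi$coefficients[["a"]], uni$coefficients[["a"]],
               tolerance = 1e-12)
})

test_that("dichotomization cuts at the interpolated quantile, high is strict", {
  flags <- dichotomize(c(1, 2, 3, 4))
  expect_equal(attr(flags, "cutoff"), 2.5)
  expect_equal(as.logical(flags), c(FALSE, FALSE, TRUE, TRUE))

  # a value equal to the cutoff goes low
  flags2 <- dichotomize(c(1, 2, 2, 3, 4)) # median 2
  expect_false(flags2[2])
  expect_error(dichotomize(rep(5, 4)), "distinct")

  # 25th percentile on 75 values: 19 low-group members absent ties
  set.seed(3)
  v <- rnorm(75)
  f <- dichotomize(v, q = 0.25)
  expect_equal(sum(!f), 19L)
})

test_that("diagnostic accuracy computes sensitivity and specificity", {
  expect_equal(
    diagnostic_accuracy(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, TRUE, FALSE, FALSE)),
    tibble::tibble(sensitivity = 1, specificity = 1,
                   tp = 2L, fp = 0L, fn = 0L, tn = 2L)
  )
  res <- diagnostic_accuracy(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 0)
  res2 <- suppressMessages(
    diagnostic_accuracy(c(TRUE, FALSE), c(FALSE, FALSE))
  )
  expect_true(is.na(res2$sensitivity))

  # independence: both near the flag prevalence margins
  set.seed(8)
  hi <- rbinom(4000, 1, 0.4) == 1
  ev <- rbinom(4000, 1, 0.5) == 1
  res3 <- diagnostic_accuracy(hi, ev)
  expect_equal(res3$sensitivity, 0.4, tolerance = 0.1)
  expect_equal(res3$specificity, 0.6, tolerance = 0.1)
})
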