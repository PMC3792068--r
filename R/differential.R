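#' Two-sample Student's t-test
#'
#' Classic equal-variance two-sample t-test (pooled variance, n1 + n2 - 2
#' degrees of freedom, two-sided p). A Welch test is available behind
#' `var_equal = FALSE` for robustness checks.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @param var_equal Pool the variances (default TRUE).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least two non-missing values.")
  }
  if (var_equal && var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical constants: no evidence of a difference
      return(tibble(t = 0, df = length(x) + length(y) - 2, p = 1,
                    mean_x = mean(x), mean_y = mean(y)))
    }
    abort("Degenerate zero pooled variance with unequal means.")
  }
  fit <- t.test(x, y, var.equal = var_equal)
  tibble(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value, mean_x = mean(x), mean_y = mean(y)
  )
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a random case value
#' exceeds a random control value, with ties counted one half. Computed
#' from midranks, which equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param values Numeric marker values.
#' @param is_case Logical vector (TRUE = case) aligned with `values`.
#' @return AUROC in \[0, 1\], oriented as P(case > control).
#' @examples
#' auroc(c(2, 3, 4, 1, 1.5, 2.5), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
auroc <- function(values, is_case) {
  stopifnot(length(values) == length(is_case))
  ok <- !is.na(values) & !is.na(is_case)
  values <- values[ok]; is_case <- as.logical(is_case[ok])
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC needs at least one case and one control.")
  }
  r <- rank(values, ties.method = "average")
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-glycan differential screening with Bonferroni control
#'
#' For every glycan column, compares case and control abundances with
#' Student's t-test and computes the AUROC oriented as P(case > control).
#' Significance uses the Bonferroni-corrected threshold `alpha / G`, where
#' G is the number of glycans tested (for a 61-glycan panel at alpha 0.05
#' this is p < 0.05/61).
#'
#' @param abundance Wide abundance tibble (`sample_id` + glycan columns).
#' @param groups Group labels aligned with abundance rows.
#' @param case,control Group labels treated as case and control.
#' @param alpha Family-wise error rate (default 0.05).
#' @param panel Panel for code/label resolution (default
#'   [reference_panel()]); pass `NULL` to keep raw column names.
#' @return A tibble with one row per glycan: `code`, `label`,
#'   `mean_case`, `mean_control`, `t`, `p`, `direction` (`"up"` when the
#'   case mean exceeds the control mean), `auroc`, `significant`, plus the
#'   threshold in the `p_threshold` column.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_uc = 10, n_hlt = 10, seed = 1))
#' differential_expression(cohort$abundance, cohort$metadata$group)
#' @export
differential_expression <- function(abundance, groups, case = "UC",
                                    control = "HLT", alpha = 0.05,
                                    panel = reference_panel()) {
  groups <- as.character(groups)
  if (length(groups) != nrow(abundance)) {
    abort("`groups` must align with the rows of `abundance`.")
  }
  if (anyNA(groups)) abort("Missing group labels.")
  if (!is.null(panel)) {
    cols <- resolve_glycan_columns(abundance, panel)
  } else {
    raw <- setdiff(names(abundance), "sample_id")
    cols <- tibble(column = raw, code = raw, label = NA_integer_)
  }
  g <- nrow(cols)
  if (g < 1) abort("No glycan columns to test.")
  threshold <- alpha / g
  is_case <- groups == case
  is_control <- groups == control
  n1 <- sum(is_case); n2 <- sum(is_control)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least two samples.")

  # vectorized pooled-variance t over all columns (identical to
  # student_t_test per column, asserted in the test suite)
  x <- as.matrix(abundance[is_case, cols$column, drop = FALSE])
  y <- as.matrix(abundance[is_control, cols$column, drop = FALSE])
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums(sweep(x, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(y, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pval <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)

  # AUROC per column from midranks (P(case > control), ties half)
  ranks <- apply(rbind(x, y), 2, rank, ties.method = "average")
  aucs <- (colSums(ranks[seq_len(n1), , drop = FALSE]) -
             n1 * (n1 + 1) / 2) / (n1 * n2)

  tibble(
    code = cols$code, label = cols$label,
    mean_case = unname(m1), mean_control = unname(m2),
    t = unname(tstat), p = unname(pval),
    direction = unname(ifelse(m1 > m2, "up", "down")),
    auroc = unname(aucs),
    significant = unname(pval < threshold),
    p_threshold = threshold
  )
}

#' Select the up/down ratio marker
#'
#' Among Bonferroni-significant glycans, takes the up-regulated glycan
#' with the highest AUROC as numerator and the down-regulated glycan with
#' the highest direction-corrected AUROC (max of 1 - AUROC as stored) as
#' denominator, then forms the per-sample abundance ratio and its AUROC.
#' Ties are broken by the smaller integer peak label. Samples with a
#' non-positive denominator abundance are excluded with a warning.
#'
#' @param results Differential table from [differential_expression()].
#' @param abundance Wide abundance tibble used for per-sample ratios.
#' @param groups Group labels aligned with abundance rows.
#' @inheritParams differential_expression
#' @return An object of class `ratio_marker`: list with `numerator`,
#'   `denominator` (one-row tibbles), `ratios` (tibble `sample_id`,
#'   `group`, `ratio`), `auroc`, `case`, `control`. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_uc = 20, n_hlt = 20, seed = 1))
#' diff <- differential_expression(cohort$abundance, cohort$metadata$group)
#' select_ratio_marker(diff, cohort$abundance, cohort$metadata$group)
#' @export
select_ratio_marker <- function(results, abundance, groups, case = "UC",
                                control = "HLT", panel = reference_panel()) {
  ups <- results[results$significant & results$direction == "up", ]
  downs <- results[results$significant & results$direction == "down", ]
  if (nrow(ups) == 0 || nrow(downs) == 0) {
    abort(paste0(
      "No marker selectable: need at least one significant up-regulated ",
      "and one significant down-regulated glycan (found ", nrow(ups),
      " up, ", nrow(downs), " down)."
    ))
  }
  pick <- function(tbl, score) {
    tbl <- tbl[order(-score, tbl$label), ]
    tbl[1, , drop = FALSE]
  }
  num <- pick(ups, ups$auroc)
  den <- pick(downs, 1 - downs$auroc)

  if (!is.null(panel)) {
    cols <- resolve_glycan_columns(abundance, panel)
  } else {
    raw <- setdiff(names(abundance), "sample_id")
    cols <- tibble(column = raw, code = raw)
  }
  num_col <- cols$column[match(num$code, cols$code)]
  den_col <- cols$column[match(den$code, cols$code)]
  groups <- as.character(groups)
  ratios <- tibble(
    sample_id = abundance$sample_id,
    group = groups,
    numerator = abundance[[num_col]],
    denominator = abundance[[den_col]]
  )
  bad <- ratios$denominator <= 0
  if (any(bad)) {
    warn(paste0(
      sum(bad), " sample(s) excluded from the ratio marker: non-positive ",
      "denominator abundance (", paste(ratios$sample_id[bad], collapse = ", "),
      ")."
    ))
    ratios <- ratios[!bad, , drop = FALSE]
  }
  ratios$ratio <- ratios$numerator / ratios$denominator
  in_groups <- ratios$group %in% c(case, control)
  marker_auroc <- auroc(ratios$ratio[in_groups],
                        ratios$group[in_groups] == case)
  structure(
    list(
      numerator = num, denominator = den,
      ratios = ratios[, c("sample_id", "group", "ratio")],
      auroc = marker_auroc, case = case, control = control
    ),
    class = "ratio_marker"
  )
}

#' @export
print.ratio_marker <- function(x, ...) {
  cat("<ratio_marker>", paste0("m/z ", x$numerator$label, "/", x$denominator$label),
      sprintf("(codes %s/%s)\n", x$numerator$code, x$denominator$code))
  cat(sprintf("  AUROC %s vs %s: %.3f over %d samples\n",
              x$case, x$control, x$auroc, nrow(x$ratios)))
  invisible(x)
}

#' Bootstrap comparison of two group means
#'
#' Resamples within each group with replacement. The point estimate per
#' group is the mean of the B bootstrap means; the two-sided bootstrap p
#' for the group difference uses the add-one rule
#' `2 * min(#(diff <= 0) + 1, #(diff >= 0) + 1) / (B + 1)`, capped at 1.
#'
#' @param values Numeric vector.
#' @param groups Two-level group labels aligned with `values`.
#' @param B Number of bootstrap resamples (>= 100; default 10000).
#' @param seed Optional integer seed for reproducible resampling.
#' @return A list with `estimates` (tibble: `group`, `n`, `observed_mean`,
#'   `boot_estimate`, `boot_se`), `p` (two-sided bootstrap p for the
#'   difference), and `B`.
#' @examples
#' bootstrap_group_means(c(1, 2, 3, 7, 8, 9),
#'                       rep(c("a", "b"), each = 3), B = 500, seed = 1)
#' @export
bootstrap_group_means <- function(values, groups, B = 10000, seed = NULL) {
  if (!is.numeric(B) || length(B) != 1 || B < 100) {
    abort("`B` must be a single number >= 100.")
  }
  B <- as.integer(B)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) abort("`groups` must have exactly two levels.")
  ns <- vapply(lev, function(g) sum(groups == g), integer(1))
  if (any(ns < 2)) abort("Each group needs at least two values.")
  run <- function() {
    boot_means <- lapply(lev, function(g) {
      v <- values[groups == g]
      m <- matrix(sample(v, length(v) * B, replace = TRUE), nrow = B)
      rowMeans(m)
    })
    diffs <- boot_means[[1]] - boot_means[[2]]
    p <- min(1, 2 * min(sum(diffs <= 0) + 1, sum(diffs >= 0) + 1) / (B + 1))
    list(
      estimates = tibble(
        group = lev, n = unname(ns),
        observed_mean = vapply(lev, function(g) mean(values[groups == g]),
                               numeric(1)),
        boot_estimate = vapply(boot_means, mean, numeric(1)),
        boot_se = vapply(boot_means, sd, numeric(1))
      ),
      p = p, B = B
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Compare a marker across clinical strata
#'
#' For each requested stratum the marker values of the two patient
#' subgroups are compared by Student's t-test and by a seeded bootstrap of
#' the group means. Built-in strata: disease extent (total vs left-sided
#' colitis), clinical activity index (CAI > 10 vs <= 10), Mayo endoscopic
#' score (3 vs 1-2; score-0 patients are excluded from this comparison),
#' and steroid-refractory status (yes vs no).
#'
#' @param values Numeric marker values (e.g. the glycan ratio or an
#'   aggregate abundance), one per patient.
#' @param metadata Patient metadata tibble with columns `extent`
#'   (`"total"`/`"left-sided"`), `cai` (integer score), `mayo` (0-3),
#'   `steroid_refractory` (logical or `"yes"`/`"no"`).
#' @param strata Which comparisons to run.
#' @param B Bootstrap resamples per comparison.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble, one row per stratum: the two level names and sizes,
#'   group means, `t`, `p_t`, bootstrap point estimates and `p_boot`.
#' @export
compare_strata <- function(values, metadata,
                           strata = c("extent", "cai", "mayo",
                                      "steroid_refractory"),
                           B = 10000, seed = NULL) {
  strata <- match.arg(strata, several.ok = TRUE)
  stopifnot(length(values) == nrow(metadata))
  defs <- list(
    extent = function(md) {
      list(high = md$extent == "total", low = md$extent == "left-sided",
           high_label = "total colitis", low_label = "left-sided colitis",
           column = "extent")
    },
    cai = function(md) {
      list(high = md$cai > 10, low = md$cai <= 10,
           high_label = "CAI > 10", low_label = "CAI <= 10", column = "cai")
    },
    mayo = function(md) {
      list(high = md$mayo == 3, low = md$mayo %in% c(1, 2),
           high_label = "Mayo 3", low_label = "Mayo 1-2", column = "mayo")
    },
    steroid_refractory = function(md) {
      sr <- md$steroid_refractory
      if (!is.logical(sr)) sr <- tolower(as.character(sr)) %in% c("yes", "true", "1")
      list(high = sr, low = !sr,
           high_label = "steroid-refractory", low_label = "not refractory",
           column = "steroid_refractory")
    }
  )
  purrr::map_dfr(strata, function(s) {
    d <- defs[[s]](metadata)
    if (!d$column %in% names(metadata)) {
      abort(paste0("Metadata lacks column `", d$column, "` needed for the ",
                   s, " comparison."))
    }
    hi <- which(d$high); lo <- which(d$low)
    if (length(hi) == 0 || length(lo) == 0) {
      abort(paste0("Empty stratum in the ", s, " comparison (",
                   d$high_label, ": ", length(hi), ", ",
                   d$low_label, ": ", length(lo), ")."))
    }
    tt <- student_t_test(values[hi], values[lo])
    bs <- bootstrap_group_means(
      c(values[hi], values[lo]),
      rep(c("high", "low"), c(length(hi), length(lo))),
      B = B, seed = seed
    )
    tibble(
      stratum = s,
      level_high = d$high_label, level_low = d$low_label,
      n_high = length(hi), n_low = length(lo),
      mean_high = tt$mean_x, mean_low = tt$mean_y,
      t = tt$t, p_t = tt$p,
      boot_high = bs$estimates$boot_estimate[1],
      boot_low = bs$estimates$boot_estimate[2],
      p_boot = bs$p
    )
  })
}
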