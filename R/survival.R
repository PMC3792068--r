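#' Kaplan-Meier product-limit estimate
#'
#' @param data Tibble with one row per subject.
#' @param time,event Names of the follow-up time (non-negative, months)
#'   and event indicator (0/1 or logical) columns.
#' @param group Optional name of a grouping column; curves are estimated
#'   per group.
#' @return A tibble of class `km_curve`, one row per distinct observed
#'   time per group: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`. S(0) = 1 is implicit; `surv` is a non-increasing step
#'   function changing only at event times.
#' @examples
#' km_estimate(tibble::tibble(time_months = c(1, 2, 3), event = c(1, 0, 1)))
#' @export
km_estimate <- function(data, time = "time_months", event = "event",
                        group = NULL) {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  if (is.null(tt) || is.null(ev)) abort("Missing time or event column.")
  if (any(tt < 0)) abort("Follow-up times must be non-negative.")
  if (!all(ev %in% c(0L, 1L))) abort("Event indicator must be 0/1.")
  grp <- if (is.null(group)) rep("all", length(tt)) else as.character(data[[group]])
  out <- purrr::map_dfr(unique(grp), function(g) {
    t_g <- tt[grp == g]; e_g <- ev[grp == g]
    times <- sort(unique(t_g))
    n_risk <- vapply(times, function(u) sum(t_g >= u), integer(1))
    n_event <- vapply(times, function(u) sum(t_g == u & e_g == 1L), integer(1))
    n_censor <- vapply(times, function(u) sum(t_g == u & e_g == 0L), integer(1))
    tibble(
      group = g, time = times, n_risk = n_risk,
      n_event = n_event, n_censor = n_censor,
      surv = cumprod(1 - n_event / n_risk)
    )
  })
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test for two survival curves
#'
#' Standard one-degree-of-freedom log-rank statistic comparing the event
#' experience of two groups against the pooled expectation.
#'
#' @inheritParams km_estimate
#' @param group Name of the two-level grouping column.
#' @return A list of class `logrank_test`: `statistic` (chi-square, 1 df),
#'   `p`, `observed` and `expected` events per group.
#' @export
logrank_test <- function(data, time = "time_months", event = "event",
                         group = "group") {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  grp <- as.character(data[[group]])
  lev <- sort(unique(grp))
  if (length(lev) != 2) abort("Log-rank test needs exactly two groups.")
  if (any(table(grp) == 0) || sum(ev) < 1) {
    abort("Both groups must be non-empty with at least one event overall.")
  }
  g1 <- grp == lev[1]
  etimes <- sort(unique(tt[ev == 1L]))
  o_minus_e <- 0; v <- 0; obs1 <- 0; exp1 <- 0
  for (u in etimes) {
    at_risk <- tt >= u
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(tt == u & ev == 1L); d1 <- sum(tt == u & ev == 1L & g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs1 <- obs1 + d1; exp1 <- exp1 + e1
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  structure(
    list(
      statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE),
      observed = setNames(c(obs1, sum(ev) - obs1), lev),
      expected = setNames(c(exp1, sum(ev) - exp1), lev)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

# Breslow/Efron negative log partial likelihood machinery shared by
# cox_fit(). Returns loglik, gradient and information at beta.
cox_partial <- function(beta, x, tt, ev, ties) {
  ord <- order(-tt)
  x <- x[ord, , drop = FALSE]; tt <- tt[ord]; ev <- ev[ord]
  p <- ncol(x)
  eta <- drop(x %*% beta)
  eta <- pmin(eta, 500) # guard against overflow under monotone likelihood
  w <- exp(eta)
  s0 <- cumsum(w)
  s1 <- apply(x * w, 2, cumsum)
  if (p == 1) s1 <- matrix(s1, ncol = 1)
  # s2 cumulatives for each covariate pair
  s2 <- array(0, dim = c(length(tt), p, p))
  for (a in seq_len(p)) {
    for (b in a:p) {
      cs <- cumsum(w * x[, a] * x[, b])
      s2[, a, b] <- cs; s2[, b, a] <- cs
    }
  }
  loglik <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (u in unique(tt[ev == 1L])) {
    dset <- which(tt == u & ev == 1L)
    d <- length(dset)
    ridx <- max(which(tt == u)) # last index with time >= u (descending sort)
    S0 <- s0[ridx]; S1 <- s1[ridx, ]; S2 <- s2[ridx, , ]
    wD <- sum(w[dset])
    S1D <- colSums(x[dset, , drop = FALSE] * w[dset])
    S2D <- matrix(0, p, p)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      S2D[a, b] <- sum(w[dset] * x[dset, a] * x[dset, b])
    }
    loglik <- loglik + sum(eta[dset])
    xsum <- colSums(x[dset, , drop = FALSE])
    grad <- grad + xsum
    ls <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in ls) {
      phi0 <- S0 - l * wD
      phi1 <- S1 - l * S1D
      phi2 <- S2 - l * S2D
      loglik <- loglik - log(phi0)
      grad <- grad - phi1 / phi0
      info <- info + phi2 / phi0 - tcrossprod(phi1 / phi0)
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Cox proportional-hazards fit
#'
#' Maximises the log partial likelihood by Newton-Raphson (Breslow tie
#' handling by default, Efron behind the `ties` flag) to a gradient norm
#' below `tol` or `max_iter` iterations. Confidence intervals and p-values
#' are Wald: `exp(b +/- 1.96 * se)`.
#'
#' @param data Tibble with follow-up, event and covariate columns.
#' @param covariates Character vector of covariate column names (numeric
#'   or logical; logicals are coerced to 0/1).
#' @inheritParams km_estimate
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol Gradient convergence tolerance (default 1e-8).
#' @param max_iter Newton-Raphson iteration cap (default 100).
#' @return Object of class `cox_ph_fit` with coefficients, standard
#'   errors, hazard ratios, Wald 95% CIs and p-values, log partial
#'   likelihoods (null and fitted), iteration count and a convergence
#'   flag. Monotone likelihoods (perfect separation) are flagged, never
#'   returned silently. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- tibble::tibble(time_months = rexp(40), event = rbinom(40, 1, 0.7),
#'                     arm = rep(0:1, 20))
#' cox_fit(d, "arm")
#' @export
cox_fit <- function(data, covariates, time = "time_months", event = "event",
                    ties = c("breslow", "efron"), tol = 1e-8,
                    max_iter = 100) {
  ties <- match.arg(ties)
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  if (is.null(tt) || is.null(ev)) abort("Missing time or event column.")
  if (sum(ev) < 1) abort("Cox model needs at least one event.")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("Missing covariate column(s): ",
                 paste(missing_cov, collapse = ", "), "."))
  }
  x <- as.matrix(as.data.frame(lapply(data[covariates], as.numeric)))
  colnames(x) <- covariates
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    abort(paste0("Constant covariate(s): ",
                 paste(covariates[const], collapse = ", "), "."))
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center) # location shift leaves coefficients unchanged
  p <- ncol(xc)
  beta <- numeric(p)
  null_fit <- cox_partial(beta, xc, tt, ev, ties)
  loglik_null <- null_fit$loglik
  fit <- null_fit
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(fit$info, fit$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_fit <- cox_partial(new_beta, xc, tt, ev, ties)
    halvings <- 0
    while (new_fit$loglik < fit$loglik && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_fit <- cox_partial(new_beta, xc, tt, ev, ties)
      halvings <- halvings + 1
    }
    beta <- new_beta
    fit <- new_fit
    if (max(abs(fit$grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > 15)) {
    converged <- FALSE
    warn("Monotone log partial likelihood (possible perfect separation); estimates are not reliable.")
  }
  if (!converged && max(abs(fit$grad)) >= tol) {
    warn(paste0("Cox fit did not converge in ", iter, " iterations."))
  }
  se <- tryCatch(sqrt(diag(solve(fit$info))), error = function(e) rep(NA_real_, p))
  z <- qnorm(0.975)
  structure(
    list(
      coefficients = setNames(beta, covariates),
      se = setNames(se, covariates),
      hr = setNames(exp(beta), covariates),
      ci_low = setNames(exp(beta - z * se), covariates),
      ci_high = setNames(exp(beta + z * se), covariates),
      p = setNames(2 * stats::pnorm(-abs(beta / se)), covariates),
      loglik = fit$loglik, loglik_null = loglik_null,
      n = length(tt), n_event = sum(ev),
      iter = iter, converged = converged, ties = ties,
      dropped = character(0)
    ),
    class = "cox_ph_fit"
  )
}

#' @export
print.cox_ph_fit <- function(x, ...) {
  cat(sprintf("<cox_ph_fit> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_event, x$ties,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a Cox proportional-hazards fit
#'
#' @param x A `cox_ph_fit`.
#' @param ... Unused.
#' @return A tibble with one row per covariate: `term`, `estimate` (log
#'   hazard ratio), `std.error`, `hr`, `conf.low`, `conf.high`, `p.value`.
#' @method tidy cox_ph_fit
#' @export
tidy.cox_ph_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    hr = unname(x$hr),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high),
    p.value = unname(x$p)
  )
}

#' @rdname tidy.cox_ph_fit
#' @return `glance()` returns a one-row tibble: `n`, `n_event`, `logLik`,
#'   `logLik_null`, `iter`, `converged`.
#' @method glance cox_ph_fit
#' @export
glance.cox_ph_fit <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event, logLik = x$loglik,
    logLik_null = x$loglik_null, iter = x$iter, converged = x$converged
  )
}

#' Univariate Cox screen
#'
#' Fits each candidate covariate in a separate univariate Cox model and
#' flags those with Wald p below the entry threshold (default 0.1, the
#' usual rule for admission to a multivariate model).
#'
#' @inheritParams cox_fit
#' @param entry_p Entry threshold on the univariate p-value.
#' @return A tibble in input covariate order: `term`, `estimate`, `hr`,
#'   `conf.low`, `conf.high`, `p.value`, `selected`.
#' @export
univariate_screen <- function(data, covariates, time = "time_months",
                              event = "event", entry_p = 0.1,
                              ties = "breslow") {
  res <- purrr::map_dfr(covariates, function(cv) {
    fit <- cox_fit(data, cv, time = time, event = event, ties = ties)
    tidy(fit)
  })
  res$selected <- res$p.value < entry_p
  res
}

#' Multivariate Cox fit with collinearity exclusion
#'
#' Before the joint fit, covariate pairs with absolute Pearson correlation
#' above `collinearity_r` are resolved by dropping the member with the
#' larger univariate Cox p-value (pairs are processed in decreasing |r|,
#' and correlations are re-examined after each drop). With a single
#' surviving covariate the result equals the univariate fit.
#'
#' @inheritParams cox_fit
#' @param selected Character vector of covariates entering the model
#'   (>= 2; typically the [univariate_screen()] selection).
#' @param collinearity_r Absolute-correlation threshold (default 0.7).
#' @param collinearity_data Optional data frame whose columns (named like
#'   `selected`) are used for the correlation screen instead of the model
#'   covariates themselves — e.g. the continuous marker values underlying
#'   dichotomized model terms.
#' @return A `cox_ph_fit`; dropped covariates are listed in `$dropped`
#'   and reported via a message.
#' @export
multivariate_cox <- function(data, selected, time = "time_months",
                             event = "event", collinearity_r = 0.7,
                             collinearity_data = NULL, ties = "breslow") {
  if (length(selected) < 2) {
    abort("Multivariate fit needs at least two selected covariates.")
  }
  uni_p <- vapply(selected, function(cv) {
    tidy(cox_fit(data, cv, time = time, event = event, ties = ties))$p.value
  }, numeric(1))
  cor_source <- if (is.null(collinearity_data)) data else collinearity_data
  keep <- selected
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    cm <- suppressWarnings(
      cor(as.data.frame(lapply(cor_source[keep], as.numeric)))
    )
    cm[!upper.tri(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (max(abs(cm)) <= collinearity_r) break
    pair <- keep[c(worst[["row"]], worst[["col"]])]
    # larger univariate p is dropped; on a tie the later-listed member goes
    drop <- if (uni_p[pair[2]] >= uni_p[pair[1]]) pair[2] else pair[1]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  if (length(dropped) > 0) {
    inform(paste0(
      "Excluded from the multivariate model for collinearity (|r| > ",
      collinearity_r, "): ", paste(dropped, collapse = ", "), "."
    ))
  }
  fit <- cox_fit(data, keep, time = time, event = event, ties = ties)
  fit$dropped <- dropped
  fit
}

#' Dichotomize marker values at an empirical quantile
#'
#' Splits values into high/low at the stated quantile (median by default),
#' computed with linear interpolation between order statistics. "High"
#' means strictly greater than the cutoff, matching the "> median"
#' convention of prognostic tables.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param q Quantile for the cutoff (0.5 = median; 0.25 = 25th percentile).
#' @return Logical vector (TRUE = high), with the cutoff in
#'   `attr(, "cutoff")`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))
#' @export
dichotomize <- function(values, q = 0.5) {
  values <- as.numeric(values)
  if (length(unique(values[!is.na(values)])) < 2) {
    abort("Cannot dichotomize: fewer than two distinct values.")
  }
  stopifnot(q > 0, q < 1)
  cutoff <- unname(quantile(values, probs = q, na.rm = TRUE, type = 7))
  out <- values > cutoff
  attr(out, "cutoff") <- cutoff
  out
}

#' Sensitivity and specificity of a dichotomized marker
#'
#' Events are taken as "ever during follow-up" (censoring is ignored; with
#' heavy censoring the event-ever definition understates true incidence,
#' which is noted in the returned message attribute).
#'
#' @param high Logical high/low marker flags.
#' @param event Logical or 0/1 event flags, same length.
#' @return One-row tibble: `sensitivity` (P(high | event)), `specificity`
#'   (P(low | no event)), and the 2x2 counts `tp`, `fp`, `fn`, `tn`.
#'   Components undefined for lack of events (or non-events) are NA.
#' @export
diagnostic_accuracy <- function(high, event) {
  stopifnot(length(high) == length(event))
  high <- as.logical(high); event <- as.logical(as.integer(event))
  tp <- sum(high & event); fn <- sum(!high & event)
  fp <- sum(high & !event); tn <- sum(!high & !event)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens)) inform("No events: sensitivity undefined.")
  if (is.na(spec)) inform("No non-events: specificity undefined.")
  tibble(sensitivity = sens, specificity = spec,
         tp = tp, fp = fp, fn = fn, tn = tn)
}
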