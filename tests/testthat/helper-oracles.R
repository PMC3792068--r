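# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses are hand-summed from residue constants,
# AUROC is brute-force pairwise counting, enumeration is a plain nested
# loop.

oracle_mz <- function(hex, hexnac, fuc, neuac) {
  hex * 162.052824 + hexnac * 203.079373 + fuc * 146.057909 +
    neuac * 291.095417 + neuac * 14.015650 + # methyl ester per sialic acid
    123.068414 +                             # BOA oxime tag
    22.989769                                # sodium adduct
}

oracle_auroc <- function(values, is_case) {
  cases <- values[is_case]
  controls <- values[!is_case]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

oracle_enumerate <- function(lo, hi, max_hex = 9, max_hexnac = 7,
                             max_fuc = 4, max_neuac = 4) {
  out <- list()
  for (h in 3:max_hex) for (n in 2:max_hexnac) {
    for (f in 0:max_fuc) for (s in 0:max_neuac) {
      mz <- oracle_mz(h, n, f, s)
      if (mz >= lo && mz <= hi) {
        out[[length(out) + 1]] <- c(hex = h, hexnac = n, fuc = f, neuac = s)
      }
    }
  }
  out
}

# Kaplan-Meier "no censoring" reference: the empirical survivor function.
oracle_ecdf_surv <- function(times, eval_at) {
  vapply(eval_at, function(u) mean(times > u), numeric(1))
}

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config())
    cache
  }
})
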