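#' Mass model for BOA-labeled, methyl-esterified N-glycans
#'
#' Theoretical m/z values are computed for glycans prepared by
#' glycoblotting: sialic acids methyl-esterified (+CH2 per NeuAc), the
#' reducing end tagged with benzyloxyamine (BOA, an oxime adding C7H9NO net
#' of water), and detection in positive-mode MALDI-TOF as the sodium adduct
#' \[M+Na\]+. All masses are monoisotopic, in Da.
#'
#' @param tolerance Annotation mass tolerance in Da (default 0.2, typical
#'   for externally calibrated MALDI-TOF).
#' @param adduct Cation adduct mass; default sodium (22.989769).
#' @return An object of class `mass_model`: a list with residue masses
#'   (`hex`, `hexnac`, `fuc`, `neuac`), `methyl_ester` increment applied
#'   once per NeuAc, reducing-end `tag` mass, `adduct` mass and `tolerance`.
#' @examples
#' mass_model()
#' @export
mass_model <- function(tolerance = 0.2, adduct = 22.989769) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1, tolerance > 0)
  stopifnot(is.numeric(adduct), length(adduct) == 1)
  structure(
    list(
      residues = c(
        hex = 162.052824, hexnac = 203.079373,
        fuc = 146.057909, neuac = 291.095417
      ),
      methyl_ester = 14.015650,
      tag = 123.068414,
      adduct = adduct,
      tolerance = tolerance
    ),
    class = "mass_model"
  )
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model> BOA-tagged, methyl-esterified N-glycan [M+adduct]+\n")
  cat(sprintf(
    "  residues: Hex %.6f  HexNAc %.6f  Fuc %.6f  NeuAc %.6f\n",
    x$residues["hex"], x$residues["hexnac"], x$residues["fuc"],
    x$residues["neuac"]
  ))
  cat(sprintf(
    "  methyl ester/NeuAc %.6f  tag %.6f  adduct %.6f  tolerance +/- %.3g Da\n",
    x$methyl_ester, x$tag, x$adduct, x$tolerance
  ))
  invisible(x)
}

#' Theoretical m/z of glycan compositions
#'
#' Sum of residue monoisotopic masses, one methyl-ester increment per
#' sialic acid, the BOA reducing-end tag, and the cation adduct.
#'
#' @param comp A composition data frame (see [parse_glycan_code()]); must
#'   pass the N-glycan validity gate.
#' @param model A [mass_model()].
#' @return Numeric vector of theoretical m/z, one per row of `comp`.
#' @examples
#' glycan_mz(parse_glycan_code("5402"))
#' @export
glycan_mz <- function(comp, model = mass_model()) {
  comp <- check_composition(comp, require_valid = TRUE)
  r <- model$residues
  comp$hex * r[["hex"]] + comp$hexnac * r[["hexnac"]] +
    comp$fuc * r[["fuc"]] +
    comp$neuac * (r[["neuac"]] + model$methyl_ester) +
    model$tag + model$adduct
}

#' Integer peak labels for glycan compositions
#'
#' Glycan peaks are conventionally named by the integer part of their
#' theoretical m/z ("glycan m/z 2378"); the label is `floor(m/z)`, not the
#' rounded value (floor(2378.862) = 2378).
#'
#' @inheritParams glycan_mz
#' @return Integer vector of peak labels.
#' @examples
#' peak_label(parse_glycan_code(c("5402", "5410")))
#' @export
peak_label <- function(comp, model = mass_model()) {
  as.integer(floor(glycan_mz(comp, model)))
}

#' Enumerate N-glycan compositions within a mass window
#'
#' Brute-force enumeration of all compositions passing the N-glycan
#' validity gate whose theoretical m/z falls inside `[lo, hi]`, in
#' lexicographic order of (hex, hexnac, fuc, neuac).
#'
#' @param lo,hi Mass window bounds in Da, `lo < hi`.
#' @param bounds Named integer vector of per-residue maximum counts,
#'   e.g. `c(hex = 9, hexnac = 7, fuc = 4, neuac = 4)`.
#' @inheritParams glycan_mz
#' @return A tibble with columns `code`, `hex`, `hexnac`, `fuc`, `neuac`,
#'   `theoretical_mz`, `label`; zero rows when the window is empty.
#' @export
enumerate_compositions <- function(lo, hi,
                                   bounds = c(hex = 9, hexnac = 7,
                                              fuc = 4, neuac = 4),
                                   model = mass_model()) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (!(lo < hi)) abort("`lo` must be strictly less than `hi`.")
  needed <- c("hex", "hexnac", "fuc", "neuac")
  if (!all(needed %in% names(bounds)) || any(!is.finite(bounds[needed]))) {
    abort("`bounds` must be finite and named hex, hexnac, fuc, neuac.")
  }
  grid <- expand.grid(
    neuac = 0:bounds[["neuac"]], fuc = 0:bounds[["fuc"]],
    hexnac = 2:max(2, bounds[["hexnac"]]), hex = 3:max(3, bounds[["hex"]]),
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- as_tibble(grid)[, needed]
  mz <- glycan_mz(grid, model)
  keep <- mz >= lo & mz <= hi
  out <- grid[keep, , drop = FALSE]
  out$theoretical_mz <- mz[keep]
  out$label <- as.integer(floor(out$theoretical_mz))
  out$code <- format_glycan_code(out)
  out <- out[order(out$hex, out$hexnac, out$fuc, out$neuac), ]
  as_tibble(out)[, c("code", needed, "theoretical_mz", "label")]
}

#' Annotate observed peaks with glycan compositions
#'
#' Each peak is matched to the candidate composition minimizing the
#' absolute m/z difference, provided it lies within the model tolerance.
#' Assignment is greedy by increasing distance and one candidate may
#' annotate at most one peak, so the result does not depend on the order
#' of the input peak list. Exact distance ties are broken by fewest total
#' residues, then lexicographic composition.
#'
#' @param peaks A data frame with columns `mz` (> 0) and optionally
#'   `intensity`, e.g. from [read_peak_list()].
#' @param candidates A composition data frame (codes or counts); its
#'   theoretical m/z values are computed with `model`.
#' @inheritParams glycan_mz
#' @return A tibble with one row per input peak (original order):
#'   `mz`, `intensity`, `code`, `theoretical_mz`, `label`, `delta`
#'   (observed minus theoretical) and `matched`. Unmatched peaks carry
#'   `matched = FALSE` and NA annotation columns.
#' @export
annotate_peaks <- function(peaks, candidates, model = mass_model()) {
  if (!is.data.frame(peaks) || !"mz" %in% names(peaks)) {
    abort("`peaks` must be a data frame with an `mz` column.")
  }
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
    abort("Peak m/z values must be positive and finite.")
  }
  cand <- check_composition(candidates, require_valid = TRUE)
  cand$code <- format_glycan_code(cand)
  cand$theoretical_mz <- glycan_mz(cand, model)
  cand$label <- as.integer(floor(cand$theoretical_mz))
  cand$n_residues <- cand$hex + cand$hexnac + cand$fuc + cand$neuac

  # all peak/candidate pairs within tolerance, ordered for greedy assignment
  pairs <- expand.grid(
    peak = seq_len(nrow(peaks)), cand = seq_len(nrow(cand)),
    KEEP.OUT.ATTRS = FALSE
  )
  pairs$dist <- abs(peaks$mz[pairs$peak] - cand$theoretical_mz[pairs$cand])
  pairs <- pairs[pairs$dist <= model$tolerance, , drop = FALSE]
  ord <- order(
    pairs$dist, cand$n_residues[pairs$cand],
    cand$hex[pairs$cand], cand$hexnac[pairs$cand],
    cand$fuc[pairs$cand], cand$neuac[pairs$cand],
    peaks$mz[pairs$peak]
  )
  pairs <- pairs[ord, , drop = FALSE]

  assign_cand <- rep(NA_integer_, nrow(peaks))
  used_cand <- logical(nrow(cand))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$peak[k]; j <- pairs$cand[k]
    if (is.na(assign_cand[i]) && !used_cand[j]) {
      assign_cand[i] <- j
      used_cand[j] <- TRUE
    }
  }

  out <- tibble(
    mz = peaks$mz,
    intensity = if ("intensity" %in% names(peaks)) {
      peaks$intensity
    } else {
      NA_real_
    },
    code = ifelse(is.na(assign_cand), NA_character_, cand$code[assign_cand]),
    theoretical_mz = ifelse(is.na(assign_cand), NA_real_,
                            cand$theoretical_mz[assign_cand]),
    label = ifelse(is.na(assign_cand), NA_integer_, cand$label[assign_cand]),
    matched = !is.na(assign_cand)
  )
  out$delta <- out$mz - out$theoretical_mz
  n_unmatched <- sum(!out$matched)
  if (n_unmatched > 0) {
    inform(paste0(n_unmatched, " peak(s) left unannotated (no candidate ",
                  "within +/- ", format(model$tolerance), " Da)."))
  }
  out[, c("mz", "intensity", "code", "theoretical_mz", "label",
          "delta", "matched")]
}

#' Read a two-column peak list
#'
#' Delimited text with columns m/z and intensity; lines starting with `#`
#' are comments. Commas and tabs/whitespace are both accepted.
#'
#' @param path Path to the peak list file.
#' @return A tibble with columns `mz` and `intensity`.
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(tibble(mz = numeric(), intensity = numeric()))
  fields <- strsplit(lines, "[,\t ]+")
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad) > 0) {
    abort(paste0("Peak list line ", bad[1], " does not have two columns."))
  }
  mz <- as.numeric(vapply(fields, `[[`, character(1), 1))
  intensity <- as.numeric(vapply(fields, `[[`, character(1), 2))
  if (anyNA(mz) || anyNA(intensity)) {
    abort("Non-numeric value in peak list.")
  }
  if (any(mz <= 0)) abort("Peak m/z values must be positive.")
  tibble(mz = mz, intensity = intensity)
}
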