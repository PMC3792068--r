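#' Composition-based structural classification of N-glycans
#'
#' Assigns every valid N-glycan composition to exactly one structural type
#' and derives the aggregate flags used throughout serum glycomics. The
#' rules are composition-only heuristics (isomers and linkages are not
#' resolved):
#'
#' * **high-mannose**: `hexnac == 2`, `5 <= hex <= 9`, no fucose or NeuAc;
#' * **hybrid**: `hexnac == 3` and `hex >= 5`;
#' * **complex**: `hexnac >= 4`, or `hexnac == 3` with `hex <= 4`
#'   (truncated mono-antennary complex);
#' * **other**: anything else passing the validity gate.
#'
#' Antennarity of complex glycans is `min(hexnac - 2, 4)`, with one
#' override: `hexnac == 5`, `hex == 3`, `neuac == 0` is treated as a
#' bisected bi-antennary structure (antennae 2), since composition alone
#' cannot distinguish a bisecting GlcNAc from a third antenna and
#' agalactosylated serum glycans of this composition are typically
#' bisected IgG-type structures. Galactose count for complex/hybrid
#' glycans is `hex - 3` (the core contributes three mannoses).
#'
#' Derived flags:
#' * `sialylated`: `neuac >= 1`; `fucosylated`: `fuc >= 1`;
#' * `agalactosyl_bi`: complex, bi-antennary, galactose count 0;
#' * `highly_sialylated_multibranched`: complex, antennae >= 3, `neuac >= 3`;
#' * `slex_potential`: complex, `neuac >= 1` and `fuc >= 2` (a single
#'   fucose is assumed core-linked; sialyl Lewis X requires an antenna
#'   fucose together with sialylation).
#'
#' @param comp Composition data frame (see [parse_glycan_code()]).
#' @return The input tibble with columns `type`, `antennae` (NA for
#'   non-complex), `galactose`, `sialylated`, `fucosylated`,
#'   `agalactosyl_bi`, `highly_sialylated_multibranched`, `slex_potential`
#'   appended.
#' @examples
#' classify_glycans(parse_glycan_code(c("5200", "5402", "7634")))
#' @export
classify_glycans <- function(comp) {
  comp <- check_composition(comp, require_valid = TRUE)
  if (!"code" %in% names(comp)) comp$code <- format_glycan_code(comp)
  out <- as_tibble(comp)
  out$type <- with(out, case_when(
    hexnac == 2 & hex >= 5 & hex <= 9 & fuc == 0 & neuac == 0 ~ "high-mannose",
    hexnac == 3 & hex >= 5 ~ "hybrid",
    hexnac >= 4 | (hexnac == 3 & hex <= 4) ~ "complex",
    TRUE ~ "other"
  ))
  is_complex <- out$type == "complex"
  ant <- pmin(out$hexnac - 2L, 4L)
  ant[out$hexnac == 5L & out$hex == 3L & out$neuac == 0L] <- 2L # bisected
  out$antennae <- ifelse(is_complex, ant, NA_integer_)
  out$galactose <- ifelse(out$type %in% c("complex", "hybrid"),
                          pmax(out$hex - 3L, 0L), NA_integer_)
  out$sialylated <- out$neuac >= 1L
  out$fucosylated <- out$fuc >= 1L
  out$agalactosyl_bi <- is_complex & !is.na(out$antennae) &
    out$antennae == 2L & out$galactose == 0L
  out$highly_sialylated_multibranched <- is_complex & !is.na(out$antennae) &
    out$antennae >= 3L & out$neuac >= 3L
  out$slex_potential <- is_complex & out$neuac >= 1L & out$fuc >= 2L
  out
}

#' Antennae count of complex glycans
#'
#' @inheritParams classify_glycans
#' @return Integer vector of antennae counts (2-4).
#' @examples
#' antennae_count(parse_glycan_code("5402"))
#' @export
antennae_count <- function(comp) {
  cls <- classify_glycans(comp)
  if (any(cls$type != "complex")) {
    abort(paste0(
      "Antennarity is defined for complex-type glycans only; got: ",
      paste(unique(cls$code[cls$type != "complex"]), collapse = ", "), "."
    ))
  }
  cls$antennae
}

#' @rdname classify_glycans
#' @export
is_agalactosyl_biantennary <- function(comp) {
  classify_glycans(comp)$agalactosyl_bi
}

#' @rdname classify_glycans
#' @export
is_highly_sialylated_multibranched <- function(comp) {
  classify_glycans(comp)$highly_sialylated_multibranched
}

#' @rdname classify_glycans
#' @export
slex_potential <- function(comp) {
  classify_glycans(comp)$slex_potential
}

# Predicate keywords accepted by aggregate_abundance()
class_predicates <- function() {
  list(
    all = function(cls) rep(TRUE, nrow(cls)),
    `high-mannose` = function(cls) cls$type == "high-mannose",
    hybrid = function(cls) cls$type == "hybrid",
    complex = function(cls) cls$type == "complex",
    sialylated = function(cls) cls$sialylated,
    fucosylated = function(cls) cls$fucosylated,
    agalactosyl_bi = function(cls) cls$agalactosyl_bi,
    highly_sialylated_multibranched =
      function(cls) cls$highly_sialylated_multibranched,
    slex_potential = function(cls) cls$slex_potential
  )
}

#' Per-sample aggregate abundance of a glycan class
#'
#' Sums abundances over the panel glycans satisfying a class predicate,
#' e.g. total glycan, complex-type glycans, sialylated glycans, the
#' agalactosyl bi-antennary aggregate (4 panel members) or the highly
#' sialylated multi-branched aggregate (13 panel members).
#'
#' @param abundance Wide abundance tibble: a `sample_id` column plus one
#'   numeric column per glycan, named by composition code or integer peak
#'   label (see [read_abundance_matrix()]).
#' @param predicate Either a keyword (`"all"`, `"high-mannose"`,
#'   `"hybrid"`, `"complex"`, `"sialylated"`, `"fucosylated"`,
#'   `"agalactosyl_bi"`, `"highly_sialylated_multibranched"`,
#'   `"slex_potential"`) or a function taking the classified panel tibble
#'   and returning a logical vector.
#' @param panel Glycan panel tibble (default [reference_panel()]).
#' @return A tibble with columns `sample_id` and `abundance` (the
#'   per-sample sum over selected glycans).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_uc = 4, n_hlt = 4, seed = 1))
#' aggregate_abundance(cohort$abundance, "complex")
#' @export
aggregate_abundance <- function(abundance, predicate, panel = reference_panel()) {
  cols <- resolve_glycan_columns(abundance, panel)
  cls <- classify_glycans(panel)
  if (is.character(predicate)) {
    preds <- class_predicates()
    if (!predicate %in% names(preds)) {
      abort(paste0(
        "Unknown class predicate ", encodeString(predicate, quote = "\""),
        "; available: ", paste(names(preds), collapse = ", "), "."
      ))
    }
    keep_codes <- cls$code[preds[[predicate]](cls)]
  } else if (is.function(predicate)) {
    sel <- predicate(cls)
    stopifnot(is.logical(sel), length(sel) == nrow(cls))
    keep_codes <- cls$code[sel]
  } else {
    abort("`predicate` must be a keyword string or a function.")
  }
  keep <- cols$column[cols$code %in% keep_codes]
  vals <- as.matrix(abundance[, keep, drop = FALSE])
  tibble(
    sample_id = abundance$sample_id,
    abundance = rowSums(vals)
  )
}

# Map abundance matrix column names (codes or integer labels) to panel
# rows. Errors listing any column that matches no panel glycan.
resolve_glycan_columns <- function(abundance, panel) {
  if (!is.data.frame(abundance) || !"sample_id" %in% names(abundance)) {
    abort("`abundance` must be a data frame with a `sample_id` column.")
  }
  cols <- setdiff(names(abundance), "sample_id")
  code <- ifelse(cols %in% panel$code, cols,
                 panel$code[match(cols, as.character(panel$label))])
  unknown <- cols[is.na(code)]
  if (length(unknown) > 0) {
    abort(paste0(
      "Abundance column(s) not in the glycan panel: ",
      paste(unknown, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(code)) {
    abort("Duplicate glycan columns after code/label resolution.")
  }
  tibble(column = cols, code = code,
         label = panel$label[match(code, panel$code)])
}

#' Classification report for a glycan panel
#'
#' One row per panel glycan with its code, label, type, antennae and
#' aggregate flags, written as delimited text.
#'
#' @param panel Glycan panel tibble.
#' @param path Output file path (CSV).
#' @return The classified tibble, invisibly.
#' @export
write_classification_report <- function(panel, path) {
  cls <- classify_glycans(panel)
  keep <- c("code", "label", "theoretical_mz", "type", "antennae",
            "galactose", "sialylated", "fucosylated", "agalactosyl_bi",
            "highly_sialylated_multibranched", "slex_potential")
  keep <- intersect(keep, names(cls))
  readr::write_csv(cls[, keep], path)
  invisible(cls)
}
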