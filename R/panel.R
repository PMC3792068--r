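# Codes of the 61-member reference panel. Membership is a synthetic
# reconstruction constrained by the published marginals of the serum
# panel: 5 high-mannose, 6 hybrid, 50 complex (25 bi- / 10 tri- /
# 15 tetra-antennary), 43 sialylated, 33 fucosylated, 13 highly
# sialylated multi-branched, 4 agalactosyl bi-antennary; anchored members
# 5200 (m/z 1362, panel minimum), 7634 (m/z 4157, maximum), 5402 (2378),
# 5410 (1914), 6523 (3341), 7624 (4011).
reference_panel_codes <- function() {
  c(
    # high-mannose Man5-Man9
    "5200", "6200", "7200", "8200", "9200",
    # hybrid
    "5300", "6300", "5310", "5301", "6301", "5311",
    # complex bi-antennary: agalactosylated (incl. bisected 35x0)
    "3400", "3410", "3500", "3510",
    # bi-antennary, neutral
    "4400", "5400", "5410", "5420",
    # bi-antennary, sialylated
    "4401", "4402", "5401", "5402", "6401", "6402",
    # bi-antennary, sialylated + fucosylated
    "4411", "4412", "4421", "5411", "5412", "5421", "5422",
    "6411", "6412", "6421", "6422",
    # tri-antennary
    "6510", "6501", "6502", "6511", "6512", "6522",
    "6503", "6513", "6523", "6533",
    # tetra-antennary
    "8600", "7601", "7602", "7611", "7612", "7622",
    "7603", "7604", "6603", "7613", "7614", "7623", "7624", "7633", "7634"
  )
}

#' The 61-glycan serum reference panel
#'
#' A synthetic reconstruction of the whole-serum N-glycan panel: 61
#' compositions whose structural-class marginals match the published
#' counts (5 high-mannose, 6 hybrid, 50 complex of which 25/10/15
#' bi/tri/tetra-antennary, 43 sialylated, 33 fucosylated, 13 highly
#' sialylated multi-branched, 4 agalactosyl bi-antennary) and whose
#' theoretical m/z range is 1362.481-4157.522. The published supplementary
#' glycan list is not available, so membership beyond the six anchored
#' codes (5200, 5402, 5410, 6523, 7624, 7634) is a constrained choice;
#' the constraint set is revalidated against [classify_glycans()] on
#' every call.
#'
#' @param model A [mass_model()] used for theoretical m/z and labels.
#' @return A tibble with 61 rows: `code`, `hex`, `hexnac`, `fuc`, `neuac`,
#'   `theoretical_mz`, `label`.
#' @examples
#' reference_panel()
#' @export
reference_panel <- function(model = mass_model()) {
  panel <- parse_glycan_code(reference_panel_codes())
  panel$theoretical_mz <- glycan_mz(panel, model)
  panel$label <- as.integer(floor(panel$theoretical_mz))
  validate_panel(panel)
  panel
}

#' Validate a glycan panel against the published marginals
#'
#' Checks the constraint set the reference panel must satisfy; the class
#' counts are recomputed with [classify_glycans()], never hard-coded from
#' the panel itself, so a classifier change that breaks the printed
#' marginals fails loudly.
#'
#' @param panel A panel tibble as returned by [reference_panel()].
#' @return The panel, invisibly; errors on any violated constraint.
#' @export
validate_panel <- function(panel) {
  fail <- function(msg) abort(paste0("Reference panel constraint violated: ", msg))
  if (nrow(panel) != 61) fail("panel must have 61 glycans.")
  if (anyDuplicated(panel$code)) fail("duplicate composition codes.")
  if (anyDuplicated(panel$label)) fail("duplicate integer labels.")
  cls <- classify_glycans(panel)
  counts <- table(factor(cls$type, levels = c("high-mannose", "hybrid",
                                              "complex", "other")))
  if (counts[["high-mannose"]] != 5) fail("expected 5 high-mannose glycans.")
  if (counts[["hybrid"]] != 6) fail("expected 6 hybrid glycans.")
  if (counts[["complex"]] != 50) fail("expected 50 complex glycans.")
  ant <- table(factor(cls$antennae[cls$type == "complex"], levels = 2:4))
  if (ant[["2"]] != 25) fail("expected 25 bi-antennary complex glycans.")
  if (ant[["3"]] != 10) fail("expected 10 tri-antennary complex glycans.")
  if (ant[["4"]] != 15) fail("expected 15 tetra-antennary complex glycans.")
  if (sum(cls$sialylated) != 43) fail("expected 43 sialylated glycans.")
  if (sum(cls$fucosylated) != 33) fail("expected 33 fucosylated glycans.")
  if (sum(cls$highly_sialylated_multibranched) != 13) {
    fail("expected 13 highly sialylated multi-branched glycans.")
  }
  if (sum(cls$agalactosyl_bi) != 4) {
    fail("expected 4 agalactosyl bi-antennary glycans.")
  }
  anchors <- c("5200" = 1362L, "5410" = 1914L, "5402" = 2378L,
               "6523" = 3341L, "7624" = 4011L, "7634" = 4157L)
  for (code in names(anchors)) {
    i <- match(code, panel$code)
    if (is.na(i)) fail(paste0("anchored composition ", code, " missing."))
    if (panel$label[i] != anchors[[code]]) {
      fail(paste0("composition ", code, " must carry label ", anchors[[code]], "."))
    }
  }
  if (panel$code[which.min(panel$theoretical_mz)] != "5200") {
    fail("5200 must be the panel minimum m/z.")
  }
  if (panel$code[which.max(panel$theoretical_mz)] != "7634") {
    fail("7634 must be the panel maximum m/z.")
  }
  invisible(panel)
}

#' Write / read a glycan panel table
#'
#' Delimited table with columns code, hex, hexnac, fuc, neuac,
#' theoretical_mz, label.
#'
#' @param panel Panel tibble.
#' @param path File path (CSV).
#' @return `write_panel()` returns the panel invisibly; `read_panel()`
#'   returns the panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_character(), hex = readr::col_integer(),
      hexnac = readr::col_integer(), fuc = readr::col_integer(),
      neuac = readr::col_integer(), theoretical_mz = readr::col_double(),
      label = readr::col_integer()
    )
  )
  as_tibble(panel)
}
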