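#' Parse four-digit glycan composition codes
#'
#' Serum N-glycan compositions are conventionally written as a four-digit
#' code giving, in order, the numbers of hexose (mannose/galactose),
#' N-acetylhexosamine (GlcNAc), deoxyhexose (fucose) and sialic acid (NeuAc)
#' residues: `"5402"` means Hex5 HexNAc4 Fuc0 NeuAc2. Counts of 10 or more
#' cannot be written contiguously, so a dash-separated form
#' (`"12-4-0-2"`) is also accepted.
#'
#' @param code Character vector of composition codes, each either four
#'   contiguous digits or four dash-separated non-negative integers.
#' @return A tibble with one row per code and columns `code` (canonical
#'   form), `hex`, `hexnac`, `fuc`, `neuac` (integer counts).
#' @seealso [format_glycan_code()], [is_valid_nglycan()]
#' @examples
#' parse_glycan_code(c("5402", "5410", "12-4-0-2"))
#' @export
parse_glycan_code <- function(code) {
  stopifnot(is.character(code), length(code) >= 1)
  counts <- lapply(code, function(x) {
    if (grepl("^[0-9]{4}$", x)) {
      as.integer(strsplit(x, "")[[1]])
    } else if (grepl("^[0-9]+(-[0-9]+){3}$", x)) {
      as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    } else {
      abort(paste0(
        "Malformed composition code ", encodeString(x, quote = "\""),
        ": expected 4 contiguous digits or 4 dash-separated counts."
      ))
    }
  })
  m <- do.call(rbind, counts)
  out <- tibble(
    hex = m[, 1], hexnac = m[, 2], fuc = m[, 3], neuac = m[, 4]
  )
  out$code <- format_glycan_code(out)
  out[, c("code", "hex", "hexnac", "fuc", "neuac")]
}

#' Format glycan compositions as canonical codes
#'
#' The canonical form is four contiguous digits when every count is below
#' 10, and dash-separated counts otherwise.
#'
#' @param comp A data frame with integer columns `hex`, `hexnac`, `fuc`,
#'   `neuac`, as returned by [parse_glycan_code()] or [glycan_composition()].
#' @return Character vector of canonical codes.
#' @export
format_glycan_code <- function(comp) {
  comp <- check_composition(comp, require_valid = FALSE)
  ifelse(
    comp$hex < 10 & comp$hexnac < 10 & comp$fuc < 10 & comp$neuac < 10,
    paste0(comp$hex, comp$hexnac, comp$fuc, comp$neuac),
    paste(comp$hex, comp$hexnac, comp$fuc, comp$neuac, sep = "-")
  )
}

#' Construct a glycan composition table
#'
#' @param hex,hexnac,fuc,neuac Non-negative integer residue counts
#'   (recycled to a common length).
#' @return A tibble with columns `code`, `hex`, `hexnac`, `fuc`, `neuac`.
#' @examples
#' glycan_composition(hex = 5, hexnac = 4, neuac = 2)
#' @export
glycan_composition <- function(hex, hexnac, fuc = 0L, neuac = 0L) {
  out <- tibble(
    hex = as.integer(hex), hexnac = as.integer(hexnac),
    fuc = as.integer(fuc), neuac = as.integer(neuac)
  )
  out <- check_composition(out, require_valid = FALSE)
  out$code <- format_glycan_code(out)
  out[, c("code", "hex", "hexnac", "fuc", "neuac")]
}

#' Test whether compositions are plausible N-glycans
#'
#' All mammalian N-glycans share the trimannosyl-chitobiose core
#' Hex3HexNAc2, so a composition is gated as a valid N-glycan when
#' `hexnac >= 2` and `hex >= 3` (all counts non-negative).
#'
#' @inheritParams format_glycan_code
#' @return Logical vector.
#' @export
is_valid_nglycan <- function(comp) {
  comp <- check_composition(comp, require_valid = FALSE)
  comp$hexnac >= 2L & comp$hex >= 3L
}

# Validate a composition table: required columns, non-negative integer
# counts; optionally enforce the N-glycan core gate.
check_composition <- function(comp, require_valid = TRUE) {
  if (!is.data.frame(comp)) {
    abort("`comp` must be a data frame with columns hex, hexnac, fuc, neuac.")
  }
  needed <- c("hex", "hexnac", "fuc", "neuac")
  missing_cols <- setdiff(needed, names(comp))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Composition table lacks column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  comp <- as_tibble(comp)
  for (col in needed) {
    v <- comp[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != trunc(v))) {
      abort(paste0("Column `", col, "` must hold non-negative integers."))
    }
    comp[[col]] <- as.integer(v)
  }
  if (require_valid) {
    bad <- !is_valid_nglycan(comp)
    if (any(bad)) {
      codes <- format_glycan_code(comp[bad, , drop = FALSE])
      abort(paste0(
        "Not valid N-glycan composition(s) (need hexnac >= 2, hex >= 3): ",
        paste(unique(codes), collapse = ", "), "."
      ))
    }
  }
  comp
}
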