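#' Tidy a ratio marker
#'
#' @param x A `ratio_marker` from [select_ratio_marker()].
#' @param ... Unused.
#' @return Per-sample tibble: `sample_id`, `group`, `ratio`.
#' @method tidy ratio_marker
#' @export
tidy.ratio_marker <- function(x, ...) {
  x$ratios
}

#' @rdname tidy.ratio_marker
#' @return `glance()` returns a one-row tibble with the numerator and
#'   denominator codes and labels, the marker AUROC and the sample count.
#' @method glance ratio_marker
#' @export
glance.ratio_marker <- function(x, ...) {
  tibble(
    numerator_code = x$numerator$code,
    numerator_label = x$numerator$label,
    denominator_code = x$denominator$code,
    denominator_label = x$denominator$label,
    auroc = x$auroc,
    n = nrow(x$ratios)
  )
}
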