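#' Broom-style accessors for call and burden tables
#'
#' `tidy()` returns the per-variant rows with the key, score and flag
#' columns; `glance()` a one-row model-level summary.
#'
#' @param x a `mirsnp_calls` or `mirsnp_burden` tibble.
#' @param ... unused.
#' @return a tibble.
#' @name mirsnp-broom
NULL

#' @rdname mirsnp-broom
#' @export
tidy.mirsnp_calls <- function(x, ...) {
  tibble::as_tibble(x)[c(
    "snp_id", "hairpin_id", "position", "ref", "alt", "origin",
    "segment_class", "ddg", "rank", "cumulative_fraction", "candidate"
  )]
}

#' @rdname mirsnp-broom
#' @export
glance.mirsnp_calls <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_candidates = sum(x$candidate),
    n_classes = dplyr::n_distinct(x$segment_class),
    knee_method = "max_distance_to_chord"
  )
}

#' @rdname mirsnp-broom
#' @export
tidy.mirsnp_burden <- function(x, ...) {
  tibble::as_tibble(x)[c(
    "snp_id", "hairpin_id", "position", "ref", "alt", "origin", "maf",
    "segment_class", "ddg", "mean_score", "selection_frequency", "burden"
  )]
}

#' @rdname mirsnp-broom
#' @export
glance.mirsnp_burden <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_burden = sum(x$burden),
    iterations = attr(x, "iterations") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}
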