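#' Apply a single-nucleotide substitution
#'
#' @param sequence character vector of sequences.
#' @param position,ref,alt substitution description (recycled with
#'   `sequence`); `ref` must match the sequence at `position` and `alt`
#'   must differ from `ref`.
#' @return the mutated sequences, differing from the input at exactly one
#'   position each.
#' @examples
#' apply_variant("AUUUUUCCAUCUUUGUAU", 16, "U", "G")
#' @export
apply_variant <- function(sequence, position, ref, alt) {
  at <- stringr::str_sub(sequence, position, position)
  if (any(at != ref)) {
    i <- which(at != ref)[1]
    stop(sprintf(
      "ref allele %s does not match sequence at position %d (%s)",
      ref[min(i, length(ref))], position[min(i, length(position))], at[i]
    ), call. = FALSE)
  }
  if (any(alt == ref)) stop("alt allele equals ref (identity variant)", call. = FALSE)
  if (any(!alt %in% RNA_BASES)) stop("alt allele not in ACGU", call. = FALSE)
  stringr::str_sub(sequence, position, position) <- alt
  sequence
}

#' Enumerate the variant universe of segmented hairpins
#'
#' For every hairpin position covered by at least one segment, three
#' artificial substitutions (one per non-reference base) are generated.
#' Known SNPs are merged in: an artificial variant colliding with a known
#' one at the same (hairpin, position, alt) is dropped in favor of the
#' known record.  The result is deterministic, ordered by
#' (`hairpin_id`, `position`, `alt`).
#'
#' @param hairpins hairpin tibble.
#' @param segments segment tibble from [segment_hairpins()].
#' @param known optional known-variant tibble from [read_snp_table()].
#' @return variant tibble: `snp_id`, `hairpin_id`, `position`, `ref`,
#'   `alt`, `origin`, `maf`.
#' @export
enumerate_artificial <- function(hairpins, segments, known = NULL) {
  art <- purrr::map_dfr(hairpins$id, function(hid) {
    seg <- dplyr::filter(segments, .data$hairpin_id == hid)
    pos <- sort(unique(unlist(purrr::map2(seg$start, seg$end, seq.int))))
    seq <- hairpins$sequence[match(hid, hairpins$id)]
    ref <- stringr::str_sub(seq, pos, pos)
    tidyr::expand_grid(position = pos, alt = RNA_BASES) |>
      dplyr::mutate(
        hairpin_id = hid,
        ref = rep(ref, each = 4L)
      ) |>
      dplyr::filter(.data$alt != .data$ref)
  })
  art <- dplyr::mutate(art,
    snp_id = sprintf("art_%s_%d%s>%s", .data$hairpin_id, .data$position, .data$ref, .data$alt),
    origin = "artificial", maf = NA_real_
  )
  if (!is.null(known) && nrow(known) > 0) {
    art <- dplyr::anti_join(art, known, by = c("hairpin_id", "position", "alt"))
    art <- dplyr::bind_rows(art, known)
  }
  cols <- c("snp_id", "hairpin_id", "position", "ref", "alt", "origin", "maf")
  dplyr::arrange(art[cols], .data$hairpin_id, .data$position, .data$alt)
}
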