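#' Infer the star (unannotated) mature arm of a hairpin
#'
#' Many hairpins have only one mature arm annotated.  The opposite arm is
#' placed artificially using the two processing principles of the
#' miRNA duplex: a 2-nt 3' overhang (the 5p arm starts 2 nt before the
#' base pairing with the 3p arm's end, and the 3p arm ends 2 nt after the
#' base pairing with the 5p arm's start) and maximal Watson-Crick + wobble
#' complementarity between the two arms.  The scan is ungapped: every
#' placement of an interval of the known arm's length on the opposite side
#' is scored (+1 per WC pair, +0.5 per G.U wobble), subject to leaving at
#' least 1 nt of terminal loop between the arms and at least 1 nt of
#' flanking extension outside the inferred arm.  Ties are broken toward the
#' placement maximizing the loop size, then the most 3' placement.
#'
#' @param sequence hairpin sequence (normalized RNA).
#' @param known_start,known_end 1-based closed interval of the annotated arm.
#' @param known_arm which arm is annotated, `"5p"` or `"3p"`.
#' @return a one-row tibble with `start`, `end`, `score` of the inferred
#'   opposite arm.
#' @examples
#' hp <- make_hairpin(stem_len = 18, loop_len = 8, seed = 1)$hairpin
#' infer_star_arm(hp$sequence, hp$mature5p_start, hp$mature5p_end, "5p")
#' @export
infer_star_arm <- function(sequence, known_start, known_end,
                           known_arm = c("5p", "3p")) {
  known_arm <- match.arg(known_arm)
  len <- nchar(sequence)
  m <- known_end - known_start + 1L
  if (m < 3L) stop("annotated arm shorter than 3 nt", call. = FALSE)
  ch <- seq_chars(sequence)
  k <- 0:(m - 3L) # paired offsets under the 2-nt overhang geometry

  if (known_arm == "5p") {
    # candidate 3p interval [s, s+m-1]; 5p(known_start+k) pairs 3p(s+m-3-k)
    s_lo <- known_end + 2L
    s_hi <- len - m # ensures >=1 nt of 3' extension
    s_range <- if (s_hi >= s_lo) seq.int(s_lo, s_hi) else integer(0)
    if (length(s_range) == 0) {
      stop("no star-arm placement leaves >=1 nt of loop and >=1 nt of extension",
        call. = FALSE
      )
    }
    score <- vapply(s_range, function(s) {
      sum(pair_comp_score(ch[known_start + k], ch[s + m - 3L - k]))
    }, numeric(1))
    # loop size = s - known_end - 1 grows with s, so both tie rules favor larger s
    ord <- order(-score, -s_range)
  } else {
    # candidate 5p interval [s, s+m-1]; 5p(s+k) pairs 3p(known_end-2-k)
    s_hi <- known_start - m - 1L # ensures >=1 nt of loop
    s_range <- if (s_hi >= 2L) seq.int(2L, s_hi) else integer(0)
    if (length(s_range) == 0) {
      stop("no star-arm placement leaves >=1 nt of loop and >=1 nt of extension",
        call. = FALSE
      )
    }
    score <- vapply(s_range, function(s) {
      sum(pair_comp_score(ch[s + k], ch[known_end - 2L - k]))
    }, numeric(1))
    # loop size = known_start - (s+m-1) - 1 grows as s shrinks
    ord <- order(-score, s_range)
  }
  s <- s_range[ord[1]]
  tibble::tibble(start = s, end = s + m - 1L, score = score[ord[1]])
}

#' Segment hairpins into terminal loop, mature duplex and extension duplex
#'
#' Each hairpin is split into five intervals grouped in three segment
#' classes: `ext5p`/`ext3p` (class `extension`, up to `ext_size` nt
#' immediately flanking the mature arms, truncated at the hairpin ends),
#' `mature5p`/`mature3p` (class `mature`), and `loop` (class `loop`, the
#' interval strictly between the two mature arms).  A missing arm is
#' inferred with [infer_star_arm()].  When the annotation leaves no
#' inter-arm interval (arms abut), the loop is taken from the MFE structure
#' of the full hairpin: the 3'-most hairpin loop of the predicted
#' structure.  Overlapping segments are legal; a base in an overlap belongs
#' to every segment that contains it.
#'
#' @param hairpins tibble as returned by [read_hairpins()]: columns `id`,
#'   `sequence`, `mature5p_start`, `mature5p_end`, `mature3p_start`,
#'   `mature3p_end` (`NA` for an absent arm).
#' @param ext_size maximum extension-arm length in nt (default 25, the
#'   approximate Drosha cleavage context).
#' @inheritParams fold_backend
#' @return a tibble with columns `hairpin_id`, `segment` (one of `ext5p`,
#'   `mature5p`, `loop`, `mature3p`, `ext3p`), `class` (`extension`,
#'   `mature`, `loop`), `start`, `end`, `star_inferred`.
#' @export
segment_hairpins <- function(hairpins, ext_size = 25, backend = c("vienna", "basic")) {
  backend <- match.arg(backend)
  stopifnot(ext_size >= 1)
  purrr::pmap_dfr(hairpins, function(id, sequence, mature5p_start, mature5p_end,
                                     mature3p_start, mature3p_end, ...) {
    len <- nchar(sequence)
    has5 <- !is.na(mature5p_start)
    has3 <- !is.na(mature3p_start)
    star <- c(`5p` = FALSE, `3p` = FALSE)
    if (!has5 && !has3) {
      stop("hairpin '", id, "': no mature arm annotated; cannot segment",
        call. = FALSE
      )
    }
    if (!has3) {
      inf <- infer_star_arm(sequence, mature5p_start, mature5p_end, "5p")
      mature3p_start <- inf$start
      mature3p_end <- inf$end
      star["3p"] <- TRUE
    }
    if (!has5) {
      inf <- infer_star_arm(sequence, mature3p_start, mature3p_end, "3p")
      mature5p_start <- inf$start
      mature5p_end <- inf$end
      star["5p"] <- TRUE
    }
    if (mature5p_end >= mature3p_start) {
      stop("hairpin '", id, "': mature arms overlap each other", call. = FALSE)
    }
    loop_start <- mature5p_end + 1L
    loop_end <- mature3p_start - 1L
    if (loop_start > loop_end) {
      # arms abut: fall back to the predicted structure's hairpin loop
      fr <- fold_mfe(sequence, backend = backend)
      iv <- loop_interval(fr$structure)[[1]]
      loop_start <- iv[1]
      loop_end <- iv[2]
    }
    ext5p_start <- max(1L, mature5p_start - as.integer(ext_size))
    ext5p_end <- mature5p_start - 1L
    ext3p_start <- mature3p_end + 1L
    ext3p_end <- min(len, mature3p_end + as.integer(ext_size))
    if (ext5p_end < ext5p_start || ext3p_end < ext3p_start) {
      stop("hairpin '", id, "': mature arm flush with the hairpin end ",
        "leaves an empty extension arm",
        call. = FALSE
      )
    }
    tibble::tibble(
      hairpin_id = id,
      segment = c("ext5p", "mature5p", "loop", "mature3p", "ext3p"),
      class = c("extension", "mature", "loop", "mature", "extension"),
      start = as.integer(c(ext5p_start, mature5p_start, loop_start, mature3p_start, ext3p_start)),
      end = as.integer(c(ext5p_end, mature5p_end, loop_end, mature3p_end, ext3p_end)),
      star_inferred = c(FALSE, star[["5p"]], FALSE, star[["3p"]], FALSE)
    )
  })
}

#' Segment classes containing a position
#'
#' @param segments segment tibble from [segment_hairpins()], already
#'   restricted to (or containing) the hairpin of interest.
#' @param position 1-based position on the hairpin.
#' @param hairpin_id optional id to filter `segments` by.
#' @return character vector, a subset of `c("extension", "loop", "mature")`
#'   (empty for a base outside every segment, e.g. beyond the extension
#'   bound on a long hairpin).
#' @examples
#' hp <- make_hairpin(seed = 1)
#' segment_membership(hp$segments, hp$segments$start[hp$segments$segment == "loop"])
#' @export
segment_membership <- function(segments, position, hairpin_id = NULL) {
  if (!is.null(hairpin_id)) {
    segments <- dplyr::filter(segments, .data$hairpin_id == .env$hairpin_id)
  }
  hit <- segments$start <= position & segments$end >= position
  sort(unique(segments$class[hit]))
}
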