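#' RNA alphabet helpers
#'
#' All sequences in the package live on the RNA alphabet `A C G U`, written
#' 5'->3'.  Input is normalized once at the reading layer: lower case is
#' folded and DNA `T` becomes `U`; anything else is a hard error that names
#' the offending record and position.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. a record id).
#' @return `normalize_rna()` returns the normalized sequences;
#'   `revcomp_rna()` the reverse complements.
#' @examples
#' normalize_rna("acgt")
#' revcomp_rna("GGAU")
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("acgut", "ACGUU", x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- stringr::str_locate(x, "[^ACGU]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    label <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i] else what
    stop(sprintf(
      "non-ACGUT character in %s '%s' at position %d",
      what, label, bad[i]
    ), call. = FALSE)
  }
  x
}

#' @rdname normalize_rna
#' @export
revcomp_rna <- function(x) {
  stringi_rev(chartr("ACGU", "UGCA", stringr::str_to_upper(x)))
}

stringi_rev <- function(x) {
  vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), character(1))
}

RNA_BASES <- c("A", "C", "G", "U")

# +1 for a Watson-Crick pair, +0.5 for a G.U wobble, 0 otherwise (vectorized)
pair_comp_score <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  wobble <- (a == "G" & b == "U") | (a == "U" & b == "G")
  as.numeric(wc) + 0.5 * as.numeric(wobble)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
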