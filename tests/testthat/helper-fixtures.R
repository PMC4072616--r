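# In-code fixtures shared across the suite.  Everything is generated at
# test time; nothing is read from disk except files the tests write.

# a minimal hairpin tibble with explicit arm annotations
manual_hairpin <- function(sequence, m5 = c(NA, NA), m3 = c(NA, NA), id = "hp") {
  tibble::tibble(
    id = id, sequence = sequence,
    mature5p_start = as.integer(m5[1]), mature5p_end = as.integer(m5[2]),
    mature3p_start = as.integer(m3[1]), mature3p_end = as.integer(m3[2]),
    strand = "+"
  )
}

# one-segment tibble for membership / enumeration tests
manual_segment <- function(hairpin_id, segment, class, start, end) {
  tibble::tibble(
    hairpin_id = hairpin_id, segment = segment, class = class,
    start = as.integer(start), end = as.integer(end), star_inferred = FALSE
  )
}

# independent knee oracle: full perpendicular point-to-chord distance,
# computed point by point with the textbook formula
knee_oracle <- function(fractions) {
  n <- length(fractions)
  if (n <= 1) return(n)
  x1 <- 1; y1 <- fractions[1]; x2 <- n; y2 <- fractions[n]
  d <- vapply(seq_len(n), function(i) {
    abs((y2 - y1) * i - (x2 - x1) * fractions[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }, numeric(1))
  which.max(d)
}

# independent minimal-prefix oracle for the 50%-of-score selection
half_mass_oracle <- function(score) {
  a <- abs(score)
  tot <- sum(a)
  sel <- logical(length(score))
  if (tot == 0) return(sel)
  o <- order(-a)
  for (k in seq_along(o)) {
    if (sum(a[o[seq_len(k)]]) >= tot / 2) {
      sel[o[seq_len(k)]] <- TRUE
      return(sel)
    }
  }
  sel
}
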