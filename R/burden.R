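#' Sample per-variant allele frequencies for one resampling round
#'
#' Frequencies follow the three origin categories: a known variant with a
#' recorded frequency always contributes its own maf; a known variant
#' without one draws Uniform(f_min, f_max) where `[f_min, f_max]` is the
#' range of the recorded frequencies; an artificial variant draws
#' Uniform(0, f_min) on the open interval (a rare-variant prior: an
#' undetected substitution should be rarer than any detected one).
#'
#' @param origin character vector of origin classes (`known_freq`,
#'   `known_nofreq`, `artificial`).
#' @param maf numeric vector of recorded frequencies (`NA` except for
#'   `known_freq`).
#' @param freq_range `c(f_min, f_max)`; defaults to the range of the
#'   `known_freq` mafs present, and is required when there are none.
#' @return numeric vector of frequencies in (0, 1).
#' @export
sample_frequencies <- function(origin, maf, freq_range = NULL) {
  if (is.null(freq_range)) {
    kf <- maf[origin == "known_freq"]
    if (length(kf) == 0) {
      stop("no known-frequency variants: the sampling range is undefined; ",
        "supply freq_range",
        call. = FALSE
      )
    }
    freq_range <- range(kf)
  }
  if (freq_range[1] <= 0) stop("freq_range minimum must be > 0", call. = FALSE)
  f <- maf
  i <- origin == "known_nofreq"
  f[i] <- runif(sum(i), freq_range[1], freq_range[2])
  i <- origin == "artificial"
  draw <- runif(sum(i), 0, freq_range[1])
  while (any(draw == 0)) draw[draw == 0] <- runif(sum(draw == 0), 0, freq_range[1])
  f[i] <- draw
  f
}

#' Select the top variants covering half the score mass
#'
#' Per segment class, variants are sorted by |score| descending and the
#' minimal prefix whose |score| sum reaches at least 50% of the class
#' total is selected (loop scores are negative and duplex scores positive,
#' so the class totals are sign-segregated by construction and magnitudes
#' are compared).  A class whose total is zero selects nothing.
#'
#' @param score numeric vector of frequency-weighted energy changes.
#' @param segment_class parallel character vector of classes.
#' @return logical vector marking the selected variants.
#' @examples
#' one_iteration_select(c(5, 3, 2), rep("extension", 3))
#' @export
one_iteration_select <- function(score, segment_class = rep("all", length(score))) {
  sel <- logical(length(score))
  for (cl in unique(segment_class)) {
    idx <- which(segment_class == cl)
    a <- abs(score[idx])
    tot <- sum(a)
    if (tot == 0) next
    o <- order(-a)
    k <- which(cumsum(a[o]) >= tot / 2)[1]
    sel[idx[o[seq_len(k)]]] <- TRUE
  }
  sel
}

#' Monte-Carlo frequency-weighted burden ranking
#'
#' Identifies the variants responsible for most cases: in each of
#' `iterations` rounds, frequencies are resampled
#' ([sample_frequencies()]), each variant is scored as
#' `frequency * ddG`, and the top variants covering 50% of the score mass
#' per segment class are selected ([one_iteration_select()]).  A variant
#' selected in at least `1 - alpha` of the rounds is flagged as a burden
#' variant.  Fully reproducible given `seed`.
#'
#' @param candidates candidate tibble from [select_inflection()]; rows
#'   with a `candidate` column are filtered to `candidate == TRUE`.
#' @param iterations number of resampling rounds (default 1000).
#' @param alpha selection-stability level (default 0.05: selected in
#'   >= 95% of rounds).
#' @param seed optional integer seed (applied locally).
#' @inheritParams sample_frequencies
#' @return a `mirsnp_burden` tibble: the candidates plus `mean_score`,
#'   `selection_count`, `selection_frequency`, `burden`; attributes
#'   `iterations` and `alpha`.
#' @export
monte_carlo_burden <- function(candidates, iterations = 1000, alpha = 0.05,
                               seed = NULL, freq_range = NULL) {
  if ("candidate" %in% names(candidates)) {
    candidates <- dplyr::filter(candidates, .data$candidate)
  }
  n <- nrow(candidates)
  if (n == 0) {
    out <- dplyr::mutate(candidates,
      mean_score = numeric(0), selection_count = integer(0),
      selection_frequency = numeric(0), burden = logical(0)
    )
    class(out) <- c("mirsnp_burden", setdiff(class(out), "mirsnp_calls"))
    attr(out, "iterations") <- iterations
    attr(out, "alpha") <- alpha
    return(out)
  }
  run <- function() {
    count <- integer(n)
    score_sum <- numeric(n)
    for (it in seq_len(iterations)) {
      f <- sample_frequencies(candidates$origin, candidates$maf, freq_range)
      s <- f * candidates$ddg
      score_sum <- score_sum + s
      count <- count + one_iteration_select(s, candidates$segment_class)
    }
    list(count = count, score_sum = score_sum)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- dplyr::mutate(candidates,
    mean_score = res$score_sum / iterations,
    selection_count = res$count,
    selection_frequency = res$count / iterations,
    burden = .data$selection_frequency >= 1 - alpha
  )
  class(out) <- c("mirsnp_burden", setdiff(class(out), "mirsnp_calls"))
  attr(out, "iterations") <- iterations
  attr(out, "alpha") <- alpha
  out
}
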