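#' Keep variants whose energy change has the causal direction
#'
#' Loop variants are causal when they stabilize the loop (ddG < 0, the
#' loop shrinks); mature and extension variants when they destabilize
#' their duplex (ddG > 0).  Zero and missing changes are dropped.
#'
#' @param energy_changes tibble from [compute_energy_changes()].
#' @return the filtered tibble.
#' @export
direction_filter <- function(energy_changes) {
  dplyr::filter(
    energy_changes,
    !is.na(.data$ddg),
    (.data$segment_class == "loop" & .data$ddg < 0) |
      (.data$segment_class %in% c("mature", "extension") & .data$ddg > 0)
  )
}

#' Cumulative contribution of ranked energy changes
#'
#' For a vector already sorted by decreasing |ddG| (all of one sign),
#' returns the running share of the total change:
#' `fraction_n = sum(ddg[1:n]) / sum(ddg)`.  The last element is 1.
#'
#' @param sorted_ddg numeric vector, sorted by |ddG| descending, one sign.
#' @return numeric vector of fractions (empty for empty input).
#' @examples
#' cumulative_fraction(c(4, 3, 2, 1))
#' @export
cumulative_fraction <- function(sorted_ddg) {
  if (length(sorted_ddg) == 0) return(numeric(0))
  cumsum(sorted_ddg) / sum(sorted_ddg)
}

#' Knee of a cumulative-contribution curve
#'
#' The selection cutoff is the rank with maximum perpendicular distance
#' from the chord joining the first point `(1, fraction[1])` to the last
#' `(N, 1)` of the cumulative-fraction curve (max-distance-to-chord knee).
#' Ties take the first (smallest) rank, so a perfectly linear curve gives
#' 1.  Deterministic and parameter-free; invariant under scaling of the
#' underlying ddG values.
#'
#' @param fractions cumulative fractions from [cumulative_fraction()].
#' @return the knee rank (>= 1 for non-empty input; 0 for empty).
#' @examples
#' knee_point(cumulative_fraction(c(10, 10, 10, 1, 1, 1, 1, 1, 1)))
#' @export
knee_point <- function(fractions) {
  n <- length(fractions)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  x <- seq_len(n)
  # |cross product| of (point - chord start) with the chord direction;
  # the positive denominator is common to all ranks and drops out
  d <- abs((fractions[n] - fractions[1]) * (x - 1) - (n - 1) * (fractions - fractions[1]))
  # first rank within numerical noise of the maximum (a flat curve gives 1)
  which(d > max(d) - 1e-9)[1]
}

#' Call candidate causal variants with the inflection cutoff
#'
#' Within each segment class the direction-filtered variants are ranked
#' by |ddG| descending (ties broken by hairpin, position, alt) and the
#' top `n*` are flagged as candidates, where `n*` is the knee of the
#' cumulative-contribution curve ([knee_point()]).
#'
#' @param filtered tibble from [direction_filter()].
#' @return a `mirsnp_calls` tibble: the input plus `rank`,
#'   `cumulative_fraction`, `candidate`.
#' @export
select_inflection <- function(filtered) {
  out <- filtered |>
    dplyr::group_by(.data$segment_class) |>
    dplyr::arrange(
      dplyr::desc(abs(.data$ddg)), .data$hairpin_id, .data$position, .data$alt,
      .by_group = TRUE
    ) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      cumulative_fraction = cumulative_fraction(.data$ddg),
      candidate = .data$rank <= knee_point(.data$cumulative_fraction)
    ) |>
    dplyr::ungroup()
  class(out) <- c("mirsnp_calls", class(out))
  out
}

#' Compare energy changes of known vs artificial candidates
#'
#' Per segment class, a Welch two-sample t-test of ddG between
#' known-origin (with or without frequency) and artificial candidates,
#' with group means, ranges and sizes.  A class where either group has
#' fewer than two members is reported with `computable = FALSE` rather
#' than failing.
#'
#' @param calls tibble from [select_inflection()].
#' @param candidates_only compare candidates only (default) or all rows.
#' @return a tidy tibble, one row per segment class.
#' @export
compare_known_artificial <- function(calls, candidates_only = TRUE) {
  if (candidates_only && "candidate" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$candidate)
  }
  calls |>
    dplyr::mutate(group = ifelse(.data$origin == "artificial", "artificial", "known")) |>
    dplyr::group_by(.data$segment_class) |>
    dplyr::group_modify(function(d, key) {
      kn <- d$ddg[d$group == "known"]
      ar <- d$ddg[d$group == "artificial"]
      base <- tibble::tibble(
        n_known = length(kn), n_artificial = length(ar),
        mean_known = if (length(kn)) mean(kn) else NA_real_,
        mean_artificial = if (length(ar)) mean(ar) else NA_real_,
        min_known = if (length(kn)) min(kn) else NA_real_,
        max_known = if (length(kn)) max(kn) else NA_real_,
        min_artificial = if (length(ar)) min(ar) else NA_real_,
        max_artificial = if (length(ar)) max(ar) else NA_real_
      )
      if (length(kn) < 2 || length(ar) < 2 ||
        (stats::sd(kn) == 0 && stats::sd(ar) == 0 && mean(kn) == mean(ar))) {
        # degenerate: identical constant groups have statistic 0, p 1
        degenerate <- length(kn) >= 2 && length(ar) >= 2
        return(dplyr::mutate(base,
          statistic = if (degenerate) 0 else NA_real_,
          p_value = if (degenerate) 1 else NA_real_,
          computable = degenerate
        ))
      }
      tt <- stats::t.test(kn, ar, var.equal = FALSE)
      dplyr::mutate(base,
        statistic = unname(tt$statistic), p_value = tt$p.value,
        computable = TRUE
      )
    }) |>
    dplyr::ungroup()
}
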