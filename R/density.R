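#' SNP density of a region
#'
#' @param count number of SNPs.
#' @param length_nt total region length in nucleotides (> 0).
#' @return tibble with `n_snps`, `length_nt`, `per_kb`
#'   (`1000 * count / length`) and `percent` (`100 * count / length`;
#'   always exactly `per_kb / 10`).  Vectorized.
#' @examples
#' snp_density(35, 3009)
#' @export
snp_density <- function(count, length_nt) {
  if (any(length_nt <= 0)) stop("length_nt must be > 0", call. = FALSE)
  tibble::tibble(
    n_snps = count, length_nt = length_nt,
    per_kb = 1000 * count / length_nt,
    percent = 100 * count / length_nt
  )
}

#' Per-class summary of the three filtering tiers
#'
#' For each segment class, counts and ddG range/mean at the three stages
#' of the pipeline: every enumerated variant, the direction-filtered set,
#' and the knee-selected candidates.  Means are of signed ddG.
#'
#' @param energy_changes tibble from [compute_energy_changes()].
#' @param calls tibble from [select_inflection()] (its `candidate` flag
#'   defines the third tier); may be `NULL` to summarize two tiers.
#' @return tibble with columns `segment_class`, `tier` (`enumerated`,
#'   `filtered`, `candidate`), `n`, `ddg_min`, `ddg_max`, `ddg_mean`.
#' @export
summarize_tiers <- function(energy_changes, calls = NULL) {
  tier_summary <- function(d) {
    d |>
      dplyr::group_by(.data$segment_class) |>
      dplyr::summarise(
        n = sum(!is.na(.data$ddg)),
        ddg_min = if (any(!is.na(.data$ddg))) min(.data$ddg, na.rm = TRUE) else NA_real_,
        ddg_max = if (any(!is.na(.data$ddg))) max(.data$ddg, na.rm = TRUE) else NA_real_,
        ddg_mean = mean(.data$ddg, na.rm = TRUE),
        .groups = "drop"
      )
  }
  classes <- tibble::tibble(
    segment_class = sort(unique(energy_changes$segment_class))
  )
  tiers <- list(
    enumerated = energy_changes,
    filtered = direction_filter(energy_changes)
  )
  if (!is.null(calls)) {
    tiers$candidate <- dplyr::filter(calls, .data$candidate)
  }
  out <- dplyr::bind_rows(lapply(names(tiers), function(label) {
    dplyr::left_join(classes, tier_summary(tiers[[label]]), by = "segment_class") |>
      tidyr::replace_na(list(n = 0L)) |>
      dplyr::mutate(tier = label)
  }))
  out$tier <- factor(out$tier, levels = c("enumerated", "filtered", "candidate"))
  dplyr::arrange(out, .data$segment_class, .data$tier)[
    c("segment_class", "tier", "n", "ddg_min", "ddg_max", "ddg_mean")
  ]
}

#' Human-readable density / tier report
#'
#' Formats segment densities (2 decimals for percents and per-kb rates)
#' and tier summaries (1 decimal for ddG) the way screening reports print
#' them.
#'
#' @param segments segment tibble (for class lengths; overlap bases count
#'   once per class).
#' @param variants variant tibble (known variants are counted).
#' @param tiers tibble from [summarize_tiers()].
#' @return character vector of report lines.
#' @export
density_report <- function(segments, variants, tiers) {
  class_len <- segments |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      length_nt = sum(.data$end - .data$start + 1L), .groups = "drop"
    )
  known <- dplyr::filter(variants, .data$origin != "artificial")
  lines <- c("Known-SNP density per segment class")
  for (i in seq_len(nrow(class_len))) {
    cl <- class_len$class[i]
    n <- sum(vapply(seq_len(nrow(known)), function(k) {
      cl %in% segment_membership(segments, known$position[k], known$hairpin_id[k])
    }, logical(1)))
    d <- snp_density(n, class_len$length_nt[i])
    lines <- c(lines, sprintf(
      "  %-10s %4d SNPs / %5d nt = %.2f per kb (%.2f%%)",
      cl, n, d$length_nt, round(d$per_kb, 2), round(d$percent, 2)
    ))
  }
  lines <- c(lines, "", "Free-energy change tiers (ddG, kcal/mol)")
  for (i in seq_len(nrow(tiers))) {
    lines <- c(lines, sprintf(
      "  %-10s %-10s n=%5d  range [%s, %s]  mean %s",
      tiers$segment_class[i], as.character(tiers$tier[i]), tiers$n[i],
      fmt1(tiers$ddg_min[i]), fmt1(tiers$ddg_max[i]), fmt1(tiers$ddg_mean[i])
    ))
  }
  lines
}

fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", round(x, 1)))
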