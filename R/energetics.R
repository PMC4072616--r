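#' Segment free energies
#'
#' The three segment classes are scored on different thermodynamic
#' quantities, all in kcal/mol:
#'
#' * terminal loop — `dg_terminal_loop()`: MFE of the loop sequence folded
#'   alone.  A substitution that lets loop bases pair shrinks the loop and
#'   lowers this energy, so causal loop variants have negative ddG.
#' * extension duplex — `dg_extension_duplex()`: the two extension arms
#'   are joined by a linker (default `"GGCGGGG"`) into a single strand and
#'   folded; the linker is bookkeeping only and is never mutated.  Causal
#'   extension variants break stem pairs and have positive ddG.
#' * mature duplex — `dg_mature()`: for each target gene, the minimum
#'   hybridization energy over its UTR isoforms is taken, and the mean
#'   over genes is returned.  Causal mature variants weaken target binding
#'   and have positive ddG.
#'
#' @param loop_sequence,ext5p_seq,ext3p_seq,mature_seq RNA sequences.
#' @param linker linker joining the extension arms (default `"GGCGGGG"`).
#' @param targets tibble with columns `gene_id`, `utr` (one row per UTR
#'   isoform) for the mature arm being scored.
#' @inheritParams fold_backend
#' @return a numeric energy (vectorized over sequences for the first two).
#' @examples
#' dg_terminal_loop("AUUUUUCCAUCUUUGGAU", backend = "basic")
#' @export
dg_terminal_loop <- function(loop_sequence, backend = c("vienna", "basic")) {
  fold_mfe(loop_sequence, backend = backend)$dg
}

#' @rdname dg_terminal_loop
#' @export
dg_extension_duplex <- function(ext5p_seq, ext3p_seq,
                                backend = c("vienna", "basic"),
                                linker = "GGCGGGG") {
  check_rna(ext5p_seq, "ext5p")
  check_rna(ext3p_seq, "ext3p")
  fold_mfe(paste0(ext5p_seq, linker, ext3p_seq), backend = backend)$dg
}

#' @rdname dg_terminal_loop
#' @export
dg_mature <- function(mature_seq, targets, backend = c("vienna", "basic")) {
  if (is.null(targets) || nrow(targets) == 0) {
    stop("mature variants cannot be scored without targets (empty target set)",
      call. = FALSE
    )
  }
  e <- hybridize_mfe(mature_seq, targets$utr, backend = backend)
  per_gene <- tapply(e, targets$gene_id, min)
  mean(per_gene)
}

#' Free-energy change of every variant in every containing segment
#'
#' For each variant and each segment class containing its position, the
#' wild-type and mutant segment energies are computed with the appropriate
#' scorer (see [dg_terminal_loop()]) and the difference
#' `ddg = dg_mut - dg_wt` is reported.  A variant in the overlap of two
#' segments yields one row per class.  Wild-type energies are computed
#' once per segment; all backend calls are batched.
#'
#' Mature-arm variants need a target map; when the arm has no entry the
#' row is kept with `NA` energies and a warning, never silently dropped.
#'
#' @param hairpins,segments,variants tibbles in the package's standard
#'   shapes.
#' @param target_map tibble `mature_id`, `gene_id`, `utr`, where
#'   `mature_id` is `"<hairpin_id>-5p"` / `"<hairpin_id>-3p"`; may be
#'   `NULL`.
#' @inheritParams dg_terminal_loop
#' @return tibble with one row per (variant, segment class): the variant
#'   key columns plus `segment_class`, `dg_wt`, `dg_mut`, `ddg`.
#' @export
compute_energy_changes <- function(hairpins, segments, variants,
                                   target_map = NULL,
                                   backend = c("vienna", "basic"),
                                   linker = "GGCGGGG") {
  backend <- match.arg(backend)
  seg <- dplyr::mutate(segments,
    seg_seq = stringr::str_sub(
      hairpins$sequence[match(.data$hairpin_id, hairpins$id)],
      .data$start, .data$end
    )
  )
  rows <- dplyr::inner_join(variants, seg,
    by = "hairpin_id", relationship = "many-to-many"
  )
  rows <- dplyr::filter(rows, .data$position >= .data$start, .data$position <= .data$end)
  rows <- dplyr::distinct(rows,
    .data$snp_id, .data$hairpin_id, .data$position, .data$alt, .data$class,
    .keep_all = TRUE
  )
  empty <- tibble::tibble(
    snp_id = character(), hairpin_id = character(), position = integer(),
    ref = character(), alt = character(), origin = character(), maf = numeric(),
    segment_class = character(), dg_wt = numeric(), dg_mut = numeric(),
    ddg = numeric()
  )
  if (nrow(rows) == 0) return(empty)
  rows <- dplyr::mutate(rows,
    rel = .data$position - .data$start + 1L,
    wt_seq = .data$seg_seq,
    mut_seq = apply_variant(.data$seg_seq, .data$rel, .data$ref, .data$alt)
  )

  out <- list()

  loop_rows <- dplyr::filter(rows, .data$class == "loop")
  ext_rows <- dplyr::filter(rows, .data$class == "extension")
  mat_rows <- dplyr::filter(rows, .data$class == "mature")

  # ---- loop and extension: single-strand folds, batched over unique seqs
  if (nrow(ext_rows) > 0) {
    arms <- tidyr::pivot_wider(
      dplyr::distinct(seg[seg$segment %in% c("ext5p", "ext3p"), ],
        .data$hairpin_id, .data$segment, .data$seg_seq
      ),
      names_from = "segment", values_from = "seg_seq"
    )
    ext_rows <- dplyr::left_join(ext_rows, arms, by = "hairpin_id")
    ext_rows <- dplyr::mutate(ext_rows,
      wt_link = paste0(.data$ext5p, linker, .data$ext3p),
      mut_link = ifelse(.data$segment == "ext5p",
        paste0(.data$mut_seq, linker, .data$ext3p),
        paste0(.data$ext5p, linker, .data$mut_seq)
      )
    )
  }
  fold_jobs <- unique(c(
    loop_rows$wt_seq, loop_rows$mut_seq,
    if (nrow(ext_rows) > 0) c(ext_rows$wt_link, ext_rows$mut_link)
  ))
  if (length(fold_jobs) > 0) {
    folded <- fold_mfe(fold_jobs, backend = backend)
    dg_of <- setNames(folded$dg, folded$sequence)
    if (nrow(loop_rows) > 0) {
      out$loop <- dplyr::mutate(loop_rows,
        segment_class = "loop",
        dg_wt = unname(dg_of[.data$wt_seq]),
        dg_mut = unname(dg_of[.data$mut_seq])
      )
    }
    if (nrow(ext_rows) > 0) {
      out$extension <- dplyr::mutate(ext_rows,
        segment_class = "extension",
        dg_wt = unname(dg_of[.data$wt_link]),
        dg_mut = unname(dg_of[.data$mut_link])
      )
    }
  }

  # ---- mature: hybridization against the arm's targets
  if (nrow(mat_rows) > 0) {
    mat_rows <- dplyr::mutate(mat_rows,
      mature_id = paste0(.data$hairpin_id, "-", sub("mature", "", .data$segment))
    )
    arm_seqs <- dplyr::distinct(dplyr::bind_rows(
      dplyr::transmute(mat_rows, mature_id = .data$mature_id, seq = .data$wt_seq),
      dplyr::transmute(mat_rows, mature_id = .data$mature_id, seq = .data$mut_seq)
    ))
    have_targets <- !is.null(target_map) && nrow(target_map) > 0
    scored <- if (have_targets) {
      jobs <- dplyr::inner_join(arm_seqs, target_map,
        by = "mature_id", relationship = "many-to-many"
      )
      if (nrow(jobs) > 0) {
        jobs$e <- hybridize_mfe(jobs$seq, jobs$utr, backend = backend)
        jobs |>
          dplyr::group_by(.data$mature_id, .data$seq, .data$gene_id) |>
          dplyr::summarise(e = min(.data$e), .groups = "drop_last") |>
          dplyr::summarise(dg = mean(.data$e), .groups = "drop")
      } else {
        tibble::tibble(mature_id = character(), seq = character(), dg = numeric())
      }
    } else {
      tibble::tibble(mature_id = character(), seq = character(), dg = numeric())
    }
    mat_rows <- dplyr::left_join(mat_rows,
      dplyr::rename(scored, dg_wt = "dg"),
      by = c(mature_id = "mature_id", wt_seq = "seq")
    )
    mat_rows <- dplyr::left_join(mat_rows,
      dplyr::rename(scored, dg_mut = "dg"),
      by = c(mature_id = "mature_id", mut_seq = "seq")
    )
    missing_arms <- unique(mat_rows$mature_id[is.na(mat_rows$dg_wt)])
    if (length(missing_arms) > 0) {
      warning("no target entry for mature arm(s): ",
        paste(missing_arms, collapse = ", "),
        "; their rows carry NA energies",
        call. = FALSE
      )
    }
    out$mature <- dplyr::mutate(mat_rows, segment_class = "mature")
  }

  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res <- dplyr::mutate(res, ddg = .data$dg_mut - .data$dg_wt)
  cols <- c(
    "snp_id", "hairpin_id", "position", "ref", "alt", "origin", "maf",
    "segment_class", "dg_wt", "dg_mut", "ddg"
  )
  dplyr::arrange(
    res[cols],
    .data$hairpin_id, .data$position, .data$alt, .data$segment_class
  )
}
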