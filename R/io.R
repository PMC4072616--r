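#' Read pre-miRNA hairpins with mature-arm annotations
#'
#' Reads a hairpin FASTA (DNA or RNA letters; everything is normalized to
#' upper-case RNA) and an optional miRBase-style annotation TSV with
#' columns `hairpin_id`, `arm` (`5p`/`3p`), `start`, `end` giving the
#' 1-based closed interval of each annotated mature arm on the hairpin's
#' own 5'->3' sequence.  Either or both arms may be absent.
#'
#' @param fasta_path path to the hairpin FASTA.
#' @param annotation_path path to the annotation TSV, or `NULL` for no
#'   annotations.
#' @return a tibble with one row per hairpin: `id`, `sequence`,
#'   `mature5p_start`, `mature5p_end`, `mature3p_start`, `mature3p_end`
#'   (`NA` where unannotated), `strand` (metadata only, defaults `"+"`).
#'   Record order follows the FASTA.
#' @export
read_hairpins <- function(fasta_path, annotation_path = NULL) {
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  seqs <- normalize_rna(seqs, what = "hairpin")
  hp <- tibble::tibble(
    id = ids, sequence = unname(seqs),
    mature5p_start = NA_integer_, mature5p_end = NA_integer_,
    mature3p_start = NA_integer_, mature3p_end = NA_integer_,
    strand = "+"
  )
  if (anyDuplicated(ids)) {
    stop("duplicated hairpin id in FASTA: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path,
      col_types = readr::cols(
        hairpin_id = readr::col_character(), arm = readr::col_character(),
        start = readr::col_integer(), end = readr::col_integer()
      )
    )
    bad <- setdiff(ann$hairpin_id, hp$id)
    if (length(bad) > 0) {
      stop("annotation references unknown hairpin id: ", bad[1], call. = FALSE)
    }
    if (!all(ann$arm %in% c("5p", "3p"))) {
      stop("annotation arm must be '5p' or '3p'", call. = FALSE)
    }
    for (i in seq_len(nrow(ann))) {
      j <- match(ann$hairpin_id[i], hp$id)
      if (ann$start[i] < 1 || ann$end[i] > nchar(hp$sequence[j]) ||
        ann$start[i] > ann$end[i]) {
        stop(sprintf(
          "annotation interval [%d,%d] outside hairpin '%s' (length %d)",
          ann$start[i], ann$end[i], ann$hairpin_id[i], nchar(hp$sequence[j])
        ), call. = FALSE)
      }
      if (ann$arm[i] == "5p") {
        hp$mature5p_start[j] <- ann$start[i]
        hp$mature5p_end[j] <- ann$end[i]
      } else {
        hp$mature3p_start[j] <- ann$start[i]
        hp$mature3p_end[j] <- ann$end[i]
      }
    }
    both <- !is.na(hp$mature5p_start) & !is.na(hp$mature3p_start)
    if (any(both & hp$mature5p_start >= hp$mature3p_start)) {
      stop("mature5p must start before mature3p (hairpin '",
        hp$id[which(both & hp$mature5p_start >= hp$mature3p_start)[1]], "')",
        call. = FALSE
      )
    }
  }
  hp
}

#' Read a known-SNP table
#'
#' TSV with columns `id`, `hairpin`, `position`, `ref`, `alt`, `maf`
#' (`maf` may be empty).  Alleles are on the hairpin sense, 1-based
#' positions on the hairpin's own sequence.  The reference allele is
#' validated against the hairpin sequence and the origin class is derived
#' from the presence of a minor allele frequency: `known_freq` when `maf`
#' is given, `known_nofreq` otherwise.
#'
#' @param path path to the SNP TSV.
#' @param hairpins hairpin tibble from [read_hairpins()].
#' @return variant tibble: `snp_id`, `hairpin_id`, `position`, `ref`,
#'   `alt`, `origin`, `maf`.
#' @export
read_snp_table <- function(path, hairpins) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), hairpin = readr::col_character(),
    position = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), maf = readr::col_double()
  ))
  tb$ref <- normalize_rna(tb$ref, "ref allele")
  tb$alt <- normalize_rna(tb$alt, "alt allele")
  out <- tibble::tibble(
    snp_id = tb$id, hairpin_id = tb$hairpin, position = tb$position,
    ref = tb$ref, alt = tb$alt,
    origin = ifelse(is.na(tb$maf), "known_nofreq", "known_freq"),
    maf = tb$maf
  )
  validate_variants(out, hairpins)
}

validate_variants <- function(variants, hairpins) {
  j <- match(variants$hairpin_id, hairpins$id)
  if (anyNA(j)) {
    stop("SNP table references unknown hairpin: ",
      variants$hairpin_id[which(is.na(j))[1]],
      call. = FALSE
    )
  }
  at <- stringr::str_sub(hairpins$sequence[j], variants$position, variants$position)
  bad <- at != variants$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "SNP '%s': ref allele %s does not match hairpin '%s' position %d (%s)",
      variants$snp_id[i], variants$ref[i], variants$hairpin_id[i],
      variants$position[i], at[i]
    ), call. = FALSE)
  }
  if (any(variants$alt == variants$ref)) {
    stop("SNP with alt equal to ref: ",
      variants$snp_id[which(variants$alt == variants$ref)[1]],
      call. = FALSE
    )
  }
  bad_maf <- !is.na(variants$maf) & (variants$maf <= 0 | variants$maf >= 1)
  if (any(bad_maf)) {
    stop("maf outside (0,1) for SNP ", variants$snp_id[which(bad_maf)[1]],
      call. = FALSE
    )
  }
  variants
}

#' Read a mature-arm -> target 3'UTR map
#'
#' TSV with columns `mature_id` (e.g. `"hp1-5p"`), `gene_id`, `utr`
#' (the 3'UTR sequence; one row per UTR isoform).
#'
#' @param path path to the target TSV.
#' @return tibble `mature_id`, `gene_id`, `utr` with normalized RNA UTRs.
#' @export
read_target_map <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    mature_id = readr::col_character(), gene_id = readr::col_character(),
    utr = readr::col_character()
  ))
  tb$utr <- normalize_rna(tb$utr, "UTR")
  tibble::as_tibble(tb)
}

#' Write hairpins / variants / targets back to disk
#'
#' Writers matching the readers above, used by the fixture generator and
#' the pipeline.  `write_hairpin_fasta()` wraps sequences at 60 columns.
#'
#' @param hairpins,variants,target_map tibbles in the package's standard
#'   shapes.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_hairpin_fasta <- function(hairpins, path) {
  lines <- unlist(purrr::map2(hairpins$id, hairpins$sequence, function(id, s) {
    c(paste0(">", id), substring(s, seq(1, nchar(s), 60), pmin(nchar(s), seq(60, nchar(s) + 59, 60))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hairpin_fasta
#' @export
write_annotation_tsv <- function(hairpins, path) {
  ann <- dplyr::bind_rows(
    dplyr::transmute(
      dplyr::filter(hairpins, !is.na(.data$mature5p_start)),
      hairpin_id = .data$id, arm = "5p",
      start = .data$mature5p_start, end = .data$mature5p_end
    ),
    dplyr::transmute(
      dplyr::filter(hairpins, !is.na(.data$mature3p_start)),
      hairpin_id = .data$id, arm = "3p",
      start = .data$mature3p_start, end = .data$mature3p_end
    )
  )
  ann <- dplyr::arrange(ann, .data$hairpin_id, .data$arm)
  readr::write_tsv(ann, path)
  invisible(path)
}

#' @rdname write_hairpin_fasta
#' @export
write_snp_tsv <- function(variants, path) {
  known <- dplyr::filter(variants, .data$origin != "artificial")
  readr::write_tsv(
    dplyr::transmute(known,
      id = .data$snp_id, hairpin = .data$hairpin_id,
      position = .data$position, ref = .data$ref, alt = .data$alt,
      maf = .data$maf
    ),
    path
  )
  invisible(path)
}

#' @rdname write_hairpin_fasta
#' @export
write_target_tsv <- function(target_map, path) {
  readr::write_tsv(target_map[c("mature_id", "gene_id", "utr")], path)
  invisible(path)
}

#' Write the per-variant result table
#'
#' One TSV row per (variant, segment class) combining the energy table
#' with candidate and burden calls.  Row order is deterministic
#' (`hairpin_id`, `position`, `alt`, `segment_class`); re-running on
#' identical inputs yields a byte-identical file.
#'
#' @param energy_changes tibble from [compute_energy_changes()].
#' @param calls tibble from [select_inflection()], optionally carrying
#'   burden columns from [monte_carlo_burden()]; may be `NULL`.
#' @param path output TSV path.
#' @return the combined tibble, invisibly.
#' @export
write_results <- function(energy_changes, calls, path) {
  out <- energy_changes
  keys <- c("snp_id", "hairpin_id", "position", "ref", "alt", "segment_class")
  if (!is.null(calls) && nrow(calls) > 0) {
    extra <- intersect(
      c("rank", "cumulative_fraction", "candidate", "selection_frequency", "burden"),
      names(calls)
    )
    out <- dplyr::left_join(out, calls[c(keys, extra)], by = keys)
  }
  for (col in c("candidate", "burden")) {
    if (!col %in% names(out)) out[[col]] <- NA
    out[[col]] <- !is.na(out[[col]]) & out[[col]]
  }
  if (!"selection_frequency" %in% names(out)) out$selection_frequency <- NA_real_
  out <- dplyr::arrange(
    out, .data$hairpin_id, .data$position, .data$alt, .data$segment_class
  )
  cols <- c(
    "snp_id", "hairpin_id", "position", "ref", "alt", "origin", "maf",
    "segment_class", "dg_wt", "dg_mut", "ddg", "candidate", "burden",
    "selection_frequency"
  )
  readr::write_tsv(out[intersect(cols, names(out))], path)
  invisible(out)
}
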