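#' Generate a synthetic pre-miRNA hairpin with known ground truth
#'
#' Builds `5'ext + arm + loop + revcomp(arm) + 3'ext` with perfectly
#' complementary mature arms at the requested GC fraction, an unpairable
#' A/C-only terminal loop, extension arms that are reverse complements of
#' each other (a fully stemmed precursor), and the canonical 2-nt 3'
#' overhang geometry: the annotated 3p arm is the complement block shifted
#' 2 nt downstream.  Deterministic under `seed`.
#'
#' @param stem_len mature-arm length (>= 15).
#' @param loop_len terminal-loop length (>= 4).
#' @param gc_fraction GC content of the stems, in `[0, 1]`.
#' @param ext_size extension-arm length.
#' @param seed integer seed (applied locally).
#' @param id hairpin id.
#' @param loop_seq,arm_seq,ext5p_seq optional sequence overrides for
#'   constructing controlled test cases.
#' @param wobble_rate probability per stem position of replacing the
#'   Watson-Crick partner with its G.U wobble partner (default 0).
#' @return list with `hairpin` (one-row tibble) and `segments` (the
#'   ground-truth segment tibble, matching [segment_hairpins()]).
#' @export
make_hairpin <- function(stem_len = 22, loop_len = 16, gc_fraction = 0.5,
                         ext_size = 25, seed = NULL, id = NULL,
                         loop_seq = NULL, arm_seq = NULL, ext5p_seq = NULL,
                         wobble_rate = 0) {
  build <- function() {
    arm <- arm_seq %||% rand_rna(stem_len, gc_fraction)
    loop <- loop_seq %||% paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
    e5 <- ext5p_seq %||% rand_rna(ext_size, gc_fraction)
    stem_len <- nchar(arm)
    loop_len <- nchar(loop)
    ext_size <- nchar(e5)
    if (stem_len < 15) stop("stem_len must be >= 15", call. = FALSE)
    if (loop_len < 4) stop("loop_len must be >= 4", call. = FALSE)
    if (ext_size < 3) stop("ext_size must be >= 3", call. = FALSE)
    rc_arm <- wobbleize(revcomp_rna(arm), wobble_rate)
    e3 <- revcomp_rna(e5)
    seqn <- paste0(e5, arm, loop, rc_arm, e3)
    m5s <- ext_size + 1L
    m5e <- ext_size + stem_len
    r1 <- m5e + loop_len + 1L # start of the complement block
    r2 <- r1 + stem_len - 1L
    m3s <- r1 + 2L # 2-nt 3' overhang
    m3e <- r2 + 2L
    hp <- tibble::tibble(
      id = id %||% sprintf("hp_s%s", seed %||% "0"),
      sequence = seqn,
      mature5p_start = m5s, mature5p_end = m5e,
      mature3p_start = m3s, mature3p_end = m3e,
      strand = "+"
    )
    segs <- tibble::tibble(
      hairpin_id = hp$id,
      segment = c("ext5p", "mature5p", "loop", "mature3p", "ext3p"),
      class = c("extension", "mature", "loop", "mature", "extension"),
      start = as.integer(c(1L, m5s, m5e + 1L, m3s, m3e + 1L)),
      end = as.integer(c(
        m5s - 1L, m5e, m3s - 1L, m3e, min(nchar(seqn), m3e + ext_size)
      )),
      star_inferred = FALSE
    )
    list(hairpin = hp, segments = segs)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

rand_rna <- function(n, gc_fraction = 0.5) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

wobbleize <- function(rc_arm, rate) {
  if (rate <= 0) return(rc_arm)
  ch <- seq_chars(rc_arm)
  # C -> U keeps a G.U wobble with the G opposite; A -> G keeps U.G
  flip <- runif(length(ch)) < rate
  ch[flip & ch == "C"] <- "U"
  ch[flip & ch == "A"] <- "G"
  paste(ch, collapse = "")
}

#' Generate a known-SNP catalog on synthetic hairpins
#'
#' Places known variants at random covered positions, with minor allele
#' frequencies drawn in `freq_range` for the `known_freq` category.
#'
#' @param hairpins,segments tibbles from [make_hairpin()] (bound by rows).
#' @param n_known_freq,n_known_nofreq category sizes.
#' @param freq_range maf sampling interval.
#' @param seed integer seed (applied locally).
#' @return a validated variant tibble.
#' @export
make_snp_catalog <- function(hairpins, segments, n_known_freq = 5,
                             n_known_nofreq = 5, freq_range = c(0.01, 0.3),
                             seed = NULL) {
  build <- function() {
    covered <- dplyr::bind_rows(lapply(seq_len(nrow(segments)), function(i) {
      tibble::tibble(
        hairpin_id = segments$hairpin_id[i],
        position = seq.int(segments$start[i], segments$end[i])
      )
    }))
    covered <- dplyr::distinct(covered)
    n <- n_known_freq + n_known_nofreq
    if (n > nrow(covered)) stop("more SNPs requested than covered positions", call. = FALSE)
    pick <- covered[sample.int(nrow(covered), n), ]
    ref <- stringr::str_sub(
      hairpins$sequence[match(pick$hairpin_id, hairpins$id)],
      pick$position, pick$position
    )
    alt <- vapply(ref, function(r) sample(setdiff(RNA_BASES, r), 1), character(1))
    out <- tibble::tibble(
      snp_id = sprintf("snp%03d", seq_len(n)),
      hairpin_id = pick$hairpin_id, position = pick$position,
      ref = ref, alt = unname(alt),
      origin = rep(c("known_freq", "known_nofreq"), c(n_known_freq, n_known_nofreq)),
      maf = c(
        round(runif(n_known_freq, freq_range[1], freq_range[2]), 4),
        rep(NA_real_, n_known_nofreq)
      )
    )
    validate_variants(out, hairpins)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate target 3'UTRs embedding a binding site for a mature arm
#'
#' Each gene gets 1-3 UTR isoforms of 200-600 nt of uniform random
#' sequence; when `match_quality > 0` every isoform embeds the reverse
#' complement of the mature sequence degraded by
#' `round((1 - match_quality) * length)` random mismatches.
#'
#' @param mature_seq the mature arm sequence.
#' @param n_genes number of target genes.
#' @param match_quality 1 = perfect planted site, 0 = no planted site.
#' @param seed integer seed (applied locally).
#' @param mature_id id recorded in the map (e.g. `"hp1-5p"`).
#' @param utr_len_range isoform length range in nt.
#' @return tibble `mature_id`, `gene_id`, `utr`.
#' @export
make_target_utrs <- function(mature_seq, n_genes = 3, match_quality = 1,
                             seed = NULL, mature_id = "mature",
                             utr_len_range = c(200, 600)) {
  build <- function() {
    site0 <- revcomp_rna(mature_seq)
    rows <- lapply(seq_len(n_genes), function(g) {
      n_iso <- sample.int(3, 1)
      utrs <- vapply(seq_len(n_iso), function(i) {
        len <- sample.int(utr_len_range[2] - utr_len_range[1] + 1L, 1) +
          utr_len_range[1] - 1L
        u <- rand_rna(len, 0.5)
        if (match_quality > 0) {
          site <- degrade_site(site0, round((1 - match_quality) * nchar(site0)))
          at <- sample.int(len - nchar(site) + 1L, 1)
          stringr::str_sub(u, at, at + nchar(site) - 1L) <- site
        }
        u
      }, character(1))
      tibble::tibble(
        mature_id = mature_id, gene_id = sprintf("gene%02d", g), utr = utrs
      )
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

degrade_site <- function(site, n_mm) {
  if (n_mm <= 0) return(site)
  ch <- seq_chars(site)
  at <- sample.int(length(ch), min(n_mm, length(ch)))
  ch[at] <- vapply(ch[at], function(b) sample(setdiff(RNA_BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

#' Full pipeline input bundle with planted causal variants
#'
#' Three synthetic hairpins carrying designed variants with known effect
#' direction: a loop-shrinker (a substitution completing a 4-bp stem
#' inside an otherwise unpairable loop; expected ddG < 0 in the loop
#' class), an extension pair-breaker (a stem G or C flipped to its own
#' complement; expected ddG > 0), a mature seed-breaker (a seed-region
#' substitution against perfect-match target UTRs; expected ddG > 0), and
#' neutral variants in unpaired A-runs (expected |ddG| ~ 0).  Planted
#' causal variants are recorded as known SNPs with frequencies; neutral
#' ones as known SNPs without.
#'
#' @param seed integer seed (applied locally).
#' @param ext_size extension-arm length.
#' @return list with `hairpins`, `segments`, `snps`, `target_map`, and
#'   `truth` (tibble `snp_id`, `role`, `expected_sign`, `segment_class`).
#' @export
make_planted_scenario <- function(seed = 1, ext_size = 25) {
  withr::with_seed(seed, {
    hp1 <- make_hairpin(
      stem_len = 20, loop_len = 16, gc_fraction = 0.5, ext_size = ext_size,
      id = "hp1", loop_seq = "GGCCAAAAAAAAGUCC"
    )
    hp2 <- make_hairpin(
      stem_len = 22, loop_len = 12, gc_fraction = 0.6, ext_size = ext_size,
      id = "hp2"
    )
    hp3 <- make_hairpin(
      stem_len = 22, loop_len = 14, gc_fraction = 0.5, ext_size = ext_size,
      id = "hp3"
    )
    hairpins <- dplyr::bind_rows(hp1$hairpin, hp2$hairpin, hp3$hairpin)
    segments <- dplyr::bind_rows(hp1$segments, hp2$segments, hp3$segments)

    base_at <- function(hp, pos) stringr::str_sub(hp$sequence, pos, pos)

    # loop-shrinker: loop block position 3 (C) -> A completes GGAC/GUCC
    p1 <- hp1$segments$start[hp1$segments$segment == "loop"] + 2L
    v1 <- tibble::tibble(
      snp_id = "planted_loop", hairpin_id = "hp1", position = p1,
      ref = base_at(hp1$hairpin, p1), alt = "A",
      origin = "known_freq", maf = round(runif(1, 0.1, 0.3), 4)
    )

    # extension pair-breaker: first stem G/C in ext5p flipped to its complement
    e5 <- seq_chars(stringr::str_sub(hp2$hairpin$sequence, 1, ext_size))
    cand <- which(e5 %in% c("G", "C"))
    cand <- cand[cand <= ext_size - 2L] # partner must lie inside the ext3p segment
    p2 <- cand[1]
    v2 <- tibble::tibble(
      snp_id = "planted_ext", hairpin_id = "hp2", position = p2,
      ref = e5[p2], alt = chartr("GC", "CG", e5[p2]),
      origin = "known_freq", maf = round(runif(1, 0.1, 0.3), 4)
    )

    # mature seed-breaker on hp3's 5p arm
    m5s <- hp3$hairpin$mature5p_start
    p3 <- m5s + 3L
    ref3 <- base_at(hp3$hairpin, p3)
    v3 <- tibble::tibble(
      snp_id = "planted_mature", hairpin_id = "hp3", position = p3,
      ref = ref3, alt = sample(setdiff(RNA_BASES, ref3), 1),
      origin = "known_freq", maf = round(runif(1, 0.1, 0.3), 4)
    )

    # neutral variants inside unpaired A-runs of the loops
    p4 <- hp1$segments$start[hp1$segments$segment == "loop"] + 7L
    p5 <- hp2$segments$start[hp2$segments$segment == "loop"] + 5L
    neutral <- tibble::tibble(
      snp_id = c("neutral_1", "neutral_2"),
      hairpin_id = c("hp1", "hp2"), position = c(p4, p5),
      ref = c(base_at(hp1$hairpin, p4), base_at(hp2$hairpin, p5)),
      alt = NA_character_, origin = "known_nofreq", maf = NA_real_
    )
    neutral$alt <- ifelse(neutral$ref == "A", "C", "A")

    snps <- validate_variants(dplyr::bind_rows(v1, v2, v3, neutral), hairpins)
    arm3 <- stringr::str_sub(
      hp3$hairpin$sequence, hp3$hairpin$mature5p_start, hp3$hairpin$mature5p_end
    )
    target_map <- make_target_utrs(
      arm3, n_genes = 3, match_quality = 1, mature_id = "hp3-5p"
    )
    truth <- tibble::tibble(
      snp_id = c("planted_loop", "planted_ext", "planted_mature", "neutral_1", "neutral_2"),
      role = c("loop_shrinker", "ext_breaker", "seed_breaker", "neutral", "neutral"),
      expected_sign = c(-1, 1, 1, 0, 0),
      segment_class = c("loop", "extension", "mature", "loop", "loop")
    )
    list(
      hairpins = hairpins, segments = segments, snps = snps,
      target_map = target_map, truth = truth
    )
  })
}

#' Synthetic candidate set for burden-recovery benchmarking
#'
#' Builds a candidate table (no folding involved) with `n_planted`
#' designed high-frequency / high-|ddG| variants among `n_noise` low-score
#' noise variants, for testing that [monte_carlo_burden()] recovers the
#' planted set.  Planted variants draw maf in `[0.15, 0.3]` and ddG in
#' `[6, 10]`; noise variants have ddG below 2 and known frequencies below
#' 0.05, so a planted score always exceeds any achievable noise score.
#'
#' @param n_noise,n_planted set sizes.
#' @param seed integer seed (applied locally).
#' @return list with `candidates` (ready for [monte_carlo_burden()]) and
#'   `truth` (the planted `snp_id`s).
#' @export
make_burden_benchmark <- function(n_noise = 195, n_planted = 5, seed = NULL) {
  build <- function() {
    n_kf <- round(n_noise * 0.23)
    n_nf <- round(n_noise * 0.385)
    n_ar <- n_noise - n_kf - n_nf
    planted <- tibble::tibble(
      snp_id = sprintf("planted%02d", seq_len(n_planted)),
      origin = "known_freq",
      maf = runif(n_planted, 0.15, 0.3),
      ddg = runif(n_planted, 6, 10)
    )
    noise <- tibble::tibble(
      snp_id = sprintf("noise%03d", seq_len(n_noise)),
      origin = rep(c("known_freq", "known_nofreq", "artificial"), c(n_kf, n_nf, n_ar)),
      maf = c(runif(n_kf, 0.01, 0.05), rep(NA_real_, n_nf + n_ar)),
      ddg = runif(n_noise, 0.2, 2)
    )
    cand <- dplyr::bind_rows(planted, noise)
    cand <- dplyr::mutate(cand,
      hairpin_id = "bench", position = dplyr::row_number(),
      ref = "A", alt = "G", segment_class = "extension", candidate = TRUE
    )
    list(candidates = cand, truth = planted$snp_id)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write a complete fixture bundle to disk
#'
#' @param scenario list from [make_planted_scenario()] (or any list with
#'   `hairpins`, `snps`, `target_map`).
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    hairpins = file.path(dir, "hairpins.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    snps = file.path(dir, "snps.tsv"),
    targets = file.path(dir, "targets.tsv")
  )
  write_hairpin_fasta(scenario$hairpins, paths$hairpins)
  write_annotation_tsv(scenario$hairpins, paths$annotation)
  write_snp_tsv(scenario$snps, paths$snps)
  write_target_tsv(scenario$target_map, paths$targets)
  invisible(paths)
}
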