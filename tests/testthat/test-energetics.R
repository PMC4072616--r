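test_that("unpairable chains fold open with zero energy on both backends", {
  for (be in c("basic", "vienna")) {
    fr <- fold_mfe("AAAAAAAA", backend = be)
    expect_equal(fr$structure, "........")
    expect_equal(fr$dg, 0)
  }
})

test_that("a GC stem folds into a stable hairpin on both backends", {
  for (be in c("basic", "vienna")) {
    fr <- fold_mfe("GGGGGAAAACCCCC", backend = be)
    expect_lt(fr$dg, 0)
    expect_true(grepl("^\\(+\\.+\\)+$", fr$structure))
    expect_equal(nchar(fr$structure), 14)
  }
})

test_that("folding rejects non-RNA input and is deterministic", {
  expect_error(fold_mfe("ACGT", backend = "basic"), "non-RNA")
  expect_error(fold_mfe("ACGT", backend = "vienna"), "non-RNA")
  a <- fold_mfe("GGCGAAAAUCGCC", backend = "vienna")
  b <- fold_mfe("GGCGAAAAUCGCC", backend = "vienna")
  expect_identical(a, b)
})

test_that("loop_size reads the 3'-most hairpin loop from dot-brackets", {
  expect_equal(loop_size("((((....))))"), 4)
  expect_equal(loop_size(strrep(".", 18)), 18)
  expect_equal(loop_size("(((...)))((....))"), 4)
  expect_equal(loop_size(".....((((....)))).") , 4)
})

test_that("a planted self-complementary loop mutation lowers loop energy", {
  wt <- "GGCCAAAAAAAAGUCC"
  mut <- apply_variant(wt, 3, "C", "A") # completes the GGAC/GUCC stem
  for (be in c("basic", "vienna")) {
    expect_lt(
      dg_terminal_loop(mut, backend = be),
      dg_terminal_loop(wt, backend = be)
    )
  }
})

test_that("complementary extension arms give strongly negative linked energy", {
  e5 <- "GCAUGCAUGCAUGCAUGCAU"
  e3 <- revcomp_rna(e5)
  for (be in c("basic", "vienna")) {
    expect_lt(dg_extension_duplex(e5, e3, backend = be), -10)
  }
})

test_that("breaking a G-C pair costs more than breaking an A-U pair", {
  # matched stems differing only in the interrogated pair's identity
  e5_gc <- "AUAUAUGCGCAUAUGCGCAU"
  e3_gc <- revcomp_rna(e5_gc)
  dd <- function(e5, e3, pos, be) {
    ref <- substr(e5, pos, pos)
    alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
    dg_extension_duplex(apply_variant(e5, pos, ref, alt), e3, backend = be) -
      dg_extension_duplex(e5, e3, backend = be)
  }
  for (be in c("basic", "vienna")) {
    ddg_gc <- dd(e5_gc, e3_gc, 7, be) # G at 7
    ddg_au <- dd(e5_gc, e3_gc, 1, be) # A at 1
    expect_gt(abs(ddg_gc), abs(ddg_au))
  }
})

test_that("hybridization finds a planted perfect site and floors at zero", {
  mature <- "UAGCUUAUCAGACUGAUGUUGA"
  site <- revcomp_rna(mature)
  utr <- paste0(strrep("A", 40), site, strrep("A", 40))
  for (be in c("basic", "vienna")) {
    e_site <- hybridize_mfe(mature, site, backend = be)
    e_utr <- hybridize_mfe(mature, utr, backend = be)
    expect_lt(e_site, -15)
    expect_equal(e_utr, e_site, tolerance = 0.15)
    expect_equal(
      hybridize_mfe(strrep("A", 20), strrep("A", 30), backend = be), 0
    )
  }
  expect_error(hybridize_mfe(mature, "ACGU"), "shorter")
})

test_that("more UTR sequence can only improve the hybridization minimum", {
  set.seed(7)
  mature <- "UAGCUUAUCAGACUGAUGUUGA"
  for (i in 1:5) {
    inner <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE), collapse = "")
    outer <- paste0(
      paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE), collapse = ""),
      inner,
      paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE), collapse = "")
    )
    expect_lte(
      hybridize_mfe(mature, outer, backend = "basic"),
      hybridize_mfe(mature, inner, backend = "basic")
    )
  }
})

test_that("dg_mature is the mean over genes of per-gene UTR minima", {
  mature <- "UAGCUUAUCAGACUGAUGUUGA"
  set.seed(3)
  targets <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    utr = vapply(1:4, function(i) {
      paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
    }, character(1))
  )
  e <- hybridize_mfe(mature, targets$utr, backend = "basic")
  expected <- mean(c(min(e[1:2]), e[3], e[4]))
  expect_equal(dg_mature(mature, targets, backend = "basic"), expected)
  expect_error(dg_mature(mature, targets[0, ], backend = "basic"), "without targets")
})

test_that("energy-change rows cover exactly the variant-segment incidences", {
  hps <- lapply(1:3, function(s) make_hairpin(stem_len = 16, loop_len = 8, seed = s))
  hairpins <- dplyr::bind_rows(lapply(hps, `[[`, "hairpin"))
  segments <- dplyr::bind_rows(lapply(hps, `[[`, "segments"))
  known <- make_snp_catalog(hairpins, segments, 6, 6, seed = 50)
  en <- suppressWarnings(compute_energy_changes(
    hairpins, segments, known,
    backend = "basic"
  ))
  expected <- sum(vapply(seq_len(nrow(known)), function(i) {
    length(segment_membership(segments, known$position[i], known$hairpin_id[i]))
  }, integer(1)))
  expect_equal(nrow(en), expected)
  expect_equal(en$ddg, en$dg_mut - en$dg_wt)
  # a variant placed outside every segment yields no rows
  v_out <- tibble::tibble(
    snp_id = "vx", hairpin_id = hairpins$id[1], position = 1L,
    ref = substr(hairpins$sequence[1], 1, 1), alt = "A", origin = "artificial",
    maf = NA_real_
  )
  v_out$alt <- ifelse(v_out$ref == "A", "G", "A")
  segs_small <- segments[segments$segment == "loop" & segments$hairpin_id == hairpins$id[1], ]
  expect_equal(
    nrow(compute_energy_changes(hairpins[1, ], segs_small, v_out, backend = "basic")),
    0
  )
})

test_that("mature rows without targets carry NA energies and warn", {
  hp <- make_hairpin(seed = 12)
  v <- tibble::tibble(
    snp_id = "m1", hairpin_id = hp$hairpin$id,
    position = hp$hairpin$mature5p_start + 2L,
    ref = substr(hp$hairpin$sequence, hp$hairpin$mature5p_start + 2L, hp$hairpin$mature5p_start + 2L),
    alt = "A", origin = "known_nofreq", maf = NA_real_
  )
  v$alt <- ifelse(v$ref == "A", "C", "A")
  expect_warning(
    en <- compute_energy_changes(hp$hairpin, hp$segments, v, backend = "basic"),
    "no target entry"
  )
  expect_true(all(is.na(en$ddg[en$segment_class == "mature"])))
  expect_equal(sum(en$segment_class == "mature"), 1)
})
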