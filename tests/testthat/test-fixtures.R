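test_that("hairpin generation is seed-deterministic with exact ground truth", {
  a <- make_hairpin(seed = 3)
  b <- make_hairpin(seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$hairpin$sequence, make_hairpin(seed = 4)$hairpin$sequence))
  # generator truth equals the segmenter's output on its own annotation
  for (seed in 1:5) {
    hp <- make_hairpin(stem_len = 15 + seed, loop_len = 4 + seed, seed = seed)
    segs <- segment_hairpins(hp$hairpin, backend = "basic")
    expect_equal(as.data.frame(segs), as.data.frame(hp$segments))
  }
  expect_error(make_hairpin(stem_len = 10, seed = 1), "stem_len")
  expect_error(make_hairpin(loop_len = 2, seed = 1), "loop_len")
})

test_that("GC-free stems are weak, GC-rich stems strong", {
  au <- make_hairpin(gc_fraction = 0, seed = 2)$hairpin
  gc <- make_hairpin(gc_fraction = 1, seed = 2)$hairpin
  expect_false(grepl("[GC]", substr(au$sequence, au$mature5p_start, au$mature5p_end)))
  dg_au <- fold_mfe(au$sequence, backend = "basic")$dg
  dg_gc <- fold_mfe(gc$sequence, backend = "basic")$dg
  expect_lt(dg_gc, dg_au)
})

test_that("a generated hairpin folds into a single loop near the design size", {
  hp <- make_hairpin(stem_len = 22, loop_len = 16, gc_fraction = 0.5, seed = 1)
  fr <- fold_mfe(hp$hairpin$sequence, backend = "vienna")
  expect_lt(fr$dg, -20)
  expect_equal(loop_size(fr$structure), 16, tolerance = 0.3)
})

test_that("snp catalogs respect requested categories and validate", {
  hp <- make_hairpin(seed = 8)
  cat1 <- make_snp_catalog(hp$hairpin, hp$segments, 4, 3, seed = 1)
  expect_equal(sum(cat1$origin == "known_freq"), 4)
  expect_equal(sum(cat1$origin == "known_nofreq"), 3)
  expect_true(all(is.na(cat1$maf[cat1$origin == "known_nofreq"])))
  expect_true(all(cat1$maf[cat1$origin == "known_freq"] >= 0.01))
  expect_identical(cat1, make_snp_catalog(hp$hairpin, hp$segments, 4, 3, seed = 1))
  # refs genuinely match the hairpin
  at <- substr(rep(hp$hairpin$sequence, nrow(cat1)), cat1$position, cat1$position)
  expect_equal(at, cat1$ref)
})

test_that("a catalog without frequencies blocks burden ranking downstream", {
  hp <- make_hairpin(seed = 8)
  cat0 <- make_snp_catalog(hp$hairpin, hp$segments, 0, 5, seed = 2)
  cand <- dplyr::mutate(cat0, segment_class = "extension", ddg = 2, candidate = TRUE)
  expect_error(monte_carlo_burden(cand, iterations = 5), "undefined")
  # a configured fallback range unblocks it
  b <- monte_carlo_burden(cand, iterations = 5, seed = 1, freq_range = c(0.01, 0.05))
  expect_equal(nrow(b), 5)
})

test_that("target UTRs embed sites whose strength tracks match quality", {
  mature <- "UAGCUUAUCAGACUGAUGUUGA"
  perfect <- make_target_utrs(mature, n_genes = 2, match_quality = 1, seed = 4)
  none <- make_target_utrs(mature, n_genes = 2, match_quality = 0, seed = 4)
  expect_true(all(nchar(perfect$utr) >= 200 & nchar(perfect$utr) <= 600))
  e_full <- hybridize_mfe(mature, revcomp_rna(mature), backend = "basic")
  for (g in unique(perfect$gene_id)) {
    utrs <- perfect$utr[perfect$gene_id == g]
    e <- hybridize_mfe(rep(mature, length(utrs)), utrs, backend = "basic")
    expect_equal(min(e), e_full, tolerance = 1e-6) # per-gene min = full duplex
  }
  e_none <- hybridize_mfe(
    rep(mature, nrow(none)), none$utr,
    backend = "basic"
  )
  expect_gt(min(e_none), e_full * 0.8) # markedly weaker without a planted site
})

test_that("planted variants show their designed effect directions", {
  sc <- make_planted_scenario(seed = 1)
  en <- compute_energy_changes(
    sc$hairpins, sc$segments, sc$snps, sc$target_map,
    backend = "vienna"
  )
  en <- dplyr::inner_join(en, sc$truth, by = c("snp_id", "segment_class"))
  planted <- en[en$role != "neutral", ]
  expect_equal(sign(planted$ddg), planted$expected_sign)
  neutral <- en[en$role == "neutral", ]
  expect_true(all(abs(neutral$ddg) < min(abs(planted$ddg))))
})

test_that("burden benchmarks separate planted from noise scores", {
  bm <- make_burden_benchmark(seed = 2)
  expect_equal(nrow(bm$candidates), 200)
  expect_length(bm$truth, 5)
  planted <- bm$candidates[bm$candidates$snp_id %in% bm$truth, ]
  noise <- bm$candidates[!bm$candidates$snp_id %in% bm$truth, ]
  # a planted worst-case score beats the best achievable noise score
  expect_gt(min(planted$maf * planted$ddg), max(noise$ddg) * 0.3)
})
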