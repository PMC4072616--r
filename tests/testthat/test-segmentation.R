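test_that("segment intervals follow the stated arithmetic", {
  set.seed(42)
  seqn <- paste(sample(c("A", "C", "G", "U"), 110, replace = TRUE), collapse = "")
  hp <- manual_hairpin(seqn, m5 = c(26, 47), m3 = c(64, 85))
  segs <- segment_hairpins(hp, backend = "basic")
  get <- function(s) unlist(segs[segs$segment == s, c("start", "end")], use.names = FALSE)
  expect_equal(get("loop"), c(48, 63))
  expect_equal(get("ext5p"), c(1, 25))
  expect_equal(get("ext3p"), c(86, 110))
  expect_equal(get("mature5p"), c(26, 47))
  expect_false(any(segs$star_inferred)) # both arms annotated: pass-through
})

test_that("segments always appear in 5'->3' hairpin order", {
  for (seed in 1:5) {
    hp <- make_hairpin(
      stem_len = 15 + seed, loop_len = 4 + 2 * seed,
      gc_fraction = 0.3 + 0.1 * seed, seed = seed
    )
    segs <- segment_hairpins(hp$hairpin, backend = "basic")
    ord <- match(c("ext5p", "mature5p", "loop", "mature3p", "ext3p"), segs$segment)
    expect_true(all(diff(segs$start[ord]) >= 0))
    expect_true(all(diff(segs$end[ord]) >= 0))
  }
})

test_that("star-arm inference matches a brute-force complementarity scan", {
  score_oracle <- function(ch, known_start, m, s) {
    # independent rescoring of a 3p placement [s, s+m-1]
    total <- 0
    for (k in 0:(m - 3)) {
      a <- ch[known_start + k]
      b <- ch[s + m - 3 - k]
      pair <- paste0(a, b)
      total <- total +
        (pair %in% c("AU", "UA", "GC", "CG")) + 0.5 * (pair %in% c("GU", "UG"))
    }
    total
  }
  for (seed in 1:6) {
    hp <- make_hairpin(stem_len = 18, loop_len = 10, seed = seed)$hairpin
    inf <- infer_star_arm(hp$sequence, hp$mature5p_start, hp$mature5p_end, "5p")
    ch <- strsplit(hp$sequence, "")[[1]]
    m <- hp$mature5p_end - hp$mature5p_start + 1
    s_all <- seq(hp$mature5p_end + 2, nchar(hp$sequence) - m)
    sc <- vapply(s_all, function(s) score_oracle(ch, hp$mature5p_start, m, s), numeric(1))
    expect_equal(inf$score, max(sc))
    expect_true(inf$start %in% s_all[sc == max(sc)])
  }
})

test_that("a hidden 3p arm is recovered from a planted duplex", {
  for (seed in 1:8) {
    hp <- make_hairpin(stem_len = 20, loop_len = 12, gc_fraction = 0.5, seed = seed)$hairpin
    hidden <- hp
    hidden$mature3p_start <- NA_integer_
    hidden$mature3p_end <- NA_integer_
    segs <- segment_hairpins(hidden, backend = "basic")
    m3 <- segs[segs$segment == "mature3p", ]
    expect_true(m3$star_inferred)
    expect_lte(abs(m3$start - hp$mature3p_start), 1)
    expect_lte(abs(m3$end - hp$mature3p_end), 1)
  }
})

test_that("hidden 5p arms are recovered too", {
  hp <- make_hairpin(stem_len = 20, loop_len = 12, seed = 9)$hairpin
  hidden <- hp
  hidden$mature5p_start <- NA_integer_
  hidden$mature5p_end <- NA_integer_
  segs <- segment_hairpins(hidden, backend = "basic")
  m5 <- segs[segs$segment == "mature5p", ]
  expect_lte(abs(m5$start - hp$mature5p_start), 1)
})

test_that("degenerate placements and bad annotations are hard errors", {
  # no room for loop + extension on the 3' side
  hp <- manual_hairpin(strrep("AUGC", 8), m5 = c(2, 25))
  expect_error(segment_hairpins(hp, backend = "basic"), "no star-arm placement")
  # overlapping mature arms
  hp2 <- manual_hairpin(strrep("AUGC", 30), m5 = c(26, 50), m3 = c(45, 70))
  expect_error(segment_hairpins(hp2, backend = "basic"), "overlap")
  # arm flush with the hairpin end leaves an empty extension
  hp3 <- manual_hairpin(strrep("AUGC", 30), m5 = c(1, 22), m3 = c(40, 61))
  expect_error(segment_hairpins(hp3, backend = "basic"), "empty extension")
  # no annotation at all
  hp4 <- manual_hairpin(strrep("AUGC", 30))
  expect_error(segment_hairpins(hp4, backend = "basic"), "no mature arm")
})

test_that("abutting arms fall back to the structure-predicted loop", {
  hp <- make_hairpin(stem_len = 20, loop_len = 12, gc_fraction = 0.6, seed = 4)
  h <- hp$hairpin
  # force the arms to abut: stretch mature5p to touch mature3p
  h$mature5p_end <- h$mature3p_start - 1L
  segs <- segment_hairpins(h, backend = "basic")
  lp <- segs[segs$segment == "loop", ]
  expect_gte(lp$end - lp$start + 1, 3)
  # the structural loop sits inside the hairpin, overlapping the arms region
  expect_gt(lp$start, 1)
  expect_lt(lp$end, nchar(h$sequence))
})

test_that("membership reports every containing class, possibly none", {
  hp <- make_hairpin(seed = 1)
  segs <- hp$segments
  lp <- segs[segs$segment == "loop", ]
  expect_equal(segment_membership(segs, lp$start + 3), "loop")
  # constructed three-base overlap between mature arm and loop
  overlap <- dplyr::bind_rows(
    manual_segment("hp", "mature5p", "mature", 10, 30),
    manual_segment("hp", "loop", "loop", 28, 45)
  )
  expect_equal(segment_membership(overlap, 29), c("loop", "mature"))
  # far outside the extension bound of a long-flank hairpin
  far <- manual_segment("hp", "ext5p", "extension", 31, 55)
  expect_length(segment_membership(far, 5), 0)
})
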