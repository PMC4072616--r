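energy_row <- function(ddg, class, id = paste0("v", seq_along(ddg))) {
  tibble::tibble(
    snp_id = id, hairpin_id = "hp", position = seq_along(ddg), ref = "A",
    alt = "G", origin = "artificial", maf = NA_real_,
    segment_class = class, dg_wt = 0, dg_mut = ddg, ddg = ddg
  )
}

test_that("direction filter keeps the causal sign per class and drops zeros", {
  en <- dplyr::bind_rows(
    energy_row(c(-1.3, 2, 0), "loop", c("l1", "l2", "l3")),
    energy_row(c(1.5, -0.5, 0), "mature", c("m1", "m2", "m3")),
    energy_row(c(3, -2, NA), "extension", c("e1", "e2", "e3"))
  )
  kept <- direction_filter(en)
  expect_setequal(kept$snp_id, c("l1", "m1", "e1"))
})

test_that("cumulative fractions are prefix sums over the total", {
  expect_equal(cumulative_fraction(c(4, 3, 2, 1)), c(0.4, 0.7, 0.9, 1.0))
  expect_equal(cumulative_fraction(rep(2, 5)), (1:5) / 5)
  expect_equal(cumulative_fraction(numeric(0)), numeric(0))
  set.seed(1)
  x <- sort(runif(40, 0.1, 5), decreasing = TRUE)
  manual <- vapply(seq_along(x), function(n) sum(x[1:n]) / sum(x), numeric(1))
  expect_equal(cumulative_fraction(x), manual)
})

test_that("the knee lands on the elbow and ties break to the first rank", {
  expect_equal(knee_point(cumulative_fraction(c(10, 10, 10, 1, 1, 1, 1, 1, 1))), 3)
  expect_equal(knee_point(cumulative_fraction(rep(3, 7))), 1) # linear curve
  expect_equal(knee_point(cumulative_fraction(5)), 1)
  expect_equal(knee_point(numeric(0)), 0)
})

test_that("knee selection agrees with the exhaustive distance oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    x <- sort(round(runif(n, 0.1, 10), 2), decreasing = TRUE)
    fr <- cumulative_fraction(x)
    expect_equal(knee_point(fr), knee_oracle(fr))
  }
})

test_that("candidate calls are scale-invariant and ranked deterministically", {
  set.seed(5)
  en <- energy_row(sort(runif(30, 0.2, 8), decreasing = TRUE), "extension")
  calls1 <- select_inflection(direction_filter(en))
  en2 <- dplyr::mutate(en, ddg = ddg * 3.7, dg_mut = ddg)
  calls2 <- select_inflection(direction_filter(en2))
  expect_equal(calls1$rank, calls2$rank)
  expect_equal(calls1$candidate, calls2$candidate)
  expect_gte(sum(calls1$candidate), 1)
  expect_true(all(diff(calls1$cumulative_fraction) >= -1e-12))
  # candidate ddG range is nested in the filtered range
  cand <- calls1$ddg[calls1$candidate]
  expect_gte(min(cand), min(calls1$ddg))
  expect_gte(min(abs(cand)), max(abs(calls1$ddg[!calls1$candidate])))
})

test_that("known-vs-artificial comparison matches a hand-computed Welch test", {
  set.seed(9)
  kn <- rnorm(30, mean = 4, sd = 0.5)
  ar <- rnorm(30, mean = 2, sd = 0.5)
  calls <- dplyr::bind_rows(
    dplyr::mutate(energy_row(kn, "extension", paste0("k", 1:30)), origin = "known_freq"),
    energy_row(ar, "extension", paste0("a", 1:30))
  )
  calls$candidate <- TRUE
  res <- compare_known_artificial(calls)
  # closed-form Welch statistic
  tstat <- (mean(kn) - mean(ar)) / sqrt(var(kn) / 30 + var(ar) / 30)
  expect_equal(res$statistic, tstat)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$mean_known, mean(kn))

  # identical groups: statistic 0
  same <- dplyr::bind_rows(
    dplyr::mutate(energy_row(c(1, 2, 3), "loop", paste0("k", 1:3)), origin = "known_freq"),
    energy_row(c(1, 2, 3), "loop", paste0("a", 1:3))
  )
  same$candidate <- TRUE
  res2 <- compare_known_artificial(same)
  expect_equal(res2$statistic, 0)

  # a group with < 2 members is reported as not computable, no crash
  small <- dplyr::bind_rows(
    dplyr::mutate(energy_row(1, "loop", "k1"), origin = "known_freq"),
    energy_row(c(1, 2, 3), "loop", paste0("a", 1:3))
  )
  small$candidate <- TRUE
  res3 <- compare_known_artificial(small)
  expect_false(res3$computable)
  expect_true(is.na(res3$p_value))
})
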