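test_that("rank_scores reproduces the published score columns", {
  spad_wheat <- c(25.8, 27.2, 27.7, 24.1, 23.6, 24.2, 22.2, 26.2, 29.0, 33.3, 29.5, 27.8)
  expect_identical(rank_scores(spad_wheat, 12),
                   c(5L, 7L, 8L, 3L, 2L, 4L, 1L, 6L, 10L, 12L, 11L, 9L))
  root_dw_maize <- c(0.3, 0.3, 0.2, 0.2, 0.2, 0.2, 0.3, 0.3)
  expect_identical(rank_scores(root_dw_maize, 8),
                   c(8L, 8L, 4L, 4L, 4L, 4L, 8L, 8L))  # max-tie rule
  expect_identical(rank_scores(c(1, 2, 3)), c(1L, 2L, 3L))
  expect_error(rank_scores(c(1, 2), n_conditions = 3), "n_conditions")
  expect_error(rank_scores(c(1, NA, 3)), "NA")
  expect_error(rank_scores(5, n_conditions = 1), "at least 2")
})

test_that("rank_scores agrees with the brute-force max-tie oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:15, 1)
    v <- sample(1:6, n, replace = TRUE) + sample(c(0, 0, 0.5), n, replace = TRUE)
    expect_identical(rank_scores(v), oracle_max_tie(v))
  }
})

test_that("scores are permutation-equivariant, monotone, and a permutation when tie-free", {
  set.seed(100)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    v <- rnorm(n)
    s <- rank_scores(v)
    expect_setequal(s, seq_len(n))               # no ties: permutation of 1..n
    perm <- sample(n)
    expect_identical(rank_scores(v[perm]), s[perm])
    i <- sample(n, 1)
    v2 <- v; v2[i] <- v2[i] + abs(rnorm(1))
    expect_gte(rank_scores(v2)[i], s[i])          # monotone in own value
  }
})

test_that("the direction flag inverts the ranking", {
  expect_identical(rank_scores(c(3, 1, 2), direction = "lower"), c(1L, 3L, 2L))
  # ties still take the maximum of their (now reversed-order) positions
  expect_identical(rank_scores(c(2, 2, 1), direction = "lower"), c(2L, 2L, 3L))
})

test_that("build_score_matrix ranks per column and handles untested cells", {
  vals <- matrix(c(1, 2, NA, 5, 3, 1, 10, 20, 30, 40), nrow = 5,
                 dimnames = list(paste0("T", 1:5), c("p1", "p2")))
  vals[1, 2] <- NA
  sm <- build_score_matrix(vals)
  expect_true(is.na(sm["T3", "p1"]))
  expect_equal(attr(sm, "n_ranked"), c(p1 = 4L, p2 = 4L))
  expect_identical(unname(unclass(sm)[, "p1"]), c(1L, 2L, NA, 4L, 3L))
  # a parameter observed on fewer than two treatments cannot be ranked
  vals[, 2] <- NA; vals[2, 2] <- 1
  expect_error(build_score_matrix(vals), "at least 2")
  # single parameter, two treatments
  m2 <- build_score_matrix(matrix(c(1, 2), 2, 1, dimnames = list(c("a", "b"), "p")))
  expect_identical(unname(unclass(m2)[, 1]), c(1L, 2L))
})

test_that("prescored columns are validated, not re-ranked", {
  vals <- matrix(c(10, 30, 20, 3, 1, 2), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("raw", "given")))
  sm <- build_score_matrix(vals, prescored = "given")
  expect_identical(unname(unclass(sm)[, "given"]), c(3L, 1L, 2L))
  vals[1, "given"] <- 7
  expect_error(build_score_matrix(vals, prescored = "given"), "in \\[1, 3\\]")
  expect_error(build_score_matrix(vals, prescored = "nope"), "not in values")
})

test_that("half-up rounding matches the published mean convention", {
  expect_equal(round_half_up(79 / 9), 8.8)
  expect_equal(round_half_up(61 / 13), 4.7)
  expect_equal(round_half_up(4.85), 4.9)     # halves go up, not to even
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("totals_and_means sums available scores and flags extremes", {
  w <- evaluate_packaged_study("wheat")
  rk <- w$ranking
  r <- function(tr) rk[rk$treatment == tr, ]
  expect_equal(r("Char_MC-B")$total, 79)
  expect_equal(r("Char_MC-B")$n_params, 9L)     # four parameters n.t.
  expect_equal(r("Char_MC-B")$mean, 8.8)
  expect_equal(r("Control")$total, 61)
  expect_equal(r("Control")$mean, 4.7)
  expect_true(any(rk$is_best) && any(rk$is_worst))

  one <- matrix(c(5L, 3L), 2, 1, dimnames = list(c("T1", "T2"), "p"))
  expect_equal(totals_and_means(one)$total, c(5L, 3L))
  expect_equal(totals_and_means(one)$mean, c(5.0, 3.0))
})

test_that("score matrix TSV export uses the n.t. literal and keeps totals", {
  w <- evaluate_packaged_study("wheat")
  path <- withr::local_tempfile(fileext = ".tsv")
  rk <- write_score_matrix(w$scores, path)
  out <- read.delim(path, colClasses = "character")
  expect_equal(out$shannon_bacteria[out$treatment == "MC-B"], "n.t.")
  expect_equal(as.integer(out$total), rk$total)
})
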