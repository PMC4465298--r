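# Two-group permutation testing machinery.

test_that("filter_all_zero drops only rows zero across the compared samples", {
  m <- toy_counts(n_transcripts = 5, seed = 51)
  m[2, ] <- 0L
  f <- filter_all_zero(m)
  expect_equal(nrow(f), 4)
  expect_identical(attr(f, "removed"), "t2")
  # no all-zero rows -> identity
  f2 <- filter_all_zero(toy_counts(seed = 52))
  expect_length(attr(f2, "removed"), 0)
  # zero in group A but positive in group B -> retained
  m3 <- toy_counts(n_transcripts = 4, seed = 53)
  m3[1, 1:4] <- 0L
  des <- toy_design()
  expect_true("t1" %in% rownames(filter_all_zero(m3, des)))
})

test_that("t_statistic is the Welch statistic", {
  expect_equal(t_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(t_statistic(c(2, 4), c(1, 3)), 1 / sqrt(2))
  # textbook oracle: stats::t.test's Welch statistic
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(5, 1); y <- rnorm(7)
    expect_equal(t_statistic(x, y),
                 unname(t.test(x, y)$statistic), tolerance = 1e-12)
  }
  expect_true(is.na(t_statistic(c(2, 2, 2), c(5, 5))))
  expect_error(t_statistic(1, c(1, 2)), ">= 2")
})

test_that("row_t_statistic matches the scalar version row by row", {
  m <- matrix(rnorm(80), 10, 8)
  t_vec <- row_t_statistic(m, 1:4, 5:8)
  t_ref <- apply(m, 1, function(r) t_statistic(r[1:4], r[5:8]))
  expect_equal(t_vec, t_ref, tolerance = 1e-12)
})

test_that("build_null enumerates exhaustively and reports combinatorics", {
  m <- toy_counts(n_transcripts = 20, n_samples = 4, seed = 71)
  des <- de_design(c("s1", "s2"), c("s3", "s4"))
  null <- build_null(m, des, max_perms = 1000)
  expect_true(null$exhaustive)
  expect_equal(null$n_perms, 5)               # choose(4,2) - identity
  expect_lte(length(null$pooled_stats), 20 * 5)

  m8 <- toy_counts(n_transcripts = 10, n_samples = 8, seed = 72)
  null8 <- build_null(m8, toy_design(), max_perms = 1000)
  expect_equal(null8$n_perms, choose(8, 4) - 1)
  expect_true(null8$exhaustive)
  # with identity included the universe is the full choose(n, k)
  nid <- build_null(m8, toy_design(), max_perms = 1000,
                    include_identity = TRUE)
  expect_equal(nid$n_perms, choose(8, 4))
  # capped: random subsample, seeded and reproducible
  sub1 <- build_null(m8, toy_design(), max_perms = 10, seed = 3)
  sub2 <- build_null(m8, toy_design(), max_perms = 10, seed = 3)
  expect_false(sub1$exhaustive)
  expect_equal(sub1$n_perms, 10)
  expect_identical(sub1$pooled_stats, sub2$pooled_stats)
})

test_that("pooled null is symmetric for exchangeable equal-sized groups", {
  set.seed(81)
  m <- matrix(rnbinom(2000 * 10, mu = 100, size = 5), 2000, 10,
              dimnames = list(paste0("t", 1:2000), paste0("s", 1:10)))
  des <- de_design(paste0("s", 1:5), paste0("s", 6:10))
  null <- build_null(normalize_global(m), des, max_perms = 1000, seed = 1)
  s <- null$pooled_stats
  expect_gte(length(s), 1e5)
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)) + 0.01)
  skew <- mean((s - mean(s))^3) / sd(s)^3
  expect_lt(abs(skew), 0.1)
})

test_that("empirical p-values match exhaustive hand enumeration on a toy", {
  # 3 transcripts, 4 samples (2+2): 5 non-identity assignments, pool of 15
  m <- matrix(c(5L, 9L, 2L, 11L,
                3L, 1L, 8L, 6L,
                10L, 12L, 4L, 7L), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  des <- de_design(c("s1", "s2"), c("s3", "s4"))
  null <- build_null(m, des, max_perms = 1000)
  t_obs <- row_t_statistic(m, 1:2, 3:4)
  p <- empirical_pvalues(t_obs, null)
  # brute-force oracle: loop over all choose(4,2) subsets by hand
  subsets <- combn(4, 2)
  pool <- c()
  for (k in seq_len(ncol(subsets))) {
    a <- subsets[, k]
    if (identical(a, c(1L, 2L))) next
    b <- setdiff(1:4, a)
    for (g in 1:3) pool <- c(pool, t_statistic(m[g, a], m[g, b]))
  }
  pool <- pool[!is.na(pool)]
  p_ref <- sapply(t_obs, function(t)
    (1 + sum(abs(pool) >= abs(t))) / (1 + length(pool)))
  expect_equal(unname(p), unname(p_ref), tolerance = 1e-12)
})

test_that("empirical p-value boundary and undefined-statistic conventions", {
  null <- structure(list(pooled_stats = rnorm(100, 0, 1)),
                    class = "degps_null")
  expect_equal(empirical_pvalues(1e6, null), 1 / 101)
  expect_equal(empirical_pvalues(0, null), 1)
  expect_equal(empirical_pvalues(NA_real_, null), 1)
  expect_error(empirical_pvalues(1, structure(list(pooled_stats = numeric(0)),
                                              class = "degps_null")),
               "empty")
  # monotone nonincreasing in |t|
  p <- empirical_pvalues(c(0.1, 0.5, 1, 2, 3), null)
  expect_true(all(diff(p) <= 0))
})

test_that("bh_adjust is the BH step-up and matches p.adjust exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(91)
  for (i in 1:20) {
    p <- runif(100)
    expect_identical(bh_adjust(p), p.adjust(p, "BH"))
  }
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("regularized T reduces to Welch at shrink 0 and pools at 1", {
  set.seed(101)
  m <- matrix(rnorm(2000 * 8, 10), 2000, 8)
  t0 <- row_regularized_t(m, 1:4, 5:8, shrink = 0)
  expect_equal(t0, row_t_statistic(m, 1:4, 5:8), tolerance = 1e-12)
  t1 <- row_regularized_t(m, 1:4, 5:8, shrink = 1)
  A <- m[, 1:4]; B <- m[, 5:8]
  va <- median(apply(A, 1, var)); vb <- median(apply(B, 1, var))
  t1_ref <- (rowMeans(A) - rowMeans(B)) / sqrt(va / 4 + vb / 4)
  expect_equal(t1, t1_ref, tolerance = 1e-10)
  # estimated shrinkage keeps the ranking close to ordinary T
  test <- row_regularized_t(m, 1:4, 5:8)
  expect_gt(cor(rank(abs(test)), rank(abs(t0))), 0.9)
})

test_that("run_degps end-to-end invariances hold", {
  set.seed(111)
  m <- toy_counts(n_transcripts = 150, n_samples = 8, seed = 112, mu = 60)
  des <- toy_design()
  res <- run_degps(m, des, method = "global", seed = 4)
  expect_s3_class(res, "degps_result")
  expect_true(all(res$table$p_adjusted >= res$table$p_value))
  expect_identical(res$table$significant, res$table$p_adjusted < 0.05)
  # permuting the sample order of the input leaves results unchanged
  perm <- sample(ncol(m))
  res2 <- run_degps(m[, perm], des, method = "global", seed = 4)
  expect_equal(res2$table, res$table, tolerance = 1e-12)
  # scale invariance of the statistic: scaling all counts by 3
  res3 <- run_degps(3L * m, des, method = "global", seed = 4)
  expect_equal(res3$table$t_stat, res$table$t_stat, tolerance = 1e-10)
  expect_equal(res3$table$p_value, res$table$p_value, tolerance = 1e-12)
  # label swap negates T and preserves p-values
  des_swap <- de_design(des$group_b, des$group_a)
  res4 <- run_degps(m, des_swap, method = "global", seed = 4)
  expect_equal(res4$table$t_stat, -res$table$t_stat, tolerance = 1e-10)
  expect_equal(res4$table$p_value, res$table$p_value, tolerance = 1e-12)
  # exhaustive enumeration is seed independent
  res5 <- run_degps(m, des, method = "global", seed = 999)
  expect_equal(res5$table, res$table, tolerance = 1e-12)
})
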