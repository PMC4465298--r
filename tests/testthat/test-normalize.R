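# Normalization strategies: GP-based methods and the comparators.

test_that("count matrix validation reports coordinates and duplicates", {
  m <- toy_counts()
  expect_silent(degps:::check_count_matrix(m))
  bad <- m; bad[2, 3] <- -1
  expect_error(degps:::check_count_matrix(bad), "row 2, column 3")
  dup <- m; rownames(dup)[2] <- rownames(dup)[1]
  expect_error(degps:::check_count_matrix(dup), "duplicate transcript")
})

test_that("gp-theta divides by theta-hat and recovers the Poisson mean", {
  set.seed(21)
  m <- matrix(rpois(4000, 50), 1000, 4,
              dimnames = list(paste0("t", 1:1000), paste0("s", 1:4)))
  nm <- normalize_gp_theta(m)
  f <- attr(nm, "per_sample_factors")
  # Poisson columns: lambda-hat ~ 0, so theta-hat ~ column mean
  expect_equal(unname(f), unname(colMeans(m)), tolerance = 0.03)
  expect_equal(unclass(nm), sweep(m, 2, f, "/"), ignore_attr = TRUE)
  expect_identical(dimnames(nm), dimnames(m))
})

test_that("gp-theta factor tracks the generating theta and depth scaling", {
  # a sample sequenced at twice the depth has theta doubled, same lambda;
  # the fitted factors then differ by ~2 and normalized distributions align
  x1 <- rgp(gp_params(2, 0.5), 10000, seed = 31)
  x2 <- rgp(gp_params(4, 0.5), 10000, seed = 32)
  m <- cbind(s1 = x1, s2 = x2)
  rownames(m) <- paste0("t", seq_len(nrow(m)))
  nm <- normalize_gp_theta(m)
  f <- attr(nm, "per_sample_factors")
  expect_equal(unname(f[1]), 2, tolerance = 0.05)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 0.1)
  expect_equal(mean(nm[, 1]), mean(nm[, 2]), tolerance = 0.05)
})

test_that("gp-quantile maps counts to strict CDF values in [0, 1)", {
  m <- toy_counts(n_transcripts = 300, n_samples = 4, seed = 5)
  nm <- normalize_gp_quantile(m)
  expect_true(all(nm >= 0 & nm < 1))
  expect_true(all(nm[m == 0] == 0))     # P(X < 0) = 0
  # within-sample monotonicity
  for (j in 1:4) {
    o <- order(m[, j])
    expect_true(all(diff(nm[o, j]) >= 0))
  }
  # Poisson column: entry value 3 maps to ~ Poisson CDF at 2
  set.seed(8)
  mp <- matrix(rpois(8000, 2), 4000, 2,
               dimnames = list(paste0("g", 1:4000), c("a", "b")))
  np <- normalize_gp_quantile(mp)
  i <- which(mp[, 1] == 3)[1]
  expect_equal(np[i, 1], ppois(2, 2), tolerance = 0.02)
})

test_that("global normalization equalizes column totals", {
  m <- toy_counts(seed = 77)
  nm <- normalize_global(m)
  expect_equal(unname(colSums(nm)), rep(mean(colSums(m)), ncol(m)))
  # already equal totals -> identity
  eq <- matrix(c(3L, 7L, 5L, 5L), 2, 2,
               dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(unclass(normalize_global(eq)), eq, ignore_attr = TRUE)
  # totals (100, 200) with target 150 -> factors (1.5, 0.75)
  m2 <- matrix(c(100L, 200L), 1, 2, dimnames = list("t1", c("a", "b")))
  expect_equal(unname(attr(normalize_global(m2), "per_sample_factors")),
               c(1.5, 0.75))
  z <- m; z[, 2] <- 0L
  expect_error(normalize_global(z), "zero total")
})

test_that("quantile normalization matches limma on tied and untied data", {
  skip_if_not_installed("limma")
  m <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L), 3, 2,
              dimnames = list(paste0("t", 1:3), c("a", "b")))
  nm <- normalize_quantile(m)
  expect_equal(unname(unclass(nm)),
               matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3, 2),
               ignore_attr = TRUE)
  # identical columns unchanged
  ident <- cbind(a = c(5L, 1L, 9L), b = c(5L, 1L, 9L))
  rownames(ident) <- paste0("t", 1:3)
  expect_equal(unclass(normalize_quantile(ident)), ident,
               ignore_attr = TRUE)
  # ties: agree with limma's independent implementation
  set.seed(13)
  tied <- matrix(sample(0:5, 60, replace = TRUE), 20, 3,
                 dimnames = list(paste0("t", 1:20), paste0("s", 1:3)))
  expect_equal(unname(unclass(normalize_quantile(tied))),
               unname(limma::normalizeQuantiles(tied)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # with tie-free columns all normalized columns share one distribution
  set.seed(3)
  free <- sapply(1:4, function(j) sample.int(1000, 30))
  dimnames(free) <- list(paste0("t", 1:30), paste0("s", 1:4))
  nm2 <- normalize_quantile(free)
  sorted <- apply(nm2, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))
})

test_that("TMM factors match edgeR's implementation", {
  skip_if_not_installed("edgeR")
  # identical columns -> factors 1
  ident <- cbind(a = c(10L, 20L, 30L, 5L), b = c(10L, 20L, 30L, 5L))
  rownames(ident) <- paste0("t", 1:4)
  expect_equal(unname(attr(normalize_tmm(ident), "per_sample_factors")),
               c(1, 1))
  # pure depth difference is absorbed by library size, TMM factor ~ 1
  set.seed(17)
  base <- rnbinom(500, mu = 100, size = 5)
  m <- cbind(a = base, b = 2L * base)
  rownames(m) <- paste0("t", 1:500)
  f <- attr(normalize_tmm(m), "per_sample_factors")
  expect_equal(unname(f), c(1, 1), tolerance = 1e-6)
  # random NB matrix with 10% DE: within 2% of edgeR
  set.seed(19)
  mu <- 10^rnorm(2000, 2, 0.8)
  mm <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 5))
  de <- sample(2000, 200)
  mm[de, 1:3] <- matrix(rnbinom(length(de) * 3, mu = mu[de] * 4, size = 5),
                        ncol = 3)
  dimnames(mm) <- list(paste0("t", 1:2000), paste0("s", 1:6))
  ours <- attr(normalize_tmm(mm), "per_sample_factors")
  ref <- edgeR::calcNormFactors(mm, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("lowess normalization removes offsets and intensity trends", {
  m <- toy_counts(n_transcripts = 500, n_samples = 4, seed = 23, mu = 100)
  # identical columns -> unchanged up to numerical noise
  ident <- m[, c(1, 1)]
  colnames(ident) <- c("a", "b")
  nid <- normalize_lowess(ident)
  expect_equal(unclass(nid), ident, tolerance = 1e-6, ignore_attr = TRUE)
  # constant log-offset removed
  off <- cbind(a = m[, 1], b = as.integer(round((m[, 1] + 1) * 4 - 1)))
  rownames(off) <- rownames(m)
  noff <- normalize_lowess(off)
  lg <- log2(unclass(noff) + 1)
  expect_lt(median(abs(lg[, 2] - lg[, 1])), 0.05)
  # intensity-dependent bias: residual M-vs-A slope < 0.05
  set.seed(29)
  mu <- 10^runif(2000, 0.5, 4)
  a <- rpois(2000, mu)
  b <- rpois(2000, mu * (1 + log10(mu) / 10))  # bias grows with abundance
  biased <- cbind(a = a, b = b)
  rownames(biased) <- paste0("t", 1:2000)
  nb <- normalize_lowess(biased)
  lgn <- log2(unclass(nb) + 1)
  M <- lgn[, 2] - lgn[, 1]; A <- rowMeans(lgn)
  expect_lt(abs(coef(lm(M ~ A))[2]), 0.05)
})

test_that("normalize_counts dispatches and preserves shape and ids", {
  m <- toy_counts(seed = 41)
  for (meth in c("gp-theta", "gp-quantile", "global", "quantile", "tmm",
                 "lowess")) {
    nm <- normalize_counts(m, meth)
    expect_identical(dim(nm), dim(m))
    expect_identical(dimnames(nm), dimnames(m))
    expect_identical(attr(nm, "method"), meth)
    if (meth != "lowess") expect_true(all(nm >= 0))
  }
  expect_error(normalize_counts(m, "rpkm"))
})
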