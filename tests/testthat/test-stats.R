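test_that("one-sample t matches hand arithmetic", {
  m <- matrix(c(0.6, 0.7, 0.8), 3, 1)
  expect_equal(one_sample_t(m, 0.5), 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(one_sample_t(matrix(0.5, 4, 3), 0.5), c(0, 0, 0))
  expect_warning(t0 <- one_sample_t(matrix(1, 3, 1), 0), "zero SD")
  expect_true(is.infinite(t0))
})

test_that("null t series exceed |2| at about the t15 tail rate", {
  set.seed(101)
  X <- matrix(rnorm(16 * 5000), 16)
  frac <- mean(abs(one_sample_t(X, 0)) > 2)
  expect_lt(abs(frac - 2 * pt(-2, df = 15)), 0.01)
})

test_that("Bonferroni is capped min(1, m p)", {
  expect_equal(bonferroni(0.001, m = 221), 0.221)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(c(0.01, 0.4)), stats::p.adjust(c(0.01, 0.4),
                                                         "bonferroni"))
})

test_that("Bonferroni controls the family-wise error on uniform nulls", {
  set.seed(102)
  fwe <- mean(vapply(1:1000, function(i) {
    any(bonferroni(runif(221)) < 0.05)
  }, NA))
  expect_lte(fwe, 0.07)  # nominal 0.05 plus binomial noise at n=1000
})

test_that("a single supra-threshold timepoint forms a length-1 cluster", {
  set.seed(103)
  X <- matrix(rnorm(8 * 30, sd = 0.05), 8)
  X[, 17] <- X[, 17] + 1  # strong effect at one timepoint
  res <- cluster_permutation(X, t_thresh = 2, n_perm = 200, seed = 1)
  hit <- res$clusters[res$clusters$start_idx <= 17 &
                        res$clusters$end_idx >= 17, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start_idx, 17)
  expect_equal(hit$end_idx, 17)
  expect_equal(hit$mass, res$t_series[17])
})

test_that("a strong injected window is detected at the permutation p floor", {
  set.seed(104)
  X <- matrix(rnorm(16 * 221, sd = 0.05), 16) + 0.5
  X[, 61:101] <- X[, 61:101] + 0.1    # 200..400 ms at 5 ms bins from -100
  times <- seq(-100, 1000, by = 5)
  res <- cluster_permutation(X, mu0 = 0.5, t_thresh = 2, n_perm = 1000,
                             seed = 2, times_ms = times)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(abs(sig$mass)), ]
  expect_lte(main$start_ms, 205)
  expect_gte(main$end_ms, 395)
  expect_equal(main$p, 1 / 1001)
})

test_that("raising the cluster-forming threshold never widens windows", {
  set.seed(105)
  X <- matrix(rnorm(10 * 80, sd = 0.1), 10)
  X[, 30:50] <- X[, 30:50] + 0.12
  lo <- cluster_permutation(X, t_thresh = 1.5, n_perm = 50, seed = 3)
  hi <- cluster_permutation(X, t_thresh = 2.5, n_perm = 50, seed = 3)
  for (i in seq_len(nrow(hi$clusters))) {
    inside <- any(lo$clusters$start_idx <= hi$clusters$start_idx[i] &
                    lo$clusters$end_idx >= hi$clusters$end_idx[i])
    expect_true(inside)
  }
})

test_that("observed statistics are invariant to participant order", {
  set.seed(106)
  X <- matrix(rnorm(12 * 60, sd = 0.1), 12)
  X[, 20:35] <- X[, 20:35] + 0.1
  perm <- sample(12)
  a <- cluster_permutation(X, t_thresh = 2, n_perm = 400, seed = 4)
  b <- cluster_permutation(X[perm, ], t_thresh = 2, n_perm = 400, seed = 4)
  expect_equal(a$t_series, b$t_series)
  expect_equal(a$clusters$mass, b$clusters$mass)
  # p-values agree within permutation Monte-Carlo error
  expect_equal(a$clusters$p, b$clusters$p, tolerance = 0.05)
})

test_that("the smallest attainable p is 1/(n_perm+1)", {
  set.seed(107)
  X <- matrix(rnorm(16 * 40, sd = 0.02), 16) + 1  # overwhelming effect
  res <- cluster_permutation(X, t_thresh = 2, n_perm = 250, seed = 5)
  expect_equal(min(res$clusters$p), 1 / 251)
})

test_that("two-tailed mode detects negative clusters", {
  set.seed(108)
  X <- matrix(rnorm(12 * 50, sd = 0.05), 12)
  X[, 10:20] <- X[, 10:20] - 0.2
  one <- cluster_permutation(X, t_thresh = 2, n_perm = 100, tail = "one",
                             seed = 6)
  two <- cluster_permutation(X, t_thresh = 2, n_perm = 100, tail = "two",
                             seed = 6)
  expect_false(any(one$clusters$mass < 0 & one$clusters$significant))
  expect_true(any(two$clusters$mass < 0 & two$clusters$significant))
})
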