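test_that("AUC handles separation, ties and the worked pair count", {
  expect_equal(auc_score(c(1, 2), c(0, 1)), 1.0)
  expect_equal(auc_score(rep(3, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  # mixed ranking: positives {1, 2, 4} vs negatives {3, 5} -> 1 of 6 pairs won
  expect_equal(auc_score(c(3, 1, 2, 5, 4), c(0, 1, 1, 0, 1)), 1 / 6)
  expect_equal(auc_score(c(3, 1, 2, 5, 4), c(0, 1, 1, 0, 1)),
               auc_brute(c(3, 1, 2, 5, 4), c(0, 1, 1, 0, 1)))
  expect_error(auc_score(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(61)
  for (i in 1:20) {
    s <- rnorm(20)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- auc_score(s, y)
    expect_equal(auc_score(exp(s), y), a)
    expect_equal(auc_score(2 * s + 7, y), a)
  }
})

test_that("rank AUC equals the all-pairs oracle on random instances", {
  set.seed(62)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(auc_score(s, y), auc_brute(s, y))
  }
})

test_that("decoding a planted window effect is near-perfect inside, chance outside", {
  ea <- shifted_epochs(40, 3, 30, seed = 71, label = "a")
  eb <- shifted_epochs(40, 3, 30, shift = 2, window = 11:20, seed = 72,
                       label = "b")
  auc <- time_resolved_decode(ea, eb, n_folds = 10, seed = 1)
  expect_gt(mean(auc[11:20]), 0.95)
  expect_lt(abs(mean(auc[c(1:10, 21:30)]) - 0.5), 0.1)
  # determinism
  auc2 <- time_resolved_decode(ea, eb, n_folds = 10, seed = 1)
  expect_identical(as.numeric(auc), as.numeric(auc2))
})

test_that("null decoding stays within 3 SE of chance at the cohort level", {
  cohort_auc <- vapply(1:12, function(i) {
    ea <- shifted_epochs(24, 3, 6, seed = 100 + i, label = "a")
    eb <- shifted_epochs(24, 3, 6, seed = 200 + i, label = "b")
    mean(time_resolved_decode(ea, eb, n_folds = 6, seed = i))
  }, 0)
  se <- sd(cohort_auc) / sqrt(length(cohort_auc))
  expect_lt(abs(mean(cohort_auc) - 0.5), 3 * se + 0.02)
})

test_that("fold-pooled scoring is available and close to fold-averaged", {
  ea <- shifted_epochs(30, 2, 4, seed = 81, label = "a")
  eb <- shifted_epochs(30, 2, 4, shift = 1.5, window = 1:4, seed = 82,
                       label = "b")
  a_avg <- time_resolved_decode(ea, eb, n_folds = 6, seed = 3)
  a_pool <- time_resolved_decode(ea, eb, n_folds = 6, seed = 3, pooled = TRUE)
  expect_equal(as.numeric(a_avg), as.numeric(a_pool), tolerance = 0.12)
})

test_that("too few trials per condition for the fold count errors clearly", {
  ea <- shifted_epochs(5, 2, 3, seed = 91, label = "a")
  eb <- shifted_epochs(5, 2, 3, seed = 92, label = "b")
  expect_error(time_resolved_decode(ea, eb, n_folds = 10), "at least")
})

test_that("decode_pairs covers pairs x features and skips missing labels", {
  mk_part <- function(seed) {
    set.seed(seed)
    a <- array(rnorm(30 * 2 * 64 * 3, sd = 0.3), c(90, 2, 64))
    ep <- epochs(a, 200, 0, rep(c("famous", "unfamiliar", "scrambled"), each = 30))
    list(epochs = ep, imfs = decompose_epochs(ep, n_imfs = 4))
  }
  cohort <- list(mk_part(1), mk_part(2))
  res <- decode_pairs(cohort, imfs = 2, include_raw = TRUE, n_folds = 5,
                      seed = 1, timepoints = c(10, 25, 40, 55))
  expect_equal(nrow(res), 3 * 2)  # 3 pairs x (raw + IMF2)
  expect_setequal(unique(res$feature), c("raw", "IMF2"))
  r <- res$result[[1]]
  expect_equal(dim(r$auc), c(2, 4))
  expect_true(all(r$auc >= 0 & r$auc <= 1))

  expect_warning(
    decode_pairs(cohort, pairs = list(c("famous", "absent")), imfs = NULL,
                 n_folds = 5),
    "skipped")
})

test_that("decoding result tidiers expose traces and summaries", {
  r <- emdecode:::new_decoding_result(matrix(runif(6), 2), c("a", "b"),
                                      "raw", c(0, 5, 10), 5, 1)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  g <- glance(r)
  expect_equal(g$n_participants, 2)
  expect_true(g$peak_time_ms %in% c(0, 5, 10))
})
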