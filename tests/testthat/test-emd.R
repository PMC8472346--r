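test_that("a pure sinusoid is its own first IMF and a ramp is monotone", {
  s <- sift(tone(5))
  expect_false(s$monotone)
  expect_gt(cor(s$imf, tone(5)), 0.999)

  r <- sift(seq(0, 1, length.out = 50))
  expect_true(r$monotone)
  expect_equal(r$imf, seq(0, 1, length.out = 50))
})

test_that("sifting a two-tone mixture extracts the fast component first", {
  x <- tone(5) + tone(40)
  s <- sift(x)
  expect_gt(abs(cor(s$imf, tone(40))), 0.95)
})

test_that("plain EMD is complete and degrades gracefully on tiny input", {
  set.seed(11)
  for (n in c(64, 221)) {
    x <- rnorm(n)
    d <- emd(x, n_imfs = 8)
    expect_lt(max(abs(reconstruct(d) - x)), 1e-8 * diff(range(x)))
  }
  d3 <- emd(c(0.1, 0.5, 0.2), n_imfs = 4)
  expect_equal(d3$meta$n_extracted, 0L)
  expect_equal(d3$residual, c(0.1, 0.5, 0.2))
})

test_that("white-noise EMD behaves as a descending filter bank", {
  set.seed(21)
  ok <- vapply(1:10, function(i) {
    d <- emd(rnorm(400), n_imfs = 6, fs = 200)
    doms <- vapply(seq_len(d$meta$n_extracted), function(k)
      dominant_frequency(marginal_spectrum(d$imfs[k, ], fs = 200)), 0)
    all(diff(doms) < 0)
  }, NA)
  expect_gte(mean(ok), 0.5)  # majority of realizations strictly descending
})

test_that("masking EMD separates an intermittent burst from a slow tone", {
  mm <- mode_mixing_signal()
  x <- mm$tone + mm$burst
  best <- function(dec) {
    max(apply(dec$imfs, 1, function(m)
      if (sd(m) > 0) abs(cor(m, mm$tone)) else 0))
  }
  c_mask <- best(masking_emd(x, 8, fs = 200))
  c_plain <- best(emd(x, 8, fs = 200))
  expect_gt(c_mask, 0.95)
  expect_gt(c_mask, c_plain)
})

test_that("masking EMD agrees with plain EMD on an unmixed sinusoid", {
  x <- tone(5)
  m <- masking_emd(x, 8, fs = 200)
  p <- emd(x, 8, fs = 200)
  km <- which.max(rowSums(m$imfs^2))
  kp <- which.max(rowSums(p$imfs^2))
  # envelope edge handling differs slightly between the two paths; away from
  # the epoch edges the dominant modes coincide
  interior <- seq(ceiling(0.1 * length(x)), floor(0.9 * length(x)))
  expect_gt(abs(cor(m$imfs[km, interior], p$imfs[kp, interior])), 0.999)
  expect_lt(max(abs(reconstruct(m) - x)), 1e-8 * diff(range(x)))
})

test_that("mask frequencies at or above Nyquist are rejected", {
  expect_error(masking_emd(rnorm(100), 8, fs = 200, mask_freqs = 100),
               "Nyquist")
})

test_that("decompose_epochs has the right shape and reconstructs", {
  set.seed(5)
  ep <- epochs(array(rnorm(2 * 2 * 221, sd = 1), c(2, 2, 221)), 200, -100)
  dec <- decompose_epochs(ep, n_imfs = 8, drop_residual = TRUE)
  expect_equal(dim(dec$data), c(7, 2, 2, 221))
  expect_equal(dec$imf_index, 1:7)

  full <- decompose_epochs(ep, n_imfs = 8, drop_residual = FALSE)
  recon <- apply(full$data, c(2, 3, 4), sum)
  expect_lt(max(abs(recon - ep$data)), 1e-8 * diff(range(ep$data)))
})

test_that("epochs of a pure tone concentrate energy in one IMF", {
  t <- seq(-100, 1000, by = 5) / 1000
  a <- array(0, c(2, 1, length(t)))
  a[1, 1, ] <- sin(2 * pi * 3 * t)
  a[2, 1, ] <- sin(2 * pi * 3 * t + 1)
  dec <- decompose_epochs(epochs(a, 200, -100), n_imfs = 8)
  energy <- vapply(1:7, function(k) sum(dec$data[k, , , ]^2), 0)
  # 3 Hz sits at the IMF4/IMF5 dyadic mask boundary, so the tone may split
  # between those two neighbours; together they must carry essentially all
  # of the energy, with a clear single leader
  lead <- which.max(energy)
  expect_gt(energy[lead] / sum(energy), 0.5)
  neighbours <- energy[lead] + max(energy[c(lead - 1, lead + 1)], na.rm = TRUE)
  expect_gt(neighbours / sum(energy), 0.95)
})

test_that("imf_component extracts the requested 1-based component", {
  ep <- epochs(array(rnorm(1 * 1 * 128), c(1, 1, 128)), 200, -100)
  dec <- decompose_epochs(ep, n_imfs = 8)
  c4 <- imf_component(dec, 4)
  expect_s3_class(c4, "epochs")
  expect_equal(c4$data[1, 1, ], dec$data[4, 1, 1, ])
  expect_error(imf_component(dec, 9), "not present")
})
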