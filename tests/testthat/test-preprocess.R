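make_raw <- function(x, fs, events = NULL) {
  raw_recording(matrix(x, nrow = 1), fs, events = events)
}

test_that("band-pass keeps the passband, kills DC, rejects bad edges", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)  # long window: the 0.5 Hz high-pass
  x <- sin(2 * pi * 10 * t)              # transient spans seconds
  out <- bandpass(make_raw(x, fs), 0.5, 100)
  interior <- seq(2000, length(t) - 2000)
  expect_lt(max(abs(out$data[1, interior] - x[interior])), 0.01)

  dc <- bandpass(make_raw(rep(1, 10000), fs), 0.5, 100)
  expect_lt(max(abs(dc$data[1, ])), 1e-6)

  expect_error(bandpass(make_raw(x, fs), 0.5, 600), "Nyquist")
  expect_error(bandpass(make_raw(x, fs), 50, 10), "lo < hi")
})

test_that("band-pass attenuates out-of-band tones by more than 20 dB", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 150 * t)
  out <- bandpass(make_raw(x, fs), 0.5, 100)$data[1, ]
  pow_at <- function(sig, f0) {
    sp <- stats::spec.pgram(stats::ts(sig, frequency = fs), plot = FALSE,
                            taper = 0)
    sum(sp$spec[abs(sp$freq - f0) < 2])
  }
  expect_gt(10 * log10(pow_at(x, 150) / pow_at(out, 150)), 20)
})

test_that("resampling has the right length, fidelity and identity", {
  fs <- 1000
  t <- seq(0, 1.1 - 1 / fs, by = 1 / fs)  # 1100 samples = 1100 ms
  x <- sin(2 * pi * 3 * t)
  out <- resample_to(make_raw(x, fs), 200)
  expect_equal(ncol(out$data), 220)
  expect_equal(out$fs, 200)
  ref <- sin(2 * pi * 3 * (seq_len(220) - 1) / 200)
  expect_gt(cor(out$data[1, ], ref), 0.999)

  same <- resample_to(make_raw(x, fs), 1000)
  expect_identical(same$data[1, ], x)
  expect_error(resample_to(make_raw(x, fs), 2000), "downsampling")
})

test_that("resampling rescales event indices", {
  ev <- data.frame(sample = c(1, 501, 1000), label = "a")
  out <- resample_to(make_raw(rnorm(1000), 1000, events = ev), 200)
  expect_equal(out$events$sample, c(1, 101, 201))
})

test_that("epoching slices exactly around events and drops out-of-bounds", {
  fs <- 200
  x <- seq_len(600)  # ramp: values identify sample indices
  ev <- data.frame(sample = c(100, 300, 5), label = c("a", "b", "a"))
  expect_warning(
    ep <- epoch_segments(raw_recording(matrix(x, 1), fs, events = ev),
                         tmin_ms = -100, tmax_ms = 1000, baseline = FALSE),
    "dropped")
  expect_equal(dim(ep$data), c(2, 1, 221))
  expect_equal(ep$labels, c("a", "b"))
  expect_equal(ep$data[1, 1, ], x[80:300])  # copy semantics on the ramp
  expect_equal(epoch_times(ep)[1], -100)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  a <- array(rnorm(3 * 2 * 221) + 5, c(3, 2, 221))
  ep <- baseline_correct(epochs(a, 200, -100))
  tt <- epoch_times(ep)
  base_mean <- apply(ep$data[, , tt <= 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base_mean)), 1e-12)
})

test_that("peak-to-peak rejection removes exactly the offending trials", {
  a <- array(0, c(3, 1, 10))
  a[1, 1, ] <- c(rep(0, 9), 1)       # p2p 1
  a[2, 1, ] <- c(rep(0, 9), 5)       # p2p 5
  a[3, 1, ] <- c(rep(0, 9), 9)       # p2p 9
  ep <- epochs(a, 200, -10)
  res <- reject_peak_to_peak(ep, 6)
  expect_equal(res$n_rejected, 1)
  expect_equal(res$rejected, 3)
  expect_identical(res$epochs$data[1, , ], ep$data[1, , ])  # untouched

  expect_equal(reject_peak_to_peak(ep, Inf)$n_rejected, 0)
  expect_error(reject_peak_to_peak(ep, 0.5), "threshold")
})

test_that("rejection count matches planted spikes", {
  set.seed(51)
  n <- 40
  a <- array(rnorm(n * 2 * 50, sd = 0.1), c(n, 2, 50))
  spiked <- sample(n, 4)
  for (i in spiked) a[i, 1, 25] <- 10
  res <- reject_peak_to_peak(epochs(a, 200, -10), 5)
  expect_equal(res$n_rejected, 4)
  expect_setequal(res$rejected, spiked)
})

test_that("filter-resample-epoch matches the analytic reference on a tone", {
  fs <- 1000
  n <- 5000
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 8 * t)
  ev <- data.frame(sample = c(1500, 3000), label = "a")
  raw <- raw_recording(matrix(x, 1), fs, events = ev)
  ep <- epoch_segments(resample_to(bandpass(raw, 0.5, 100), 200),
                       tmin_ms = -100, tmax_ms = 1000, baseline = FALSE)
  # 8 Hz is deep in the passband: each epoch should be the analytically
  # resampled tone around its event time
  for (i in 1:2) {
    t_ep <- (ev$sample[i] - 1) / fs + epoch_times(ep) / 1000
    expect_gt(cor(ep$data[i, 1, ], sin(2 * pi * 8 * t_ep)), 0.995)
  }
})
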