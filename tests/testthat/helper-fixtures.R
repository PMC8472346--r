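# shared fixtures: all data built in code, deterministically

tone <- function(freq, fs = 200, dur = 2, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

# classic mode-mixing input: continuous 5 Hz tone plus an intermittent 40 Hz
# burst riding on it mid-epoch
mode_mixing_signal <- function(fs = 200, dur = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  list(t = t,
       tone = sin(2 * pi * 5 * t),
       burst = as.numeric(t >= 0.8 & t <= 1.2) * 0.4 * sin(2 * pi * 40 * t))
}

# independent extrema / zero-crossing counter (kept separate from the
# package's internal bookkeeping on purpose)
imf_count_deviation <- function(m) {
  d <- diff(sign(diff(m)))
  n_ext <- sum(d != 0)
  s <- sign(m)
  s <- s[s != 0]
  n_zc <- if (length(s) < 2) 0L else sum(diff(s) != 0)
  n_ext - n_zc
}

# brute-force AUC over all positive-negative pairs (ties count one half)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# small epochs object with a deterministic mean shift on one channel inside a
# sample window, for separability checks
shifted_epochs <- function(n_trials, n_chan, n_samp, shift = 0, window = NULL,
                           sd = 0.2, fs = 200, seed = 1, label = "a") {
  set.seed(seed)
  a <- array(stats::rnorm(n_trials * n_chan * n_samp, sd = sd),
             c(n_trials, n_chan, n_samp))
  if (!is.null(window) && shift != 0) a[, 1, window] <- a[, 1, window] + shift
  epochs(a, fs, tmin_ms = 0, labels = label)
}

# tiny simulation spec used where full study-scale conditions are overkill
small_spec <- function(...) {
  simulation_spec(n_participants = 3, n_sensors = 10,
                  n_trials_per_condition = 12, ...)
}
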