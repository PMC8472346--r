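#' @title Deterministic epoch preprocessing
#' @description Band-pass filtering (zero-phase IIR), anti-aliased
#'   resampling, epoch segmentation around events, baseline correction and
#'   peak-to-peak artifact rejection - the standard sensor-level chain
#'   applied before decomposition.
#' @name preprocess
NULL

#' Continuous multichannel recording
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate, Hz.
#' @param channel_ids Optional channel names.
#' @param events Data frame with columns `sample` (1-based sample index) and
#'   `label` (condition), or NULL.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, fs, channel_ids = NULL, events = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(channel_ids)) channel_ids <- sprintf("MEG%03d", seq_len(nrow(data)))
  if (!is.null(events)) {
    stopifnot(all(c("sample", "label") %in% names(events)))
    if (any(events$sample < 1 | events$sample > ncol(data))) {
      stop("event sample indices must lie within the recording", call. = FALSE)
    }
  }
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

apply_channelwise <- function(data, f) {
  t(apply(data, 1, f))
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the passband has unit gain, zero phase shift and
#' the DC component is removed. An FIR alternative (windowed-sinc, also
#' applied zero-phase) is selectable.
#'
#' @param raw A `raw_recording` (or `epochs`).
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @param type `"iir"` (default) or `"fir"`.
#' @param order Filter order (per direction).
#' @return The same class as the input, filtered.
#' @export
bandpass <- function(raw, lo, hi, type = c("iir", "fir"), order = 4) {
  type <- match.arg(type)
  fs <- raw$fs
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2) stop("upper edge ", hi, " Hz is at or above Nyquist (",
                         fs / 2, " Hz)", call. = FALSE)
  # cascade of high-pass and low-pass sections: a single transfer-function
  # band-pass with edges at 0.0005 and 0.2 of Nyquist is numerically
  # ill-conditioned, the cascade is not
  if (type == "iir") {
    hp <- signal::butter(order, lo / (fs / 2), type = "high")
    lp <- signal::butter(order, hi / (fs / 2), type = "low")
    # mean removal first: the DC offset is formally in the stopband but a
    # finite-window zero-phase pass leaves a visible transient of it
    run <- function(x) {
      signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))
    }
  } else {
    flt <- signal::fir1(max(order, 64), c(lo, hi) / (fs / 2), type = "pass")
    run <- function(x) signal::filtfilt(flt, x - mean(x))
  }
  if (inherits(raw, "epochs")) {
    d <- dim(raw$data)
    out <- raw
    for (i in seq_len(d[1])) {
      out$data[i, , ] <- apply_channelwise(matrix(raw$data[i, , ], d[2]), run)
    }
    return(out)
  }
  out <- raw
  out$data <- apply_channelwise(raw$data, run)
  out
}

#' Anti-aliased resampling
#'
#' Polyphase resampling (`signal::resample`) by the rational factor
#' `fs_new / fs`; event sample indices are rescaled accordingly. Resampling
#' to the current rate is the identity.
#'
#' @param raw A `raw_recording` or `epochs` object.
#' @param fs_new Target sampling rate in Hz (must divide into a rational
#'   ratio with the current rate; upsampling is refused).
#' @return Same class as input at the new rate.
#' @export
resample_to <- function(raw, fs_new) {
  fs <- raw$fs
  stopifnot(fs_new > 0)
  if (fs_new == fs) return(raw)
  if (fs_new > fs) stop("only downsampling is supported", call. = FALSE)
  frac <- MASS_fractions(fs_new / fs)
  p <- frac[1]; q <- frac[2]
  if (p == 1) {
    # integer decimation: zero-phase anti-alias IIR then subsample - smaller
    # edge transients than the polyphase FIR path
    aa <- signal::butter(8, 0.8 * fs_new / fs, type = "low")
    run <- function(x) signal::filtfilt(aa, x)[seq(1, length(x), by = q)]
  } else {
    run <- function(x) signal::resample(x, p, q)
  }
  out <- raw
  if (inherits(raw, "epochs")) {
    d <- dim(raw$data)
    n_new <- length(run(raw$data[1, 1, ]))
    nd <- array(0, c(d[1], d[2], n_new))
    for (i in seq_len(d[1])) {
      nd[i, , ] <- apply_channelwise(matrix(raw$data[i, , ], d[2]), run)
    }
    out$data <- nd
  } else {
    out$data <- apply_channelwise(raw$data, run)
    if (!is.null(raw$events)) {
      out$events <- raw$events
      out$events$sample <- pmax(1L, round((raw$events$sample - 1) * p / q) + 1L)
    }
  }
  out$fs <- fs_new
  out
}

# small rational approximation (continued fractions), enough for sample-rate
# ratios like 200/1000
MASS_fractions <- function(x, max_den = 10000, tol = 1e-9) {
  for (den in seq_len(max_den)) {
    num <- round(x * den)
    if (abs(num / den - x) < tol && num >= 1) return(c(num, den))
  }
  stop("sampling-rate ratio is not (nearly) rational", call. = FALSE)
}

#' Segment a continuous recording into epochs
#'
#' One trial per event, spanning `tmin_ms` to `tmax_ms` relative to the event
#' sample (both endpoints included: -100..1000 ms at 200 Hz gives 221
#' samples). Events whose window does not fit inside the recording are
#' dropped with a warning. Mean-baseline subtraction over the pre-stimulus
#' interval is on by default, since downstream decoding is offset-sensitive.
#'
#' @param raw A `raw_recording` with events.
#' @param tmin_ms,tmax_ms Epoch window in ms (tmin < 0 <= tmax).
#' @param baseline Subtract the per-trial, per-channel mean of the
#'   `tmin_ms..0` interval?
#' @param participant_id Stamped on the output.
#' @return An `epochs` object.
#' @export
epoch_segments <- function(raw, tmin_ms = -100, tmax_ms = 1000,
                           baseline = TRUE, participant_id = NA_character_) {
  stopifnot(inherits(raw, "raw_recording"), !is.null(raw$events),
            tmin_ms < 0, tmax_ms >= 0)
  fs <- raw$fs
  off_lo <- round(tmin_ms * fs / 1000)
  off_hi <- round(tmax_ms * fs / 1000)
  n_total <- ncol(raw$data)
  ok <- raw$events$sample + off_lo >= 1 & raw$events$sample + off_hi <= n_total
  if (!all(ok)) {
    warning(sum(!ok), " event(s) dropped: epoch window out of bounds",
            call. = FALSE)
  }
  ev <- raw$events[ok, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events fit within the recording", call. = FALSE)
  n_samp <- off_hi - off_lo + 1L
  data <- array(0, c(nrow(ev), nrow(raw$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample[i] + off_lo):(ev$sample[i] + off_hi)
    data[i, , ] <- raw$data[, idx]
  }
  ep <- epochs(data, fs, tmin_ms, ev$label, raw$channel_ids, participant_id)
  if (baseline) ep <- baseline_correct(ep) else ep
}

#' Baseline correction
#'
#' Subtracts the per-trial, per-channel mean over `window_ms` (default: the
#' full pre-stimulus interval).
#'
#' @param x An `epochs` object.
#' @param window_ms Length-2 window in ms.
#' @return Corrected `epochs`.
#' @export
baseline_correct <- function(x, window_ms = c(x$tmin_ms, 0)) {
  stopifnot(inherits(x, "epochs"))
  tt <- epoch_times(x)
  sel <- tt >= window_ms[1] & tt <= window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  mu <- apply(x$data[, , sel, drop = FALSE], c(1, 2), mean)
  x$data <- x$data - array(mu, dim(x$data))
  x
}

#' Peak-to-peak artifact rejection
#'
#' Removes every trial in which any channel's max-minus-min amplitude within
#' the trial exceeds `threshold`. Surviving trials are untouched.
#'
#' @param x An `epochs` object.
#' @param threshold Positive rejection threshold in channel units.
#' @return A list: `epochs` (survivors), `n_rejected`, `rejected` (indices).
#' @export
reject_peak_to_peak <- function(x, threshold) {
  stopifnot(inherits(x, "epochs"), is.numeric(threshold), threshold > 0)
  p2p <- apply(x$data, c(1, 2), function(v) max(v) - min(v))
  bad <- apply(p2p, 1, max) > threshold
  if (all(bad)) {
    stop("all trials exceed the peak-to-peak threshold (", threshold, ")",
         call. = FALSE)
  }
  keep <- which(!bad)
  out <- epochs(x$data[keep, , , drop = FALSE], x$fs, x$tmin_ms,
                x$labels[keep], x$channel_ids, x$participant_id)
  list(epochs = out, n_rejected = sum(bad), rejected = which(bad))
}

#' Remove externally identified ICA components (optional hook)
#'
#' The package never classifies components automatically: artifact
#' identification is a manual step. Given an externally computed unmixing
#' matrix and a list of component indices to drop, this reconstructs the
#' recording without them.
#'
#' @param raw A `raw_recording`.
#' @param unmixing Components x channels unmixing matrix.
#' @param drop Integer indices of components to remove.
#' @return The cleaned `raw_recording`.
#' @export
remove_ica_components <- function(raw, unmixing, drop) {
  stopifnot(inherits(raw, "raw_recording"),
            ncol(unmixing) == nrow(raw$data))
  sources <- unmixing %*% raw$data
  sources[drop, ] <- 0
  mixing <- solve(unmixing)
  out <- raw
  out$data <- mixing %*% sources
  out
}
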