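#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes the negative frequencies and doubles the positive ones in the DFT,
#' so the imaginary part of the result is the Hilbert transform of the input;
#' the real part is the input itself (restored exactly).
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
#' @examples
#' fs <- 200; t <- seq(0, 1, by = 1 / fs)
#' a <- analytic_signal(cos(2 * pi * 5 * t))
#' summary(Mod(a)[20:180])  # ~1 in the interior
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(a))
}

#' Instantaneous frequency and amplitude
#'
#' Amplitude is the modulus of the analytic signal; frequency is the central
#' difference of the unwrapped phase scaled to Hz (one-sided at the ends).
#' Negative instantaneous frequencies - spline-overshoot artifacts in EMD
#' modes - are set to `NA` and counted.
#'
#' @param a Complex analytic signal (see [analytic_signal()]).
#' @param fs Sampling rate in Hz.
#' @return A list with numeric vectors `freq` (Hz, `NA` where undefined or
#'   negative), `amp`, and `n_negative` (count of clipped negative-frequency
#'   samples).
#' @export
inst_freq_amp <- function(a, fs) {
  stopifnot(is.complex(a), fs > 0)
  n <- length(a)
  amp <- Mod(a)
  if (all(amp == 0)) {
    return(list(freq = rep(NA_real_, n), amp = amp, n_negative = 0L))
  }
  phase <- signal::unwrap(Arg(a))
  dphi <- numeric(n)
  if (n >= 3) {
    dphi[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
    dphi[1] <- phase[2] - phase[1]
    dphi[n] <- phase[n] - phase[n - 1]
  } else if (n == 2) {
    dphi[] <- phase[2] - phase[1]
  }
  freq <- dphi * fs / (2 * pi)
  neg <- is.finite(freq) & freq < 0
  freq[neg] <- NA_real_
  list(freq = freq, amp = amp, n_negative = sum(neg))
}

new_hilbert_spectrum <- function(freq, energy, meta = list()) {
  structure(list(freq = freq, energy = energy, meta = meta),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d bins, %g-%g Hz, total energy %.4g\n",
              length(x$freq), min(x$freq), max(x$freq), sum(x$energy)))
  if (sum(x$energy) > 0) {
    cat(sprintf("  dominant frequency: %g Hz\n", dominant_frequency(x)))
  }
  invisible(x)
}

#' Marginal Hilbert energy spectrum
#'
#' Accumulates squared instantaneous amplitude into instantaneous-frequency
#' bins over one or many signals (rows of a matrix, or one IMF component of
#' an `imf_epochs` stack, over all trials and channels). The first and last
#' `edge_trim` fraction of each signal is excluded - EMD's spline envelopes
#' distort epoch edges - as are samples with negative or out-of-range
#' instantaneous frequency. Within the retained samples energy is conserved:
#' the bin totals sum to the accumulated amplitude-squared.
#'
#' @param x Numeric vector, signals-in-rows matrix, or `imf_epochs`.
#' @param fs Sampling rate in Hz (taken from `x` for `imf_epochs`).
#' @param imf For `imf_epochs` input: which 1-based component to pool.
#' @param label Optional condition filter for `imf_epochs` input.
#' @param bin_width Frequency bin width in Hz.
#' @param f_max Upper edge of the frequency grid in Hz.
#' @param edge_trim Fraction of samples trimmed from each end of every signal.
#' @return A `hilbert_spectrum`: bin-centre frequencies, per-bin energy
#'   (a.u.), and metadata incl. the count of dropped negative-frequency
#'   samples.
#' @export
marginal_spectrum <- function(x, fs = NULL, imf = NULL, label = NULL,
                              bin_width = 0.25, f_max = 100,
                              edge_trim = 0.05) {
  if (inherits(x, "imf_epochs")) {
    stopifnot(!is.null(imf))
    ep <- imf_component(x, imf)
    if (!is.null(label)) ep <- filter_epochs(ep, label)
    d <- dim(ep$data)
    x <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = d[1] * d[2], byrow = TRUE)
    fs <- ep$fs
  } else if (inherits(x, "epochs")) {
    if (!is.null(label)) x <- filter_epochs(x, label)
    d <- dim(x$data)
    fs <- x$fs
    x <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[1] * d[2], byrow = TRUE)
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.numeric(fs), fs > 0)
  # bin centres on integer multiples of bin_width, so canonical rhythm
  # frequencies (1, 3, 7 Hz, ...) sit at a centre rather than on an edge
  edges <- seq(-bin_width / 2, f_max + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  energy <- numeric(length(centers))
  n_neg <- 0L
  if (nrow(x) > 0 && ncol(x) > 0) {
    n <- ncol(x)
    trim <- floor(edge_trim * n)
    keep <- seq.int(trim + 1, n - trim)
    for (i in seq_len(nrow(x))) {
      fa <- inst_freq_amp(analytic_signal(x[i, ]), fs)
      n_neg <- n_neg + fa$n_negative
      f <- fa$freq[keep]
      e <- fa$amp[keep]^2
      ok <- is.finite(f) & f >= 0 & f <= f_max
      if (!any(ok)) next
      b <- findInterval(f[ok], edges, rightmost.closed = TRUE)
      acc <- rowsum(e[ok], b)
      energy[as.integer(rownames(acc))] <-
        energy[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  new_hilbert_spectrum(centers, energy,
                       meta = list(bin_width = bin_width, f_max = f_max,
                                   edge_trim = edge_trim, fs = fs,
                                   n_negative_dropped = n_neg,
                                   imf = imf, label = label))
}

#' Dominant frequency of a marginal spectrum
#'
#' Centre of the maximum-energy bin; exact ties are broken toward the lower
#' frequency.
#'
#' @param spec A `hilbert_spectrum`.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spec) {
  stopifnot(inherits(spec, "hilbert_spectrum"))
  if (length(spec$energy) == 0 || all(spec$energy == 0)) {
    stop("spectrum has no energy; dominant frequency undefined", call. = FALSE)
  }
  spec$freq[which.max(spec$energy)]  # freq ascending => ties -> lower bin
}

#' @export
#' @rdname tidy.imf_set
tidy.hilbert_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, energy = x$energy)
}

#' Write a marginal spectrum as TSV plus JSON metadata
#'
#' @param x A `hilbert_spectrum`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "hilbert_spectrum"))
  utils::write.table(tidy.hilbert_spectrum(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(x$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
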