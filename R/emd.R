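#' @title Empirical mode decomposition (plain and masking)
#' @description Single-channel EMD: the sifting loop that extracts one
#'   intrinsic mode function (IMF), plain EMD into a fixed number of modes
#'   plus a residual trend, and masking EMD, which steers each mode toward a
#'   dyadic frequency band by sifting the signal with added mask sinusoids at
#'   several phases and averaging, mitigating mode mixing.
#' @name emd-core
NULL

# Local extrema of a discrete series. Strict sign changes of the first
# difference; flat plateaus (measure zero for continuous-valued data) are
# collapsed to their first sample.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the previous non-zero difference across plateaus
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  s_filled <- s
  if (!all(nz)) {
    idx <- cumsum(nz)
    s_nz <- s[nz]
    s_filled <- ifelse(idx == 0, 0, s_nz[pmax(idx, 1)])
  }
  ds <- diff(s_filled)
  maxima <- which(ds < 0) + 1L
  minima <- which(ds > 0) + 1L
  list(maxima = maxima, minima = minima)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Envelope through the given extrema, extended by mirroring up to two edge
# extrema across each boundary so the spline is anchored beyond the signal.
envelope_through <- function(idx, val, n) {
  k <- length(idx)
  left_i <- 2 - idx[seq_len(min(2, k))]          # reflect about sample 1
  left_v <- val[seq_len(min(2, k))]
  right_sel <- seq.int(max(1, k - 1), k)
  right_i <- 2 * n - idx[right_sel]              # reflect about sample n
  right_v <- val[right_sel]
  xs <- c(rev(left_i), idx, rev(right_i))
  ys <- c(rev(left_v), val, rev(right_v))
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  o <- order(xs)
  stats::spline(xs[o], ys[o], xout = seq_len(n), method = "natural")$y
}

#' Extract one intrinsic mode function by sifting
#'
#' Iteratively subtracts the mean of the upper and lower cubic-spline
#' envelopes (through local maxima and minima, edge-extended by mirroring the
#' two outermost extrema) until the S-number stopping rule is met: the counts
#' of extrema and zero crossings differ by at most one and have stayed
#' unchanged for `s_number` consecutive iterations.
#'
#' @param x Numeric vector (finite, length >= 8 for a meaningful result).
#' @param s_number Consecutive-iteration count for the stopping rule.
#' @param max_sift Hard cap on sifting iterations.
#' @return A list with `imf` (the extracted mode; equal to `x` when the input
#'   is monotone or has too few extrema), `monotone` (flag: no oscillatory
#'   mode could be extracted), and `n_sift`.
#' @export
#' @examples
#' fs <- 200; t <- seq(0, 2, by = 1 / fs)
#' m <- sift(sin(2 * pi * 5 * t) + 0.1 * t)
#' m$n_sift
sift <- function(x, s_number = 4, max_sift = 100) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  h <- x
  prev_counts <- NULL
  stable <- 0L
  h_valid <- NULL  # last iterate satisfying the IMF count property
  for (it in seq_len(max_sift)) {
    ext <- find_extrema(h)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) {
      # monotone (or near-monotone) remainder: nothing left to sift
      return(list(imf = h, monotone = TRUE, n_sift = it - 1L))
    }
    upper <- envelope_through(ext$maxima, h[ext$maxima], n)
    lower <- envelope_through(ext$minima, h[ext$minima], n)
    h <- h - (upper + lower) / 2
    ne <- length(find_extrema(h)$maxima) + length(find_extrema(h)$minima)
    nz <- count_zero_crossings(h)
    if (abs(ne - nz) <= 1) h_valid <- h
    if (abs(ne - nz) <= 1 && !is.null(prev_counts) &&
        all(c(ne, nz) == prev_counts)) {
      stable <- stable + 1L
      if (stable >= s_number) {
        return(list(imf = h, monotone = FALSE, n_sift = it))
      }
    } else {
      stable <- 0L
    }
    prev_counts <- c(ne, nz)
  }
  # iteration budget exhausted (the count criterion can cycle): fall back to
  # the most recent iterate that satisfied the IMF count property
  list(imf = if (is.null(h_valid)) h else h_valid, monotone = FALSE,
       n_sift = max_sift)
}

new_imf_set <- function(imfs, residual, fs, x, meta = list()) {
  structure(
    list(imfs = imfs, residual = residual, fs = fs, input = x, meta = meta),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, %d samples @ %g Hz (%s)\n",
              nrow(x$imfs), ncol(x$imfs), x$fs,
              if (isTRUE(x$meta$masking)) "masking EMD" else "plain EMD"))
  invisible(x)
}

#' Plain empirical mode decomposition
#'
#' Repeatedly sifts and subtracts, producing up to `n_imfs - 1` oscillatory
#' modes; whatever remains (at latest after `n_imfs - 1` modes, earlier if the
#' remainder turns monotone) is stored as the residual trend, so mode
#' `n_imfs` of the conventional numbering is the residual. The decomposition
#' is complete by construction: input = sum of IMFs + residual.
#'
#' @param x Numeric vector.
#' @param n_imfs Total number of components including the residual trend.
#' @param fs Sampling rate in Hz (metadata only for plain EMD).
#' @inheritParams sift
#' @return An `imf_set`: `imfs` is an (`n_imfs - 1`) x samples matrix (rows
#'   beyond the last extractable mode are zero), `residual` the trend.
#' @export
emd <- function(x, n_imfs = 8, fs = 200, s_number = 4, max_sift = 100) {
  stopifnot(is.numeric(x), all(is.finite(x)), n_imfs >= 2)
  n <- length(x)
  imfs <- matrix(0, n_imfs - 1, n)
  r <- x
  extracted <- 0L
  for (k in seq_len(n_imfs - 1)) {
    s <- sift(r, s_number = s_number, max_sift = max_sift)
    if (s$monotone) break
    imfs[k, ] <- s$imf
    r <- r - s$imf
    extracted <- k
  }
  new_imf_set(imfs, r, fs, x,
              meta = list(masking = FALSE, n_extracted = extracted))
}

#' Masking empirical mode decomposition
#'
#' For each mode k a mask sinusoid at the dyadic frequency
#' `f_mask(k) = fs / 2^(k + 1)` and amplitude `amp_factor` times the SD of the
#' current working signal is added at `n_phases` equispaced phases; each
#' masked signal is sifted and the first IMFs are averaged (the mask terms sum
#' to zero across phases), steering mode k toward the band between
#' consecutive mask frequencies and suppressing mode mixing from intermittent
#' oscillations. The phase-averaged candidate is passed through one final
#' plain sift so every returned mode satisfies the IMF extrema/zero-crossing
#' property (averaging alone leaves micro-ripples that violate it). An
#' alternative schedule sets each mask frequency from the amplitude-weighted
#' mean instantaneous frequency of the previous mode.
#'
#' @inheritParams emd
#' @param mask_freqs Optional explicit vector of mask frequencies in Hz, one
#'   per oscillatory mode (recycled/truncated); overrides `schedule`.
#' @param schedule `"dyadic"` (default) or `"adaptive"` (mean instantaneous
#'   frequency of the previous IMF, halved).
#' @param amp_factor Mask amplitude as a multiple of the working signal's SD.
#' @param n_phases Number of mask phases averaged over.
#' @return An `imf_set` (see [emd()]).
#' @export
#' @examples
#' fs <- 200; t <- seq(0, 2, by = 1 / fs)
#' dec <- masking_emd(sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t), fs = fs)
#' dec
masking_emd <- function(x, n_imfs = 8, fs = 200, mask_freqs = NULL,
                        schedule = c("dyadic", "adaptive"), amp_factor = 2,
                        n_phases = 4, s_number = 4, max_sift = 100) {
  stopifnot(is.numeric(x), all(is.finite(x)), n_imfs >= 2, fs > 0)
  schedule <- match.arg(schedule)
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  if (!is.null(mask_freqs)) {
    if (any(mask_freqs >= fs / 2)) {
      stop("mask frequency at or above Nyquist (", fs / 2, " Hz)",
           call. = FALSE)
    }
    mask_freqs <- rep_len(mask_freqs, n_imfs - 1)
  }
  imfs <- matrix(0, n_imfs - 1, n)
  r <- x
  extracted <- 0L
  f_prev <- NA_real_
  used_freqs <- rep(NA_real_, n_imfs - 1)
  for (k in seq_len(n_imfs - 1)) {
    f_k <- if (!is.null(mask_freqs)) {
      mask_freqs[k]
    } else if (schedule == "dyadic" || k == 1 || !is.finite(f_prev)) {
      fs / 2^(k + 1)
    } else {
      f_prev / 2
    }
    a_k <- amp_factor * stats::sd(r)
    ext <- find_extrema(r)
    if (a_k == 0 || length(ext$maxima) < 2 || length(ext$minima) < 2) break
    acc <- numeric(n)
    monotone_all <- TRUE
    for (p in seq_len(n_phases)) {
      phase <- 2 * pi * (p - 1) / n_phases
      m <- a_k * sin(2 * pi * f_k * tt + phase)
      s <- sift(r + m, s_number = s_number, max_sift = max_sift)
      if (!s$monotone) monotone_all <- FALSE
      acc <- acc + (s$imf - m)
    }
    if (monotone_all) break
    # polishing sift: restore the IMF extrema/zero-crossing property that
    # phase averaging perturbs
    pol <- sift(acc / n_phases, s_number = s_number, max_sift = max_sift)
    imf_k <- pol$imf
    if (pol$monotone) break
    imfs[k, ] <- imf_k
    r <- r - imf_k
    extracted <- k
    used_freqs[k] <- f_k
    if (schedule == "adaptive") {
      a <- analytic_signal(imf_k)
      fr <- inst_freq_amp(a, fs)
      w <- fr$amp^2
      ok <- is.finite(fr$freq) & fr$freq > 0
      f_prev <- if (any(ok)) sum(fr$freq[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
  }
  new_imf_set(imfs, r, fs, x,
              meta = list(masking = TRUE, n_extracted = extracted,
                          mask_freqs = used_freqs, amp_factor = amp_factor,
                          n_phases = n_phases, schedule = schedule))
}

#' Reconstruct the input from a decomposition
#'
#' @param x An `imf_set`.
#' @return Numeric vector: column sums of the IMFs plus the residual.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  colSums(x$imfs) + x$residual
}

#' Long-format view of an IMF decomposition
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return A tibble with columns `component` (`"IMF1"` ... and
#'   `"residual"`), `imf` (integer index, residual = n_imfs), `time_s`,
#'   `value`.
#' @export
tidy.imf_set <- function(x, ...) {
  n <- ncol(x$imfs)
  k <- nrow(x$imfs)
  tt <- (seq_len(n) - 1) / x$fs
  tibble::tibble(
    component = rep(c(sprintf("IMF%d", seq_len(k)), "residual"), each = n),
    imf = rep(c(seq_len(k), k + 1L), each = n),
    time_s = rep(tt, k + 1),
    value = c(as.vector(t(x$imfs)), x$residual)
  )
}

#' Decompose every trial and channel of an epochs object
#'
#' Applies [masking_emd()] (or plain [emd()]) independently to each
#' trial x channel series, yielding a component-indexed stack of epochs.
#' Component numbering is 1-based; component `n_imfs` is the residual trend
#' and is excluded when `drop_residual = TRUE` (the usual analysis path keeps
#' the oscillatory modes only).
#'
#' @param x An `epochs` object.
#' @param n_imfs Total components including the residual.
#' @param method `"masking"` (default) or `"plain"`.
#' @param drop_residual Drop the residual trend component?
#' @param ... Passed on to [masking_emd()] / [emd()].
#' @return An `imf_epochs` object: `data` is a components x trials x
#'   channels x samples array plus the metadata of the input epochs and
#'   `imf_index` (the 1-based component numbers retained).
#' @export
decompose_epochs <- function(x, n_imfs = 8, method = c("masking", "plain"),
                             drop_residual = TRUE, ...) {
  stopifnot(inherits(x, "epochs"))
  method <- match.arg(method)
  d <- dim(x$data)
  n_comp <- if (drop_residual) n_imfs - 1L else n_imfs
  out <- array(0, c(n_comp, d))
  failed <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      sig <- x$data[i, j, ]
      dec <- tryCatch(
        if (method == "masking") masking_emd(sig, n_imfs, fs = x$fs, ...)
        else emd(sig, n_imfs, fs = x$fs, ...),
        error = function(e) NULL
      )
      if (is.null(dec)) {
        warning(sprintf("decomposition failed for trial %d channel %d", i, j),
                call. = FALSE)
        failed[i, j] <- TRUE
        next
      }
      comps <- rbind(dec$imfs, dec$residual)
      out[, i, j, ] <- comps[seq_len(n_comp), ]
    }
  }
  structure(
    list(data = out, fs = x$fs, tmin_ms = x$tmin_ms, labels = x$labels,
         channel_ids = x$channel_ids, participant_id = x$participant_id,
         imf_index = seq_len(n_comp), n_imfs = n_imfs, method = method,
         drop_residual = drop_residual, failed = failed),
    class = "imf_epochs"
  )
}

#' @export
print.imf_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<imf_epochs> %d components x %d trials x %d channels x %d samples @ %g Hz (%s EMD)\n",
    d[1], d[2], d[3], d[4], x$fs, x$method))
  invisible(x)
}

#' Extract one IMF component as an epochs object
#'
#' @param x An `imf_epochs` object.
#' @param imf 1-based component number (the paper-style IMF index).
#' @return An `epochs` object holding that component.
#' @export
imf_component <- function(x, imf) {
  stopifnot(inherits(x, "imf_epochs"))
  k <- match(imf, x$imf_index)
  if (is.na(k)) stop("component IMF", imf, " not present", call. = FALSE)
  epochs(array(x$data[k, , , ], dim(x$data)[-1]), x$fs, x$tmin_ms,
         x$labels, x$channel_ids, x$participant_id)
}
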