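#' @title Simplified minimum-norm source estimation with dSPM
#' @description L2 minimum-norm inverse of a (toy or externally supplied)
#'   lead field with optional dSPM noise normalisation and region-of-interest
#'   time-course extraction. Fixed source orientation, identity source
#'   covariance, no depth weighting - adequate for the package's toy patch
#'   geometry; a precomputed gain matrix from real anatomy can be supplied
#'   in its place.
#' @name inverse
NULL

#' Estimate a noise covariance from noise segments
#'
#' Empirical covariance of the concatenated segments, shrunk toward its
#' diagonal: `(1 - w) C + w diag(C)`.
#'
#' @param segments `epochs` object, trials x channels x samples array, or a
#'   channels x samples matrix of noise (e.g. empty-room or pre-stimulus
#'   data).
#' @param shrinkage Shrinkage weight `w` in `[0, 1]`.
#' @return A `noise_covariance`: `cov` (channels x channels),
#'   `n_samples_used`, `regularization`.
#' @export
estimate_noise_cov <- function(segments, shrinkage = 0.05) {
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  if (inherits(segments, "epochs")) segments <- segments$data
  X <- if (is.matrix(segments)) {
    segments
  } else {
    stopifnot(length(dim(segments)) == 3, dim(segments)[1] >= 2)
    d <- dim(segments)
    matrix(aperm(segments, c(2, 1, 3)), d[2])
  }
  C <- stats::cov(t(X))
  Cs <- (1 - shrinkage) * C + shrinkage * diag(diag(C), nrow(C))
  ev <- eigen(Cs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 && shrinkage == 0) {
    warning("noise covariance is rank deficient; consider shrinkage > 0",
            call. = FALSE)
  }
  structure(list(cov = Cs, n_samples_used = ncol(X),
                 regularization = shrinkage),
            class = "noise_covariance")
}

#' Assemble a minimum-norm inverse operator
#'
#' Computes the L2 minimum-norm kernel `M = R G' (G R G' + lambda2 C)^-1`
#' with identity source covariance `R` (fixed orientation, no depth
#' weighting), plus the per-source dSPM normalisation
#' `sqrt(diag(M C M'))` - the noise sensitivity of each source estimate.
#'
#' @param G A `lead_field` or a sensors x sources gain matrix.
#' @param C A `noise_covariance` or a sensors x sensors matrix.
#' @param lambda2 Regularisation parameter (default 1/9, the SNR = 3
#'   convention when gain and noise are on comparable scales).
#' @return An `inverse_operator`: `kernel` (sources x sensors), `dspm_norm`,
#'   `lambda2`, `source_labels`.
#' @export
make_inverse <- function(G, C, lambda2 = 1 / 9) {
  source_labels <- NULL
  if (inherits(G, "lead_field")) {
    source_labels <- G$source_labels
    G <- G$gain
  }
  if (inherits(C, "noise_covariance")) C <- C$cov
  stopifnot(is.matrix(G), is.matrix(C), nrow(G) == nrow(C), lambda2 >= 0)
  A <- tcrossprod(G) + lambda2 * C
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("(G G' + lambda2 C) is singular; use lambda2 > 0 or a ",
         "non-degenerate noise covariance", call. = FALSE)
  })
  M <- t(G) %*% Ainv
  dspm_norm <- sqrt(rowSums((M %*% C) * M))
  if (any(!is.finite(dspm_norm)) || any(dspm_norm <= 0)) {
    stop("non-positive dSPM normalisation; check the noise covariance",
         call. = FALSE)
  }
  structure(list(kernel = M, dspm_norm = dspm_norm, lambda2 = lambda2,
                 source_labels = source_labels),
            class = "inverse_operator")
}

#' Apply an inverse operator
#'
#' `s(t) = M x(t)` per trial (or on a single evoked matrix); with
#' `normalize = TRUE` each source row is divided by its dSPM noise
#' sensitivity, giving noise-normalised (z-like) activations.
#'
#' @param x An `epochs` object or a channels x samples matrix.
#' @param inv An `inverse_operator`.
#' @param normalize Apply dSPM normalisation?
#' @return For matrix input a `source_estimate` (sources x samples); for
#'   epochs a list of class `source_epochs` with `data` (trials x sources x
#'   samples) sharing the epochs metadata.
#' @export
apply_inverse <- function(x, inv, normalize = TRUE) {
  stopifnot(inherits(inv, "inverse_operator"))
  M <- inv$kernel
  if (normalize) M <- M / inv$dspm_norm
  if (is.matrix(x)) {
    if (ncol(M) != nrow(x)) {
      stop("channel mismatch: inverse expects ", ncol(M), " channels, got ",
           nrow(x), call. = FALSE)
    }
    return(structure(list(data = M %*% x, source_labels = inv$source_labels,
                          normalized = normalize),
                     class = "source_estimate"))
  }
  stopifnot(inherits(x, "epochs"))
  if (ncol(M) != n_channels(x)) {
    stop("channel mismatch: inverse expects ", ncol(M), " channels, got ",
         n_channels(x), " (", paste(utils::head(x$channel_ids, 5),
                                    collapse = ", "), " ...)", call. = FALSE)
  }
  d <- dim(x$data)
  out <- array(0, c(d[1], nrow(M), d[3]))
  for (i in seq_len(d[1])) out[i, , ] <- M %*% matrix(x$data[i, , ], d[2])
  structure(list(data = out, fs = x$fs, tmin_ms = x$tmin_ms,
                 labels = x$labels, source_labels = inv$source_labels,
                 participant_id = x$participant_id, normalized = normalize),
            class = "source_epochs")
}

#' Region-of-interest time courses
#'
#' Reduces the member sources of each ROI at every timepoint, either by the
#' plain mean or by the mean of absolute values (sign-insensitive, the usual
#' choice for minimum-norm amplitudes whose polarity is arbitrary).
#'
#' @param stc A `source_estimate` (matrix path) or `source_epochs`.
#' @param rois Named list of integer source-index vectors (or source-label
#'   vectors when the estimate carries labels).
#' @param reduce `"mean"` or `"abs-mean"`.
#' @return For a `source_estimate`: ROIs x samples matrix. For
#'   `source_epochs`: an `epochs` object whose "channels" are the ROIs,
#'   directly consumable by the decoding stage.
#' @export
roi_timecourse <- function(stc, rois, reduce = c("mean", "abs-mean")) {
  reduce <- match.arg(reduce)
  stopifnot(length(rois) >= 1, !is.null(names(rois)))
  resolve <- function(members, labels, n_src) {
    if (is.character(members)) {
      idx <- match(members, labels)
      if (anyNA(idx)) stop("unknown source label(s): ",
                           paste(members[is.na(idx)], collapse = ", "),
                           call. = FALSE)
      idx
    } else {
      if (length(members) == 0 || any(members < 1 | members > n_src)) {
        stop("ROI indices out of range or empty", call. = FALSE)
      }
      as.integer(members)
    }
  }
  red <- function(block) {  # sources x samples
    if (reduce == "abs-mean") block <- abs(block)
    colMeans(block)
  }
  if (inherits(stc, "source_estimate")) {
    n_src <- nrow(stc$data)
    out <- t(vapply(rois, function(m) {
      red(stc$data[resolve(m, stc$source_labels, n_src), , drop = FALSE])
    }, numeric(ncol(stc$data))))
    rownames(out) <- names(rois)
    return(out)
  }
  stopifnot(inherits(stc, "source_epochs"))
  d <- dim(stc$data)
  out <- array(0, c(d[1], length(rois), d[3]))
  for (r in seq_along(rois)) {
    idx <- resolve(rois[[r]], stc$source_labels, d[2])
    for (i in seq_len(d[1])) {
      out[i, r, ] <- red(matrix(stc$data[i, idx, ], length(idx)))
    }
  }
  epochs(out, stc$fs, stc$tmin_ms, stc$labels, names(rois),
         stc$participant_id)
}
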