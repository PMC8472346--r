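#' @title Group-level inference on effect time series
#' @description One-sample t statistics per timepoint, Bonferroni
#'   correction, and the cluster-based sign-flip permutation test used to
#'   assess decoding time courses (per-participant AUC minus chance) at the
#'   group level.
#' @name group-stats
NULL

#' Per-timepoint one-sample t statistics
#'
#' @param effect Participants x timepoints numeric matrix.
#' @param mu0 Null value subtracted from each column mean.
#' @return Numeric vector of t values (df = participants - 1). Columns with
#'   zero SD yield `Inf` (signed) with a warning.
#' @export
one_sample_t <- function(effect, mu0 = 0) {
  stopifnot(is.matrix(effect), nrow(effect) >= 2)
  n <- nrow(effect)
  m <- colMeans(effect) - mu0
  s <- sqrt((colSums(effect^2) - n * colMeans(effect)^2) / (n - 1))
  if (any(s == 0)) {
    if (any(s == 0 & m != 0)) {
      warning("zero SD at ", sum(s == 0 & m != 0),
              " timepoint(s); t set to +/-Inf", call. = FALSE)
    }
    out <- m / (s / sqrt(n))
    out[s == 0] <- sign(m[s == 0]) * Inf
    out[s == 0 & m == 0] <- 0
    return(out)
  }
  m / (s / sqrt(n))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise; with the default `m` this is
#' `p.adjust(p, "bonferroni")`.
#'
#' @param p Vector of p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  if (m == length(p)) stats::p.adjust(p, method = "bonferroni")
  else pmin(1, m * p)
}

# maximal runs of TRUE; returns start/end index pairs
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

max_cluster_mass <- function(tvals, thresh, tail) {
  best <- 0
  pos <- runs_of(tvals > thresh)
  if (nrow(pos)) {
    best <- max(vapply(seq_len(nrow(pos)), function(i)
      sum(tvals[pos[i, 1]:pos[i, 2]]), 0))
  }
  if (tail == "two") {
    neg <- runs_of(tvals < -thresh)
    if (nrow(neg)) {
      best <- max(best, max(vapply(seq_len(nrow(neg)), function(i)
        -sum(tvals[neg[i, 1]:neg[i, 2]]), 0)))
    }
  }
  best
}

#' Cluster-based sign-flip permutation test
#'
#' Thresholds the observed group t series at `t_thresh`, forms maximal
#' contiguous supra-threshold clusters and sums the t values in each
#' (cluster mass). The null distribution of the maximal cluster mass is built
#' by flipping the sign of each participant's entire (mean-centred) series
#' independently with probability one half, `n_perm` times; each cluster's
#' p-value is `(1 + #(null max >= mass)) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`. One-tailed by default (positive
#' effects); `tail = "two"` also forms negative clusters and compares
#' absolute masses.
#'
#' @param effect Participants x timepoints matrix (e.g. AUC time courses).
#' @param mu0 Chance level subtracted before testing (0.5 for AUC).
#' @param t_thresh Cluster-forming t threshold.
#' @param n_perm Number of sign-flip permutations.
#' @param alpha Significance level for flagging clusters.
#' @param tail `"one"` or `"two"`.
#' @param seed Integer seed for the sign flips.
#' @param times_ms Optional per-timepoint times (ms) used in the cluster
#'   table; defaults to the sample index.
#' @return A `cluster_result`: tibble of clusters (`start_ms`, `end_ms`,
#'   `mass`, `p`, `significant`), the observed `t_series`, and `params`.
#' @export
cluster_permutation <- function(effect, mu0 = 0, t_thresh = 2, n_perm = 1000,
                                alpha = 0.05, tail = c("one", "two"),
                                seed = 1, times_ms = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(effect), nrow(effect) >= 2)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  X <- effect - mu0
  n <- nrow(X)
  n_t <- ncol(X)
  if (is.null(times_ms)) times_ms <- seq_len(n_t)
  t_obs <- one_sample_t(X, 0)

  # observed clusters; mass keeps the sign of its cluster
  collect <- function(mask) {
    rr <- runs_of(mask)
    if (!nrow(rr)) return(NULL)
    data.frame(start = rr[, 1], end = rr[, 2],
               mass = vapply(seq_len(nrow(rr)), function(i)
                 sum(t_obs[rr[i, 1]:rr[i, 2]]), 0))
  }
  cl <- collect(t_obs > t_thresh)
  if (tail == "two") cl <- rbind(cl, collect(t_obs < -t_thresh))

  # permutation null of the maximal cluster mass (vectorised t recompute:
  # sign flips leave column sums of squares unchanged)
  old <- .Random.seed_save()
  set.seed(as.integer(seed %% .Machine$integer.max))
  S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  .Random.seed_restore(old)
  ssq <- colSums(X^2)
  M <- crossprod(S, X) / n                        # n_perm x n_t means
  V <- sweep(-(n * M^2), 2, ssq, "+") / (n - 1)   # per-perm variances
  Tn <- M / sqrt(V / n)
  Tn[!is.finite(Tn)] <- 0
  null_max <- vapply(seq_len(n_perm), function(i)
    max_cluster_mass(Tn[i, ], t_thresh, tail), 0)

  clusters <- if (is.null(cl) || nrow(cl) == 0) {
    tibble::tibble(start_idx = integer(0), end_idx = integer(0),
                   start_ms = numeric(0), end_ms = numeric(0),
                   mass = numeric(0), p = numeric(0), significant = logical(0))
  } else {
    p <- vapply(abs(cl$mass), function(m)
      (1 + sum(null_max >= m)) / (n_perm + 1), 0)
    tibble::tibble(start_idx = cl$start, end_idx = cl$end,
                   start_ms = times_ms[cl$start], end_ms = times_ms[cl$end],
                   mass = cl$mass, p = p, significant = p < alpha)
  }
  structure(
    list(clusters = clusters, t_series = t_obs, times_ms = times_ms,
         null_max = null_max,
         params = list(t_thresh = t_thresh, n_perm = n_perm, alpha = alpha,
                       tail = tail, seed = seed, mu0 = mu0,
                       n_participants = n)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d significant (alpha %g, %d permutations)\n",
              nrow(x$clusters), sum(x$clusters$significant),
              x$params$alpha, x$params$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Cluster table
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The tibble of clusters (one row per cluster).
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' One-row summary of a cluster permutation test
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble: number of clusters, number significant, minimum p (NA
#'   when no clusters), test parameters.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    t_thresh = x$params$t_thresh,
    n_perm = x$params$n_perm,
    alpha = x$params$alpha,
    tail = x$params$tail
  )
}

#' Write a cluster table as TSV (+ JSON parameters)
#'
#' @param x A `cluster_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_result"))
  utils::write.table(x$clusters, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(x$params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
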