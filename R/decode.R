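#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' score outranks a random negative one, with ties counting one half.
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1 (or two-level) class labels, positive = 1 / second
#'   level.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(3, 1, 2, 5, 4), c(1, 0, 0, 1, 1))  # 5/6
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# stratified fold assignment: within each class, shuffle and deal out folds
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop("condition '", cl, "' has ", length(idx),
           " trials; need at least n_folds = ", n_folds, call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

fit_ridge_logistic <- function(X, y, lambda) {
  # glmnet advises against single-lambda fits and tiny classes; both are
  # deliberate here (fixed penalty, small CV folds)
  withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE, intercept = TRUE),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations|one single lambda",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Time-resolved two-condition decoding
#'
#' For each timepoint, the feature vector is the value of every channel at
#' that timepoint. Trials of the two conditions are shuffled once into
#' `n_folds` stratified subsets (seeded); each subset serves once as the test
#' set for an L2-regularised logistic-regression classifier (ridge penalty,
#' maximum-likelihood logistic loss) trained on the remaining subsets, with
#' feature standardisation fitted on the training folds only. The reported
#' score per timepoint is the mean over folds of the held-out-fold ROC AUC
#' (`pooled = TRUE` instead pools all held-out scores into a single AUC).
#'
#' @param epochs_a,epochs_b `epochs` objects for the two conditions (same
#'   channels and time axis).
#' @param n_folds Number of CV subsets (each condition needs at least this
#'   many trials).
#' @param seed Integer seed for the fold shuffle.
#' @param lambda Ridge penalty passed to `glmnet`; default `1 / n_train`,
#'   the inverse-regularisation-strength-1 convention.
#' @param pooled Pool held-out scores instead of averaging fold AUCs.
#' @param timepoints Optional integer subset of sample indices to decode.
#' @return Numeric vector of AUC per (decoded) timepoint, with attributes
#'   `time_ms`, `n_folds`, `seed`.
#' @export
time_resolved_decode <- function(epochs_a, epochs_b, n_folds = 30, seed = 1,
                                 lambda = NULL, pooled = FALSE,
                                 timepoints = NULL) {
  stopifnot(inherits(epochs_a, "epochs"), inherits(epochs_b, "epochs"),
            n_channels(epochs_a) == n_channels(epochs_b),
            n_samples(epochs_a) == n_samples(epochs_b))
  na <- n_trials(epochs_a); nb <- n_trials(epochs_b)
  y <- c(rep(0L, na), rep(1L, nb))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  fold <- stratified_folds(y, n_folds)
  n_samp <- n_samples(epochs_a)
  tp <- if (is.null(timepoints)) seq_len(n_samp) else timepoints
  if (is.null(lambda)) lambda <- 1 / (length(y) - min(table(fold)))
  auc_t <- numeric(length(tp))
  for (ti in seq_along(tp)) {
    t <- tp[ti]
    X <- rbind(matrix(epochs_a$data[, , t], na),
               matrix(epochs_b$data[, , t], nb))
    # glmnet needs >= 2 predictors; a constant zero column changes nothing
    if (ncol(X) == 1) X <- cbind(X, 0)
    if (all(apply(X, 2, stats::sd) == 0)) {
      auc_t[ti] <- 0.5  # no information at this timepoint (e.g. empty IMF)
      next
    }
    fold_auc <- numeric(n_folds)
    pool_scores <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      if (length(unique(y[tr])) < 2) {
        stop("training folds lost a class; reduce n_folds", call. = FALSE)
      }
      fit <- tryCatch(fit_ridge_logistic(Xs[tr, , drop = FALSE], y[tr],
                                         lambda),
                      error = function(e) NULL)
      # degenerate training fold (all features constant): uninformative
      sc <- if (is.null(fit)) numeric(sum(!tr)) else {
        as.numeric(stats::predict(fit, Xs[!tr, , drop = FALSE]))
      }
      if (pooled) {
        pool_scores[!tr] <- sc
      } else {
        fold_auc[f] <- auc_score(sc, y[!tr])
      }
    }
    auc_t[ti] <- if (pooled) auc_score(pool_scores, y) else mean(fold_auc)
  }
  structure(auc_t, time_ms = epoch_times(epochs_a)[tp], n_folds = n_folds,
            seed = seed)
}

new_decoding_result <- function(auc, pair, feature, time_ms, n_folds, seed) {
  structure(list(auc = auc, pair = pair, feature = feature,
                 time_ms = time_ms, n_folds = n_folds, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s vs %s [%s]: %d participants x %d timepoints, mean AUC %.3f\n",
    x$pair[1], x$pair[2], x$feature, nrow(x$auc), ncol(x$auc), mean(x$auc)))
  invisible(x)
}

#' Per-participant AUC traces in long format
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble with `participant`, `time_ms`, `auc`.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(
    participant = rep(seq_len(nrow(x$auc)), times = ncol(x$auc)),
    time_ms = rep(x$time_ms, each = nrow(x$auc)),
    auc = as.vector(x$auc)
  )
}

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble with the condition pair, feature space, grand-mean AUC,
#'   peak group-mean AUC and its latency.
#' @export
glance.decoding_result <- function(x, ...) {
  gm <- colMeans(x$auc)
  tibble::tibble(
    pair = paste(x$pair, collapse = " vs "),
    feature = x$feature,
    n_participants = nrow(x$auc),
    n_timepoints = ncol(x$auc),
    mean_auc = mean(x$auc),
    peak_auc = max(gm),
    peak_time_ms = x$time_ms[which.max(gm)]
  )
}

#' Decode all condition pairs across IMF components and participants
#'
#' Runs [time_resolved_decode()] for every participant, condition pair and
#' requested IMF component (and optionally the undecomposed epochs),
#' assembling participants x timepoints AUC matrices.
#'
#' @param cohort A list with one element per participant; each element must
#'   contain `epochs` (the raw `epochs`) and, if IMF features are requested,
#'   `imfs` (the matching `imf_epochs` from [decompose_epochs()]).
#' @param pairs List of length-2 character vectors of condition labels;
#'   default: all pairs among famous / unfamiliar / scrambled present in the
#'   data.
#' @param imfs Integer IMF components to decode (default 4:6); `NULL` for
#'   none.
#' @param include_raw Also decode the undecomposed epochs?
#' @inheritParams time_resolved_decode
#' @return A tibble with columns `pair`, `feature` and a list-column
#'   `result` of `decoding_result` objects.
#' @export
decode_pairs <- function(cohort, pairs = NULL, imfs = 4:6,
                         include_raw = TRUE, n_folds = 30, seed = 1,
                         lambda = NULL, timepoints = NULL) {
  stopifnot(length(cohort) >= 1)
  labels_present <- unique(unlist(lapply(cohort,
                                         function(p) unique(p$epochs$labels))))
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(labels_present), 2, simplify = FALSE)
  }
  features <- c(if (include_raw) "raw",
                if (!is.null(imfs)) sprintf("IMF%d", imfs))
  rows <- list()
  for (pair in pairs) {
    if (!all(pair %in% labels_present)) {
      warning("labels ", paste(pair, collapse = "/"),
              " not all present; pair skipped", call. = FALSE)
      next
    }
    for (feat in features) {
      auc_rows <- lapply(seq_along(cohort), function(i) {
        p <- cohort[[i]]
        ep <- if (feat == "raw") p$epochs else {
          imf_component(p$imfs, as.integer(sub("IMF", "", feat)))
        }
        time_resolved_decode(filter_epochs(ep, pair[1]),
                             filter_epochs(ep, pair[2]),
                             n_folds = n_folds, seed = seed + i,
                             lambda = lambda, timepoints = timepoints)
      })
      auc <- do.call(rbind, lapply(auc_rows, as.numeric))
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair = paste(pair, collapse = ":"), feature = feat,
        result = list(new_decoding_result(
          auc, pair, feat, attr(auc_rows[[1]], "time_ms"), n_folds, seed)))
    }
  }
  dplyr::bind_rows(rows)
}
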