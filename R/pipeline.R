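#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one
#' validated object. Unknown arguments are rejected. The configuration hash
#' (and the stage seeds) are stamped on every report for provenance.
#'
#' @param band Band-pass edges in Hz (applied only by the raw-data path).
#' @param fs_new Target sampling rate in Hz.
#' @param tmin_ms,tmax_ms Epoch window in ms.
#' @param p2p_threshold Peak-to-peak rejection threshold (`Inf` disables).
#' @param n_imfs Total EMD components including the residual trend.
#' @param mask_schedule Mask-frequency schedule for [masking_emd()].
#' @param imfs IMF components fed to the decoder (paper-style 1-based).
#' @param include_raw Also decode undecomposed epochs?
#' @param pairs Condition pairs (list of length-2 character vectors), or NULL
#'   for all pairs present.
#' @param n_folds CV subsets per condition pair.
#' @param decode_seed,stats_seed Integer stage seeds.
#' @param t_thresh,n_perm,alpha,tail Cluster permutation parameters.
#' @param lambda2 Inverse regularisation (source-space path).
#' @param timepoints Optional integer subset of sample indices to decode.
#' @return A `pipeline_config` list with a `hash` field.
#' @export
pipeline_config <- function(band = c(0.5, 100), fs_new = 200,
                            tmin_ms = -100, tmax_ms = 1000,
                            p2p_threshold = Inf, n_imfs = 8,
                            mask_schedule = "dyadic", imfs = 4:6,
                            include_raw = TRUE, pairs = NULL, n_folds = 30,
                            decode_seed = 7, t_thresh = 2, n_perm = 1000,
                            alpha = 0.05, tail = "one", lambda2 = 1 / 9,
                            stats_seed = 11, timepoints = NULL) {
  cfg <- list(band = band, fs_new = fs_new, tmin_ms = tmin_ms,
              tmax_ms = tmax_ms, p2p_threshold = p2p_threshold,
              n_imfs = n_imfs, mask_schedule = mask_schedule, imfs = imfs,
              include_raw = include_raw, pairs = pairs, n_folds = n_folds,
              decode_seed = decode_seed, t_thresh = t_thresh,
              n_perm = n_perm, alpha = alpha, tail = tail, lambda2 = lambda2,
              stats_seed = stats_seed, timepoints = timepoints)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' End-to-end replica of the three-source simulation study
#'
#' Simulates the benchmark cohort (two phase-locked 3 Hz supramarginal
#' sources, one 7 Hz right inferior frontal source), applies masking EMD to
#' each participant's trial-averaged evoked sensor signals, determines which
#' IMF component carries the delta and the theta energy at the sensors
#' dominated by each source group, measures those components' dominant
#' Hilbert frequencies, and source-localises the IMF-resolved grand-average
#' evoked with the dSPM-normalised minimum-norm inverse over a candidate
#' space that also contains the background nuisance patches.
#'
#' @param seed Master seed for the cohort simulation.
#' @param spec A [simulation_spec()]; the default is the benchmark study
#'   configuration.
#' @param n_imfs Total EMD components including the residual.
#' @param n_top_sensors Number of sensors per source-dominated group.
#' @param lambda2 Inverse regularisation.
#' @param config Optional [pipeline_config()] recorded in the report.
#' @return A `sim_replica_report` list: `imf_summary` (per group x IMF
#'   energy fractions), `delta_imf`, `theta_imf`, their dominant frequencies,
#'   `theta_below_delta` (theta component has the lower index), and
#'   `localization` (per true source: hit and peak label).
#' @export
run_simulation_replica <- function(seed = 1, spec = simulation_spec(),
                                   n_imfs = 8, n_top_sensors = 4,
                                   lambda2 = 1 / 9, config = NULL) {
  cohort <- simulate_cohort(spec, seed)
  lf <- spec$lead_field
  n_sens <- nrow(lf$gain)
  src_freq <- vapply(spec$sources, `[[`, 0, "freq")
  delta_cols <- which(src_freq <= 4)
  theta_cols <- which(src_freq > 4)

  delta_gain <- apply(lf$gain[, delta_cols, drop = FALSE], 1, max)
  theta_gain <- apply(lf$gain[, theta_cols, drop = FALSE], 1, max)
  delta_sensors <- order(delta_gain, decreasing = TRUE)[seq_len(n_top_sensors)]
  theta_sensors <- setdiff(order(theta_gain, decreasing = TRUE),
                           delta_sensors)[seq_len(n_top_sensors)]

  # masking EMD of each participant's evoked (trial-averaged) sensor signals
  n_comp <- n_imfs - 1L
  n_samp <- length(seq(spec$tmin_ms, spec$tmax_ms, by = 1000 / spec$fs))
  imf_stack <- array(0, c(length(cohort$participants), n_comp, n_sens, n_samp))
  for (i in seq_along(cohort$participants)) {
    evk <- evoked(cohort$participants[[i]]$epochs)
    for (j in seq_len(n_sens)) {
      dec <- masking_emd(evk[j, ], n_imfs = n_imfs, fs = spec$fs)
      imf_stack[i, , j, ] <- dec$imfs
    }
  }

  group_energy <- function(sensors) {
    vapply(seq_len(n_comp), function(k)
      sum(imf_stack[, k, sensors, ]^2), 0)
  }
  e_delta <- group_energy(delta_sensors)
  e_theta <- group_energy(theta_sensors)
  delta_imf <- which.max(e_delta)
  theta_imf <- which.max(e_theta)

  group_spectrum <- function(k, sensors) {
    sigs <- matrix(aperm(imf_stack[, k, sensors, , drop = FALSE],
                         c(4, 1, 2, 3)),
                   nrow = length(cohort$participants) * length(sensors),
                   byrow = TRUE)
    marginal_spectrum(sigs, fs = spec$fs)
  }
  delta_freq <- dominant_frequency(group_spectrum(delta_imf, delta_sensors))
  theta_freq <- dominant_frequency(group_spectrum(theta_imf, theta_sensors))

  # --- source localisation over an honest candidate space (true patches
  #     plus the nuisance patches that generated the background) ---
  nm <- spec$noise
  cand <- data.frame(
    label = vapply(spec$sources, `[[`, "", "label"),
    x = lf$patch_pos[, 1], y = lf$patch_pos[, 2], z = lf$patch_pos[, 3])
  if (nm$n_background > 0) {
    bg_pos <- sensor_positions(nm$n_background, radius = 0.8,
                               jitter_sd = 0.1,
                               seed = spec$geometry_seed + 1)
    cand <- rbind(cand, data.frame(
      label = sprintf("bg%02d", seq_len(nm$n_background)),
      x = bg_pos[, 1], y = bg_pos[, 2], z = bg_pos[, 3]))
  }
  cand_lf <- make_toy_lead_field(n_sens, cand,
                                 geometry_seed = spec$geometry_seed)
  noise_mats <- lapply(cohort$participants, function(p) {
    d <- dim(p$noise_epochs$data)
    matrix(aperm(p$noise_epochs$data, c(2, 1, 3)), d[2])
  })
  ncov <- estimate_noise_cov(do.call(cbind, noise_mats), shrinkage = 0.05)
  inv <- make_inverse(cand_lf, ncov, lambda2 = lambda2)

  # localization: dSPM of the grand-average evoked, each candidate scored by
  # its narrowband power at the dominant frequency the Hilbert stage measured
  # for the source group. Frequency-indexed scoring is needed because the
  # short evoked bursts are spectrally broad: the delta burst's upper
  # sidebands leak into the theta-carrying IMF, so a raw spatial peak on that
  # component reflects the (stronger) delta pair rather than the theta patch.
  ga <- Reduce(`+`, lapply(cohort$participants,
                           function(p) evoked(p$epochs))) /
    length(cohort$participants)
  stc <- apply_inverse(ga, inv, normalize = TRUE)
  fgrid <- (seq_len(n_samp) - 1) * spec$fs / n_samp
  narrowband_power <- function(x, f0) {
    P <- Mod(stats::fft(x))^2
    P[which.min(abs(fgrid - f0))]
  }
  delta_score <- apply(stc$data, 1, narrowband_power, f0 = delta_freq)
  theta_score <- apply(stc$data, 1, narrowband_power, f0 = theta_freq)
  delta_labels <- cand$label[delta_cols]
  theta_labels <- cand$label[theta_cols]
  delta_top <- cand$label[order(delta_score,
                                decreasing = TRUE)][seq_along(delta_labels)]
  theta_top <- cand$label[order(theta_score,
                                decreasing = TRUE)][seq_along(theta_labels)]
  localization <- tibble::tibble(
    source = c(delta_labels, theta_labels),
    freq = c(src_freq[delta_cols], src_freq[theta_cols]),
    imf = c(rep(delta_imf, length(delta_labels)),
            rep(theta_imf, length(theta_labels))),
    hit = c(delta_labels %in% delta_top, theta_labels %in% theta_top)
  )

  imf_summary <- tibble::tibble(
    imf = rep(seq_len(n_comp), 2),
    group = rep(c("delta_sensors", "theta_sensors"), each = n_comp),
    energy = c(e_delta, e_theta),
    energy_fraction = c(e_delta / sum(e_delta), e_theta / sum(e_theta))
  )

  structure(
    list(imf_summary = imf_summary,
         delta_imf = delta_imf, theta_imf = theta_imf,
         delta_dominant_freq = delta_freq,
         theta_dominant_freq = theta_freq,
         theta_below_delta = theta_imf < delta_imf,
         localization = localization,
         delta_sensors = delta_sensors, theta_sensors = theta_sensors,
         seed = seed, spec = spec,
         config_hash = if (is.null(config)) NA_character_ else config$hash),
    class = "sim_replica_report"
  )
}

#' @export
print.sim_replica_report <- function(x, ...) {
  cat("<sim_replica_report>\n")
  cat(sprintf("  delta (3 Hz) energy peaks in IMF%d, dominant frequency %.2f Hz\n",
              x$delta_imf, x$delta_dominant_freq))
  cat(sprintf("  theta (7 Hz) energy peaks in IMF%d, dominant frequency %.2f Hz\n",
              x$theta_imf, x$theta_dominant_freq))
  cat(sprintf("  theta component below delta component: %s\n",
              x$theta_below_delta))
  cat(sprintf("  localization hits: %d / %d\n", sum(x$localization$hit),
              nrow(x$localization)))
  invisible(x)
}

#' @export
#' @rdname tidy.imf_set
tidy.sim_replica_report <- function(x, ...) x$imf_summary

#' Full sensor-level decoding study on a cohort
#'
#' For each participant: optional peak-to-peak rejection, masking EMD
#' decomposition, then time-resolved decoding of every condition pair on the
#' configured IMF components (and optionally the raw epochs); finally, for
#' each pair x feature, group-level cluster-based sign-flip permutation
#' inference on the chance-centred AUC matrices.
#'
#' @param epochs_list List of per-participant `epochs` objects (or a
#'   `sim_cohort`).
#' @param config A [pipeline_config()].
#' @return A `decoding_study` tibble: columns `pair`, `feature`, list-columns
#'   `result` (`decoding_result`) and `clusters` (`cluster_result`, NULL when
#'   the cohort has a single participant), with the config hash in
#'   `attr(, "config_hash")`.
#' @export
run_decoding_study <- function(epochs_list, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(epochs_list, "sim_cohort")) {
    epochs_list <- lapply(epochs_list$participants, `[[`, "epochs")
  }
  stopifnot(length(epochs_list) >= 1)
  cohort <- lapply(epochs_list, function(ep) {
    stopifnot(inherits(ep, "epochs"))
    if (is.finite(config$p2p_threshold)) {
      ep <- reject_peak_to_peak(ep, config$p2p_threshold)$epochs
    }
    imfs <- if (is.null(config$imfs)) NULL else {
      decompose_epochs(ep, n_imfs = config$n_imfs,
                       schedule = config$mask_schedule)
    }
    list(epochs = ep, imfs = imfs)
  })
  res <- decode_pairs(cohort, pairs = config$pairs, imfs = config$imfs,
                      include_raw = config$include_raw,
                      n_folds = config$n_folds, seed = config$decode_seed,
                      timepoints = config$timepoints)
  if (length(cohort) < 2) {
    warning("group statistics require at least 2 participants; ",
            "cluster inference skipped", call. = FALSE)
    res$clusters <- list(NULL)
  } else {
    res$clusters <- lapply(res$result, function(r) {
      cluster_permutation(r$auc, mu0 = 0.5, t_thresh = config$t_thresh,
                          n_perm = config$n_perm, alpha = config$alpha,
                          tail = config$tail, seed = config$stats_seed,
                          times_ms = r$time_ms)
    })
  }
  attr(res, "config_hash") <- config$hash
  class(res) <- c("decoding_study", class(res))
  res
}

#' Cluster summary of a decoding study
#'
#' @param x The tibble returned by [run_decoding_study()].
#' @return A tibble with one row per (pair, feature, cluster).
#' @export
study_cluster_table <- function(x) {
  stopifnot(inherits(x, "decoding_study"))
  rows <- purrr::pmap(list(x$pair, x$feature, x$clusters),
                      function(pair, feature, cl) {
                        if (is.null(cl) || nrow(cl$clusters) == 0) return(NULL)
                        dplyr::mutate(cl$clusters, pair = pair,
                                      feature = feature, .before = 1)
                      })
  dplyr::bind_rows(rows)
}
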