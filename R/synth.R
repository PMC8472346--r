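#' @title Synthetic MEG cohort generator
#' @description Builds toy lead fields and simulates sensor-space epochs as
#'   mixtures of narrow-band evoked cortical sources, structured 1/f
#'   background projected from nuisance patches, and white sensor noise. The
#'   default configuration is the three-source benchmark used throughout the
#'   package: two phase-locked 3 Hz (delta) evoked bursts at the left and
#'   right supramarginal gyri and one 7 Hz (theta) burst at the right
#'   inferior frontal gyrus, 200 Hz sampling, -100..1000 ms epochs, 16
#'   participants, 60 trials per condition.
#' @name synth
NULL

#' Cortical source specification
#'
#' @param label Patch identifier (unique within a simulation).
#' @param freq Oscillation frequency in Hz (0 < freq < fs/2).
#' @param amplitude Source strength in arbitrary units (before cohort-level
#'   SNR calibration).
#' @param hemisphere `"left"` or `"right"`.
#' @param onset_ms,rise_ms,fall_ms,end_ms Raised-cosine burst envelope:
#'   zero before `onset_ms`, cosine ramp of `rise_ms`, plateau, cosine fall
#'   of `fall_ms` ending at `end_ms`.
#' @param position Numeric length-3 patch location (head frame, arbitrary
#'   units on the unit hemisphere).
#' @return A `source_spec` list.
#' @export
source_spec <- function(label, freq, amplitude = 1,
                        hemisphere = c("left", "right"),
                        onset_ms = 80, rise_ms = 50, fall_ms = 50,
                        end_ms = 500, position = c(0, 0, 1)) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(freq > 0, amplitude >= 0, onset_ms < end_ms,
            rise_ms >= 0, fall_ms >= 0, length(position) == 3)
  structure(list(label = label, freq = freq, amplitude = amplitude,
                 hemisphere = hemisphere, onset_ms = onset_ms,
                 rise_ms = rise_ms, fall_ms = fall_ms, end_ms = end_ms,
                 position = as.numeric(position)),
            class = "source_spec")
}

#' The three-source benchmark patch set
#'
#' Two delta-band (3 Hz) evoked sources at the left and right supramarginal
#' gyri and one theta-band (7 Hz) source at the right inferior frontal gyrus.
#'
#' @return A list of three [source_spec()] objects.
#' @export
default_sources <- function() {
  list(
    source_spec("left_supramarginal", 3, hemisphere = "left",
                position = c(-0.60, -0.25, 0.60)),
    source_spec("right_supramarginal", 3, hemisphere = "right",
                position = c(0.60, -0.25, 0.60)),
    source_spec("right_inferior_frontal", 7, hemisphere = "right",
                position = c(0.45, 0.55, 0.45))
  )
}

raised_cosine_envelope <- function(t_ms, onset, rise, fall, end) {
  env <- numeric(length(t_ms))
  up <- t_ms >= onset & t_ms < onset + rise
  env[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - onset) / rise))
  flat <- t_ms >= onset + rise & t_ms <= end - fall
  env[flat] <- 1
  dn <- t_ms > end - fall & t_ms <= end
  env[dn] <- 0.5 * (1 + cos(pi * (t_ms[dn] - (end - fall)) / fall))
  env
}

# Deterministic quasi-uniform sensor layout on the upper hemisphere
# (Fibonacci lattice), with small seeded jitter.
sensor_positions <- function(n_sensors, radius = 1.1, jitter_sd = 0.02,
                             seed = 1) {
  i <- seq_len(n_sensors) - 0.5
  z <- i / n_sensors                      # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos + matrix(stats::rnorm(3 * n_sensors, sd = jitter_sd), ncol = 3)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Toy lead field
#'
#' Places `n_sensors` on a quasi-uniform upper-hemisphere helmet (with small
#' seeded positional jitter) and assigns each source patch a smooth,
#' distance-decaying gain pattern: `exp(-(d / decay)^2)` of the
#' sensor-to-patch Euclidean distance, column-scaled to unit maximum. A toy
#' stand-in for a boundary-element forward model, adequate for the package's
#' source-localisation logic.
#'
#' @param n_sensors Number of sensors (>= 3).
#' @param patches A list of [source_spec()] objects, or a data frame with
#'   columns `label`, `x`, `y`, `z`.
#' @param geometry_seed Seed for the sensor jitter; same seed, same matrix.
#' @param decay Spatial decay scale of the gain pattern.
#' @return A `lead_field`: `gain` (sensors x sources), `sensor_ids`,
#'   `source_labels`, `sensor_pos`, `patch_pos`.
#' @export
make_toy_lead_field <- function(n_sensors, patches, geometry_seed = 1,
                                decay = 0.45) {
  stopifnot(n_sensors >= 3)
  if (is.data.frame(patches)) {
    labels <- patches$label
    pos <- as.matrix(patches[, c("x", "y", "z")])
  } else {
    labels <- vapply(patches, `[[`, "", "label")
    pos <- t(vapply(patches, `[[`, numeric(3), "position"))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate patch labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pos)) stop("patch positions must be distinct",
                               call. = FALSE)
  sens <- sensor_positions(n_sensors, seed = geometry_seed)
  gain <- matrix(0, n_sensors, nrow(pos))
  for (j in seq_len(nrow(pos))) {
    d <- sqrt(colSums((t(sens) - pos[j, ])^2))
    g <- exp(-(d / decay)^2)
    gain[, j] <- g / max(g)
  }
  structure(list(gain = gain,
                 sensor_ids = sprintf("MEG%03d", seq_len(n_sensors)),
                 source_labels = labels, sensor_pos = sens, patch_pos = pos),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d sources (%s)\n", nrow(x$gain),
              ncol(x$gain), paste(utils::head(x$source_labels, 4),
                                  collapse = ", ")))
  invisible(x)
}

#' Noise model for the simulator
#'
#' @param sensor_white_sd Per-channel white-noise SD (sensor units).
#' @param background_exponent Spectral slope alpha of the 1/f^alpha source
#'   background, in `[0, 2]`.
#' @param background_scale Amplitude of each background nuisance source.
#' @param n_background Number of random nuisance patches whose 1/f activity
#'   is projected through the lead field (giving spatially structured noise
#'   covariance, as the dSPM stage assumes).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sensor_white_sd = 0.2, background_exponent = 1,
                        background_scale = 1, n_background = 20) {
  stopifnot(sensor_white_sd >= 0, background_exponent >= 0,
            background_exponent <= 2, background_scale >= 0,
            n_background >= 0)
  structure(list(sensor_white_sd = sensor_white_sd,
                 background_exponent = background_exponent,
                 background_scale = background_scale,
                 n_background = n_background),
            class = "noise_model")
}

#' Simulation specification
#'
#' Bundles sources, lead field, noise model and design parameters. The
#' defaults are the package's benchmark study conditions: 200 Hz sampling,
#' -100..1000 ms epochs, 60 trials per condition, 16 participants, evoked
#' (phase-locked) bursts at single-trial evoked-to-noise RMS ratio 0.5.
#'
#' @param sources List of [source_spec()]s (default [default_sources()]).
#' @param n_sensors Sensors in the toy helmet.
#' @param noise A [noise_model()].
#' @param n_trials_per_condition Trials per condition and participant.
#' @param n_participants Cohort size.
#' @param fs Sampling rate, Hz.
#' @param tmin_ms,tmax_ms Epoch window (endpoint-inclusive).
#' @param snr Target single-trial evoked-to-noise RMS ratio at the most
#'   strongly driven sensor.
#' @param conditions Character vector of condition labels.
#' @param condition_effects Named list (per condition) of lists with elements
#'   `amplitude` (multiplier) and `latency_ms` (envelope shift); conditions
#'   not listed get amplitude 1, shift 0. An all-equal list is the null.
#' @param phase_locked Evoked mode: fixed source phase at envelope onset
#'   (TRUE, default) or per-trial random phase (induced mode).
#' @param participant_amp_sdlog SD (log scale) of the lognormal
#'   per-participant amplitude multiplier.
#' @param geometry_seed Seed for the toy helmet geometry.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(sources = default_sources(), n_sensors = 30,
                            noise = noise_model(),
                            n_trials_per_condition = 60, n_participants = 16,
                            fs = 200, tmin_ms = -100, tmax_ms = 1000,
                            snr = 0.5, conditions = "stim",
                            condition_effects = list(), phase_locked = TRUE,
                            participant_amp_sdlog = 0.2, geometry_seed = 1) {
  stopifnot(fs > 0, tmin_ms < 0, tmax_ms > 0, n_trials_per_condition >= 1,
            n_participants >= 1, snr > 0)
  for (s in sources) {
    if (s$freq >= fs / 2) stop("source frequency ", s$freq,
                               " at or above Nyquist", call. = FALSE)
    if (s$onset_ms < tmin_ms || s$end_ms > tmax_ms) {
      stop("envelope of source '", s$label, "' (", s$onset_ms, "..",
           s$end_ms, " ms) does not fit the epoch window", call. = FALSE)
    }
  }
  lf <- make_toy_lead_field(n_sensors, sources, geometry_seed = geometry_seed)
  structure(list(sources = sources, lead_field = lf, noise = noise,
                 n_trials_per_condition = n_trials_per_condition,
                 n_participants = n_participants, fs = fs, tmin_ms = tmin_ms,
                 tmax_ms = tmax_ms, snr = snr, conditions = conditions,
                 condition_effects = condition_effects,
                 phase_locked = phase_locked,
                 participant_amp_sdlog = participant_amp_sdlog,
                 geometry_seed = geometry_seed),
            class = "simulation_spec")
}

# 1/f^alpha noise via spectral shaping of white noise; unit SD.
one_over_f <- function(n, alpha, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-12, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  scale <- c(0, (f[-1])^(-alpha / 2))  # kill DC
  y <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Simulate one participant
#'
#' Each trial is `gain %*% (enveloped source sinusoids) + structured 1/f
#' background + white sensor noise`. The evoked component is phase-locked at
#' envelope onset (unless `spec$phase_locked` is FALSE, in which case each
#' trial draws a uniform phase). Source amplitudes are calibrated so the
#' single-trial evoked-to-noise RMS ratio at the most strongly driven sensor
#' matches `spec$snr` (given the participant's realised noise), then scaled
#' by the participant's amplitude multiplier.
#'
#' @param spec A [simulation_spec()].
#' @param participant_seed Integer seed; all randomness in the participant
#'   flows from it.
#' @param amp_multiplier Per-participant amplitude multiplier (set by
#'   [simulate_cohort()]).
#' @param participant_id Identifier stamped on the output epochs.
#' @return A list: `epochs` (the sensor data), `sources` (noise-free source
#'   traces, sources x samples, per condition), `noise_epochs` (the
#'   source-free noise trials, usable as empty-room segments), `amp_factor`.
#' @export
simulate_participant <- function(spec, participant_seed,
                                 amp_multiplier = 1,
                                 participant_id = "sim") {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(participant_seed %% .Machine$integer.max))

  fs <- spec$fs
  t_ms <- seq(spec$tmin_ms, spec$tmax_ms, by = 1000 / fs)
  n_samp <- length(t_ms)
  lf <- spec$lead_field
  n_sens <- nrow(lf$gain)
  conds <- spec$conditions
  n_trial <- spec$n_trials_per_condition * length(conds)
  labels <- rep(conds, each = spec$n_trials_per_condition)

  # --- noise: structured 1/f background through nuisance patches + white ---
  nm <- spec$noise
  noise <- array(0, c(n_trial, n_sens, n_samp))
  if (nm$n_background > 0 && nm$background_scale > 0) {
    bg_pos <- sensor_positions(nm$n_background, radius = 0.8, jitter_sd = 0.1,
                               seed = spec$geometry_seed + 1)
    bg_patches <- data.frame(label = sprintf("bg%02d", seq_len(nm$n_background)),
                             x = bg_pos[, 1], y = bg_pos[, 2], z = bg_pos[, 3])
    bg_lf <- make_toy_lead_field(n_sens, bg_patches,
                                 geometry_seed = spec$geometry_seed)
    for (i in seq_len(n_trial)) {
      B <- t(vapply(seq_len(nm$n_background),
                    function(j) nm$background_scale *
                      one_over_f(n_samp, nm$background_exponent, fs),
                    numeric(n_samp)))
      noise[i, , ] <- bg_lf$gain %*% B
    }
  }
  if (nm$sensor_white_sd > 0) {
    noise <- noise + array(stats::rnorm(length(noise),
                                        sd = nm$sensor_white_sd),
                           dim(noise))
  }

  # --- clean evoked source traces per condition (unit base amplitude) ---
  src_traces <- lapply(conds, function(cond) {
    eff <- spec$condition_effects[[cond]]
    amp_c <- if (is.null(eff$amplitude)) 1 else eff$amplitude
    lat_c <- if (is.null(eff$latency_ms)) 0 else eff$latency_ms
    t(vapply(spec$sources, function(s) {
      env <- raised_cosine_envelope(t_ms - lat_c, s$onset_ms, s$rise_ms,
                                    s$fall_ms, s$end_ms)
      s$amplitude * amp_c * env *
        sin(2 * pi * s$freq * (t_ms - lat_c - s$onset_ms) / 1000)
    }, numeric(n_samp)))
  })
  names(src_traces) <- conds

  # --- SNR calibration at the most strongly driven sensor ---
  clean_ref <- lf$gain %*% src_traces[[1]]
  ref_sensor <- which.max(apply(abs(clean_ref), 1, max))
  active <- abs(clean_ref[ref_sensor, ]) > 0
  rms_clean <- sqrt(mean(clean_ref[ref_sensor, active]^2))
  rms_noise <- sqrt(mean(noise[, ref_sensor, ]^2))
  amp_factor <- if (rms_clean > 0 && rms_noise > 0) {
    spec$snr * rms_noise / rms_clean
  } else 1
  amp_factor <- amp_factor * amp_multiplier

  # --- assemble trials ---
  data <- noise
  for (i in seq_len(n_trial)) {
    S <- src_traces[[labels[i]]]
    if (!spec$phase_locked) {
      eff <- spec$condition_effects[[labels[i]]]
      lat_c <- if (is.null(eff$latency_ms)) 0 else eff$latency_ms
      S <- t(vapply(seq_along(spec$sources), function(k) {
        s <- spec$sources[[k]]
        env <- raised_cosine_envelope(t_ms - lat_c, s$onset_ms, s$rise_ms,
                                      s$fall_ms, s$end_ms)
        amp_c <- if (is.null(eff$amplitude)) 1 else eff$amplitude
        s$amplitude * amp_c * env *
          sin(2 * pi * s$freq * (t_ms - lat_c - s$onset_ms) / 1000 +
                stats::runif(1, 0, 2 * pi))
      }, numeric(n_samp)))
    }
    data[i, , ] <- data[i, , ] + amp_factor * (lf$gain %*% S)
  }

  ep <- epochs(data, fs, spec$tmin_ms, labels, lf$sensor_ids, participant_id)
  noise_ep <- epochs(noise, fs, spec$tmin_ms, rep("noise", n_trial),
                     lf$sensor_ids, participant_id)
  list(epochs = ep,
       sources = lapply(src_traces, function(S) amp_factor * S),
       noise_epochs = noise_ep, amp_factor = amp_factor,
       ref_sensor = ref_sensor)
}

#' Simulate a cohort
#'
#' Participant seeds are derived deterministically from `master_seed`;
#' per-participant amplitude multipliers are lognormal with log-SD
#' `spec$participant_amp_sdlog`.
#'
#' @param spec A [simulation_spec()].
#' @param master_seed Integer master seed.
#' @return A list of class `sim_cohort`: `participants` (each the value of
#'   [simulate_participant()]), `spec`, `master_seed`, `participant_seeds`,
#'   `amp_multipliers`.
#' @export
simulate_cohort <- function(spec, master_seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"), spec$n_participants >= 1)
  old <- .Random.seed_save()
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  seeds <- sample.int(.Machine$integer.max - 1, spec$n_participants)
  mult <- stats::rlnorm(spec$n_participants, 0, spec$participant_amp_sdlog)
  .Random.seed_restore(old)
  participants <- lapply(seq_len(spec$n_participants), function(i) {
    simulate_participant(spec, seeds[i], amp_multiplier = mult[i],
                         participant_id = sprintf("sub%02d", i))
  })
  structure(list(participants = participants, spec = spec,
                 master_seed = master_seed, participant_seeds = seeds,
                 amp_multipliers = mult),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d participants, %d trials each, seed %d\n",
              length(x$participants), n_trials(x$participants[[1]]$epochs),
              x$master_seed))
  invisible(x)
}

#' Null chance-level AUC cohort
#'
#' Generates per-participant AUC time series under the null: 0.5 plus a
#' stationary AR(1) deviation, emulating the smooth chance-level traces that
#' time-resolved decoding of autocorrelated signals produces. Used for
#' calibrating the cluster permutation test's family-wise error rate.
#'
#' @param n_participants,n_timepoints Matrix dimensions.
#' @param sd Stationary SD of the AUC deviation (0.05 approximates the
#'   sampling SD of a 30-fold CV AUC at 60 trials per class).
#' @param ar AR(1) coefficient of the temporal autocorrelation.
#' @param seed Integer seed.
#' @return A participants x timepoints matrix of AUC values in `[0, 1]`.
#' @export
simulate_null_auc <- function(n_participants = 16, n_timepoints = 221,
                              sd = 0.05, ar = 0.5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- matrix(0, n_participants, n_timepoints)
  innov_sd <- sd * sqrt(1 - ar^2)
  for (i in seq_len(n_participants)) {
    e <- numeric(n_timepoints)
    e[1] <- stats::rnorm(1, 0, sd)
    for (t in seq_len(n_timepoints - 1)) {
      e[t + 1] <- ar * e[t] + stats::rnorm(1, 0, innov_sd)
    }
    out[i, ] <- pmin(1, pmax(0, 0.5 + e))
  }
  out
}
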