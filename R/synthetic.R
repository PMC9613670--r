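#' Synthetic session configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' study conditions of intraoperative motor mapping: 10-30 s testing epochs
#' (default 10 s), 60 Hz video of a 21-landmark hand model, 44 kHz
#' single-channel subthalamic voltage with 80-125 Hz multi-unit background
#' rates (default 100 Hz), movement-modulated inhomogeneous-Poisson spiking
#' with configurable coupling gain and latency, and occlusion dropouts in
#' the tracking.
#'
#' @param n_epochs number of epochs per session.
#' @param movement_mix fraction of passive epochs.
#' @param epoch_duration_s epoch length in seconds (10-30).
#' @param fs_video video frame rate (Hz).
#' @param fs_neural voltage sampling rate (Hz).
#' @param coupling_gain fraction of rate modulation driven by movement, in
#'   \[0, 1\].
#' @param coupled_fraction fraction of epochs generated with
#'   `coupling_gain` (the rest get gain 0).
#' @param latency_s neural lag behind movement, seconds in \[0, 0.4\].
#' @param base_rate_hz background multi-unit rate (80-125 Hz expected for
#'   the subthalamic nucleus).
#' @param noise_sd background-noise SD, microvolts.
#' @param spike_amplitude_snr spike peak amplitude as a multiple of
#'   `noise_sd`.
#' @param dropout_rate fraction of video frames occluded, in \[0, 0.5\].
#' @param label_error_rate probability that a synthetic clinician label
#'   contradicts the true coupling.
#' @param clench_hz_range active-movement cycle frequency range (Hz).
#' @param seed integer master seed; every generator output is a pure
#'   function of (config, seed).
#' @return A `session_config` list.
#' @export
session_config <- function(n_epochs = 20, movement_mix = 0.5,
                           epoch_duration_s = 10, fs_video = 60,
                           fs_neural = 44000, coupling_gain = 0.8,
                           coupled_fraction = 0.5, latency_s = 0.05,
                           base_rate_hz = 100, noise_sd = 10,
                           spike_amplitude_snr = 10, dropout_rate = 0.02,
                           label_error_rate = 0,
                           clench_hz_range = c(0.5, 2), seed = 1L) {
  assert_that(coupling_gain >= 0 && coupling_gain <= 1,
              "nmmap_validation_error", "coupling_gain must lie in [0, 1]")
  assert_that(dropout_rate >= 0 && dropout_rate <= 0.5,
              "nmmap_validation_error", "dropout_rate must lie in [0, 0.5]")
  assert_that(epoch_duration_s > 0 && fs_video > 0 && fs_neural > 0 &&
                base_rate_hz > 0, "nmmap_validation_error",
              "rates and durations must be positive")
  structure(list(n_epochs = n_epochs, movement_mix = movement_mix,
                 epoch_duration_s = epoch_duration_s, fs_video = fs_video,
                 fs_neural = fs_neural, coupling_gain = coupling_gain,
                 coupled_fraction = coupled_fraction, latency_s = latency_s,
                 base_rate_hz = base_rate_hz, noise_sd = noise_sd,
                 spike_amplitude_snr = spike_amplitude_snr,
                 dropout_rate = dropout_rate,
                 label_error_rate = label_error_rate,
                 clench_hz_range = clench_hz_range,
                 seed = as.integer(seed)),
            class = "session_config")
}

# underlying movement drive c(t) in [0, 1] on a fine 1200 Hz grid, plus the
# normalized speed envelope used to modulate spiking
.gen_drive <- function(cfg, movement, n_frames, seed) {
  fs_fine <- 1200
  n_fine <- n_frames * fs_fine / cfg$fs_video
  t <- (seq_len(n_fine) - 1) / fs_fine
  with_seed(seed, {
    if (movement == "active") {
      # quasi-periodic clenches: every cycle's duration is drawn afresh
      # around the epoch's nominal frequency (human repetitions are not
      # phase-stable), and a slow multiplicative jitter varies amplitude
      f <- runif(1, cfg$clench_hz_range[1], cfg$clench_hz_range[2])
      phase <- runif(1, 0, 1)  # starting fraction of the first cycle
      dur_total <- max(t) + 2
      periods <- numeric(0)
      while (sum(periods) < dur_total) {
        periods <- c(periods, exp(rnorm(1, log(1 / f), 0.18)))
      }
      edges <- cumsum(c(-phase / f, periods))
      cyc_phase <- numeric(n_fine)
      j <- 1
      for (i in seq_len(n_fine)) {
        while (t[i] >= edges[j + 1]) j <- j + 1
        cyc_phase[i] <- (t[i] - edges[j]) / (edges[j + 1] - edges[j])
      }
      jit <- .moving_average(rnorm(n_fine, 0, 1), 2 * fs_fine)
      jit <- 1 + 0.25 * jit / max(abs(jit) + 1e-12)
      drive <- 0.5 * (1 - cos(2 * pi * cyc_phase)) * jit
    } else {
      # clinician-paced flexion bouts: stochastic onsets, ~1.2 s half-cosine
      # pulses, lower amplitude than active clenches
      drive <- numeric(n_fine)
      t_next <- runif(1, 0, 1.5)
      while (t_next < max(t)) {
        dur <- runif(1, 0.8, 1.6)
        idx <- which(t >= t_next & t < t_next + dur)
        drive[idx] <- drive[idx] +
          0.5 * 0.5 * (1 - cos(2 * pi * (t[idx] - t_next) / dur))
        t_next <- t_next + dur + rexp(1, rate = 0.8)
      }
      drive <- pmin(drive, 1)
    }
    speed <- abs(c(diff(drive), 0)) * fs_fine
    speed <- .moving_average(speed, 60)  # 50 ms smoothing of the envelope
    env <- if (max(speed) > min(speed)) normalize_01(speed)
           else rep(0, n_fine)
    list(drive = drive, envelope = env, fs = fs_fine)
  })
}

# fixed rest layout for the 21-landmark hand model (pixels, 640x480 frame)
.hand_layout <- function() {
  finger_x <- seq(220, 420, length.out = 5)
  rows <- rbind(
    data.frame(landmark = "palm_base", x = 320, y = 420, depth = 0.02),
    data.frame(landmark = "palm_center", x = 320, y = 340, depth = 0.05),
    data.frame(landmark = paste0(c("thumb", "index", "middle", "ring",
                                   "little"), "_mcp"),
               x = finger_x, y = 295, depth = 0.2),
    data.frame(landmark = paste0(c("thumb", "index", "middle", "ring",
                                   "little"), "_pip"),
               x = finger_x, y = 245, depth = 0.5),
    data.frame(landmark = paste0(c("index", "middle", "ring", "little"),
                                 "_dip"),
               x = finger_x[2:5], y = 205, depth = 0.7),
    data.frame(landmark = paste0(c("thumb", "index", "middle", "ring",
                                   "little"), "_tip"),
               x = finger_x, y = 170, depth = 0.9))
  rows
}

#' Generate a synthetic keypoint table
#'
#' Active epochs are quasi-periodic hand clenches (0.5-2 Hz with jittered
#' amplitude and phase; all digits co-modulated, fingertips moving most);
#' passive epochs are irregular clinician-paced flexion bouts with lower
#' amplitude. Landmarks move from a rest layout toward the palm center in
#' proportion to the movement drive, with 0.5 px tracking noise. Occlusion
#' dropouts are inserted as short runs of low-likelihood frames with absent
#' coordinates. Deterministic given `(cfg, movement, seed)`.
#'
#' @param cfg a [session_config()].
#' @param movement `"active"` or `"passive"`.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return A [keypoint_table()]; the underlying 1200 Hz movement-speed
#'   envelope is attached as attribute `"envelope"` (a normalized
#'   [kinematic_signal()]).
#' @export
gen_kinematics <- function(cfg, movement = c("active", "passive"),
                           seed = cfg$seed) {
  movement <- match.arg(movement)
  n_frames <- round(cfg$epoch_duration_s * cfg$fs_video)
  dr <- .gen_drive(cfg, movement, n_frames, derive_seed(seed, "drive"))
  step <- dr$fs / cfg$fs_video
  c60 <- dr$drive[1 + round((seq_len(n_frames) - 1) * step)]
  layout <- .hand_layout()
  nl <- nrow(layout)
  with_seed(derive_seed(seed, "track"), {
    x <- matrix(0, n_frames, nl)
    y <- matrix(0, n_frames, nl)
    cx <- layout$x[layout$landmark == "palm_center"]
    cy <- layout$y[layout$landmark == "palm_center"]
    for (j in seq_len(nl)) {
      dx <- cx - layout$x[j]
      dy <- cy - layout$y[j]
      x[, j] <- layout$x[j] + layout$depth[j] * c60 * dx +
        rnorm(n_frames, 0, 0.5)
      y[, j] <- layout$y[j] + layout$depth[j] * c60 * dy +
        rnorm(n_frames, 0, 0.5)
    }
    lk <- matrix(runif(n_frames * nl, 0.9, 1), n_frames, nl)
    # occlusion runs: global (a hand or instrument blocks the camera view)
    if (cfg$dropout_rate > 0) {
      mean_run <- 3
      starts <- which(runif(n_frames) < cfg$dropout_rate / mean_run)
      occluded <- rep(FALSE, n_frames)
      for (s in starts) {
        len <- 1 + stats::rgeom(1, 1 / mean_run)
        occluded[s:min(n_frames, s + len - 1)] <- TRUE
      }
      if (any(occluded)) {
        x[occluded, ] <- NA
        y[occluded, ] <- NA
        lk[occluded, ] <- runif(sum(occluded) * nl, 0, 0.3)
      }
    }
    colnames(x) <- colnames(y) <- colnames(lk) <- layout$landmark
    tab <- keypoint_table(x, y, lk, cfg$fs_video)
    attr(tab, "envelope") <- kinematic_signal(dr$envelope, dr$fs,
                                              stage = "normalized")
    attr(tab, "drive") <- dr$drive
    tab
  })
}

#' Generate a synthetic voltage trace
#'
#' Inhomogeneous Poisson multi-unit spiking at rate
#' `base_rate_hz * (1 + coupling_gain * envelope(t - latency_s))`, rendered
#' as 1 ms biphasic waveforms (a sharp main lobe at
#' `spike_amplitude_snr * noise_sd`, a 30% rebound of opposite sign) on
#' Gaussian background noise bandlimited to 100-4000 Hz. Deterministic
#' given `(cfg, envelope, seed)`.
#'
#' @param cfg a [session_config()].
#' @param movement_envelope normalized [kinematic_signal()] at 1200 Hz (as
#'   attached by [gen_kinematics()]); `NULL` for fully uncoupled spiking.
#' @param coupling_gain overrides `cfg$coupling_gain` when given.
#' @param duration_s overrides `cfg$epoch_duration_s` when given.
#' @param seed integer seed.
#' @return A [voltage_trace()]; true spike sample indices are attached as
#'   attribute `"true_spikes"`, the rate envelope as `"rate_envelope"`.
#' @export
gen_voltage <- function(cfg, movement_envelope = NULL,
                        coupling_gain = NULL, duration_s = NULL,
                        seed = cfg$seed) {
  gain <- coupling_gain %||% cfg$coupling_gain
  dur <- duration_s %||% cfg$epoch_duration_s
  fs <- cfg$fs_neural
  n <- round(dur * fs)
  env_fs <- 1200
  if (!is.null(movement_envelope)) {
    ev <- .signal_values(movement_envelope)
    env_fs <- movement_envelope$fs %||% 1200
    assert_that(length(ev) >= round(dur * env_fs), "nmmap_validation_error",
                "movement envelope (%d samples) shorter than the epoch",
                length(ev))
    assert_that(min(ev) >= 0 && max(ev) <= 1, "nmmap_validation_error",
                "envelope must be normalized to [0, 1]")
  } else {
    ev <- rep(0, round(dur * env_fs))
    gain <- 0
  }
  with_seed(seed, {
    # rate at the neural grid, with the envelope delayed by the latency
    lag <- round(cfg$latency_s * env_fs)
    ev_lag <- if (lag > 0) c(rep(ev[1], lag), ev[seq_len(length(ev) - lag)])
              else ev
    idx <- pmin(length(ev_lag), 1 + floor((seq_len(n) - 1) / fs * env_fs))
    rate <- cfg$base_rate_hz * (1 + gain * ev_lag[idx])
    spikes <- which(runif(n) < rate / fs)
    # 1 ms asymmetric biphasic waveform
    wlen <- round(fs / 1000)
    t1 <- seq_len(round(wlen * 0.4))
    t2 <- seq_len(wlen - length(t1))
    amp <- cfg$spike_amplitude_snr * cfg$noise_sd
    wave <- c(-amp * sin(pi * t1 / length(t1)),
              0.15 * amp * sin(pi * t2 / length(t2)))
    v <- numeric(n)
    for (s in spikes) {
      e <- min(n, s + wlen - 1)
      v[s:e] <- v[s:e] + wave[seq_len(e - s + 1)]
    }
    if (cfg$noise_sd > 0) {
      bp <- signal::butter(2, c(100, 4000) / (fs / 2), type = "pass")
      noise <- signal::filter(bp, rnorm(n))
      v <- v + as.numeric(noise) / sd(noise) * cfg$noise_sd
    }
    tr <- voltage_trace(v, fs)
    attr(tr, "true_spikes") <- spikes - 1L  # 0-based
    attr(tr, "rate_envelope") <- rate
    tr
  })
}

#' Generate a null database of uncoupled recordings
#'
#' `n_recordings` independent, fully uncoupled (gain 0) voltage traces of
#' at least 35 s each, processed once through the standard MUA path into a
#' [mua_segment_db()] with a manifest (synthetic subject and depth labels).
#' Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [session_config()].
#' @param n_recordings number of recordings (default 12).
#' @param duration_s recording length (default `max(35, epoch + 5)` s).
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return A [mua_segment_db()].
#' @export
gen_null_database <- function(cfg, n_recordings = 12, duration_s = NULL,
                              seed = cfg$seed) {
  dur <- duration_s %||% max(35, cfg$epoch_duration_s + 5)
  traces <- lapply(seq_len(n_recordings), function(i)
    gen_voltage(cfg, NULL, coupling_gain = 0, duration_s = dur,
                seed = derive_seed(seed, paste0("nulldb", i))))
  manifest <- data.frame(
    recording_id = sprintf("rec%03d", seq_len(n_recordings)),
    subject = sprintf("synthS%02d", 1 + (seq_len(n_recordings) - 1) %% 4),
    depth_mm = round(seq(-4, 4, length.out = n_recordings), 1),
    stringsAsFactors = FALSE)
  build_segment_db(traces, manifest)
}

#' Generate a fully labeled synthetic session
#'
#' Mixes coupled (gain `cfg$coupling_gain`) and uncoupled (gain 0) epochs
#' across active and passive movements, and assigns synthetic clinician
#' labels as a noisy function of the true coupling (`label_error_rate`
#' flip probability), emulating the observed structure of
#' clinician/quantitative disagreement. Deterministic given `cfg`.
#'
#' @param cfg a [session_config()].
#' @return List with `epochs` (list of [epoch_record()]s) and `truth`
#'   (data.frame: `epoch_id`, `movement_type`, `coupling_gain`,
#'   `latency_s`, `clinician_label`).
#' @export
gen_labeled_session <- function(cfg) {
  n <- cfg$n_epochs
  assign_seed <- derive_seed(cfg$seed, "assign")
  plan <- with_seed(assign_seed, {
    movement <- ifelse(runif(n) < cfg$movement_mix, "passive", "active")
    coupled <- runif(n) < cfg$coupled_fraction
    data.frame(epoch_id = sprintf("ep%03d", seq_len(n)),
               movement_type = movement,
               coupling_gain = ifelse(coupled, cfg$coupling_gain, 0),
               latency_s = cfg$latency_s,
               stringsAsFactors = FALSE)
  })
  truth_label <- ifelse(plan$coupling_gain > 0, "clin_plus", "clin_minus")
  flip <- with_seed(derive_seed(cfg$seed, "labels"),
                    runif(n) < cfg$label_error_rate)
  plan$clinician_label <- ifelse(flip,
                                 ifelse(truth_label == "clin_plus",
                                        "clin_minus", "clin_plus"),
                                 truth_label)
  epochs <- lapply(seq_len(n), function(i) {
    kt <- gen_kinematics(cfg, plan$movement_type[i],
                         seed = derive_seed(cfg$seed, plan$epoch_id[i]))
    vt <- gen_voltage(cfg, attr(kt, "envelope"),
                      coupling_gain = plan$coupling_gain[i],
                      seed = derive_seed(cfg$seed,
                                         paste0(plan$epoch_id[i], "_v")))
    epoch_record(plan$epoch_id[i], plan$movement_type[i],
                 plan$clinician_label[i], kt, vt)
  })
  list(epochs = epochs, truth = plan)
}
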