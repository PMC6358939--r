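# Synthetic plant: posture-dependent static pressure maps with an additive
# heartbeat component, paired with an ECG-like reference trace. Stands in for
# human-subject recordings so the posture classifier, extraction and sensor
# selection stages can be exercised and validated end to end.

# Parametric description of each posture's back-contact footprint. Each
# component is an elliptical Gaussian pressure blob (amplitude in volts,
# centre in grid coordinates, spreads in cells). Postures 1-4 are distinct
# comfortable driving postures (different recline/height, hence different
# contact height, spread and lateral position); postures 5 and 6 are posture 1
# with the torso leaning 10 degrees left/right: the contact mass translates
# 2-3 columns sideways, compresses laterally and loads one side more, and the
# cardiac coupling into the mat collapses (the lean decouples the back from
# the sensor plane), which is modelled by a strong attenuation factor.
posture_params <- function(posture_id) {
  if (!is.numeric(posture_id) || length(posture_id) != 1L ||
      is.na(posture_id) || posture_id != as.integer(posture_id) ||
      posture_id < 1L || posture_id > 6L) {
    stop_domain("`posture_id` must be an integer in 1..6")
  }
  base <- switch(as.integer(posture_id),
    # posture 1: reference comfortable posture, spine around column 5,
    # densest lumbar contact at row 12 / column 5 (sensor 181)
    `1` = list(
      components = list(
        c(amp = 1.70, r0 = 12.0, c0 = 5.0, sr = 2.2, sc = 2.6),
        c(amp = 1.20, r0 = 12.0, c0 = 5.0, sr = 0.55, sc = 0.55),
        c(amp = 1.10, r0 = 4.5, c0 = 2.5, sr = 1.6, sc = 1.7),
        c(amp = 1.20, r0 = 4.5, c0 = 8.0, sr = 1.6, sc = 1.7)
      ),
      col_shift = 0, side_gradient = 0, coupling_atten = 1
    ),
    # posture 2: upright, compact low contact around column 10 (peak 186)
    `2` = list(
      components = list(
        c(amp = 1.80, r0 = 12.0, c0 = 10.0, sr = 1.7, sc = 2.0),
        c(amp = 1.20, r0 = 12.0, c0 = 10.0, sr = 0.55, sc = 0.55),
        c(amp = 0.50, r0 = 5.0, c0 = 7.0, sr = 1.4, sc = 1.5),
        c(amp = 0.55, r0 = 5.0, c0 = 13.0, sr = 1.4, sc = 1.5)
      ),
      col_shift = 0, side_gradient = 0, coupling_atten = 1
    ),
    # posture 3: reclined, broad contact with strong shoulder load (peak 202)
    `3` = list(
      components = list(
        c(amp = 1.60, r0 = 13.0, c0 = 10.0, sr = 2.8, sc = 2.9),
        c(amp = 1.20, r0 = 13.0, c0 = 10.0, sr = 0.55, sc = 0.55),
        c(amp = 1.60, r0 = 4.0, c0 = 7.0, sr = 2.0, sc = 1.9),
        c(amp = 1.70, r0 = 4.0, c0 = 13.0, sr = 2.0, sc = 1.9)
      ),
      col_shift = 0, side_gradient = 0, coupling_atten = 1
    ),
    # posture 4: tall, vertically stretched and narrow contact (peak 185)
    `4` = list(
      components = list(
        c(amp = 1.70, r0 = 12.0, c0 = 9.0, sr = 3.2, sc = 1.7),
        c(amp = 1.20, r0 = 12.0, c0 = 9.0, sr = 0.55, sc = 0.55),
        c(amp = 1.00, r0 = 3.5, c0 = 6.0, sr = 1.8, sc = 1.4),
        c(amp = 1.00, r0 = 3.5, c0 = 12.0, sr = 1.8, sc = 1.4)
      ),
      col_shift = 0, side_gradient = 0, coupling_atten = 1
    ),
    # posture 5: posture 1 leaning left 10 degrees
    `5` = list(
      components = list(
        c(amp = 1.70, r0 = 12.0, c0 = 5.0, sr = 2.2, sc = 2.6 * 0.8),
        c(amp = 1.20, r0 = 12.0, c0 = 5.0, sr = 0.55, sc = 0.55 * 0.8),
        c(amp = 1.10, r0 = 4.5, c0 = 2.5, sr = 1.6, sc = 1.7 * 0.8),
        c(amp = 1.20, r0 = 4.5, c0 = 8.0, sr = 1.6, sc = 1.7 * 0.8)
      ),
      col_shift = -2.5, side_gradient = -0.08, coupling_atten = 0.01
    ),
    # posture 6: posture 1 leaning right 10 degrees
    `6` = list(
      components = list(
        c(amp = 1.70, r0 = 12.0, c0 = 5.0, sr = 2.2, sc = 2.6 * 0.8),
        c(amp = 1.20, r0 = 12.0, c0 = 5.0, sr = 0.55, sc = 0.55 * 0.8),
        c(amp = 1.10, r0 = 4.5, c0 = 2.5, sr = 1.6, sc = 1.7 * 0.8),
        c(amp = 1.20, r0 = 4.5, c0 = 8.0, sr = 1.6, sc = 1.7 * 0.8)
      ),
      col_shift = 2.5, side_gradient = 0.08, coupling_atten = 0.01
    )
  )
  base
}

# Evaluate the sum-of-Gaussians pressure surface on the 16x16 grid.
build_base_map <- function(params) {
  rr <- matrix(seq_len(MAT_NROW), MAT_NROW, MAT_NCOL)
  cc <- matrix(seq_len(MAT_NCOL), MAT_NROW, MAT_NCOL, byrow = TRUE)
  g <- matrix(0, MAT_NROW, MAT_NCOL)
  for (cmp in params$components) {
    c0 <- cmp[["c0"]] + params$col_shift
    g <- g + cmp[["amp"]] *
      exp(-((rr - cmp[["r0"]])^2 / (2 * cmp[["sr"]]^2) +
            (cc - c0)^2 / (2 * cmp[["sc"]]^2)))
  }
  if (params$side_gradient != 0) {
    centre <- mean(range(cc)) + params$col_shift
    g <- g * pmax(0, 1 + params$side_gradient * (cc - centre))
  }
  g
}

#' Deterministic pressure template for a driving posture
#'
#' Builds the noise-free 16x16 static pressure distribution for one of the six
#' driving postures, together with the contact mask (cells pressed by the
#' driver's back) and the per-cell heartbeat coupling gain. Postures 1-4 are
#' distinct comfortable postures differing in contact height, spread and
#' lateral position; postures 5 and 6 lean the torso 10 degrees left/right of
#' posture 1, translating the contact mass sideways and attenuating the
#' cardiac coupling so strongly that the heartbeat cannot be recovered.
#'
#' Coupling is additive and proportional to the local static pressure:
#' `coupling_map = coupling_fraction * base_map` inside the contact mask and
#' zero outside. The mat is indexed row-major from the top-left corner.
#'
#' @param posture_id Integer 1-6.
#' @param contact_threshold Pressure (volts) above which a cell counts as in
#'   contact with the back. Default 0.3 V.
#' @param coupling_fraction Peak-to-peak heartbeat amplitude as a fraction of
#'   the local static pressure. Default 0.012 (about 30 mV at a 2.5 V cell).
#' @return An object of class `posture_template`: a list with `posture_id`,
#'   `base_map` (16x16 volts), `contact_mask` (16x16 logical) and
#'   `coupling_map` (16x16 volts per unit waveform).
#' @export
#' @examples
#' tpl <- posture_template(1)
#' which(tpl$base_map == max(tpl$base_map), arr.ind = TRUE)
posture_template <- function(posture_id, contact_threshold = 0.3,
                             coupling_fraction = 0.012) {
  params <- posture_params(posture_id)
  base_map <- build_base_map(params)
  contact_mask <- base_map >= contact_threshold
  coupling_map <- coupling_fraction * base_map * contact_mask *
    params$coupling_atten
  structure(
    list(posture_id = as.integer(posture_id), base_map = base_map,
         contact_mask = contact_mask, coupling_map = coupling_map),
    class = "posture_template"
  )
}

#' @export
print.posture_template <- function(x, ...) {
  cat(sprintf("<posture_template> posture %d: %d contact cells, peak %.2f V at sensor %d\n",
              x$posture_id, sum(x$contact_mask), max(x$base_map),
              template_best_sensor(x)))
  invisible(x)
}

# Row-major sensor index of the maximum-coupling cell (ties: lowest index).
template_best_sensor <- function(template) {
  v <- grid_to_sensor_vector(template$coupling_map)
  which.max(v)
}

#' Unit-amplitude heartbeat waveform
#'
#' Periodic mechanical cardiac waveform embedded in the pressure signals.
#' `"sine"` is a pure sinusoid at the heart-rate fundamental; `"pulse"` is a
#' train of narrow Gaussian bumps (one per beat), a cruder stand-in for the
#' impulsive ballistocardiographic push. Both have peak magnitude 1 and
#' period `60/heart_rate` seconds, with beats centred at
#' `(k + 1/2) * 60/heart_rate`.
#'
#' @param t Numeric vector of sample times (seconds).
#' @param heart_rate Beats per minute, > 0.
#' @param kind `"sine"` (default) or `"pulse"`.
#' @param pulse_width Standard deviation of each Gaussian bump in seconds
#'   (pulse kind only).
#' @return Numeric vector, same length as `t`, peak magnitude 1.
#' @export
heartbeat_waveform <- function(t, heart_rate, kind = c("sine", "pulse"),
                               pulse_width = 0.06) {
  check_scalar_number(heart_rate, "heart_rate", min = 0, strict_min = TRUE)
  kind <- match.arg(kind)
  period <- 60 / heart_rate
  if (kind == "sine") {
    sin(2 * pi * t / period)
  } else {
    # nearest beat centre for each sample; bumps are narrow relative to the
    # period, so summing just the nearest beat suffices
    k <- round(t / period - 0.5)
    centre <- (k + 0.5) * period
    exp(-(t - centre)^2 / (2 * pulse_width^2))
  }
}

#' Synthetic ECG-like reference trace
#'
#' Emulates an electrocardiogram reference recorded simultaneously with the
#' pressure mat: a quasi-periodic train of sharp R-like spikes at the heart
#' rate, phase-locked to [heartbeat_waveform()] of the same configuration
#' (beats at `(k + 1/2)` periods), plus additive measurement noise. No P/Q/S/T
#' morphology is modelled: only the periodicity and phase matter to the
#' downstream correlation stage.
#'
#' @param duration Recording length in seconds.
#' @param sample_rate Sampling rate in Hz; must exceed twice the heart-rate
#'   fundamental.
#' @param heart_rate Beats per minute, > 0.
#' @param seed Integer seed for the additive noise (optional).
#' @param spike_width R-spike standard deviation in seconds.
#' @param noise_sd Additive Gaussian noise level (spike amplitude is 1).
#' @return Numeric vector of length `round(duration * sample_rate)`.
#' @export
synth_ecg <- function(duration, sample_rate, heart_rate, seed = NULL,
                      spike_width = 0.025, noise_sd = 0.02) {
  check_scalar_number(duration, "duration", min = 0, strict_min = TRUE)
  check_scalar_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  check_scalar_number(heart_rate, "heart_rate", min = 0, strict_min = TRUE)
  if (sample_rate <= 2 * heart_rate / 60) {
    stop_domain("`sample_rate` must exceed twice the heart-rate fundamental (Nyquist)")
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  period <- 60 / heart_rate
  k <- round(t / period - 0.5)
  centre <- (k + 0.5) * period
  spikes <- exp(-(t - centre)^2 / (2 * spike_width^2))
  with_seed(seed, spikes + rnorm(n, sd = noise_sd))
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of one synthetic pressure-mat
#' recording. Defaults reflect the study conditions: 60 s recordings sampled
#' at 30 Hz, a resting heart rate in the high 70s bpm, millivolt-scale sensor
#' noise and a unit body-weight scale.
#'
#' @param posture_id Driving posture 1-6.
#' @param duration Recording length, seconds (> 0).
#' @param sample_rate Sampling rate, Hz.
#' @param heart_rate Beats per minute.
#' @param kind Heartbeat waveform kind, `"sine"` or `"pulse"`.
#' @param coupling_scale Dimensionless multiplier on the template coupling map.
#' @param noise_sd Per-sample Gaussian sensor noise, volts.
#' @param subject_scale Dimensionless body-weight multiplier on the static map.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(posture_id = 1L, duration = 60, sample_rate = 30,
                       heart_rate = 78, kind = "sine", coupling_scale = 1,
                       noise_sd = 0.004, subject_scale = 1, seed = 1L) {
  posture_params(posture_id) # validates the id
  check_scalar_number(duration, "duration", min = 0, strict_min = TRUE)
  check_scalar_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  check_scalar_number(heart_rate, "heart_rate", min = 0, strict_min = TRUE)
  check_scalar_number(coupling_scale, "coupling_scale", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(subject_scale, "subject_scale", min = 0, strict_min = TRUE)
  if (sample_rate <= 2 * heart_rate / 60) {
    stop_domain("`sample_rate` must exceed twice the heart-rate fundamental (Nyquist)")
  }
  kind <- match.arg(kind, c("sine", "pulse"))
  structure(
    list(posture_id = as.integer(posture_id), duration = duration,
         sample_rate = sample_rate, heart_rate = heart_rate, kind = kind,
         coupling_scale = coupling_scale, noise_sd = noise_sd,
         subject_scale = subject_scale, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> posture %d, %g s @ %g Hz, HR %g bpm (%s), coupling x%g, noise %g V, subject x%g, seed %d\n",
    x$posture_id, x$duration, x$sample_rate, x$heart_rate, x$kind,
    x$coupling_scale, x$noise_sd, x$subject_scale, x$seed))
  invisible(x)
}

#' Simulate a pressure-mat recording with ground truth
#'
#' Generates one synthetic recording under the additive signal model: sensor
#' `s` reads `base_map[s] * subject_scale + coupling_scale * coupling_map[s] *
#' w(t) + N(0, noise_sd)` where `w(t)` is the unit-amplitude heartbeat
#' waveform. A phase-locked ECG-like reference and the identity of the
#' maximum-coupling sensor are returned as ground truth for validation.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `recording` (class `pressure_recording`:
#'   `samples` T x 256 matrix in row-major sensor order, `sample_rate`,
#'   `duration`, `posture_id`) and `truth` (class `synthetic_truth`:
#'   `heartbeat_waveform`, `ecg_reference`, `true_best_sensor`, `config`).
#' @export
#' @examples
#' sim <- generate_recording(sim_config(posture_id = 1, duration = 10, seed = 7))
#' dim(sim$recording$samples)
#' sim$truth$true_best_sensor
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  template <- posture_template(config$posture_id)
  n <- round(config$duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  w <- heartbeat_waveform(t, config$heart_rate, config$kind)
  base <- grid_to_sensor_vector(template$base_map) * config$subject_scale
  coup <- grid_to_sensor_vector(template$coupling_map) * config$subject_scale *
    config$coupling_scale
  samples <- with_seed(config$seed, {
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(n * MAT_NSENSOR, sd = config$noise_sd), n, MAT_NSENSOR)
    } else {
      matrix(0, n, MAT_NSENSOR)
    }
    rep(1, n) %o% base + w %o% coup + noise
  })
  colnames(samples) <- sprintf("s%03d", seq_len(MAT_NSENSOR))
  ecg <- synth_ecg(config$duration, config$sample_rate, config$heart_rate,
                   seed = config$seed + 1000000L)
  recording <- structure(
    list(samples = samples, sample_rate = config$sample_rate,
         duration = config$duration, posture_id = config$posture_id),
    class = "pressure_recording"
  )
  truth <- structure(
    list(heartbeat_waveform = w, ecg_reference = ecg,
         true_best_sensor = template_best_sensor(template), config = config),
    class = "synthetic_truth"
  )
  list(recording = recording, truth = truth)
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> %d samples x %d sensors @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate, x$duration))
  invisible(x)
}

#' Labelled synthetic posture-frame dataset
#'
#' Generates the posture-classification dataset: for every subject x posture x
#' group one static 16x16 pressure frame, drawn from the posture template with
#' a per-subject body-weight scale, per-frame postural jitter (small shifts,
#' spread and amplitude perturbations of the template components) and additive
#' cell noise. The defaults (10 subjects, 20 groups, 6 postures) reproduce the
#' study's 1200-frame design.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_groups_per_posture Frames per subject and posture (>= 1).
#' @param postures Integer vector of posture ids, each in 1-6, non-empty.
#' @param seed Integer RNG seed.
#' @param frame_noise_sd Additive per-cell Gaussian noise, volts.
#' @param subject_scale_range Range of the uniform per-subject weight scale.
#' @return An object of class `posture_dataset`: list with `frames` (16 x 16 x
#'   N array), `labels` (integer posture per frame), `subject` (integer
#'   subject per frame).
#' @export
generate_posture_dataset <- function(n_subjects = 10L,
                                     n_groups_per_posture = 20L,
                                     postures = 1:6, seed = 1L,
                                     frame_noise_sd = 0.05,
                                     subject_scale_range = c(0.85, 1.15)) {
  if (length(postures) < 1L) stop_domain("`postures` must be non-empty")
  lapply(postures, posture_params) # validates ids
  n_subjects <- as.integer(n_subjects)
  n_groups <- as.integer(n_groups_per_posture)
  if (n_subjects < 1L || n_groups < 1L) {
    stop_domain("subject and group counts must be >= 1")
  }
  n_total <- n_subjects * n_groups * length(postures)
  frames <- array(NA_real_, c(MAT_NROW, MAT_NCOL, n_total))
  labels <- integer(n_total)
  subject <- integer(n_total)
  with_seed(seed, {
    idx <- 0L
    for (subj in seq_len(n_subjects)) {
      sscale <- runif(1, subject_scale_range[1], subject_scale_range[2])
      for (p in postures) {
        for (g in seq_len(n_groups)) {
          params <- posture_params(p)
          # postural jitter: the sitter never reproduces a posture exactly
          params$components <- lapply(params$components, function(cmp) {
            cmp[["r0"]] <- cmp[["r0"]] + runif(1, -0.5, 0.5)
            cmp[["c0"]] <- cmp[["c0"]] + runif(1, -0.5, 0.5)
            sp <- runif(1, 0.92, 1.08)
            cmp[["sr"]] <- cmp[["sr"]] * sp
            cmp[["sc"]] <- cmp[["sc"]] * sp
            cmp[["amp"]] <- cmp[["amp"]] * runif(1, 0.95, 1.05)
            cmp
          })
          frame <- build_base_map(params) * sscale
          frame <- frame + matrix(rnorm(MAT_NROW * MAT_NCOL,
                                        sd = frame_noise_sd),
                                  MAT_NROW, MAT_NCOL)
          frame[frame < 0] <- 0
          idx <- idx + 1L
          frames[, , idx] <- frame
          labels[idx] <- as.integer(p)
          subject[idx] <- subj
        }
      }
    }
  })
  structure(list(frames = frames, labels = labels, subject = subject),
            class = "posture_dataset")
}

#' @export
print.posture_dataset <- function(x, ...) {
  cat(sprintf("<posture_dataset> %d frames, %d postures, %d subjects\n",
              length(x$labels), length(unique(x$labels)),
              length(unique(x$subject))))
  invisible(x)
}
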