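# Band conversion, brick-wall filtering, periodogram peaks, extraction maps.

test_that("bpm-to-band conversion implements both documented modes", {
  b <- bpm_to_band(75, 80, "physical", margin = 0)
  expect_equal(c(b$f_lo, b$f_hi), c(75 / 60, 80 / 60), tolerance = 1e-12)
  bl <- bpm_to_band(75, 80, "paper-literal")
  expect_equal(c(bl$f_lo, bl$f_hi), c(0.75, 0.80), tolerance = 1e-12)
  b1 <- bpm_to_band(60, 60, "physical", margin = 0)
  expect_equal(c(b1$f_lo, b1$f_hi), c(1, 1))
  bm <- bpm_to_band(75, 80, "physical", margin = 0.05)
  expect_equal(c(bm$f_lo, bm$f_hi), c(1.2, 80 / 60 + 0.05), tolerance = 1e-12)
  expect_error(bpm_to_band(0, 80), "lo_bpm")
  expect_error(bpm_to_band(80, 75), "hi_bpm")
  # bands outside (0, Nyquist) are rejected when applied
  expect_error(bandpass_fft(rnorm(100), 30, c(14, 16)), "Nyquist")
  expect_error(bandpass_fft(rnorm(100), 30, c(-1, 2)), "Nyquist")
})

test_that("brick-wall filtering passes, stops and superposes exactly", {
  fs <- 30; n <- 600
  t <- (0:(n - 1)) / fs
  band <- c(1.0, 1.6)
  x_in <- sin(2 * pi * 1.3 * t) # 1.3 Hz sits on DFT bin 26
  y <- bandpass_fft(x_in, fs, band)
  expect_lt(max(abs(y - (x_in - mean(x_in)))), 1e-9)
  x_out <- sin(2 * pi * 4.8 * t) # 3x f_hi, on a bin
  expect_lt(max(abs(bandpass_fft(x_out, fs, band))), 1e-9)
  # linearity
  a <- 2.5; b <- -1.2
  mix <- bandpass_fft(a * x_in + b * x_out, fs, band)
  expect_lt(max(abs(mix - (a * bandpass_fft(x_in, fs, band) +
                             b * bandpass_fft(x_out, fs, band)))), 1e-9)
  # near-full band reproduces the centred signal (odd length, so no energy
  # sits on an exact Nyquist bin outside the open band)
  set.seed(2)
  z <- rnorm(601)
  wide <- bandpass_fft(z, fs, c(fs / 601, fs / 2 - 1e-9))
  expect_lt(max(abs(wide - (z - mean(z)))), 1e-9)
  expect_equal(mean(bandpass_fft(z, fs, band)), 0, tolerance = 1e-12)
  expect_error(bandpass_fft(1, fs, band), "length")
})

test_that("the matrix filter matches the per-column filter", {
  set.seed(3)
  m <- matrix(rnorm(300), 100, 3)
  got <- seatbeat:::bandpass_fft_matrix(m, 30, c(1, 2))
  for (j in 1:3) {
    expect_equal(got[, j], bandpass_fft(m[, j], 30, c(1, 2)),
                 tolerance = 1e-12)
  }
})

test_that("periodogram peaks follow the closed form for sinusoids", {
  fs <- 30; n <- 900
  t <- (0:(n - 1)) / fs
  f0 <- 1.3 # bin 39
  x <- sin(2 * pi * f0 * t)
  pk <- power_spectrum_peak(x, fs, c(0.5, 2))
  expect_equal(pk$peak_frequency, f0, tolerance = 1e-12)
  expect_equal(pk$peak_value, n / 4, tolerance = 1e-6)
  # doubling the amplitude quadruples the peak
  pk2 <- power_spectrum_peak(2 * x, fs, c(0.5, 2))
  expect_equal(pk2$peak_value / pk$peak_value, 4, tolerance = 1e-9)
  # zero signal -> zero peak at the lowest in-band bin
  pk0 <- power_spectrum_peak(numeric(n), fs, c(0.5, 2))
  expect_equal(pk0$peak_value, 0)
  expect_error(power_spectrum_peak(x, fs, c(1.301, 1.302)), "no positive DFT bin")
  # Parseval consistency of the periodogram convention: the full-spectrum
  # sum of |X|^2 / n over all bins, divided by n, is the mean square
  P_all <- Mod(fft(x))^2 / n
  expect_equal(sum(P_all) / n, mean(x^2), tolerance = 1e-9)
})

test_that("mean pressure map averages sensors onto the grid", {
  rec <- structure(list(samples = matrix(2.5, 10, 256), sample_rate = 30,
                        duration = 1 / 3, posture_id = 1L),
                   class = "pressure_recording")
  expect_equal(mean_pressure_map(rec), matrix(2.5, 16, 16))
  # posture-1 recording: grid maximum sits at sensor 181
  sim <- generate_recording(sim_config(posture_id = 1, duration = 5, seed = 2))
  m <- mean_pressure_map(sim$recording)
  expect_equal(which.max(seatbeat:::grid_to_sensor_vector(m)), 181L)
  # sample order does not matter
  rec2 <- sim$recording
  rec2$samples <- rec2$samples[rev(seq_len(nrow(rec2$samples))), ]
  expect_equal(mean_pressure_map(rec2), m)
})

test_that("extraction recovers the cardiac frequency and mirrors the pressure map", {
  sim <- generate_recording(sim_config(posture_id = 1, seed = 5))
  ext <- extract_heartbeat(sim$recording)
  tpl <- posture_template(1)
  contact <- seatbeat:::grid_to_sensor_vector(tpl$contact_mask)
  best <- sim$truth$true_best_sensor
  # peak frequency within one DFT bin of heart_rate / 60
  bin_width <- sim$recording$sample_rate / nrow(sim$recording$samples)
  f_true <- sim$truth$config$heart_rate / 60
  f_best <- seatbeat:::grid_to_sensor_vector(ext$peak_freq_map)[best]
  expect_lte(abs(f_best - f_true), bin_width + 1e-12)
  # peak map concordant with the mean pressure map over contact sensors
  pmap <- seatbeat:::grid_to_sensor_vector(ext$peak_map)
  mmap <- seatbeat:::grid_to_sensor_vector(mean_pressure_map(sim$recording))
  expect_gte(cor(pmap[contact], mmap[contact], method = "spearman"), 0.9)
  # filtered signals are centred
  expect_lt(max(abs(colMeans(ext$filtered))), 1e-9)
  # filtered best-sensor cycle count matches the reference beat count
  fs <- sim$recording$sample_rate
  cycles <- sum(diff(sign(ext$filtered[, best])) > 0)
  beats <- oracle_count_peaks(sim$truth$ecg_reference, 0.5)
  expect_lte(abs(cycles - beats), 1)
})

test_that("a coupling-free noiseless recording extracts to silence", {
  cfg <- sim_config(posture_id = 1, duration = 10, noise_sd = 0,
                    coupling_scale = 0, seed = 1)
  sim <- generate_recording(cfg)
  ext <- extract_heartbeat(sim$recording)
  expect_lt(max(ext$peak_map), 1e-18)
  expect_lt(max(abs(ext$filtered)), 1e-9)
})
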