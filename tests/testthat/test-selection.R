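# Correlation mapping, optimal-sensor selection, posture extractability.

test_that("absolute Pearson correlation matches the from-definition oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_abs(x, 3 * x + 7), 1)
  expect_equal(pearson_abs(x, -x), 1)
  # hand arithmetic: deviations (-2,-1,0,1,2) and (-1,-2,1,0,2) give 8/10
  expect_equal(pearson_abs(x, c(2, 1, 4, 3, 5)), 0.8, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearson_abs(a, b), oracle_pearson_abs(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(v <- pearson_abs(rep(1, 5), x), "constant")
  expect_equal(v, 0)
  expect_error(pearson_abs(1:4, 1:5), "equal length")
})

test_that("lag alignment finds shifted copies and reduces to plain correlation", {
  set.seed(14)
  x <- as.vector(bandpass_fft(rnorm(400), 30, c(0.5, 3)))
  y <- c(rep(0, 5), x[1:395]) # x delayed by 5 samples
  r <- lag_aligned_rho(x, y, 30, lag_window = 10 / 30)
  expect_equal(r$value, 1, tolerance = 1e-6)
  expect_equal(r$best_lag, 5L)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(lag_aligned_rho(a, b, 30, 0)$value, pearson_abs(a, b),
               tolerance = 1e-12)
  # independent white noise stays uncorrelated even after alignment
  set.seed(15)
  vals <- replicate(5, {
    lag_aligned_rho(rnorm(1800), rnorm(1800), 30, 24 / 30)$value
  })
  expect_lt(max(vals), 0.2)
  expect_error(lag_aligned_rho(a, b, 30, 10), "shorter")
})

test_that("widening the lag window never decreases the aligned correlation", {
  set.seed(16)
  for (i in 1:5) {
    x <- rnorm(300); y <- rnorm(300)
    v1 <- lag_aligned_rho(x, y, 30, 5 / 30)$value
    v2 <- lag_aligned_rho(x, y, 30, 15 / 30)$value
    expect_gte(v2, v1)
  }
})

test_that("noiseless recordings correlate perfectly at every coupled sensor", {
  cfg <- sim_config(posture_id = 1, duration = 20, noise_sd = 0, seed = 2)
  sim <- generate_recording(cfg)
  ext <- extract_heartbeat(sim$recording)
  cmap <- correlation_map(ext, sim$truth$heartbeat_waveform,
                          reference_id = "plant waveform")
  coupled <- seatbeat:::grid_to_sensor_vector(
    posture_template(1)$coupling_map) > 0
  expect_true(all(cmap$rho[coupled] > 1 - 1e-6))
  expect_true(all(cmap$rho >= 0 & cmap$rho <= 1))
})

test_that("contact sensors correlate strongly and non-contact sensors weakly", {
  sim <- generate_recording(sim_config(posture_id = 1, seed = 6))
  ext <- extract_heartbeat(sim$recording)
  cmap <- correlation_map(ext, sim$truth$ecg_reference)
  contact <- seatbeat:::grid_to_sensor_vector(posture_template(1)$contact_mask)
  expect_gt(min(cmap$rho[contact]), max(cmap$rho[!contact]))
  expect_gte(min(cmap$rho[contact]), 0.8)
  expect_lt(max(cmap$rho[!contact]), 0.4)
})

test_that("a resampled reference gives the same selection as the native one", {
  sim <- generate_recording(sim_config(posture_id = 1, duration = 20, seed = 3))
  ext <- extract_heartbeat(sim$recording)
  native <- correlation_map(ext, sim$truth$ecg_reference)
  # reference regenerated at 60 Hz, linearly resampled internally
  ref60 <- synth_ecg(20, 60, sim$truth$config$heart_rate,
                     seed = sim$truth$config$seed + 1000000L)
  res <- correlation_map(ext, ref60, reference_rate = 60)
  expect_equal(max(res$rho), max(native$rho), tolerance = 0.02)
  contact <- seatbeat:::grid_to_sensor_vector(posture_template(1)$contact_mask)
  expect_true(contact[which.max(res$rho)])
  expect_true(contact[which.max(native$rho)])
})

test_that("selection picks the maximum with low-index tie-breaking and thresholds extractability", {
  mk_map <- function(rho) structure(
    list(rho = rho, lag = integer(256), lag_window = 0,
         reference_id = "x", band = bpm_to_band(75, 80)),
    class = "correlation_map")
  rho <- rep(0.2, 256); rho[181] <- 0.99
  sel <- select_optimal(mk_map(rho), threshold = 0.6)
  expect_equal(sel$best_sensor, 181L)
  expect_equal(sel$best_rho, 0.99)
  expect_true(sel$extractable)
  sel2 <- select_optimal(mk_map(rep(0.3, 256)), threshold = 0.6)
  expect_false(sel2$extractable)
  expect_equal(sel2$best_sensor, 1L)
  rho3 <- rep(0.1, 256); rho3[c(40, 200)] <- 0.7
  expect_equal(select_optimal(mk_map(rho3))$best_sensor, 40L)
})

test_that("selection recovers the true coupled sensor across seeded simulations", {
  hits <- 0L
  for (s in 1:20) {
    sim <- generate_recording(sim_config(posture_id = 1, seed = 200 + s))
    ext <- extract_heartbeat(sim$recording)
    cmap <- correlation_map(ext, sim$truth$ecg_reference)
    sel <- select_optimal(cmap)
    hits <- hits + (sel$best_sensor == sim$truth$true_best_sensor)
  }
  expect_gte(hits, 19L)
})

test_that("the posture sweep is reproducible and honours the truth for extractable postures", {
  cfg <- sim_config(duration = 30, seed = 40)
  tab <- posture_sweep(c(1, 5), cfg)
  tab2 <- posture_sweep(c(1, 5), cfg)
  expect_identical(tab, tab2)
  expect_true(tab$extractable[tab$posture == 1])
  expect_false(tab$extractable[tab$posture == 5])
  expect_true(tab$sensor_matches_truth[tab$posture == 1])
})
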