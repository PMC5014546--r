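test_that("sensor topographies are unit-norm, dipolar and reproducible", {
  sens <- make_sensor_topographies(32, seed = 4)
  for (topo in sens$topographies)
    expect_equal(sqrt(sum(topo^2)), 1, tolerance = 1e-12)
  # dipolar maps carry both polarities
  expect_true(all(vapply(sens$topographies,
                         function(t) any(t > 0) && any(t < 0), logical(1))))
  # M50 and M100 have opposite polarity (negative mutual projection)
  expect_lt(sum(sens$topographies$m50 * sens$topographies$m100), 0)
  sens2 <- make_sensor_topographies(32, seed = 4)
  expect_identical(sens, sens2)
  expect_error(make_sensor_topographies(4), "channels")
  # noise subspace is orthonormal and orthogonal to the component maps
  M <- sens$noise_mixing
  expect_equal(crossprod(M), diag(ncol(M)), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (topo in sens$topographies)
    expect_lt(max(abs(crossprod(M, topo))), 1e-9)
})

test_that("noiseless evoked responses carry the planted condition effects", {
  sens <- make_sensor_topographies(32, seed = 1)
  fx <- effect_config()
  times_app <- seq(-200, by = 4, length.out = 150)
  times_scene <- seq(-200, by = 4, length.out = 250)

  # all amplitudes zero -> zero evoked
  fx0 <- effect_config()
  fx0$appearance$components$amp[] <- 0
  fx0$appearance$m100_amp[] <- 0
  ev0 <- simulate_subject_evoked(list(lock = "appearance", scene = "REG"),
                                 "Passive", fx0, sens)
  expect_true(all(ev0$data == 0))

  # Passive appearance: REG/RAND RMS ratio at the M50 peak is 1.22
  reg <- rms_timecourse(simulate_subject_evoked(
    list(lock = "appearance", scene = "REG"), "Passive", fx, sens))
  rand <- rms_timecourse(simulate_subject_evoked(
    list(lock = "appearance", scene = "RAND"), "Passive", fx, sens))
  i_peak <- which.min(abs(times_app - 88))
  expect_equal(reg$values[i_peak] / rand$values[i_peak], 1.22,
               tolerance = 0.005)
  # and no REG/RAND difference before the group's effect onset
  pre <- times_app < 87 & times_app >= -200
  expect_lt(max(abs(reg$values[pre] - rand$values[pre])), 1e-9)

  # Passive appearance response lacks the M100 component entirely
  fx_m100 <- effect_config()
  fx_m100$appearance$components$amp[] <- 0   # m100 is set via m100_amp
  ev_p <- simulate_subject_evoked(list(lock = "appearance", scene = "RAND"),
                                  "Passive", fx_m100, sens)
  ev_a <- simulate_subject_evoked(list(lock = "appearance", scene = "RAND"),
                                  "Active", fx_m100, sens)
  expect_true(all(ev_p$data == 0))
  expect_gt(max(abs(ev_a$data)), 1)

  # scene lock: REG-RAND difference zero before 436 ms (Passive), then grows
  sreg <- rms_timecourse(simulate_subject_evoked(
    list(lock = "scene", scene = "REG"), "Passive", fx, sens))
  srand <- rms_timecourse(simulate_subject_evoked(
    list(lock = "scene", scene = "RAND"), "Passive", fx, sens))
  d <- sreg$values - srand$values
  expect_lt(max(abs(d[times_scene < 436])), 1e-9)
  expect_gt(max(d[times_scene > 500]), 0.1)
  # Active group's sustained effect starts later (476 ms)
  areg <- rms_timecourse(simulate_subject_evoked(
    list(lock = "scene", scene = "REG"), "Active", fx, sens))
  arand <- rms_timecourse(simulate_subject_evoked(
    list(lock = "scene", scene = "RAND"), "Active", fx, sens))
  da <- areg$values - arand$values
  expect_lt(max(abs(da[times_scene < 476])), 1e-9)

  # appearance-locked no-change epochs carry no appearance components
  nc <- simulate_subject_evoked(list(lock = "appearance", scene = "REG",
                                     change = FALSE), "Passive", fx, sens)
  expect_true(all(nc$data == 0))
})

test_that("trial simulation adds calibrated noise and outliers", {
  sens <- make_sensor_topographies(16, seed = 2)
  fx <- effect_config()
  ev <- simulate_subject_evoked(list(lock = "appearance", scene = "RAND"),
                                "Active", fx, sens)
  # zero noise -> every trial equals the evoked response
  silent <- list(sd = 0, ar_rho = 0.9, sensor_sd = 0, outlier_frac = 0,
                 outlier_scale = 10)
  tt <- simulate_trials(ev, sens, silent, n_trials = 4, seed = 9)
  for (i in 1:4) expect_equal(tt$data[, , i], ev$data, tolerance = 1e-12)

  # outlier bookkeeping: 2% of 100 trials -> exactly 2 scaled trials
  tt2 <- simulate_trials(ev, sens, fx$noise, n_trials = 100, seed = 10)
  expect_length(tt2$outlier_trials, 2)

  # trial mean converges on the evoked response (SE ~ 1/sqrt(n))
  quiet <- fx$noise
  quiet$outlier_frac <- 0
  tt3 <- simulate_trials(ev, sens, quiet, n_trials = 400, seed = 11)
  avg <- apply(tt3$data, c(1, 2), mean)
  resid <- sqrt(mean((avg - ev$data)^2))
  chan_sd <- sqrt(mean((tt3$data[, , 1] - ev$data)^2))
  expect_lt(resid, 2 * chan_sd / sqrt(400))

  # determinism
  expect_identical(simulate_trials(ev, sens, fx$noise, 8, seed = 5)$data,
                   simulate_trials(ev, sens, fx$noise, 8, seed = 5)$data)
})

test_that("full dataset has the group/condition structure", {
  fx <- effect_config()
  ds <- simulate_dataset(fx, n_passive = 3, n_active = 2, n_channels = 16,
                         n_trials = 6, seed = 42)
  expect_length(ds$Passive, 3)
  expect_length(ds$Active, 2)
  s <- ds$Passive[[1]]
  expect_named(s$scene, c("REG", "RAND"))
  expect_named(s$appearance, c("REG.regular", "REG.random",
                               "RAND.regular", "RAND.random"))
  expect_named(s$nochange, c("REG", "RAND"))
  expect_identical(dim(s$scene$REG$data), c(16L, 250L, 6L))
  expect_identical(dim(s$appearance$REG.regular$data), c(16L, 150L, 6L))
  # reproducibility from the seed
  ds2 <- simulate_dataset(fx, n_passive = 3, n_active = 2, n_channels = 16,
                          n_trials = 6, seed = 42)
  expect_identical(ds$Passive[[2]]$scene$RAND$data,
                   ds2$Passive[[2]]$scene$RAND$data)

  # zero between-subject jitter and zero noise -> identical subjects
  fx_flat <- effect_config()
  fx_flat$subject$gain_sd_log <- 0
  fx_flat$subject$latency_jitter_sd_ms <- 0
  fx_flat$noise <- list(sd = 0, ar_rho = 0.9, sensor_sd = 0,
                        outlier_frac = 0, outlier_scale = 1)
  ds3 <- simulate_dataset(fx_flat, n_passive = 2, n_active = 2,
                          n_channels = 16, n_trials = 2, seed = 1)
  expect_equal(ds3$Passive[[1]]$scene$REG$data,
               ds3$Passive[[2]]$scene$REG$data, tolerance = 1e-12)
})

test_that("behavioural simulation reproduces the planted detection profile", {
  fx <- effect_config()
  tab <- simulate_behavior(fx, n_subjects = 200, n_change_per_cell = 96,
                           n_nochange_per_scene = 192, seed = 8)
  expect_s3_class(tab, "behavior_table")
  expect_true(all(tab$hits <= tab$n_change & tab$hits >= 0))
  expect_true(all(tab$false_alarms <= tab$n_nochange))
  # group-mean hit rate near the planted 76.1%
  expect_equal(mean(tab$hits / tab$n_change), 0.761, tolerance = 0.02)
  expect_equal(mean(tab$false_alarms / tab$n_nochange), 0.0625,
               tolerance = 0.01)
  # regular appearing sources detected ~27 ms faster
  rt <- vapply(split(seq_len(nrow(tab)), tab$appearing), function(i)
    mean(unlist(tab$detection_times_ms[i])), numeric(1))
  expect_equal(unname(rt["regular"] - rt["random"]), -27, tolerance = 6)
  # REG scenes faster than RAND scenes
  rt_scene <- vapply(split(seq_len(nrow(tab)), tab$scene), function(i)
    mean(unlist(tab$detection_times_ms[i])), numeric(1))
  expect_lt(rt_scene[["REG"]], rt_scene[["RAND"]])
  expect_identical(simulate_behavior(fx, 5, seed = 3),
                   simulate_behavior(fx, 5, seed = 3))
})
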