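make_regular_source <- function(carrier = 500, tone = 100, gap = 50,
                                offset = 0, onset = 0) {
  structure(list(carrier_hz = carrier, tone_dur_ms = tone,
                 gap_mode = "regular", gap_ms = gap, gap_range_ms = c(1, 167),
                 gaps_ms = NULL, start_offset_ms = offset, onset_ms = onset),
            class = "source_spec")
}

test_that("regular sources render as an arithmetic pip train", {
  fs <- 44100
  src <- make_regular_source(tone = 100, gap = 50)
  x <- render_source(src, duration_ms = 1000, rate_hz = fs)
  expect_length(x, 44100)
  active <- abs(x) > 0
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pip_starts <- starts[r$values]
  # pip onsets at k * (tone + gap) in samples (the very first sample of a
  # pip is sin(0) = 0, so runs of nonzero samples start one sample later)
  expect_equal(pip_starts - 2L,
               round((0:(length(pip_starts) - 1)) * 150 * fs / 1000),
               tolerance = 1e-8)
  # a full 100 ms pip spans 4410 samples (first exactly zero)
  expect_equal(r$lengths[r$values][1], 4409)
  # interior RMS of a pip is peak / sqrt(2)
  interior <- x[500:3900]
  expect_equal(sqrt(mean(interior^2)), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(render_source(make_regular_source(carrier = 30000), 1000, fs),
               "Nyquist")
})

test_that("scenes are normalised, ramped, and event-stamped", {
  spec <- draw_scene_spec(seed = 21)
  w <- render_scene(spec)
  expect_s3_class(w, "waveform")
  expect_length(w$samples, round(spec$duration_ms * 44.1))
  expect_lte(max(abs(w$samples)), 0.9 + 1e-12)
  expect_named(w$events, c("onset", "appearance", "offset"))
  # the 30 ms raised-cosine onset ramp keeps early samples small
  n30 <- round(0.03 * 44100)
  early <- max(abs(w$samples[1:round(n30 / 6)]))
  expect_lt(early, 0.1)
  # empty scene renders silence
  empty <- spec
  empty$sources <- list()
  empty$has_change <- FALSE
  empty$appearing_source <- NULL
  expect_true(all(render_scene(empty)$samples == 0))
})

test_that("matched pairs are bit-identical before the appearance", {
  spec <- draw_scene_spec(seed = 31, has_change = TRUE)
  pair <- make_matched_pair(spec)
  ws <- render_pair(pair)
  n_pre <- floor(spec$appearance_time_ms * 44100 / 1000)
  expect_identical(ws$change$samples[seq_len(n_pre)],
                   ws$no_change$samples[seq_len(n_pre)])
  d <- ws$change$samples - ws$no_change$samples
  expect_gt(max(abs(d)), 0)
  expect_gte(min(which(d != 0)), n_pre)
})

test_that("rendering is deterministic down to WAV bytes", {
  spec <- draw_scene_spec(seed = 41)
  w <- render_scene(spec)
  f1 <- tempfile(fileext = ".wav")
  f2 <- tempfile(fileext = ".wav")
  write_wav(w, f1)
  write_wav(render_scene(draw_scene_spec(seed = 41)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # float32 round trip preserves samples to float precision
  f3 <- tempfile(fileext = ".wav")
  write_wav(w, f3, encoding = "float32")
  back <- read_wav(f3)
  expect_equal(back$rate_hz, 44100)
  expect_equal(back$samples, w$samples, tolerance = 1e-6)
  unlink(c(f1, f2, f3))
})

test_that("auditory spectrogram isolates and tracks sources", {
  pool <- build_carrier_pool(200, 2800, 2)
  params <- stimulus_params(pool = pool)
  spec <- draw_scene_spec(params, "REG", has_change = FALSE, seed = 7)
  spec$sources <- list(make_regular_source(carrier = pool$freqs_hz[4],
                                           tone = 80, gap = 70))
  w <- render_scene(spec)
  m <- auditory_spectrogram(w, pool)
  e <- rowMeans(m)
  expect_identical(which(e > 0.1 * max(e)), 4L)
  # silence maps to zero
  silent <- structure(list(samples = numeric(4410), rate_hz = 44100,
                           events = NULL), class = "waveform")
  expect_true(all(auditory_spectrogram(silent, pool) == 0))
  # regular source: band energy periodic at tone + gap = 150 ms
  ch <- m[4, ]
  frame_ms <- attr(m, "frame_ms")
  ac <- stats::acf(ch, lag.max = round(220 / frame_ms), plot = FALSE)$acf[-1]
  lag_ms <- which.max(ac[round(100 / frame_ms):round(220 / frame_ms)]) +
    round(100 / frame_ms) - 1
  expect_lt(abs(lag_ms * frame_ms - 150), 10)
})

test_that("stimulus sets write WAV, JSON and CSV artefacts", {
  dir <- tempfile()
  manifest <- draw_block_manifest(n_blocks = 1, trials_per_block = 8,
                                  seed = 3)
  expect_identical(nrow(manifest), 8L)
  expect_identical(sum(manifest$change), 4L)
  out <- write_stimulus_set(manifest, dir)
  expect_true(all(file.exists(out$wav)))
  expect_true(all(file.exists(out$json)))
  expect_true(file.exists(file.path(dir, "manifest_block01.csv")))
  side <- jsonlite::read_json(out$json[1])
  expect_true(all(c("duration_ms", "scene_regularity", "sources",
                    "events_ms") %in% names(side)))
  # no-change members must not exceed the matched change duration rules
  expect_true(all(out$duration_ms >= 2500 - 1e-6 &
                  out$duration_ms <= 3500 + 1e-6))
  unlink(dir, recursive = TRUE)
})
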