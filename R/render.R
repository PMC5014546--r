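#' Render one tone-pip source to a waveform
#'
#' Generates the pure-tone pip train of a single source: pips of fixed
#' duration at the source carrier, separated by fixed (regular source) or
#' pre-drawn random (random source) silent gaps, starting at
#' `onset_ms + start_offset_ms`. Each pip carries a short cosine on/off ramp
#' to suppress spectral splatter; the final pip is truncated at scene end.
#'
#' @param src a `source_spec` (see [draw_scene_spec()]).
#' @param duration_ms scene duration in ms.
#' @param rate_hz sampling rate in Hz.
#' @param pip_ramp_ms per-pip cosine ramp duration (ms).
#' @return numeric vector of `round(duration_ms * rate_hz / 1000)` samples,
#'   peak amplitude 1 before any scene-level normalisation.
#' @export
render_source <- function(src, duration_ms, rate_hz = 44100, pip_ramp_ms = 5) {
  if (src$carrier_hz >= rate_hz / 2)
    stop("carrier frequency at or above Nyquist")
  if (duration_ms <= 0) stop("'duration_ms' must be positive")
  n <- as.integer(round(duration_ms * rate_hz / 1000))
  x <- numeric(n)
  tone <- src$tone_dur_ms
  cur <- src$onset_ms + src$start_offset_ms
  k <- 0L
  nramp_full <- max(1L, round(pip_ramp_ms * rate_hz / 1000))
  while (cur < duration_ms) {
    i0 <- as.integer(round(cur * rate_hz / 1000)) + 1L
    i1 <- min(as.integer(round((cur + tone) * rate_hz / 1000)), n)
    if (i0 <= n && i1 >= i0) {
      len <- i1 - i0 + 1L
      tt <- (seq_len(len) - 1L) / rate_hz
      pip <- sin(2 * pi * src$carrier_hz * tt)
      nr <- min(nramp_full, floor(len / 2))
      if (nr > 0L) {
        env <- raised_cosine(nr)
        pip[seq_len(nr)] <- pip[seq_len(nr)] * env
        pip[len - seq_len(nr) + 1L] <- pip[len - seq_len(nr) + 1L] * env
      }
      x[i0:i1] <- x[i0:i1] + pip
    }
    k <- k + 1L
    gap <- if (src$gap_mode == "regular") src$gap_ms
           else if (k <= length(src$gaps_ms)) src$gaps_ms[k]
           else mean(src$gap_range_ms)
    cur <- cur + tone + gap
  }
  x
}

# Sum all sources of a spec into one un-normalised scene signal.
render_scene_raw <- function(spec, rate_hz) {
  n <- as.integer(round(spec$duration_ms * rate_hz / 1000))
  x <- numeric(n)
  pip_ramp <- spec$params$pip_ramp_ms %||% 5
  for (src in spec$sources)
    x <- x + render_source(src, spec$duration_ms, rate_hz, pip_ramp)
  if (isTRUE(spec$has_change) && !is.null(spec$appearing_source))
    x <- x + render_source(spec$appearing_source, spec$duration_ms,
                           rate_hz, pip_ramp)
  x
}

#' Render a scene specification to audio
#'
#' Sums the rendered sources (original plus, for change scenes, the
#' appearing source delayed to the appearance time), peak-normalises the
#' sum, then applies the whole-scene 30 ms raised-cosine onset and offset
#' ramps. Matched change/no-change pairs must share the change member's
#' normalisation factor so that pre-appearance samples stay identical; use
#' [render_pair()] or pass `peak_ref`.
#'
#' @param spec a `scene_spec`.
#' @param rate_hz sampling rate (Hz); defaults to the spec's stimulus rate.
#' @param peak_ref optional externally supplied peak used for normalisation
#'   (the raw-sum peak of a matched change scene).
#' @return an object of class `waveform`: list with `samples` (|x| <= 1),
#'   `rate_hz`, `events` (named ms markers: onset, appearance if any,
#'   offset) and `raw_peak` (peak of the un-normalised sum).
#' @export
render_scene <- function(spec, rate_hz = NULL, peak_ref = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  rate_hz <- rate_hz %||% spec$params$rate_hz
  x <- render_scene_raw(spec, rate_hz)
  raw_peak <- max(abs(x))
  peak <- peak_ref %||% raw_peak
  target <- spec$params$norm_peak %||% 0.9
  if (peak > 0) x <- x * (target / peak)
  nramp <- round((spec$params$scene_ramp_ms %||% 30) * rate_hz / 1000)
  n <- length(x)
  if (nramp > 0 && n >= 2 * nramp) {
    env <- raised_cosine(nramp)
    x[seq_len(nramp)] <- x[seq_len(nramp)] * env
    x[n - seq_len(nramp) + 1L] <- x[n - seq_len(nramp) + 1L] * env
  }
  if (any(abs(x) > 1))
    stop("internal error: normalised scene exceeds unit amplitude")
  events <- c(onset = 0, offset = spec$duration_ms)
  if (isTRUE(spec$has_change))
    events <- c(events[1], appearance = spec$appearance_time_ms, events[2])
  structure(list(samples = x, rate_hz = rate_hz, events = events,
                 raw_peak = raw_peak),
            class = "waveform")
}

#' Render a matched change/no-change pair with shared normalisation
#'
#' @param pair output of [make_matched_pair()].
#' @param rate_hz sampling rate (Hz).
#' @return list of two `waveform`s (`change`, `no_change`), bit-identical
#'   before the appearance time.
#' @export
render_pair <- function(pair, rate_hz = NULL) {
  w_change <- render_scene(pair$change, rate_hz)
  w_nochange <- render_scene(pair$no_change, rate_hz,
                             peak_ref = w_change$raw_peak)
  list(change = w_change, no_change = w_nochange)
}

#' ERB-channel auditory spectrogram
#'
#' A visualisation aid: band energy per pool carrier, obtained by
#' heterodyning the signal at each channel frequency and smoothing the
#' magnitude envelope (two passes of a moving average). Rows are ordered by
#' ERB-number (ascending frequency).
#'
#' @param wave a `waveform`.
#' @param pool a `carrier_pool`; channel centre frequencies.
#' @param smooth_ms envelope smoothing window (ms).
#' @param frame_ms output frame step (ms).
#' @return matrix channels x frames of smoothed band envelopes, with
#'   attributes `freqs_hz` and `frame_ms`.
#' @export
auditory_spectrogram <- function(wave, pool = build_carrier_pool(),
                                 smooth_ms = 10, frame_ms = 2) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  fs <- wave$rate_hz
  nw <- max(1L, round(smooth_ms * fs / 1000))
  step <- max(1L, round(frame_ms * fs / 1000))
  frames <- seq(1L, length(x), by = step)
  tt <- (seq_along(x) - 1L) / fs
  out <- matrix(0, nrow = length(pool$freqs_hz), ncol = length(frames))
  kern <- rep(1 / nw, nw)
  for (i in seq_along(pool$freqs_hz)) {
    f <- pool$freqs_hz[i]
    zr <- x * cos(2 * pi * f * tt)
    zi <- x * sin(2 * pi * f * tt)
    for (pass in 1:2) {
      zr <- as.numeric(stats::filter(zr, kern, sides = 2))
      zi <- as.numeric(stats::filter(zi, kern, sides = 2))
      zr[is.na(zr)] <- 0
      zi[is.na(zi)] <- 0
    }
    out[i, ] <- sqrt(zr[frames]^2 + zi[frames]^2)
  }
  attr(out, "freqs_hz") <- pool$freqs_hz
  attr(out, "frame_ms") <- frame_ms
  out
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.1f ms), peak %.3f\n",
              length(x$samples), x$rate_hz,
              1000 * length(x$samples) / x$rate_hz, max(abs(x$samples))))
  invisible(x)
}
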