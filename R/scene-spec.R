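#' Default stimulus parameters for scene synthesis
#'
#' Returns the parameter set describing the stimulus family: scene duration
#' range, number of concurrent sources, tone-pip duration and silent-gap
#' supports, appearance-time range, and the fixed appearance-to-offset
#' interval. All times are milliseconds.
#'
#' @param duration_range_ms scene duration support (uniform), default
#'   `c(2500, 3500)`.
#' @param n_sources_set admissible numbers of original sources, default `7:8`.
#' @param tone_range_ms tone-pip duration support, default `c(22, 167)`.
#' @param gap_range_ms silent-gap support, default `c(1, 167)`.
#' @param appearance_range_ms appearance-time support, default `c(1000, 2000)`.
#' @param change_to_offset_ms fixed interval between source appearance and
#'   scene offset, default 1500.
#' @param pool a [build_carrier_pool()] object for carrier frequencies.
#' @param rate_hz audio sampling rate, default 44100.
#' @param scene_ramp_ms whole-scene raised-cosine on/off ramp, default 30.
#' @param pip_ramp_ms per-pip cosine on/off ramp (click suppression), default 5.
#' @param norm_peak peak amplitude after scene normalisation, default 0.9.
#' @return a named list of class `stimulus_params`.
#' @export
stimulus_params <- function(duration_range_ms = c(2500, 3500),
                            n_sources_set = 7:8,
                            tone_range_ms = c(22, 167),
                            gap_range_ms = c(1, 167),
                            appearance_range_ms = c(1000, 2000),
                            change_to_offset_ms = 1500,
                            pool = build_carrier_pool(200, 2800, 2),
                            rate_hz = 44100,
                            scene_ramp_ms = 30,
                            pip_ramp_ms = 5,
                            norm_peak = 0.9) {
  structure(list(
    duration_range_ms = duration_range_ms,
    n_sources_set = as.integer(n_sources_set),
    tone_range_ms = tone_range_ms,
    gap_range_ms = gap_range_ms,
    appearance_range_ms = appearance_range_ms,
    change_to_offset_ms = change_to_offset_ms,
    pool = pool,
    rate_hz = rate_hz,
    scene_ramp_ms = scene_ramp_ms,
    pip_ramp_ms = pip_ramp_ms,
    norm_peak = norm_peak
  ), class = "stimulus_params")
}

# Draw one source's temporal parameters. For regular sources the silent gap
# is drawn once; for random sources a whole gap sequence is pre-drawn, long
# enough to cover the scene, so a spec renders deterministically.
draw_source_spec <- function(carrier_hz, gap_mode, params, duration_ms,
                             onset_ms = 0, start_offset = TRUE) {
  tone <- stats::runif(1, params$tone_range_ms[1], params$tone_range_ms[2])
  gr <- params$gap_range_ms
  if (gap_mode == "regular") {
    gap <- stats::runif(1, gr[1], gr[2])
    gaps <- NULL
    first_gap <- gap
  } else {
    span <- duration_ms - onset_ms
    n_gaps <- ceiling(span / (tone + gr[1])) + 2L
    gaps <- stats::runif(n_gaps, gr[1], gr[2])
    gap <- NA_real_
    first_gap <- gaps[1]
  }
  offset <- if (start_offset) stats::runif(1, 0, tone + first_gap) else 0
  structure(list(
    carrier_hz = carrier_hz, tone_dur_ms = tone, gap_mode = gap_mode,
    gap_ms = gap, gap_range_ms = gr, gaps_ms = gaps,
    start_offset_ms = offset, onset_ms = onset_ms
  ), class = "source_spec")
}

#' Draw a random scene specification
#'
#' Draws the complete symbolic description of one acoustic scene: duration,
#' number of sources, carrier frequencies (sampled without replacement from
#' the pool), per-source tone-pip durations, and gap structure. In `REG`
#' scenes every original source has a fixed tone/gap cycle; in `RAND` scenes
#' tone duration is fixed per source but each silent interval is drawn
#' independently from the same support. Change scenes carry an appearing
#' source whose onset is uniform on the appearance range; scene duration is
#' then appearance time plus the fixed 1500 ms change-to-offset interval.
#' The appearing source's carrier is drawn uniformly from pool entries not
#' used by the original sources and its temporal regularity is independent
#' of the scene's.
#'
#' @param params a [stimulus_params()] list.
#' @param scene_regularity `"REG"` or `"RAND"` (drawn at random if `NULL`).
#' @param has_change logical; does a new source appear partway through?
#' @param appearing_regularity `"regular"` or `"random"` for the appearing
#'   source (drawn at random if `NULL`; ignored when `has_change = FALSE`).
#' @param seed optional integer seed for reproducible draws.
#' @return an object of class `scene_spec`.
#' @seealso [make_matched_pair()], [render_scene()]
#' @export
draw_scene_spec <- function(params = stimulus_params(),
                            scene_regularity = NULL,
                            has_change = TRUE,
                            appearing_regularity = NULL,
                            seed = NULL) {
  pool <- params$pool
  n_src_max <- max(params$n_sources_set)
  if (length(pool$freqs_hz) < n_src_max + 1L)
    stop("carrier pool smaller than source count + 1")
  with_seed(seed, {
    if (is.null(scene_regularity))
      scene_regularity <- sample(c("REG", "RAND"), 1L)
    scene_regularity <- match.arg(scene_regularity, c("REG", "RAND"))
    if (has_change) {
      appearance <- stats::runif(1, params$appearance_range_ms[1],
                                 params$appearance_range_ms[2])
      # round to the nearest audio sample so event markers land on samples
      appearance <- round(appearance * params$rate_hz / 1000) *
        1000 / params$rate_hz
      duration <- appearance + params$change_to_offset_ms
      if (is.null(appearing_regularity))
        appearing_regularity <- sample(c("regular", "random"), 1L)
      appearing_regularity <- match.arg(appearing_regularity,
                                        c("regular", "random"))
    } else {
      appearance <- NA_real_
      duration <- stats::runif(1, params$duration_range_ms[1],
                               params$duration_range_ms[2])
    }
    n_sources <- if (length(params$n_sources_set) == 1L) params$n_sources_set
                 else sample(params$n_sources_set, 1L)
    carriers <- sample(pool$freqs_hz, n_sources)
    gap_mode <- if (scene_regularity == "REG") "regular" else "random"
    sources <- lapply(carriers, draw_source_spec, gap_mode = gap_mode,
                      params = params, duration_ms = duration)
    appearing <- NULL
    if (has_change) {
      free <- setdiff(pool$freqs_hz, carriers)
      app_carrier <- if (length(free) == 1L) free else sample(free, 1L)
      appearing <- draw_source_spec(app_carrier, appearing_regularity,
                                    params, duration_ms = duration,
                                    onset_ms = appearance,
                                    start_offset = FALSE)
    }
    structure(list(
      duration_ms = duration,
      sources = sources,
      scene_regularity = scene_regularity,
      has_change = has_change,
      appearing_source = appearing,
      appearing_regularity = if (has_change) appearing_regularity else NA,
      appearance_time_ms = appearance,
      params = params
    ), class = "scene_spec")
  })
}

#' Derive the matched change/no-change pair from a change scene
#'
#' The no-change member shares every original source (carriers, tone
#' durations, gap sequences, start offsets) and the duration of the change
#' member; only the appearing source is removed. Rendered with a shared
#' normalisation factor (see [render_pair()]), the two waveforms are
#' bit-identical before the appearance time.
#'
#' @param spec a `scene_spec` with `has_change = TRUE`.
#' @return list with elements `change` and `no_change` (both `scene_spec`).
#' @export
make_matched_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!isTRUE(spec$has_change))
    stop("'spec' must be a change scene (has_change = TRUE)")
  nochange <- spec
  nochange$has_change <- FALSE
  nochange$appearing_source <- NULL
  nochange$appearing_regularity <- NA
  list(change = spec, no_change = nochange)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene: %s, %d sources, %.0f ms%s\n",
              x$scene_regularity, length(x$sources), x$duration_ms,
              if (isTRUE(x$has_change))
                sprintf(", %s source appears at %.1f ms",
                        x$appearing_regularity, x$appearance_time_ms)
              else ", no change"))
  invisible(x)
}
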