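#' RMS time-course across sensors
#'
#' Summarises a multichannel evoked response as the root mean square across
#' sensors at each time sample — a polarity-free measure of instantaneous
#' response magnitude.
#'
#' @param evoked an `evoked_response`, or a channels x time matrix (then
#'   supply `rate_hz` and `t0_ms`).
#' @param rate_hz,t0_ms metadata for matrix input.
#' @return object of class `rms_series`: list with `values` (>= 0, one per
#'   time sample), `rate_hz`, `t0_ms`.
#' @export
rms_timecourse <- function(evoked, rate_hz = NULL, t0_ms = NULL) {
  if (inherits(evoked, "evoked_response")) {
    X <- evoked$data
    rate_hz <- evoked$rate_hz
    t0_ms <- evoked$t0_ms
  } else {
    X <- as.matrix(evoked)
    if (is.null(rate_hz) || is.null(t0_ms))
      stop("supply 'rate_hz' and 't0_ms' for matrix input")
  }
  if (nrow(X) < 1) stop("need at least one channel")
  structure(list(values = sqrt(colMeans(X^2)),
                 rate_hz = rate_hz, t0_ms = t0_ms),
            class = "rms_series")
}

# Stack a list of rms_series (or numeric vectors) into subjects x time.
stack_series <- function(series) {
  if (is.matrix(series)) return(series)
  rows <- lapply(series, function(s)
    if (inherits(s, "rms_series")) s$values else as.numeric(s))
  n <- unique(vapply(rows, length, integer(1)))
  if (length(n) != 1) stop("series differ in length")
  do.call(rbind, rows)
}

series_meta <- function(series, rate_hz, t0_ms) {
  if (is.list(series) && length(series) &&
      inherits(series[[1]], "rms_series")) {
    rate_hz <- rate_hz %||% series[[1]]$rate_hz
    t0_ms <- t0_ms %||% series[[1]]$t0_ms
  }
  if (is.null(rate_hz) || is.null(t0_ms))
    stop("supply 'rate_hz' and 't0_ms' (or pass rms_series objects)")
  list(rate_hz = rate_hz, t0_ms = t0_ms)
}
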