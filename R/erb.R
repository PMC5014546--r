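#' ERB-number (Cam) scale conversions
#'
#' The ERB-number scale maps frequency to units of equivalent rectangular
#' bandwidths (Glasberg & Moore 1990): `E(f) = 21.4 * log10(0.00437 f + 1)`
#' with `f` in Hz. Scene carriers are spaced uniformly on this scale so that
#' neighbouring sources are separated by a fixed number of auditory filter
#' bandwidths, minimising peripheral (energetic) masking between sources.
#'
#' @param freq_hz numeric vector of frequencies in Hz (> 0).
#' @return `erb_number`: ERB-number in ERB units. `erb_to_hz`: frequency in
#'   Hz. `erb_bandwidth`: equivalent rectangular bandwidth in Hz.
#' @examples
#' erb_number(1000)
#' erb_to_hz(erb_number(1000))
#' @export
erb_number <- function(freq_hz) {
  if (!is.numeric(freq_hz) || any(!is.finite(freq_hz)) || any(freq_hz <= 0))
    stop("'freq_hz' must be finite and strictly positive")
  21.4 * log10(0.00437 * freq_hz + 1)
}

#' @rdname erb_number
#' @param erb numeric vector of ERB-numbers (>= 0).
#' @export
erb_to_hz <- function(erb) {
  if (!is.numeric(erb) || any(!is.finite(erb)) || any(erb < 0))
    stop("'erb' must be finite and non-negative")
  (10^(erb / 21.4) - 1) / 0.00437
}

#' @rdname erb_number
#' @export
erb_bandwidth <- function(freq_hz) {
  if (any(freq_hz <= 0)) stop("'freq_hz' must be strictly positive")
  24.7 * (4.37 * freq_hz / 1000 + 1)
}

#' Build a pool of carrier frequencies equally spaced on the ERB-number scale
#'
#' Starting at `fmin_hz`, carriers step upward by `step_erb` ERB units until
#' the next candidate would exceed `fmax_hz`. Every source in a scene draws
#' its carrier from this pool, so sources are separated by at least
#' `step_erb` auditory filter bandwidths.
#'
#' @param fmin_hz,fmax_hz pool bounds in Hz, `0 < fmin_hz <= fmax_hz`.
#' @param step_erb spacing between consecutive carriers in ERB units (> 0).
#' @return An object of class `carrier_pool`: list with `freqs_hz`
#'   (increasing carrier frequencies), `step_erb`, `fmin_hz`, `fmax_hz`.
#' @examples
#' pool <- build_carrier_pool(200, 2800, 2)
#' length(pool$freqs_hz)
#' @export
build_carrier_pool <- function(fmin_hz = 200, fmax_hz = 2800, step_erb = 2) {
  if (!(fmin_hz > 0) || !(fmax_hz >= fmin_hz)) stop("need 0 < fmin_hz <= fmax_hz")
  if (!(step_erb > 0)) stop("'step_erb' must be positive")
  e0 <- erb_number(fmin_hz)
  emax <- erb_number(fmax_hz)
  n <- floor((emax - e0) / step_erb + 1e-9) + 1L
  if (n < 1L) stop("carrier pool is empty; reduce 'step_erb'")
  freqs <- erb_to_hz(e0 + step_erb * (seq_len(n) - 1L))
  freqs[1L] <- fmin_hz
  structure(
    list(freqs_hz = freqs, step_erb = step_erb,
         fmin_hz = fmin_hz, fmax_hz = fmax_hz),
    class = "carrier_pool"
  )
}

#' @export
print.carrier_pool <- function(x, ...) {
  cat(sprintf("Carrier pool: %d carriers, %.4g-%.4g Hz, %.3g-ERB spacing\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz), x$step_erb))
  invisible(x)
}
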