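#' Sensor array with component topographies
#'
#' Builds a planar sensor layout (sunflower packing of the unit disk, a
#' stand-in for a helmet array seen from above) and smooth synthetic field
#' maps for the simulated neural components: bilateral dipolar maps over the
#' temporal regions for the transient auditory deflections (an early
#' middle-latency onset deflection, M50, M100, M200), with the M100 map of
#' opposite polarity to the M50 map, a distinct
#' but auditory-cortex-correlated map for the sustained response, and an
#' orthonormal basis of smooth noise-subspace maps used to spatially
#' correlate the sensor noise. All component maps have unit norm.
#'
#' @param n_channels number of sensors (>= 8; default 274, the size of a
#'   whole-head axial gradiometer array).
#' @param seed optional integer seed.
#' @param n_noise number of noise-subspace maps (default 20).
#' @return object of class `sensor_array`: list with `n_channels`,
#'   `positions` (n x 2), `topographies` (named list of unit-norm weight
#'   vectors: `mlr`, `m50`, `m100`, `m200`, `sustained`), `noise_mixing`
#'   (n_channels x n_noise, orthonormal columns).
#' @export
make_sensor_topographies <- function(n_channels = 274, seed = NULL,
                                     n_noise = 20) {
  if (n_channels < 8) stop("need at least 8 channels")
  # the noise subspace is orthogonalised against the 5 component maps, so
  # at most n_channels - 5 orthonormal noise directions exist
  n_noise <- min(n_noise, n_channels - 5L)
  with_seed(seed, {
    # sunflower layout: quasi-uniform points in the unit disk
    k <- seq_len(n_channels)
    r <- sqrt((k - 0.5) / n_channels)
    th <- k * pi * (3 - sqrt(5))
    pos <- cbind(x = r * cos(th), y = r * sin(th))

    gauss_blob <- function(cx, cy, w)
      exp(-((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2) / (2 * w^2))
    smooth_field <- function(n_blobs = 6) {
      f <- numeric(n_channels)
      for (j in seq_len(n_blobs))
        f <- f + stats::rnorm(1) *
          gauss_blob(stats::runif(1, -0.8, 0.8),
                     stats::runif(1, -0.8, 0.8),
                     stats::runif(1, 0.2, 0.45))
      f
    }
    unitize <- function(v) v / sqrt(sum(v^2))
    # bilateral source/sink pair over each temporal region
    dipole_map <- function(y_src, y_snk, w = 0.28, jitter = 0.15) {
      base <- gauss_blob(-0.55, y_src, w) - gauss_blob(-0.55, y_snk, w) +
        gauss_blob(0.55, y_src, w) - gauss_blob(0.55, y_snk, w)
      unitize(base + jitter * smooth_field())
    }
    mlr <- dipole_map(0.25, -0.25, w = 0.22)
    m50 <- dipole_map(0.15, -0.35)
    # M100: opposite-polarity field over the same cortex
    m100 <- unitize(-dipole_map(0.18, -0.32))
    if (sum(m50 * m100) >= 0) m100 <- -m100
    m200 <- dipole_map(0.05, -0.45)
    sustained <- unitize(0.75 * m50 + 0.45 * unitize(smooth_field()))
    noise_raw <- matrix(0, n_channels, n_noise)
    for (j in seq_len(n_noise)) noise_raw[, j] <- smooth_field()
    # orthogonalise the noise subspace against the component maps so the
    # structured noise perturbs the evoked topographies without living on
    # them (the iid sensor-noise floor still does); evoked magnitudes then
    # fluctuate no more in signal-carrying periods than at baseline
    comp_basis <- qr.Q(qr(cbind(mlr, m50, m100, m200, sustained)))
    noise_raw <- noise_raw - comp_basis %*% (t(comp_basis) %*% noise_raw)
    noise_mixing <- qr.Q(qr(noise_raw))
    structure(list(
      n_channels = as.integer(n_channels),
      positions = pos,
      topographies = list(mlr = mlr, m50 = m50, m100 = m100, m200 = m200,
                          sustained = sustained),
      noise_mixing = noise_mixing
    ), class = "sensor_array")
  })
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("Sensor array: %d channels, %d component maps, %d noise maps\n",
              x$n_channels, length(x$topographies), ncol(x$noise_mixing)))
  invisible(x)
}
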