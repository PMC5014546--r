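#' Fit a denoising source separation (DSS) model
#'
#' DSS ranks linear sensor combinations by the reproducibility of the
#' evoked response across trials. The data are first whitened by PCA on the
#' channel covariance pooled over all trials (eigenvalues below `1e-6` of
#' the largest are discarded); the channel covariance of the trial average
#' is then eigendecomposed in the whitened space. The resulting eigenvalues
#' are reproducibility ratios in `[0, 1]`: 1 for a perfectly reproducible
#' (noise-free) component, about `1/n_trials` for pure noise. Covariances
#' are raw second-moment matrices (the epochs are baseline-corrected
#' upstream, so no additional demeaning is applied).
#'
#' @param data a `trial_tensor` with >= 2 trials and >= 2 channels, already
#'   epoched on the bias window of interest (the scene-onset epoch in the
#'   standard chain; the model may then be applied to other epochs of the
#'   same subject).
#' @param n_keep default number of components retained on
#'   [dss_apply()] (default 2).
#' @return object of class `dss_model`: list with `whitener` (k x channels),
#'   `rotation` (k x k), `unmixing` (k x channels), `patterns`
#'   (channels x k, back-projection maps), `eigenvalues` (descending
#'   reproducibility scores), `n_keep`, `n_channels`.
#' @export
dss_fit <- function(data, n_keep = 2) {
  stopifnot(inherits(data, "trial_tensor"))
  d <- dim(data$data)
  if (d[3] < 2 || d[1] < 2) stop("need >= 2 trials and >= 2 channels")
  nt <- d[2]
  c_total <- matrix(0, d[1], d[1])
  for (i in seq_len(d[3]))
    c_total <- c_total + tcrossprod(data$data[, , i]) / nt
  c_total <- c_total / d[3]
  avg <- rowMeans(data$data, dims = 2)
  c_evoked <- tcrossprod(avg) / nt
  eg <- eigen(c_total, symmetric = TRUE)
  keep <- eg$values > 1e-6 * eg$values[1]
  if (sum(keep) < 2) stop("data rank < 2 after discarding tiny eigenvalues")
  W <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep])
  cw <- W %*% c_evoked %*% t(W)
  cw <- (cw + t(cw)) / 2
  eg2 <- eigen(cw, symmetric = TRUE)
  evals <- pmax(eg2$values, 0)
  Q <- eg2$vectors
  structure(list(
    whitener = W,
    rotation = Q,
    unmixing = t(Q) %*% W,
    patterns = eg$vectors[, keep] %*% diag(sqrt(eg$values[keep]), sum(keep)) %*% Q,
    eigenvalues = evals,
    n_keep = n_keep,
    n_channels = d[1]
  ), class = "dss_model")
}

#' Denoise epochs by projection onto the leading DSS components
#'
#' Projects every trial onto the `n_keep` most reproducible components and
#' back into sensor space. With `n_keep` equal to the full model rank the
#' operation is the identity (up to numerical tolerance); for any `n_keep`
#' it is idempotent. A model fitted on scene-locked epochs may be applied to
#' appearance-locked epochs of the same subject (the spatial filters carry
#' over; only the channel count must match).
#'
#' @param model a [dss_fit()] model.
#' @param data a `trial_tensor` (or `evoked_response`) with the same channel
#'   count the model was fitted on.
#' @param n_keep number of components retained (default `model$n_keep`).
#' @return `data` with every trial replaced by its denoised projection.
#' @export
dss_apply <- function(model, data, n_keep = NULL) {
  stopifnot(inherits(model, "dss_model"))
  n_keep <- n_keep %||% model$n_keep
  if (n_keep > length(model$eigenvalues))
    stop("'n_keep' exceeds the number of available components")
  nc <- if (inherits(data, "trial_tensor")) dim(data$data)[1]
        else nrow(data$data)
  if (nc != model$n_channels)
    stop("channel count does not match the fitted model")
  P <- model$patterns[, seq_len(n_keep), drop = FALSE] %*%
    model$unmixing[seq_len(n_keep), , drop = FALSE]
  out <- data
  if (inherits(data, "trial_tensor")) {
    for (i in seq_len(dim(data$data)[3]))
      out$data[, , i] <- P %*% data$data[, , i]
  } else {
    out$data <- P %*% data$data
  }
  out
}

#' Component time-courses under a DSS model
#'
#' @param model a [dss_fit()] model.
#' @param data a `trial_tensor` or `evoked_response`.
#' @param n_keep components to extract.
#' @return components x time matrix (for tensors, of the trial average).
#' @export
dss_timecourses <- function(model, data, n_keep = NULL) {
  n_keep <- n_keep %||% model$n_keep
  X <- if (inherits(data, "trial_tensor")) rowMeans(data$data, dims = 2)
       else data$data
  model$unmixing[seq_len(n_keep), , drop = FALSE] %*% X
}

#' @export
print.dss_model <- function(x, ...) {
  cat(sprintf("DSS model: %d channels, %d components, top eigenvalues %s\n",
              x$n_channels, length(x$eigenvalues),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)),
                    collapse = ", ")))
  invisible(x)
}
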