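#' Polarity-preserving channel-subset mean time-courses
#'
#' Ranks channels by their mean signal inside a peak window on the
#' condition-pooled group average, then averages the raw (polarity
#' preserved) signal within the `n_select` most positive and `n_select`
#' most negative channels for each subject. Used to separate overlapping
#' components of opposite polarity (e.g. M50 versus M100) that RMS
#' summaries confound.
#'
#' @param evoked_list per-subject evoked responses (condition-pooled for
#'   ranking): list of `evoked_response` or channels x time matrices.
#' @param window_ms peak window `c(w0, w1)` in ms (half-open).
#' @param n_select channels per subset (default 20; at most half the
#'   array).
#' @param rate_hz,t0_ms time metadata for matrix input.
#' @return list with `positive`, `negative` (subjects x time mean
#'   time-courses), `positive_channels`, `negative_channels` (indices),
#'   `times_ms`.
#' @export
channel_subset_means <- function(evoked_list, window_ms = c(72, 112),
                                 n_select = 20, rate_hz = NULL,
                                 t0_ms = NULL) {
  mats <- lapply(evoked_list, function(e)
    if (inherits(e, "evoked_response")) e$data else as.matrix(e))
  if (inherits(evoked_list[[1]], "evoked_response")) {
    rate_hz <- rate_hz %||% evoked_list[[1]]$rate_hz
    t0_ms <- t0_ms %||% evoked_list[[1]]$t0_ms
  }
  if (is.null(rate_hz) || is.null(t0_ms))
    stop("supply 'rate_hz' and 't0_ms' for matrix input")
  nc <- nrow(mats[[1]])
  nt <- ncol(mats[[1]])
  if (n_select > nc / 2) stop("'n_select' exceeds half the channel count")
  times <- t0_ms + (seq_len(nt) - 1) * 1000 / rate_hz
  sel <- in_window(times, window_ms)
  if (!any(sel)) stop("peak window lies outside the epoch")
  grand <- Reduce(`+`, mats) / length(mats)
  win_mean <- rowMeans(grand[, sel, drop = FALSE])
  ord <- order(win_mean, decreasing = TRUE)
  pos <- ord[seq_len(n_select)]
  neg <- rev(ord)[seq_len(n_select)]
  list(
    positive = do.call(rbind, lapply(mats, function(m)
      colMeans(m[pos, , drop = FALSE]))),
    negative = do.call(rbind, lapply(mats, function(m)
      colMeans(m[neg, , drop = FALSE]))),
    positive_channels = pos,
    negative_channels = neg,
    times_ms = times)
}
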