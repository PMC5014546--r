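# Zero-phase FIR low-pass of a time x series matrix (columns are series).
# Linear-phase windowed-sinc kernel applied as a centred convolution with
# reflection padding, so the passband is flat (ripple < 1% well past
# 0.8 x cutoff) and the group delay is exactly zero.
fir_lowpass_mat <- function(X, rate_hz, cutoff_hz) {
  nt <- nrow(X)
  order <- round(4 * rate_hz / cutoff_hz)
  order <- min(order + order %% 2, 2 * floor((nt - 1) / 4))
  if (order < 4) stop("record too short to filter")
  h <- signal::fir1(order, min(1.25 * cutoff_hz / (rate_hz / 2), 0.99))
  h <- h / sum(h)   # exact unit gain at DC
  pad <- length(h)
  idx_pre <- pmin(pad + 1 - seq_len(pad), nt)   # reflected head
  idx_post <- pmax(nt - seq_len(pad), 1)        # reflected tail
  Xp <- rbind(X[idx_pre, , drop = FALSE], X, X[idx_post, , drop = FALSE])
  Y <- stats::filter(Xp, h, sides = 2)
  Y <- as.matrix(Y)[(pad + 1):(pad + nt), , drop = FALSE]
  Y
}

# Best rational approximation p/q of x with bounded denominator.
rational_approx <- function(x, max_den = 1000) {
  best <- c(round(x), 1)
  err <- abs(x - best[1])
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Zero-phase low-pass filter and resample an epoch tensor
#'
#' Applies a zero-phase FIR low-pass at `cutoff_hz` (flat passband: gain
#' within 1% up to at least 0.8 x cutoff; stopband attenuation > 40 dB by
#' twice the cutoff) followed by anti-aliased resampling to
#' `target_rate_hz` — plain decimation when the rate ratio is an integer,
#' polyphase resampling otherwise.
#'
#' @param data a `trial_tensor`, or a channels x time matrix with `rate_hz`
#'   supplied.
#' @param cutoff_hz low-pass cutoff (must be below the target Nyquist).
#' @param target_rate_hz output sampling rate; `NULL` keeps the input rate
#'   (filter only).
#' @param rate_hz input rate when `data` is a bare matrix.
#' @return same type as `data`, filtered and resampled, with updated
#'   `rate_hz`.
#' @export
lowpass_and_resample <- function(data, cutoff_hz = 30, target_rate_hz = 250,
                                 rate_hz = NULL) {
  is_tensor <- inherits(data, "trial_tensor")
  fs <- if (is_tensor) data$rate_hz else rate_hz
  if (is.null(fs)) stop("supply 'rate_hz' for matrix input")
  target <- target_rate_hz %||% fs
  if (cutoff_hz >= target / 2)
    stop("'cutoff_hz' must be below the target Nyquist frequency")
  proc <- function(M) {   # channels x time
    Y <- t(fir_lowpass_mat(t(M), fs, cutoff_hz))
    if (target == fs) return(Y)
    r <- fs / target
    if (abs(r - round(r)) < 1e-9) {
      Y[, seq(1, ncol(Y), by = round(r)), drop = FALSE]
    } else {
      pq <- rational_approx(target / fs)
      t(apply(Y, 1, function(row) signal::resample(row, pq[1], pq[2])))
    }
  }
  if (!is_tensor) return(proc(data))
  slices <- lapply(seq_len(dim(data$data)[3]),
                   function(i) proc(data$data[, , i]))
  out <- data
  out$data <- array(unlist(slices),
                    dim = c(dim(slices[[1]]), length(slices)))
  out$rate_hz <- target
  out
}

#' Cut epochs and apply baseline correction
#'
#' Epochs are cut on the half-open window `[t0, t1)` relative to each lock
#' event, so an epoch at rate `r` has exactly `round((t1 - t0) * r / 1000)`
#' samples. Per channel and trial, the mean over the half-open baseline
#' window `[b0, b1)` is subtracted; after correction the baseline mean is
#' zero to machine precision. Lock events too close to the record edge are
#' dropped with a warning. Already-epoched tensors (with `lock_times_ms =
#' NULL`) are re-baselined in place.
#'
#' @param data channels x time matrix of a continuous record (time starting
#'   at 0 ms), or a `trial_tensor` to re-baseline.
#' @param lock_times_ms event times (ms) to epoch around, or `NULL`.
#' @param window_ms epoch window `c(t0, t1)` in ms relative to the lock.
#' @param baseline_ms baseline window `c(b0, b1)`, contained in `window_ms`.
#' @param rate_hz sampling rate for matrix input.
#' @param lock label for the lock event (metadata).
#' @return a `trial_tensor` with `t0_ms = window_ms[1]`.
#' @export
epoch_and_baseline <- function(data, lock_times_ms = NULL,
                               window_ms = c(-200, 800),
                               baseline_ms = c(-200, 0),
                               rate_hz = NULL, lock = "scene_onset") {
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])
    stop("baseline window must be contained in the epoch window")
  if (inherits(data, "trial_tensor")) {
    fs <- data$rate_hz
    n <- dim(data$data)[2]
    times <- epoch_times_ms(data$t0_ms, n, fs)
    sel <- in_window(times, baseline_ms)
    if (!any(sel)) stop("baseline window contains no samples")
    out <- data
    bl <- apply(data$data[, sel, , drop = FALSE], c(1, 3), mean)
    for (i in seq_len(dim(data$data)[3]))
      out$data[, , i] <- data$data[, , i] - bl[, i]
    return(out)
  }
  fs <- rate_hz
  if (is.null(fs)) stop("supply 'rate_hz' for matrix input")
  nT <- ncol(data)
  n <- window_n_samples(window_ms, fs)
  times <- epoch_times_ms(window_ms[1], n, fs)
  sel <- in_window(times, baseline_ms)
  if (!any(sel)) stop("baseline window contains no samples")
  epochs <- list()
  dropped <- integer(0)
  for (j in seq_along(lock_times_ms)) {
    i0 <- as.integer(round(lock_times_ms[j] * fs / 1000)) +
      as.integer(round(window_ms[1] * fs / 1000)) + 1L
    i1 <- i0 + n - 1L
    if (i0 < 1L || i1 > nT) { dropped <- c(dropped, j); next }
    ep <- data[, i0:i1, drop = FALSE]
    ep <- ep - rowMeans(ep[, sel, drop = FALSE])
    epochs[[length(epochs) + 1L]] <- ep
  }
  if (length(dropped))
    warning(sprintf("dropped %d lock event(s) too close to the record edge: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(epochs)) stop("no epochs could be cut")
  structure(list(
    data = array(unlist(epochs), dim = c(nrow(data), n, length(epochs))),
    rate_hz = fs, t0_ms = window_ms[1], lock = lock,
    labels = list(), dropped_events = dropped
  ), class = "trial_tensor")
}

#' Reject outlier trials by deviation from the across-trial mean
#'
#' Each trial's deviation score is the root-mean-square over channels and
#' samples of its difference from the across-trial mean. Trials whose score
#' exceeds the mean score by more than `k_sd` standard deviations (of the
#' scores) are removed in a single pass. The decision is scale invariant.
#'
#' @param data a `trial_tensor` with at least 4 trials.
#' @param k_sd rejection threshold in score standard deviations (default 3).
#' @return list with `tensor` (retained trials), `rejected` (indices into
#'   the input), `scores` (all trial scores).
#' @export
reject_outlier_trials <- function(data, k_sd = 3) {
  stopifnot(inherits(data, "trial_tensor"))
  n <- dim(data$data)[3]
  if (n < 4) stop("need at least 4 trials for outlier rejection")
  m <- rowMeans(data$data, dims = 2)
  scores <- vapply(seq_len(n), function(i)
    sqrt(mean((data$data[, , i] - m)^2)), numeric(1))
  thr <- mean(scores) + k_sd * stats::sd(scores)
  rejected <- which(scores > thr)
  if (length(rejected) == n) stop("all trials rejected; degenerate data")
  out <- data
  out$data <- data$data[, , setdiff(seq_len(n), rejected), drop = FALSE]
  list(tensor = out, rejected = rejected, scores = scores)
}

#' Average a trial tensor into an evoked response
#'
#' @param data a `trial_tensor`.
#' @return an `evoked_response` (plain mean over trials).
#' @export
average_trials <- function(data) {
  stopifnot(inherits(data, "trial_tensor"))
  structure(list(data = rowMeans(data$data, dims = 2),
                 rate_hz = data$rate_hz, t0_ms = data$t0_ms,
                 lock = data$lock, labels = data$labels),
            class = "evoked_response")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Trial tensor: %d channels x %d samples x %d trials @ %g Hz, t0 = %g ms (%s lock)\n",
              d[1], d[2], d[3], x$rate_hz, x$t0_ms, x$lock))
  invisible(x)
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("Evoked response: %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              nrow(x$data), ncol(x$data), x$rate_hz, x$t0_ms))
  invisible(x)
}
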