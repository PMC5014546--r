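# Gaussian deflection centred at latency_ms with given FWHM.
component_bump <- function(times_ms, latency_ms, fwhm_ms) {
  sigma <- fwhm_ms / 2.355
  exp(-(times_ms - latency_ms)^2 / (2 * sigma^2))
}

# Smoothed logistic step settling at onset_ms: ~0 before onset - rise,
# ~1 (settled) from onset onward.
logistic_step <- function(times_ms, onset_ms, rise_ms) {
  stats::plogis((times_ms - onset_ms + rise_ms / 2) / max(rise_ms / 4.4, 1e-6))
}

# Sharp gate used for condition-effect onsets: half-cosine rise over
# rise_ms, centred on the onset so the gain is complete by onset + rise/2.
effect_gate <- function(times_ms, onset_ms, rise_ms) {
  g <- (times_ms - onset_ms + rise_ms / 2) / rise_ms
  g <- pmin(pmax(g, 0), 1)
  0.5 * (1 - cos(pi * g))
}

#' Simulate one subject's noiseless evoked response
#'
#' Builds the deterministic (pre-noise) evoked field for one condition as a
#' sum of component topographies times component time-courses: Gaussian
#' deflections for the transient M50/M100/M200 components and a smoothed
#' step for the sustained response. Condition effects are applied as
#' multiplicative gains gated in time at the group-specific effect-onset
#' latency, so REG and RAND responses are identical before that latency by
#' construction. Appearance-locked no-change epochs contain no
#' appearance-evoked components (ongoing activity common to both conditions
#' is removed by baseline correction and is not modelled).
#'
#' @param condition list with `lock` (`"scene"` or `"appearance"`), `scene`
#'   (`"REG"`/`"RAND"`), optional `appearing` (`"regular"`/`"random"`) and
#'   `change` (logical, appearance lock only; default TRUE).
#' @param group `"Passive"` or `"Active"`.
#' @param fx an [effect_config()].
#' @param sensors a [make_sensor_topographies()] array.
#' @param rate_hz sampling rate (default 250).
#' @param window_ms epoch window; defaults to (-200, 800) for scene lock and
#'   (-200, 400) for appearance lock.
#' @param subject optional list with `gain` (multiplicative) and
#'   `latency_shift_ms` (added to component latencies; group-level effect
#'   onsets are not shifted, so the planted onset is a group property).
#' @return object of class `evoked_response`: list with `data`
#'   (channels x time), `rate_hz`, `t0_ms`, `lock`, `labels`.
#' @export
simulate_subject_evoked <- function(condition, group = "Passive",
                                    fx = effect_config(),
                                    sensors = make_sensor_topographies(32, seed = 1),
                                    rate_hz = 250, window_ms = NULL,
                                    subject = NULL) {
  group <- match.arg(group, c("Passive", "Active"))
  lock <- match.arg(condition$lock, c("scene", "appearance"))
  scene <- match.arg(condition$scene, c("REG", "RAND"))
  change <- condition$change %||% TRUE
  window_ms <- window_ms %||%
    (if (lock == "scene") c(-200, 800) else c(-200, 400))
  n <- window_n_samples(window_ms, rate_hz)
  times <- epoch_times_ms(window_ms[1], n, rate_hz)
  gain <- subject$gain %||% 1
  lshift <- subject$latency_shift_ms %||% 0
  topo <- sensors$topographies
  X <- matrix(0, sensors$n_channels, n)

  if (lock == "scene") {
    comp <- fx$scene$components
    for (i in seq_len(nrow(comp))) {
      tc <- gain * comp$amp[i] *
        component_bump(times, comp$latency_ms[i] + lshift, comp$fwhm_ms[i])
      X <- X + topo[[comp$name[i]]] %o% tc
    }
    sus <- gain * fx$scene$sustained_amp *
      logistic_step(times, fx$scene$sustained_onset_ms + lshift,
                    fx$scene$sustained_rise_ms)
    if (scene == "REG" && fx$scene$reg_gain != 0) {
      gate <- effect_gate(times, fx$scene$reg_onset_ms[[group]],
                          fx$scene$reg_rise_ms)
      sus <- sus + gain * fx$scene$reg_gain * fx$scene$sustained_amp * gate
    }
    X <- X + topo$sustained %o% sus
  } else if (change) {
    comp <- fx$appearance$components
    amps <- comp$amp
    amps[comp$name == "m100"] <- fx$appearance$m100_amp[[group]]
    reg_mult <- if (scene == "REG" && fx$appearance$reg_gain != 0)
      1 + fx$appearance$reg_gain *
        effect_gate(times, fx$appearance$reg_onset_ms[[group]],
                    fx$appearance$reg_rise_ms)
    else rep(1, n)
    for (i in seq_len(nrow(comp))) {
      if (amps[i] == 0) next
      tc <- gain * amps[i] * reg_mult *
        component_bump(times, comp$latency_ms[i] + lshift, comp$fwhm_ms[i])
      X <- X + topo[[comp$name[i]]] %o% tc
    }
  }
  structure(list(data = X, rate_hz = rate_hz, t0_ms = window_ms[1],
                 lock = lock,
                 labels = list(group = group, scene = scene,
                               appearing = condition$appearing %||% NA,
                               change = change)),
            class = "evoked_response")
}

#' Simulate an epoch tensor around a noiseless evoked response
#'
#' Each trial is the evoked field plus spatially correlated, temporally
#' autocorrelated Gaussian noise: AR(1) source time-series (approximating a
#' 1/f spectrum at low frequencies) mixed through the array's smooth
#' noise-subspace maps, plus a small independent per-sensor noise floor. A
#' configurable fraction of trials is scaled up to emulate occasional
#' artefact-contaminated outlier epochs.
#'
#' @param evoked an `evoked_response`.
#' @param sensors the `sensor_array` whose `noise_mixing` maps are used.
#' @param noise list of noise parameters (see [effect_config()]`$noise`):
#'   `sd` (stationary SD of each noise source), `ar_rho` (AR(1)
#'   coefficient), `sensor_sd`, `outlier_frac`, `outlier_scale`.
#' @param n_trials number of trials (>= 2).
#' @param seed optional integer seed.
#' @return object of class `trial_tensor`: list with `data`
#'   (channels x time x trials), `rate_hz`, `t0_ms`, `lock`, `labels`,
#'   `outlier_trials` (indices of the scaled trials).
#' @export
simulate_trials <- function(evoked, sensors, noise = effect_config()$noise,
                            n_trials = 96, seed = NULL) {
  stopifnot(inherits(evoked, "evoked_response"), n_trials >= 2)
  nc <- nrow(evoked$data)
  nt <- ncol(evoked$data)
  M <- sensors$noise_mixing
  n_src <- ncol(M)
  rho <- noise$ar_rho
  innov_sd <- noise$sd * sqrt(1 - rho^2)
  burn <- 50L
  with_seed(seed, {
    arr <- array(0, dim = c(nc, nt, n_trials))
    n_out <- round((noise$outlier_frac %||% 0) * n_trials)
    out_idx <- if (n_out > 0) sort(sample.int(n_trials, n_out)) else integer(0)
    # all AR(1) source series at once; columns are (source, trial) pairs
    E <- matrix(stats::rnorm(n_src * n_trials * (nt + burn), sd = innov_sd),
                nt + burn, n_src * n_trials)
    Z <- stats::filter(E, rho, method = "recursive")
    Z <- Z[(burn + 1):(burn + nt), , drop = FALSE]
    sens_noise <- if ((noise$sensor_sd %||% 0) > 0)
      array(stats::rnorm(nc * nt * n_trials, sd = noise$sensor_sd),
            dim = c(nc, nt, n_trials))
    else NULL
    for (i in seq_len(n_trials)) {
      cols <- (i - 1L) * n_src + seq_len(n_src)
      tr <- evoked$data + M %*% t(Z[, cols, drop = FALSE])
      if (!is.null(sens_noise)) tr <- tr + sens_noise[, , i]
      if (i %in% out_idx) tr <- tr * noise$outlier_scale
      arr[, , i] <- tr
    }
    structure(list(data = arr, rate_hz = evoked$rate_hz,
                   t0_ms = evoked$t0_ms, lock = evoked$lock,
                   labels = evoked$labels, outlier_trials = out_idx),
              class = "trial_tensor")
  })
}

#' Simulate the full two-group dataset
#'
#' Generates, for every subject in a passive and an active group, the
#' scene-locked epoch tensors (REG, RAND), the appearance-locked change
#' tensors for the four scene-by-appearing-source cells, and the matched
#' appearance-locked no-change tensors. Between-subject variability is a
#' lognormal amplitude gain and a Gaussian shift of component latencies.
#'
#' @param fx an [effect_config()].
#' @param n_passive,n_active group sizes (defaults 14 and 13).
#' @param n_channels sensors (default 274; use 32 for fast runs).
#' @param n_trials trials per condition cell (default 96).
#' @param rate_hz sampling rate (default 250).
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `meg_dataset`: list with `Passive` and `Active`
#'   subject lists, the shared `sensors`, `fx` and the call parameters. Each
#'   subject is a list with elements `scene` (`REG`, `RAND` tensors),
#'   `appearance` (`REG.regular`, `REG.random`, `RAND.regular`,
#'   `RAND.random`), `nochange` (`REG`, `RAND`), and `subject` (the drawn
#'   gain and latency shift).
#' @export
simulate_dataset <- function(fx = effect_config(), n_passive = 14,
                             n_active = 13, n_channels = 274, n_trials = 96,
                             rate_hz = 250, seed = 1) {
  stopifnot(n_passive >= 2, n_active >= 2)
  sensors <- make_sensor_topographies(n_channels,
                                      seed = child_seed(seed, "sensors"))
  sim_group <- function(group, n_subj) {
    lapply(seq_len(n_subj), function(s) {
      sseed <- child_seed(seed, sprintf("%s-subject-%02d", group, s))
      subj <- with_seed(sseed, list(
        gain = stats::rlnorm(1, 0, fx$subject$gain_sd_log),
        latency_shift_ms = stats::rnorm(1, 0, fx$subject$latency_jitter_sd_ms)))
      make <- function(lock, scene, appearing = NA, change = TRUE, tag) {
        ev <- simulate_subject_evoked(
          list(lock = lock, scene = scene, appearing = appearing,
               change = change),
          group, fx, sensors, rate_hz, subject = subj)
        simulate_trials(ev, sensors, fx$noise, n_trials,
                        seed = child_seed(sseed, tag))
      }
      list(
        subject = subj,
        scene = list(REG = make("scene", "REG", tag = "scene-REG"),
                     RAND = make("scene", "RAND", tag = "scene-RAND")),
        appearance = list(
          REG.regular = make("appearance", "REG", "regular", tag = "app-REG-reg"),
          REG.random = make("appearance", "REG", "random", tag = "app-REG-rand"),
          RAND.regular = make("appearance", "RAND", "regular", tag = "app-RAND-reg"),
          RAND.random = make("appearance", "RAND", "random", tag = "app-RAND-rand")),
        nochange = list(
          REG = make("appearance", "REG", change = FALSE, tag = "nc-REG"),
          RAND = make("appearance", "RAND", change = FALSE, tag = "nc-RAND")))
    })
  }
  structure(list(
    Passive = sim_group("Passive", n_passive),
    Active = sim_group("Active", n_active),
    sensors = sensors, fx = fx,
    params = list(n_passive = n_passive, n_active = n_active,
                  n_channels = n_channels, n_trials = n_trials,
                  rate_hz = rate_hz, seed = seed)
  ), class = "meg_dataset")
}
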