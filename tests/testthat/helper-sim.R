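# Shared simulation helpers for the test suite. All are thin wrappers over
# exported package functions so that the tests exercise the same chain the
# pipeline uses.

# Per-subject REG-minus-RAND RMS difference after outlier rejection and
# trial averaging, for one simulated subject.
sim_subject_diff <- function(group, lock, n_trials, sens, seed,
                             fx = effect_config()) {
  subj <- with_test_seed(seed, list(
    gain = stats::rlnorm(1, 0, fx$subject$gain_sd_log),
    latency_shift_ms = stats::rnorm(1, 0, fx$subject$latency_jitter_sd_ms)))
  ev_reg <- simulate_subject_evoked(list(lock = lock, scene = "REG"),
                                    group, fx, sens, subject = subj)
  ev_rand <- simulate_subject_evoked(list(lock = lock, scene = "RAND"),
                                     group, fx, sens, subject = subj)
  t_reg <- reject_outlier_trials(
    simulate_trials(ev_reg, sens, fx$noise, n_trials, seed = seed + 1))$tensor
  t_rand <- reject_outlier_trials(
    simulate_trials(ev_rand, sens, fx$noise, n_trials, seed = seed + 2))$tensor
  rms_timecourse(average_trials(t_reg))$values -
    rms_timecourse(average_trials(t_rand))$values
}

# Subjects x time matrix of REG-RAND RMS differences for one group.
sim_group_diff <- function(group, n_subj, lock, n_trials, sens, seed,
                           fx = effect_config()) {
  t(vapply(seq_len(n_subj),
           function(s) sim_subject_diff(group, lock, n_trials, sens,
                                        seed + s * 97, fx),
           numeric(window_samples(lock))))
}

window_samples <- function(lock) if (lock == "scene") 250L else 150L

# Two independent same-condition RMS series sets (a null paired design).
sim_null_rms_pair <- function(n_subj, n_trials, sens, seed,
                              fx = null_effect_config()) {
  a <- vector("list", n_subj)
  b <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    subj <- with_test_seed(seed + s, list(
      gain = stats::rlnorm(1, 0, fx$subject$gain_sd_log),
      latency_shift_ms = stats::rnorm(1, 0, fx$subject$latency_jitter_sd_ms)))
    ev <- simulate_subject_evoked(list(lock = "appearance", scene = "RAND"),
                                  "Active", fx, sens, subject = subj)
    a[[s]] <- rms_timecourse(average_trials(
      simulate_trials(ev, sens, fx$noise, n_trials, seed = seed + s * 13)))
    b[[s]] <- rms_timecourse(average_trials(
      simulate_trials(ev, sens, fx$noise, n_trials,
                      seed = seed + s * 13 + 500000)))
  }
  list(a = a, b = b)
}

# Evaluate expr under a seed without clobbering the session RNG.
with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# A tiny deterministic trial tensor built from a known evoked + white noise.
tiny_tensor <- function(n_ch = 6, n_t = 40, n_trials = 12, sd = 0.5,
                        seed = 1) {
  with_test_seed(seed, {
    ev <- outer(stats::rnorm(n_ch), sin(seq(0, 2 * pi, length.out = n_t)))
    arr <- array(stats::rnorm(n_ch * n_t * n_trials, sd = sd),
                 dim = c(n_ch, n_t, n_trials)) + as.vector(ev)
    structure(list(data = arr, rate_hz = 250, t0_ms = -40, lock = "scene",
                   labels = list()),
              class = "trial_tensor")
  })
}
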