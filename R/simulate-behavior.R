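#' Simulate trial-level detection behaviour
#'
#' Generates per-subject hit and false-alarm counts and detection times for
#' the 2 x 2 within-subject design (scene structure REG/RAND by appearing
#' source regular/random). Hits are binomial with a higher detection
#' probability in REG scenes; false alarms are binomial on the matched
#' no-change trials of each scene structure; detection times are Gaussian
#' with a REG-scene advantage and an additional shift when the appearing
#' source is regular. Subjects get a shared logit-scale shift of their hit
#' probability and a Gaussian shift of their mean detection time.
#'
#' @param fx an [effect_config()]; only `fx$behavior` is used.
#' @param n_subjects number of subjects (default 13).
#' @param n_change_per_cell change trials per design cell (default 96).
#' @param n_nochange_per_scene no-change trials per scene structure
#'   (default 192).
#' @param seed optional integer seed.
#' @return data.frame of class `behavior_table`, one row per subject x
#'   cell: `subject`, `scene`, `appearing`, `n_change`, `hits`,
#'   `n_nochange`, `false_alarms` (scene-level, repeated across the two
#'   appearing-source cells), and list column `detection_times_ms`.
#' @export
simulate_behavior <- function(fx = effect_config(), n_subjects = 13,
                              n_change_per_cell = 96,
                              n_nochange_per_scene = 192, seed = NULL) {
  stopifnot(n_subjects >= 1, n_change_per_cell >= 1)
  b <- fx$behavior
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      logit_shift <- stats::rnorm(1, 0, b$subj_hit_logit_sd)
      rt_shift <- stats::rnorm(1, 0, b$subj_rt_sd_ms)
      fa_p <- min(max(b$p_fa, 1e-6), 1 - 1e-6)
      fas <- c(REG = stats::rbinom(1, n_nochange_per_scene, fa_p),
               RAND = stats::rbinom(1, n_nochange_per_scene, fa_p))
      for (scene in c("REG", "RAND")) {
        p_base <- if (scene == "REG") b$p_hit_reg else b$p_hit_rand
        p <- stats::plogis(stats::qlogis(p_base) + logit_shift)
        for (appearing in c("regular", "random")) {
          hits <- stats::rbinom(1, n_change_per_cell, p)
          mu <- b$rt_mean_ms + rt_shift +
            (if (scene == "REG") b$rt_scene_reg_shift_ms else 0) +
            (if (appearing == "regular") b$rt_appear_reg_shift_ms else 0)
          rts <- if (hits > 0)
            pmax(stats::rnorm(hits, mu, b$rt_sd_ms), 100) else numeric(0)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, scene = scene, appearing = appearing,
            n_change = n_change_per_cell, hits = hits,
            n_nochange = n_nochange_per_scene,
            false_alarms = fas[[scene]])
          rows[[length(rows)]]$detection_times_ms <- I(list(rts))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("behavior_table", "data.frame")
    out
  })
}
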