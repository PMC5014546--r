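#' Default run configuration
#'
#' Two profiles: `"fast"` (32 channels, 6 subjects per group, 16 trials per
#' cell, 200 permutations) suitable for quick checks and CI, and `"paper"`
#' (274 channels, 14 passive / 13 active subjects, 96 trials per cell, 5000
#' permutations) matching the study-scale design.
#'
#' @param profile `"fast"` or `"paper"`.
#' @param seed master seed (mandatory for [run_experiment()]).
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("fast", "paper"), seed = NULL) {
  profile <- match.arg(profile)
  sizes <- if (profile == "paper")
    list(n_channels = 274, n_passive = 14, n_active = 13, n_trials = 96,
         n_perm = 5000, n_select = 20,
         n_change_per_cell = 96, n_nochange_per_scene = 192)
  else
    list(n_channels = 32, n_passive = 6, n_active = 6, n_trials = 16,
         n_perm = 200, n_select = 8,
         n_change_per_cell = 48, n_nochange_per_scene = 96)
  list(
    profile = profile,
    seed = seed,
    simulation = list(
      n_channels = sizes$n_channels,
      n_passive = sizes$n_passive,
      n_active = sizes$n_active,
      n_trials = sizes$n_trials,
      rate_hz = 250,
      effects = effect_config()),
    preprocessing = list(
      cutoff_hz = 30,
      k_sd = 3,
      n_keep = 2,
      scene_window_ms = c(-200, 800),
      appearance_window_ms = c(-200, 400),
      baseline_ms = c(-200, 0)),
    stats = list(
      height_p = 0.05,
      n_perm = sizes$n_perm,
      onset_baseline_ms = c(-200, 0),
      m50_window_ms = c(72, 112),
      n_select = sizes$n_select),
    behavior = list(
      n_change_per_cell = sizes$n_change_per_cell,
      n_nochange_per_scene = sizes$n_nochange_per_scene))
}

#' Validate and resolve a run configuration
#'
#' Fills missing fields from [default_config()], then checks ranges and
#' cross-field consistency. Each violation is reported with its field path.
#'
#' @param cfg a (possibly partial) configuration list, or the path of a
#'   YAML file containing one. An empty input resolves to pure defaults.
#' @return list with `config` (resolved), `errors` (character vector, empty
#'   when valid), `ok`.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1L)
    cfg <- yaml::read_yaml(cfg) %||% list()
  if (is.null(cfg)) cfg <- list()
  profile <- cfg$profile %||% "fast"
  resolved <- utils::modifyList(default_config(profile), cfg)
  errors <- character(0)
  add <- function(path, msg) errors <<- c(errors, sprintf("%s: %s", path, msg))
  sim <- resolved$simulation
  pp <- resolved$preprocessing
  st <- resolved$stats
  if (sim$n_passive < 3) add("simulation.n_passive", "need at least 3 subjects")
  if (sim$n_active < 3) add("simulation.n_active", "need at least 3 subjects")
  if (sim$n_channels < 8) add("simulation.n_channels", "need at least 8 channels")
  if (sim$n_trials < 4) add("simulation.n_trials", "need at least 4 trials per cell")
  if (pp$cutoff_hz >= sim$rate_hz / 2)
    add("preprocessing.cutoff_hz",
        sprintf("cutoff %g Hz is not below the Nyquist frequency of the %g Hz analysis rate",
                pp$cutoff_hz, sim$rate_hz))
  check_window <- function(win, base, path) {
    if (base[1] < win[1] || base[2] > win[2])
      add(path, sprintf("baseline (%g, %g) not contained in window (%g, %g)",
                        base[1], base[2], win[1], win[2]))
  }
  check_window(pp$scene_window_ms, pp$baseline_ms, "preprocessing.scene_window_ms")
  check_window(pp$appearance_window_ms, pp$baseline_ms,
               "preprocessing.appearance_window_ms")
  if (st$height_p <= 0 || st$height_p >= 1)
    add("stats.height_p", "must be in (0, 1)")
  if (st$n_perm < 100) add("stats.n_perm", "need at least 100 permutations")
  if (st$n_select > sim$n_channels / 2)
    add("stats.n_select", "exceeds half the channel count")
  if (st$m50_window_ms[1] < pp$appearance_window_ms[1] ||
      st$m50_window_ms[2] > pp$appearance_window_ms[2])
    add("stats.m50_window_ms", "outside the appearance epoch window")
  list(config = resolved, errors = errors, ok = length(errors) == 0L)
}

# Deterministic md5 hash of an R object (written as deparsed text).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("stage %-12s %6.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

# Preprocess one subject: outlier rejection on every tensor, DSS fitted on
# the pooled scene-locked epochs, projection of all tensors onto the kept
# components, then plain trial averaging.
preprocess_subject <- function(subj, k_sd = 3, n_keep = 2) {
  clean <- function(tensor) reject_outlier_trials(tensor, k_sd)$tensor
  scene <- lapply(subj$scene, clean)
  appearance <- lapply(subj$appearance, clean)
  nochange <- lapply(subj$nochange, clean)
  pooled <- scene$REG
  pooled$data <- array(c(scene$REG$data, scene$RAND$data),
                       dim = c(dim(scene$REG$data)[1:2],
                               dim(scene$REG$data)[3] + dim(scene$RAND$data)[3]))
  model <- dss_fit(pooled, n_keep = n_keep)
  denoise_avg <- function(tensor) average_trials(dss_apply(model, tensor))
  list(
    scene = lapply(scene, denoise_avg),
    appearance = lapply(appearance, denoise_avg),
    nochange = lapply(nochange, denoise_avg),
    dss = model)
}

# Average two evoked responses (pooling design cells).
pool_evoked <- function(a, b) {
  out <- a
  out$data <- (a$data + b$data) / 2
  out
}

#' Run the full simulated experiment end to end
#'
#' Executes every stage from a single configuration: behavioural simulation
#' and statistics; MEG dataset simulation for both groups; per-subject
#' preprocessing (3-SD outlier-trial rejection, DSS fitted on scene-locked
#' epochs and applied to all epochs, trial averaging); RMS time-courses;
#' cluster-based permutation tests of scene structure on the scene-locked,
#' appearance-locked and no-change responses, and of appearing-source
#' structure; jackknife onset-latency estimates of the scene-structure
#' effect per group with the between-group jackknife-adjusted test; and the
#' polarity-preserving channel-subset analysis at the appearance-evoked M50.
#'
#' @param cfg configuration list or YAML path (see [validate_config()]);
#'   `cfg$seed` is mandatory.
#' @return object of class `run_report` with elements `config`,
#'   `config_hash`, `seed`, `behavior`, `meg` (per group: cluster results,
#'   jackknife estimates, channel-subset means), `group_tests`.
#' @export
run_experiment <- function(cfg = default_config("fast", seed = 1)) {
  v <- validate_config(cfg)
  if (!v$ok)
    stop(sprintf("invalid configuration:\n  %s",
                 paste(v$errors, collapse = "\n  ")))
  cfg <- v$config
  if (is.null(cfg$seed)) stop("cfg$seed is mandatory")
  seed <- cfg$seed
  sim <- cfg$simulation
  pp <- cfg$preprocessing
  st <- cfg$stats

  behavior <- run_stage("behavior", {
    tab <- simulate_behavior(sim$effects, n_subjects = sim$n_active,
                             n_change_per_cell = cfg$behavior$n_change_per_cell,
                             n_nochange_per_scene = cfg$behavior$n_nochange_per_scene,
                             seed = child_seed(seed, "behavior"))
    list(table = tab, stats = behavior_summary(tab))
  })

  dataset <- run_stage("simulate", simulate_dataset(
    sim$effects, n_passive = sim$n_passive, n_active = sim$n_active,
    n_channels = sim$n_channels, n_trials = sim$n_trials,
    rate_hz = sim$rate_hz, seed = child_seed(seed, "meg")))

  prep <- run_stage("preprocess", lapply(
    list(Passive = dataset$Passive, Active = dataset$Active),
    function(group) lapply(group, preprocess_subject,
                           k_sd = pp$k_sd, n_keep = pp$n_keep)))

  meg <- run_stage("stats", {
    lapply(stats::setNames(names(prep), names(prep)), function(gname) {
      subs <- prep[[gname]]
      rms_of <- function(getter) lapply(subs, function(s) rms_timecourse(getter(s)))
      scene_reg <- rms_of(function(s) s$scene$REG)
      scene_rand <- rms_of(function(s) s$scene$RAND)
      app_reg <- rms_of(function(s)
        pool_evoked(s$appearance$REG.regular, s$appearance$REG.random))
      app_rand <- rms_of(function(s)
        pool_evoked(s$appearance$RAND.regular, s$appearance$RAND.random))
      appsrc_reg <- rms_of(function(s)
        pool_evoked(s$appearance$REG.regular, s$appearance$RAND.regular))
      appsrc_rand <- rms_of(function(s)
        pool_evoked(s$appearance$REG.random, s$appearance$RAND.random))
      nc_reg <- rms_of(function(s) s$nochange$REG)
      nc_rand <- rms_of(function(s) s$nochange$RAND)
      diff_mat <- function(a, b) stack_series(a) - stack_series(b)
      sseed <- child_seed(seed, paste0("perm-", gname))
      list(
        scene_cluster = cluster_permutation_test(
          scene_reg, scene_rand, "paired", st$height_p, st$n_perm,
          seed = sseed),
        appearance_cluster = cluster_permutation_test(
          app_reg, app_rand, "paired", st$height_p, st$n_perm,
          seed = child_seed(sseed, "app")),
        appearing_source_cluster = cluster_permutation_test(
          appsrc_reg, appsrc_rand, "paired", st$height_p, st$n_perm,
          seed = child_seed(sseed, "appsrc")),
        nochange_cluster = cluster_permutation_test(
          nc_reg, nc_rand, "paired", st$height_p, st$n_perm,
          seed = child_seed(sseed, "nc")),
        scene_onset = jackknife_onset(
          diff_mat(scene_reg, scene_rand), st$onset_baseline_ms,
          rate_hz = sim$rate_hz, t0_ms = pp$scene_window_ms[1]),
        appearance_onset = jackknife_onset(
          diff_mat(app_reg, app_rand), st$onset_baseline_ms,
          rate_hz = sim$rate_hz, t0_ms = pp$appearance_window_ms[1]),
        m50_subsets = channel_subset_means(
          lapply(subs, function(s) pool_evoked(
            pool_evoked(s$appearance$REG.regular, s$appearance$REG.random),
            pool_evoked(s$appearance$RAND.regular, s$appearance$RAND.random))),
          st$m50_window_ms, st$n_select))
    })
  })

  group_tests <- list(
    scene_onset = tryCatch(
      jackknife_two_sample_test(meg$Passive$scene_onset,
                                meg$Active$scene_onset),
      error = function(e) list(error = conditionMessage(e))),
    appearance_onset = tryCatch(
      jackknife_two_sample_test(meg$Passive$appearance_onset,
                                meg$Active$appearance_onset),
      error = function(e) list(error = conditionMessage(e))))

  structure(list(
    config = cfg,
    config_hash = config_hash(cfg),
    seed = seed,
    behavior = behavior,
    meg = meg,
    group_tests = group_tests
  ), class = "run_report")
}

#' Write a run report to machine-readable files
#'
#' @param report a [run_experiment()] report.
#' @param out_dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cluster_df <- function(cr) cbind(
    data.frame(n_perm = cr$n_perm, threshold_t = cr$threshold_t),
    cr$clusters)
  js <- list(
    config_hash = report$config_hash,
    seed = report$seed,
    behavior = list(
      summary = report$behavior$stats$summary,
      dprime_anova = report$behavior$stats$dprime_anova,
      rt_anova = report$behavior$stats$rt_anova),
    meg = lapply(report$meg, function(g) list(
      scene_clusters = cluster_df(g$scene_cluster),
      appearance_clusters = cluster_df(g$appearance_cluster),
      appearing_source_clusters = cluster_df(g$appearing_source_cluster),
      nochange_clusters = cluster_df(g$nochange_cluster),
      scene_onset = g$scene_onset[c("mean_ms", "corrected_se_ms", "n",
                                    "complete")],
      appearance_onset = g$appearance_onset[c("mean_ms", "corrected_se_ms",
                                              "n", "complete")])),
    group_tests = report$group_tests)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  cells_path <- file.path(out_dir, "behavior_cells.csv")
  utils::write.csv(report$behavior$stats$cells, cells_path,
                   row.names = FALSE)
  invisible(c(json_path, cells_path))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report (profile %s, seed %s, hash %s)\n",
              x$config$profile, x$seed, substr(x$config_hash, 1, 8)))
  for (g in names(x$meg)) {
    cat(sprintf("\n-- %s group --\n", g))
    cat("Scene-structure effect, scene-locked:\n")
    print(x$meg[[g]]$scene_cluster)
    cat("Scene-structure effect, appearance-locked:\n")
    print(x$meg[[g]]$appearance_cluster)
    cat("Scene-effect onset: ")
    print(x$meg[[g]]$scene_onset)
    cat("Appearance-effect onset: ")
    print(x$meg[[g]]$appearance_onset)
  }
  gt <- x$group_tests$appearance_onset
  if (is.null(gt$error))
    cat(sprintf("\nPassive vs Active appearance-effect onset: t(%d) = %.2f, p = %.4g\n",
                gt$df, gt$t, gt$p))
  invisible(x)
}
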