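#' Draw the trial manifest for one or more presentation blocks
#'
#' Trial sequencing metadata for the experiment: blocks of randomly ordered
#' trials crossing scene regularity (REG/RAND), change status (half the
#' trials carry an appearing source) and, for change trials, the temporal
#' regularity of the appearing source, with an inter-stimulus interval drawn
#' uniformly per trial. No audio is concatenated; this is bookkeeping from
#' which each scene renders independently.
#'
#' @param n_blocks number of blocks (default 8).
#' @param trials_per_block trials per block (default 96).
#' @param isi_range_ms inter-stimulus interval support (default
#'   `c(900, 1100)` ms).
#' @param seed optional integer seed.
#' @return data.frame with one row per trial: `block`, `trial`, `scene`
#'   (REG/RAND), `change`, `appearing` (regular/random/NA), `isi_ms`,
#'   `scene_seed` (per-trial seed from which the scene spec draws).
#' @export
draw_block_manifest <- function(n_blocks = 8, trials_per_block = 96,
                                isi_range_ms = c(900, 1100), seed = NULL) {
  stopifnot(trials_per_block %% 8 == 0)
  with_seed(seed, {
    out <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      cell <- trials_per_block / 8L
      df <- expand.grid(scene = c("REG", "RAND"),
                        change = c(TRUE, FALSE),
                        appearing = c("regular", "random"),
                        rep = seq_len(cell), stringsAsFactors = FALSE)
      df$appearing[!df$change] <- NA
      df <- df[sample.int(nrow(df)), c("scene", "change", "appearing")]
      df$block <- b
      df$trial <- seq_len(nrow(df))
      df$isi_ms <- stats::runif(nrow(df), isi_range_ms[1], isi_range_ms[2])
      df$scene_seed <- sample.int(2147483646L, nrow(df))
      out[[b]] <- df
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df[, c("block", "trial", "scene", "change", "appearing",
           "isi_ms", "scene_seed")]
  })
}

#' Synthesise and write a stimulus set to disk
#'
#' For each manifest trial, draws the scene spec (matched pairs share the
#' change member's configuration and normalisation), renders the audio and
#' writes one WAV per scene plus a JSON sidecar with the full spec and event
#' times, and a CSV manifest per block.
#'
#' @param manifest a [draw_block_manifest()] data.frame (or a subset).
#' @param out_dir output directory (created if needed).
#' @param params a [stimulus_params()] list.
#' @param encoding WAV encoding, see [write_wav()].
#' @return the manifest with added columns `wav`, `json`,
#'   `appearance_time_ms`, `duration_ms`, invisibly.
#' @export
write_stimulus_set <- function(manifest, out_dir,
                               params = stimulus_params(),
                               encoding = "pcm16") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest$wav <- NA_character_
  manifest$json <- NA_character_
  manifest$appearance_time_ms <- NA_real_
  manifest$duration_ms <- NA_real_
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    spec <- draw_scene_spec(params, scene_regularity = row$scene,
                            has_change = TRUE,
                            appearing_regularity =
                              if (row$change) row$appearing else NULL,
                            seed = row$scene_seed)
    stem <- sprintf("block%02d_trial%03d", row$block, row$trial)
    if (row$change) {
      wave <- render_scene(spec)
      out_spec <- spec
    } else {
      pair <- make_matched_pair(spec)
      wave <- render_pair(pair)$no_change
      out_spec <- pair$no_change
    }
    wav_path <- file.path(out_dir, paste0(stem, ".wav"))
    json_path <- file.path(out_dir, paste0(stem, ".json"))
    write_wav(wave, wav_path, encoding)
    side <- scene_spec_to_list(out_spec)
    side$events_ms <- as.list(wave$events)
    side$seed <- row$scene_seed
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$wav[i] <- wav_path
    manifest$json[i] <- json_path
    manifest$appearance_time_ms[i] <-
      if (row$change) out_spec$appearance_time_ms else NA_real_
    manifest$duration_ms[i] <- out_spec$duration_ms
  }
  for (b in unique(manifest$block)) {
    utils::write.csv(
      manifest[manifest$block == b,
               c("block", "trial", "scene", "change", "appearing", "isi_ms",
                 "scene_seed", "appearance_time_ms", "duration_ms", "wav")],
      file.path(out_dir, sprintf("manifest_block%02d.csv", b)),
      row.names = FALSE)
  }
  invisible(manifest)
}

# Serialisable plain-list view of a scene spec (for JSON sidecars).
scene_spec_to_list <- function(spec) {
  src_list <- function(s) list(
    carrier_hz = s$carrier_hz, tone_dur_ms = s$tone_dur_ms,
    gap_mode = s$gap_mode,
    gap_ms = if (is.na(s$gap_ms %||% NA)) NULL else s$gap_ms,
    gaps_ms = s$gaps_ms, start_offset_ms = s$start_offset_ms,
    onset_ms = s$onset_ms)
  list(
    duration_ms = spec$duration_ms,
    scene_regularity = spec$scene_regularity,
    has_change = spec$has_change,
    appearance_time_ms =
      if (isTRUE(spec$has_change)) spec$appearance_time_ms else NULL,
    appearing_regularity =
      if (isTRUE(spec$has_change)) spec$appearing_regularity else NULL,
    sources = lapply(spec$sources, src_list),
    appearing_source =
      if (isTRUE(spec$has_change)) src_list(spec$appearing_source) else NULL)
}
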