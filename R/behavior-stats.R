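#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. Rates are clamped to
#' `[1/(2N), 1 - 1/(2N)]` with the respective trial count `N`, so extreme
#' observed rates (0 or 1) give finite sensitivity.
#'
#' @param hits,n_change hit count and number of change trials.
#' @param fas,n_nochange false-alarm count and number of no-change trials.
#' @return d-prime (scalar or vectorised over the inputs).
#' @examples
#' dprime(73, 96, 12, 192)
#' @export
dprime <- function(hits, n_change, fas, n_nochange) {
  if (any(n_change <= 0) || any(n_nochange <= 0))
    stop("trial totals must be positive")
  clamp <- function(k, n) pmin(pmax(k / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clamp(hits, n_change)) - stats::qnorm(clamp(fas, n_nochange))
}

#' Condition-wise behavioural summary and repeated-measures ANOVA
#'
#' Computes per-subject, per-cell d-prime and mean detection time, group
#' means with within-subject standard errors (subject-mean centred, with
#' the Morey small-cell correction), and classical 2 x 2 repeated-measures
#' ANOVAs (scene structure x appearing-source structure) on d-prime and on
#' detection time. Subjects with no hit trials in a cell have that cell's
#' detection-time mean missing and are excluded from the detection-time
#' ANOVA with a warning.
#'
#' @param table a [simulate_behavior()]-style `behavior_table`.
#' @return list with `cells` (per-subject cell measures), `summary` (cell
#'   means and within-subject SEs), `dprime_anova`, `rt_anova` (data.frames
#'   with effect, F, df and p).
#' @export
behavior_summary <- function(table) {
  stopifnot(is.data.frame(table))
  if (length(unique(table$subject)) < 2) stop("need at least 2 subjects")
  cells <- table[, c("subject", "scene", "appearing")]
  cells$dprime <- dprime(table$hits, table$n_change,
                         table$false_alarms, table$n_nochange)
  cells$rt_ms <- vapply(table$detection_times_ms, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))

  ws_se <- function(value) {
    m <- tapply(value, cells$subject, mean, na.rm = TRUE)
    centred <- value - m[as.character(cells$subject)] +
      mean(value, na.rm = TRUE)
    agg <- tapply(centred, interaction(cells$scene, cells$appearing),
                  function(v) stats::sd(v, na.rm = TRUE) /
                    sqrt(sum(!is.na(v))))
    # Morey correction for the number of within-subject cells
    n_cells <- 4
    agg * sqrt(n_cells / (n_cells - 1))
  }
  mean_by_cell <- function(value)
    tapply(value, interaction(cells$scene, cells$appearing), mean,
           na.rm = TRUE)
  cell_names <- names(mean_by_cell(cells$dprime))
  summary_df <- data.frame(
    cell = cell_names,
    dprime_mean = as.numeric(mean_by_cell(cells$dprime)),
    dprime_ws_se = as.numeric(ws_se(cells$dprime)),
    rt_mean_ms = as.numeric(mean_by_cell(cells$rt_ms)),
    rt_ws_se_ms = as.numeric(ws_se(cells$rt_ms)))

  rm_anova <- function(df, value_col) {
    df$subject <- factor(df$subject)
    df$scene <- factor(df$scene)
    df$appearing <- factor(df$appearing)
    df$y <- df[[value_col]]
    fit <- stats::aov(y ~ scene * appearing +
                        Error(subject / (scene * appearing)), data = df)
    sm <- summary(fit)
    out <- list()
    for (stratum in sm) {
      tab <- stratum[[1]]
      terms <- trimws(rownames(tab))
      for (i in seq_along(terms)) {
        if (terms[i] == "Residuals") next
        out[[terms[i]]] <- data.frame(
          effect = terms[i],
          F = tab[i, "F value"],
          df1 = tab[i, "Df"],
          df2 = tab[nrow(tab), "Df"],
          p = tab[i, "Pr(>F)"])
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }

  dp_anova <- rm_anova(cells, "dprime")
  rt_cells <- cells
  bad <- unique(rt_cells$subject[is.na(rt_cells$rt_ms)])
  if (length(bad)) {
    warning(sprintf(
      "excluding %d subject(s) with empty detection-time cells from the RT ANOVA: %s",
      length(bad), paste(bad, collapse = ", ")))
    rt_cells <- rt_cells[!(rt_cells$subject %in% bad), ]
  }
  rt_anova <- if (length(unique(rt_cells$subject)) >= 2)
    rm_anova(rt_cells, "rt_ms") else NULL

  list(cells = cells, summary = summary_df,
       dprime_anova = dp_anova, rt_anova = rt_anova)
}
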