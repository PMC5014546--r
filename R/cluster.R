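# Vectorised paired t statistics under a matrix of sign assignments.
# D: subjects x time; S: perms x subjects of +-1. Because flipping signs
# leaves per-subject squares unchanged, each permutation's per-sample SD
# follows from the fixed column sums of squares and the permuted mean.
signflip_tmat <- function(D, S) {
  n <- nrow(D)
  ss <- colSums(D^2)
  M <- (S %*% D) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 0] <- 0
  Tm <- M / sqrt(V / n)
  Tm[is.nan(Tm)] <- 0
  Tm
}

# Maximal runs of supra-threshold samples; returns list of (start, end, stat).
find_clusters <- function(tvals, threshold) {
  supra <- abs(tvals) > threshold
  supra[is.na(supra)] <- FALSE
  if (!any(supra)) return(list())
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i)
    list(start = starts[i], end = ends[i],
         stat = sum(abs(tvals[starts[i]:ends[i]]))))
}

max_cluster_stat <- function(tvals, threshold) {
  cl <- find_clusters(tvals, threshold)
  if (!length(cl)) 0 else max(vapply(cl, `[[`, numeric(1), "stat"))
}

#' Cluster-based permutation test on RMS time-courses
#'
#' Computes a per-sample t statistic (paired or two-sample), forms
#' temporally contiguous clusters of samples exceeding the two-tailed
#' critical t at the cluster-defining height threshold, and summarises each
#' cluster by its mass (sum of |t|). Family-wise error is controlled by the
#' permutation distribution of the maximum cluster mass: per-subject sign
#' flips of the condition difference for paired designs, group-label
#' shuffles for two-sample designs. Positive and negative clusters are
#' pooled in the max-statistic null. Monte-Carlo p-values use the +1
#' correction and so are never exactly zero; with `method = "exhaustive"`
#' (paired designs, up to 20 subjects) all `2^n` sign assignments are
#' enumerated and the p-value is the exact proportion of the null at or
#' above the observed mass.
#'
#' @param series_a,series_b per-subject RMS series: lists of
#'   [rms_timecourse()] objects or subjects x time matrices. Paired designs
#'   need equal counts in matched order.
#' @param design `"paired"` or `"two_sample"`.
#' @param height_p cluster-defining height threshold (two-tailed, default
#'   0.05).
#' @param n_perm number of permutations (default 5000; >= 100).
#' @param seed optional integer seed for the permutation draw.
#' @param method `"montecarlo"` or `"exhaustive"` (paired only).
#' @param rate_hz,t0_ms time metadata for matrix input.
#' @return object of class `cluster_result`: `clusters` data.frame
#'   (`start_ms`, `end_ms`, `cluster_stat`, `fwe_p`), `tvals`,
#'   `threshold_t`, `height_p`, `n_perm`, `method`, `design`, `null_max`
#'   (the permutation null distribution), `times_ms`.
#' @export
cluster_permutation_test <- function(series_a, series_b,
                                     design = c("paired", "two_sample"),
                                     height_p = 0.05, n_perm = 5000,
                                     seed = NULL,
                                     method = c("montecarlo", "exhaustive"),
                                     rate_hz = NULL, t0_ms = NULL) {
  design <- match.arg(design)
  method <- match.arg(method)
  meta <- series_meta(if (is.list(series_a)) series_a else list(), rate_hz, t0_ms)
  A <- stack_series(series_a)
  B <- stack_series(series_b)
  if (method == "montecarlo" && n_perm < 100) stop("need n_perm >= 100")
  if (design == "paired") {
    if (nrow(A) != nrow(B))
      stop("paired design needs equal subject counts in matched order")
    n <- nrow(A)
    if (n < 3) stop("need at least 3 subjects")
    D <- A - B
    thr <- stats::qt(1 - height_p / 2, df = n - 1)
    tobs <- signflip_tmat(D, matrix(1, 1, n))[1, ]
    tobs[colSums(abs(D)) == 0] <- 0
    S <- if (method == "exhaustive") {
      if (n > 20) stop("exhaustive enumeration limited to 20 subjects")
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      with_seed(seed,
        matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
    }
    Tnull <- signflip_tmat(D, S)
    Tnull[, colSums(abs(D)) == 0] <- 0
    null_max <- apply(Tnull, 1, max_cluster_stat, threshold = thr)
  } else {
    na <- nrow(A); nb <- nrow(B)
    if (na < 3 || nb < 3) stop("need at least 3 subjects per group")
    X <- rbind(A, B)
    labels <- rep(c(TRUE, FALSE), c(na, nb))
    thr <- stats::qt(1 - height_p / 2, df = na + nb - 2)
    two_t <- function(lab) {
      ma <- colMeans(X[lab, , drop = FALSE])
      mb <- colMeans(X[!lab, , drop = FALSE])
      va <- apply(X[lab, , drop = FALSE], 2, stats::var)
      vb <- apply(X[!lab, , drop = FALSE], 2, stats::var)
      sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      tt <- (ma - mb) / sqrt(sp * (1 / na + 1 / nb))
      tt[!is.finite(tt)] <- 0
      tt
    }
    tobs <- two_t(labels)
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      max_cluster_stat(two_t(sample(labels)), thr), numeric(1)))
  }
  obs <- find_clusters(tobs, thr)
  pval <- function(stat) {
    if (method == "exhaustive") mean(null_max >= stat)
    else (1 + sum(null_max >= stat)) / (1 + length(null_max))
  }
  dt <- 1000 / meta$rate_hz
  times <- meta$t0_ms + (seq_along(tobs) - 1) * dt
  clusters <- if (length(obs)) data.frame(
    start_ms = vapply(obs, function(c) times[c$start], numeric(1)),
    end_ms = vapply(obs, function(c) times[c$end], numeric(1)),
    cluster_stat = vapply(obs, `[[`, numeric(1), "stat"),
    fwe_p = vapply(obs, function(c) pval(c$stat), numeric(1))
  ) else data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    cluster_stat = numeric(0), fwe_p = numeric(0))
  structure(list(clusters = clusters, tvals = tobs, threshold_t = thr,
                 height_p = height_p, n_perm = length(null_max),
                 method = method, design = design, null_max = null_max,
                 times_ms = times),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %s, %d permutations, |t| > %.2f):\n",
              x$design, x$method, x$n_perm, x$threshold_t))
  if (!nrow(x$clusters)) cat("  no supra-threshold clusters\n")
  else for (i in seq_len(nrow(x$clusters)))
    cat(sprintf("  %7.1f-%7.1f ms  mass %8.2f  FWE p = %.4f%s\n",
                x$clusters$start_ms[i], x$clusters$end_ms[i],
                x$clusters$cluster_stat[i], x$clusters$fwe_p[i],
                ifelse(x$clusters$fwe_p[i] < 0.05, " *", "")))
  invisible(x)
}
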