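# Circular binary segmentation (CBS) of per-window log2 copy-number ratios.
#
# Per chromosome, the algorithm repeatedly finds the arc of windows whose
# mean differs most from its complement (pooled-variance t-like statistic,
# compiled scan over all arcs), accepts the split when its within-chromosome
# permutation p-value falls below alpha, and recurses on the pieces. Because
# |T| is symmetric under exchanging an arc with its complement, enumerating
# ordinary arcs [i, j) covers the circularly wrapped ones too. An optional
# pruning pass merges adjacent segments whose means are closer than
# prune_sd x the per-window noise SD (estimated robustly from MAPD).

#' CBS configuration
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_permutations Permutations per split test (default 10000;
#'   must be >= 100).
#' @param min_segment_windows Minimum windows in an arc and in its
#'   complement (default 3).
#' @param seed Integer seed; permutation streams are derived per tested
#'   segment from it, so results are fully deterministic and the set of
#'   accepted splits is monotone in `alpha`.
#' @param prune_sd Merge adjacent segments whose means differ by less than
#'   `prune_sd` per-window noise SDs, the SD estimated as MAPD / 0.9539
#'   (the i.i.d.-Gaussian closed form). 0 disables pruning. Default 0.75:
#'   at low coverage the per-window noise SD is comparable to a single-copy
#'   log2 shift (0.58), so a larger multiple would merge away genuine
#'   single-copy events.
#' @param early_accept Stop a permutation test early after this many
#'   permutations without an exceedance (upper 95% CI on p then sits well
#'   below the default alpha); 0 disables early accept. Early rejection
#'   (exceedances already imply p >= alpha) is always on.
#' @param mode `"circular"` (default) or `"binary"` (single-changepoint
#'   splits only).
#' @return A list of class `cbs_config`.
#' @export
cbs_config <- function(alpha = 0.01, n_permutations = 10000L,
                       min_segment_windows = 3L, seed = 1L, prune_sd = 0.75,
                       early_accept = 300L,
                       mode = c("circular", "binary")) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (n_permutations < 100) abort("`n_permutations` must be >= 100.")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_segment_windows = as.integer(min_segment_windows),
                 seed = as.integer(seed), prune_sd = prune_sd,
                 early_accept = as.integer(early_accept),
                 mode = match.arg(mode)),
            class = "cbs_config")
}

#' Arc statistic of circular binary segmentation
#'
#' The pooled-variance two-sample t-like statistic \eqn{|T|} comparing the
#' mean of the arc `x[(i+1):j]` (0-based half-open `[i, j)`) against the mean
#' of its complement. A perfect step with zero within-group variance returns
#' a large sentinel value so that it dominates any finite statistic.
#'
#' @param x Numeric vector.
#' @param i,j Arc bounds, 0-based half-open; `0 <= i < j <= length(x)`, arc
#'   and complement both non-empty.
#' @return \eqn{|T|} as a single non-negative number.
#' @export
arc_statistic <- function(x, i, j) {
  n <- length(x)
  if (i < 0 || j <= i || j > n || (j - i) >= n)
    abort("need 0 <= i < j <= n with both arc and complement non-empty.")
  arc <- x[(i + 1):j]
  comp <- x[-((i + 1):j)]
  m1 <- mean(arc); m2 <- mean(comp)
  d <- m1 - m2
  sp2 <- if (n > 2)
    (sum((arc - m1)^2) + sum((comp - m2)^2)) / (n - 2) else 0
  if (sp2 < 1e-12) {
    if (abs(d) < 1e-12) return(0)
    return(1e100 * (1 + abs(d)))
  }
  abs(d) / sqrt(sp2 * (1 / length(arc) + 1 / length(comp)))
}

# Deterministic per-segment permutation seed: depends only on the global
# seed and the segment's identity, never on the path that reached it.
segment_seed <- function(seed, chrom_index, lo, hi) {
  as.integer((as.numeric(seed) * 7919 + chrom_index * 104729 +
                lo * 1299709 + hi * 15485863) %% 2147483647)
}

#' Segment a normalized profile by circular binary segmentation
#'
#' Runs CBS independently on the unmasked windows of every chromosome and
#' returns the fitted segmentation. Deterministic given `config$seed`.
#'
#' @param profile A `normalized_profile`.
#' @param config A [cbs_config()].
#' @return An object of class `cbs_fit`: list with `segments` (tibble:
#'   `chrom`, `start_bp`, `end_bp`, `start_window`, `end_window`,
#'   `n_windows`, `mean_log2_ratio`), `profile`, `config`, `noise_sd`.
#'   [tidy()] returns the segment tibble, [glance()] a one-row summary,
#'   [autoplot()] the genome plot.
#' @export
segment_cbs <- function(profile, config = cbs_config()) {
  chroms <- unique(profile$chrom)
  h_reject <- max(1L, as.integer(ceiling(config$alpha * config$n_permutations)))
  binary <- config$mode == "binary"
  min_w <- config$min_segment_windows

  seg_rows <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    idx <- which(profile$chrom == chrom & !profile$mask)
    if (!length(idx)) next
    x <- profile$log2_ratio[idx]
    n <- length(x)

    queue <- list(c(1L, n))
    final <- list()
    while (length(queue)) {
      piece <- queue[[1]]; queue <- queue[-1]
      lo <- piece[1]; hi <- piece[2]
      len <- hi - lo + 1L
      if (len < 2L * min_w) { final <- c(final, list(piece)); next }
      xx <- x[lo:hi]
      cand <- cpp_max_arc(xx, min_w, binary)
      if (cand$stat <= 0) { final <- c(final, list(piece)); next }
      set.seed(segment_seed(config$seed, ci, lo, hi))
      pt <- cpp_perm_test(xx, min_w, cand$stat, config$n_permutations,
                          h_reject, config$early_accept, binary)
      accept <- !pt$reject && pt$p < config$alpha
      if (!accept) { final <- c(final, list(piece)); next }
      a <- lo + cand$i          # arc is [a, b] in 1-based inclusive indices
      b <- lo + cand$j - 1L
      pieces <- list(c(lo, a - 1L), c(a, b), c(b + 1L, hi))
      for (p in pieces) if (p[1] <= p[2]) queue <- c(queue, list(p))
    }

    ord <- order(vapply(final, `[`, integer(1), 1L))
    for (p in final[ord]) {
      seg_rows[[length(seg_rows) + 1L]] <- list(chrom = chrom,
                                                lo = p[1], hi = p[2],
                                                idx = idx)
    }
  }

  noise_sd <- tryCatch(mapd(profile) / (sqrt(2) * stats::qnorm(0.75)),
                       error = function(e) NA_real_)

  segs <- bind_rows(lapply(seg_rows, function(s) {
    win <- s$idx[s$lo:s$hi]
    tibble(chrom = s$chrom,
           start_bp = profile$start[win[1]],
           end_bp = profile$end[win[length(win)]],
           start_window = win[1], end_window = win[length(win)],
           n_windows = length(win),
           mean_log2_ratio = mean(profile$log2_ratio[win]))
  }))

  if (nrow(segs) && config$prune_sd > 0 && is.finite(noise_sd))
    segs <- prune_segments(segs, profile, config$prune_sd * noise_sd)

  structure(list(segments = segs, profile = profile, config = config,
                 noise_sd = noise_sd),
            class = "cbs_fit")
}

# Iteratively merge the closest pair of adjacent same-chromosome segments
# until all adjacent mean differences reach `threshold`.
prune_segments <- function(segs, profile, threshold) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    d <- abs(diff(segs$mean_log2_ratio))
    same <- segs$chrom[-1] == segs$chrom[-nrow(segs)]
    d[!same] <- Inf
    k <- which.min(d)
    if (!is.finite(d[k]) || d[k] >= threshold) return(segs)
    win <- segs$start_window[k]:segs$end_window[k + 1]
    merged <- tibble(chrom = segs$chrom[k],
                     start_bp = segs$start_bp[k],
                     end_bp = segs$end_bp[k + 1],
                     start_window = segs$start_window[k],
                     end_window = segs$end_window[k + 1],
                     n_windows = segs$n_windows[k] + segs$n_windows[k + 1],
                     mean_log2_ratio =
                       mean(profile$log2_ratio[win][!profile$mask[win]]))
    segs <- bind_rows(if (k > 1) segs[1:(k - 1), ], merged,
                      if (k + 1 < nrow(segs)) segs[(k + 2):nrow(segs), ])
  }
}

#' @export
print.cbs_fit <- function(x, ...) {
  cat(sprintf("# cbs_fit: %d segments on %d chromosomes (alpha %.3g, seed %d)\n",
              nrow(x$segments), length(unique(x$segments$chrom)),
              x$config$alpha, x$config$seed))
  print(x$segments)
  invisible(x)
}

#' @rdname segment_cbs
#' @param x A `cbs_fit`.
#' @param ... Unused.
#' @export
tidy.cbs_fit <- function(x, ...) x$segments

#' @rdname segment_cbs
#' @export
glance.cbs_fit <- function(x, ...) {
  tibble(n_segments = nrow(x$segments),
         n_chromosomes = length(unique(x$segments$chrom)),
         n_windows = sum(x$segments$n_windows),
         noise_sd = x$noise_sd,
         alpha = x$config$alpha,
         seed = x$config$seed)
}
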