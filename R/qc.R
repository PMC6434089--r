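# Sample-level quality metrics: MAPD (median absolute pairwise difference of
# adjacent-window log2 ratios), coverage uniformity at 20% of mean depth,
# the GC distribution of kept reads, and Pearson correlation between
# profiles (reproducibility / fidelity).

#' MAPD: median absolute pairwise difference of adjacent log2 ratios
#'
#' The median over all pairs of adjacent unmasked windows (within a
#' chromosome; pairs never span a chromosome boundary) of
#' \eqn{|x_{i+1} - x_i|}, where \eqn{x} is the log2 normalized copy-number
#' ratio. For i.i.d. Gaussian noise of SD \eqn{\sigma},
#' MAPD \eqn{= \sigma \sqrt{2}\,\Phi^{-1}(3/4) \approx 0.9539\,\sigma}, so
#' MAPD is a robust per-sample noise statistic; samples with MAPD above 0.4
#' (at the QC window size) are conventionally rejected.
#'
#' @param profile A `normalized_profile`.
#' @param adjacency `"skip_masked"` (default): the next unmasked window on
#'   the same chromosome counts as adjacent; `"strict"`: only consecutive
#'   grid windows pair, pairs touching a masked window are dropped.
#' @return MAPD as a single non-negative number.
#' @export
mapd <- function(profile, adjacency = c("skip_masked", "strict")) {
  adjacency <- match.arg(adjacency)
  diffs <- unlist(lapply(split(seq_len(nrow(profile)), profile$chrom),
                         function(idx) {
    x <- profile$log2_ratio[idx]
    m <- profile$mask[idx]
    if (adjacency == "skip_masked") {
      x <- x[!m]
      if (length(x) < 2) return(numeric(0))
      abs(diff(x))
    } else {
      d <- abs(diff(x))
      ok <- !m[-length(m)] & !m[-1]
      d[ok]
    }
  }), use.names = FALSE)
  if (length(diffs) < 2)
    abort("fewer than 2 usable adjacent window pairs; MAPD undefined.")
  median(diffs)
}

#' MAPD across window sizes
#'
#' For each aggregation factor, re-aggregates the raw counts and the grid,
#' redoes GC correction and control normalization, and computes MAPD —
#' larger windows average out amplification noise at the cost of CNV
#' resolution.
#'
#' @param sample,control `window_counts` on `grid` (raw counts; correction is
#'   redone per size).
#' @param grid The base `window_grid`.
#' @param factors Integer aggregation factors (default 1:5, i.e. 20–100 kb
#'   for a 20-kb base grid).
#' @param span GC-correction span.
#' @return A tibble with columns `factor`, `window_size`, `mapd`.
#' @export
mapd_by_window_size <- function(sample, control, grid, factors = 1:5,
                                span = 0.3) {
  base_ws <- grid_window_size(grid)
  rows <- lapply(factors, function(f) {
    g <- aggregate_grid(grid, f)
    s <- aggregate_counts(sample, f, grid)
    k <- aggregate_counts(control, f, grid)
    prof <- normalize_to_control(gc_correct(s, g, span = span),
                                 gc_correct(k, g, span = span), g)
    tibble(factor = as.integer(f), window_size = base_ws * as.integer(f),
           mapd = mapd(prof))
  })
  bind_rows(rows)
}

#' Coverage uniformity: fraction of windows at 20% of mean depth
#'
#' Over usable windows, the fraction whose count reaches at least
#' `depth_fraction` (default 0.2) of the mean window count. Samples with a
#' fraction below 0.90 are conventionally regarded as not quantitative for
#' copy-number analysis. Scale-invariant in the counts.
#'
#' @param wc A `window_counts`.
#' @param grid The `window_grid`.
#' @param depth_fraction Depth threshold as a fraction of the mean.
#' @return Fraction in \[0, 1\].
#' @export
coverage_uniformity <- function(wc, grid, depth_fraction = 0.2) {
  cnt <- wc$count[grid$usable]
  if (!length(cnt)) abort("no usable windows.")
  mean(cnt >= depth_fraction * mean(cnt))
}

#' Pearson correlation between two normalized profiles
#'
#' Computed on the (linear-scale) ratios over jointly unmasked windows; used
#' both for reproducibility (repeat vs repeat of one kit) and fidelity
#' (amplified vs unamplified bulk).
#'
#' @param a,b `normalized_profile`s on the same grid.
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ok <- !a$mask & !b$mask
  if (sum(ok) < 3) abort("fewer than 3 jointly unmasked windows.")
  cor(a$ratio[ok], b$ratio[ok])
}

#' GC distribution of kept reads
#'
#' Fraction of kept reads falling in windows of each GC bin; sums to 1.
#' A right-shifted distribution relative to an unbiased sample indicates
#' preferential amplification of GC-rich loci.
#'
#' @param wc A `window_counts`.
#' @param grid The annotated `window_grid`.
#' @param bin_width GC bin width (default 0.01).
#' @return A tibble with columns `gc_bin` (left edge) and `read_fraction`.
#' @export
gc_read_distribution <- function(wc, grid, bin_width = 0.01) {
  ok <- grid$usable & !is.na(grid$gc)
  total <- sum(wc$count[ok])
  if (total <= 0) abort("no reads in usable windows.")
  bin <- floor(grid$gc[ok] / bin_width) * bin_width
  agg <- tapply(wc$count[ok], bin, sum)
  tibble(gc_bin = as.numeric(names(agg)),
         read_fraction = as.numeric(agg) / total)
}

#' Full quality report for a sample
#'
#' Computes MAPD at the QC window size (default: 5x aggregation of the base
#' grid, i.e. 100 kb for 20-kb windows), the coverage-uniformity fraction,
#' the GC read histogram, and the two pass/fail verdicts (MAPD <= `mapd_max`,
#' coverage fraction >= `coverage_min`).
#'
#' @param sample,control `window_counts` on `grid`.
#' @param grid The base `window_grid`.
#' @param qc_factor Aggregation factor defining the QC window size.
#' @param mapd_max MAPD rejection threshold (default 0.4).
#' @param coverage_min Minimum coverage-uniformity fraction (default 0.90).
#' @param span GC-correction span.
#' @return A list of class `qc_report`; see [glance.qc_report()].
#' @export
qc_report <- function(sample, control, grid, qc_factor = 5L, mapd_max = 0.4,
                      coverage_min = 0.9, span = 0.3) {
  m <- mapd_by_window_size(sample, control, grid,
                           factors = c(1L, qc_factor), span = span)
  cov_frac <- coverage_uniformity(sample, grid)
  out <- list(
    sample_id = attr(sample, "sample_id") %||% "sample",
    mapd_by_window_size = m,
    mapd_qc = m$mapd[m$factor == qc_factor],
    qc_window_size = grid_window_size(grid) * qc_factor,
    coverage_fraction_at_20pct = cov_frac,
    mapd_max = mapd_max,
    coverage_min = coverage_min,
    qc_pass_mapd = m$mapd[m$factor == qc_factor] <= mapd_max,
    qc_pass_coverage = cov_frac >= coverage_min,
    gc_histogram = gc_read_distribution(sample, grid)
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("# qc_report: %s\n", x$sample_id))
  cat(sprintf("  MAPD (%d kb windows): %.3f  [pass <= %.2f: %s]\n",
              x$qc_window_size / 1000, x$mapd_qc, x$mapd_max,
              ifelse(x$qc_pass_mapd, "yes", "NO")))
  cat(sprintf("  coverage fraction at 20%% mean depth: %.3f  [pass >= %.2f: %s]\n",
              x$coverage_fraction_at_20pct, x$coverage_min,
              ifelse(x$qc_pass_coverage, "yes", "NO")))
  invisible(x)
}

#' @rdname qc_report
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
glance.qc_report <- function(x, ...) {
  tibble(sample_id = x$sample_id, mapd_qc = x$mapd_qc,
         qc_window_size = x$qc_window_size,
         coverage_fraction_at_20pct = x$coverage_fraction_at_20pct,
         qc_pass_mapd = x$qc_pass_mapd,
         qc_pass_coverage = x$qc_pass_coverage,
         qc_pass = x$qc_pass_mapd && x$qc_pass_coverage)
}

#' Write a QC report as key=value text
#'
#' @param x A `qc_report`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(x, path) {
  g <- glance(x)
  writeLines(sprintf("%s=%s", names(g), unlist(lapply(g, format))), path)
  invisible(path)
}
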