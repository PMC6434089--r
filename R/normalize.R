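# GC correction by locally weighted regression and normalization against a
# matched euploid control.
#
# Correction is multiplicative: counts are divided by the fitted GC response
# and rescaled to its median, preserving non-negativity. The fit uses usable,
# non-zero autosomal windows only (sex chromosomes would confound the fit
# through their copy number), with robustness iterations so that windows
# inside genuine CNVs do not drag the GC curve.

#' GC-correct window counts by locally weighted regression
#'
#' Fits a smooth count-versus-GC response over usable, non-zero autosomal
#' windows ([stats::lowess], robust local linear regression with span
#' `span`), then rescales every window's count by `median(fit) / fit(gc_i)`.
#' Windows whose GC lies outside the fitted range use the nearest fitted
#' value. If the GC spread is degenerate (all windows the same GC), the
#' correction is the identity and a warning is emitted.
#'
#' @param wc A `window_counts`.
#' @param grid The annotated `window_grid` the counts align to.
#' @param span Smoother span (fraction of points in each local fit,
#'   default 0.3).
#' @param min_fit_windows Minimum usable non-zero autosomal windows required
#'   to attempt a fit (default 100).
#' @return `wc` with an added `corrected` column of non-negative reals.
#' @export
gc_correct <- function(wc, grid, span = 0.3, min_fit_windows = 100L) {
  stopifnot(nrow(wc) == nrow(grid))
  count <- wc$count
  gc <- grid$gc
  fit_idx <- which(grid$usable & is_autosome(grid$chrom) & count > 0 &
                     !is.na(gc))
  if (length(fit_idx) < min_fit_windows)
    abort(sprintf(
      "insufficient data for GC regression: %d usable non-zero autosomal windows (need >= %d).",
      length(fit_idx), min_fit_windows))

  out <- wc
  if (diff(range(gc[fit_idx])) < 1e-8) {
    warn("degenerate GC spread; GC correction is the identity.")
    out$corrected <- as.numeric(count)
    return(out)
  }

  # The trend is fitted on log2 counts: amplification GC response is
  # multiplicative (approximately exponential in GC), so it is near-linear
  # on the log scale and the local fit stays accurate in the sparse GC
  # tails, where a count-space fit under- or over-shoots systematically.
  lw <- lowess(gc[fit_idx], log2(count[fit_idx]), f = span)
  gc_cl <- pmin(max(lw$x), pmax(min(lw$x), gc))
  f <- approx(lw$x, lw$y, xout = gc_cl, rule = 2, ties = mean)$y
  out$corrected <- count * 2^(stats::median(lw$y) - f)
  out$corrected[is.na(gc)] <- as.numeric(count[is.na(gc)])
  out
}

#' Normalize GC-corrected counts against a control profile
#'
#' Forms the depth-scaled per-window ratio
#' \eqn{r_i = (s'_i / S) / (k'_i / K)} between the GC-corrected sample counts
#' \eqn{s'} and control counts \eqn{k'}, where \eqn{S} and \eqn{K} are the
#' respective totals over unmasked windows, together with
#' \eqn{x_i = \log_2 r_i}. A window is masked when it is unusable in the grid
#' or when either side has a zero (or zero-corrected) count, so no
#' infinities or NaNs appear. For an autosomal diploid-versus-diploid
#' comparison \eqn{x_i \approx \log_2(\mathrm{CN}_i/2)}.
#'
#' @param sample,control `window_counts` with a `corrected` column (from
#'   [gc_correct()]); a plain `count` column is used when `corrected` is
#'   absent.
#' @param grid The shared `window_grid`.
#' @return A tibble of class `normalized_profile` with columns `chrom`,
#'   `start`, `end`, `gc`, `ratio`, `log2_ratio`, `mask`.
#' @export
normalize_to_control <- function(sample, control, grid) {
  stopifnot(nrow(sample) == nrow(grid), nrow(control) == nrow(grid))
  col <- function(df, nm, default) if (nm %in% names(df)) df[[nm]] else default
  s <- col(sample, "corrected", as.numeric(sample$count))
  k <- col(control, "corrected", as.numeric(control$count))
  s_raw <- col(sample, "count", s)
  k_raw <- col(control, "count", k)
  if (sum(k) <= 0) abort("control has zero total count.")

  mask <- !grid$usable | s <= 0 | k <= 0 | s_raw <= 0 | k_raw <= 0
  S <- sum(s[!mask])
  K <- sum(k[!mask])
  if (S <= 0) abort("sample has zero total count over unmasked windows.")

  ratio <- rep(NA_real_, nrow(grid))
  ratio[!mask] <- (s[!mask] / S) / (k[!mask] / K)
  out <- tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                gc = grid$gc, ratio = ratio,
                log2_ratio = log2(ratio), mask = mask)
  attr(out, "sample_id") <- attr(sample, "sample_id") %||% "sample"
  attr(out, "control_id") <- attr(control, "sample_id") %||% "control"
  attr(out, "grid_checksum") <- grid_checksum(grid)
  class(out) <- c("normalized_profile", class(tibble()))
  out
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("# normalized_profile: %s vs %s, %d windows (%d masked)\n",
              attr(x, "sample_id"), attr(x, "control_id"), nrow(x),
              sum(x$mask)))
  NextMethod()
}

#' Pool control count profiles
#'
#' Sums the counts of several controls on the same grid into one pooled
#' control.
#'
#' @param ... `window_counts` objects on a common grid.
#' @param grid The shared grid.
#' @return A pooled `window_counts`.
#' @export
pool_controls <- function(..., grid) {
  lst <- list(...)
  stopifnot(length(lst) >= 1)
  count <- Reduce(`+`, lapply(lst, function(w) w$count))
  new_window_counts(count, grid, sample_id = "pooled_control",
                    kit = attr(lst[[1]], "kit") %||% "none",
                    sample_type = "bulk")
}
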