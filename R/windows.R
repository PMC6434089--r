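# Window grid construction, FASTA annotation and aggregation.
#
# All coordinates are 0-based half-open, matching BED. A grid tiles each
# chromosome completely; trailing partial windows are kept (so window indices
# are reproducible from chromosome lengths alone) but flagged usable = FALSE.

#' Build a fixed-size window grid over a genome
#'
#' Tiles every chromosome with consecutive windows of `window_size` bp
#' (0-based, half-open). A trailing window shorter than `window_size` is kept
#' in the grid but marked `usable = FALSE`, so that window indexing depends
#' only on the chromosome lengths.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window_size Window width in bp (default 20000, i.e. 20 kbp).
#' @param genome_id Free-text identifier recorded with the grid.
#'
#' @return A tibble of class `window_grid` with columns `chrom`, `start`,
#'   `end`, `gc`, `n_fraction`, `usable` and attributes `window_size` and
#'   `genome_id`. `gc`/`n_fraction` are `NA` until [annotate_grid_fasta()] or
#'   [simulate_grid_gc()] fills them in.
#'
#' @examples
#' make_window_grid(c(chr1 = 1e5), 20000)
#' @export
make_window_grid <- function(chrom_lengths, window_size = 20000L,
                             genome_id = "custom") {
  if (length(window_size) != 1L || is.na(window_size) || window_size <= 0)
    abort("`window_size` must be a single positive integer.")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    abort("`chrom_lengths` must be a named vector.")
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive.")
  window_size <- as.integer(window_size)

  rows <- imap(chrom_lengths, function(len, chrom) {
    starts <- seq.int(0L, len - 1L, by = window_size)
    tibble(
      chrom = chrom,
      start = starts,
      end = pmin(starts + window_size, as.numeric(len))
    )
  })
  grid <- bind_rows(rows) %>%
    mutate(
      gc = NA_real_,
      n_fraction = NA_real_,
      usable = (.data$end - .data$start) == window_size
    )
  new_window_grid(grid, window_size = window_size, genome_id = genome_id)
}

new_window_grid <- function(df, window_size, genome_id) {
  out <- as_tibble(df)
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "genome_id") <- genome_id
  class(out) <- c("window_grid", class(tibble()))
  out
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("# window_grid: %d windows of %d bp on %d chromosome(s) [%s]\n",
              nrow(x), attr(x, "window_size"),
              length(unique(x$chrom)), attr(x, "genome_id")))
  NextMethod()
}

grid_window_size <- function(grid) attr(grid, "window_size")

#' Annotate a window grid with GC and N content from a reference FASTA
#'
#' Computes, for every window, the fraction of G/C bases and of ambiguous `N`
#' bases over the full window length. Windows with `n_fraction > n_max`
#' (default 0: any `N` disqualifies) are set `usable = FALSE`, as are trailing
#' partial windows. The operation is idempotent.
#'
#' @param grid A [make_window_grid()] grid.
#' @param fasta Path to a reference FASTA containing every grid chromosome.
#' @param n_max Maximum tolerated `n_fraction` for a usable window.
#'
#' @return The grid with `gc`, `n_fraction` and `usable` filled in.
#' @export
annotate_grid_fasta <- function(grid, fasta, n_max = 0) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort("annotate_grid_fasta() needs the Biostrings package.")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ws <- grid_window_size(grid)

  missing <- setdiff(unique(grid$chrom), names(seqs))
  if (length(missing))
    abort(paste0("reference FASTA lacks chromosome(s): ",
                 paste(missing, collapse = ", ")))

  out <- grid
  for (chrom in unique(grid$chrom)) {
    idx <- which(grid$chrom == chrom)
    seq <- seqs[[chrom]]
    if (length(seq) < max(grid$end[idx]))
      abort(sprintf("reference sequence for %s is shorter (%d bp) than the grid (%d bp).",
                    chrom, length(seq), max(grid$end[idx])))
    v <- Biostrings::Views(seq, start = grid$start[idx] + 1L,
                           end = as.integer(grid$end[idx]))
    lf <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
    width <- grid$end[idx] - grid$start[idx]
    out$gc[idx] <- (lf[, "G"] + lf[, "C"]) / width
    out$n_fraction[idx] <- lf[, "N"] / width
  }
  out$usable <- (out$end - out$start) == ws & out$n_fraction <= n_max
  out
}

#' Aggregate a window grid to a larger window size
#'
#' Merges consecutive runs of `factor` windows within each chromosome. GC and
#' N fractions of the merged window are length-weighted means of the members;
#' a merged window is usable only if all members are usable.
#'
#' @param grid A `window_grid`.
#' @param factor Positive integer aggregation factor (1 returns the grid
#'   unchanged).
#' @return A `window_grid` with `window_size` multiplied by `factor`.
#' @export
aggregate_grid <- function(grid, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1)
    abort("`factor` must be a single integer >= 1.")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)

  gid <- aggregation_groups(grid$chrom, factor)
  firsts <- which(!duplicated(gid))
  lasts <- c(firsts[-1] - 1L, length(gid))
  w <- grid$end - grid$start
  gsum <- function(x) unname(rowsum(x, gid, reorder = FALSE)[, 1])
  sw <- gsum(w)
  agg <- tibble(
    chrom = grid$chrom[firsts],
    start = grid$start[firsts],
    end = grid$end[lasts],
    gc = gsum(grid$gc * w) / sw,
    n_fraction = gsum(grid$n_fraction * w) / sw,
    usable = gsum(as.integer(!grid$usable)) == 0L)
  # a merged window shorter than the new nominal size (chromosome tail) is
  # not usable, mirroring make_window_grid()
  new_ws <- grid_window_size(grid) * factor
  agg$usable <- agg$usable & (agg$end - agg$start) == new_ws
  new_window_grid(agg, window_size = new_ws,
                  genome_id = attr(grid, "genome_id"))
}

# Integer group ids (1..G, in encounter order) merging runs of `factor`
# consecutive rows within each chromosome block. Rows are assumed ordered,
# contiguous per chromosome — the window-grid invariant.
aggregation_groups <- function(chrom, factor) {
  r <- rle(chrom)$lengths
  blk <- rep(seq_along(r), r)
  sub <- (sequence(r) - 1L) %/% factor
  per_blk <- (r + factor - 1L) %/% factor
  c(0L, cumsum(per_blk))[blk] + sub + 1L
}

#' Draw a smooth synthetic GC landscape for a grid
#'
#' Fills the grid's `gc` column with an autocorrelated GC fraction series
#' (AR(1) along windows within each chromosome, restarted per chromosome),
#' emulating the ~100-kb-scale GC structure of a mammalian genome, and sets
#' `n_fraction = 0`. Used by the simulator when no reference FASTA is in play.
#'
#' @param grid A `window_grid`.
#' @param gc_mean,gc_sd Marginal mean and SD of the GC fraction (defaults
#'   0.41 / 0.05, matching typical human window-level GC).
#' @param autocorr AR(1) coefficient between adjacent 20-kb windows.
#' @param seed Integer seed; the landscape is deterministic given the seed.
#' @return The grid with `gc`, `n_fraction`, `usable` populated.
#' @export
simulate_grid_gc <- function(grid, gc_mean = 0.41, gc_sd = 0.05,
                             autocorr = 0.98, seed = 20170707L) {
  out <- grid
  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  for (chrom in unique(grid$chrom)) {
    idx <- which(grid$chrom == chrom)
    z <- ar1_series(length(idx), autocorr, sd = gc_sd)
    out$gc[idx] <- pmin(0.65, pmax(0.25, gc_mean + z))
  }
  out$n_fraction <- 0
  ws <- grid_window_size(grid)
  out$usable <- (out$end - out$start) == ws
  out
}

# Save/restore the global RNG state around seeded internals.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# Stationary AR(1) series with marginal SD `sd`.
ar1_series <- function(n, rho, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    eps <- rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) z[i] <- rho * z[i - 1] + eps[i - 1]
  }
  z
}

# Cheap deterministic checksum of the window coordinates + size, used to
# refuse re-interpreting a count table on a different grid.
grid_checksum <- function(grid) {
  m <- 2147483647
  ch <- vapply(unique(grid$chrom), function(s) sum(utf8ToInt(s)), numeric(1))
  chv <- ch[grid$chrom]
  term <- (chv * 131071 + (grid$start + 1) * 8191 + grid$end * 127) %% m
  val <- (sum(term) + grid_window_size(grid) * 524287) %% m
  sprintf("%d", as.integer(val))
}
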