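# Shared small grids / simulations for the test suite. Everything here is
# deterministic; helpers memoise the expensive objects within a test run.

# Two-chromosome toy grid with a flat GC landscape: GC-correction is a
# near-no-op on it, so expectations stay hand-computable.
toy_grid <- function(n1 = 50L, n2 = 40L, window_size = 1000L, gc = 0.40) {
  grid <- make_window_grid(
    c(chr1 = n1 * window_size, chr2 = n2 * window_size),
    window_size = window_size, genome_id = "toy")
  grid$gc <- gc
  grid$n_fraction <- 0
  grid
}

toy_counts <- function(grid, counts, sample_id = "s", kit = "none",
                       sample_type = "single_cell") {
  wgacnv:::new_window_counts(counts, grid, sample_id = sample_id, kit = kit,
                             sample_type = sample_type)
}

# A normalized_profile built directly from a log2-ratio vector on `grid`
# (mask defaults to !usable), bypassing counts — for segmentation/calling
# tests that need exact inputs.
toy_profile <- function(grid, log2_ratio, mask = NULL) {
  ratio <- 2^log2_ratio
  out <- tibble::tibble(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    gc = grid$gc, ratio = ratio, log2_ratio = log2_ratio,
    mask = if (is.null(mask)) !grid$usable else mask)
  attr(out, "window_size") <- attr(grid, "window_size")
  attr(out, "grid_checksum") <- wgacnv:::grid_checksum(grid)
  attr(out, "sample_id") <- "toy"
  class(out) <- c("normalized_profile", class(tibble::tibble()))
  out
}

# The default scaled study grid, built once per test run.
study_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_grid()
    cache
  }
})

study_lengths <- function() hg19_chrom_lengths(scale = 0.1)
study_bands <- function() read_cytoband(scale = 0.1)

# Scaled-genome calling config: the 4-Mbp minimum size scales with the
# genome to 0.4 Mbp.
scaled_calling <- function(...) calling_config(min_size_bp = 4e5, ...)

# Calling config for end-to-end smoke tests on the 10%-scale genome: a
# 50-window (1-Mbp) minimum. The genome-proportional 0.4-Mbp rule spans
# only 20 windows there, few enough that noise-level excursions
# occasionally pass the size filter (see the methods vignette, section
# "Specificity and the validation scale"), which would make fixed-seed
# whole-chromosome assertions flaky by construction.
smoke_calling <- function(...) calling_config(min_size_bp = 1e6, ...)
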