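# Built-in genome descriptions for simulation and testing.

# GRCh37/hg19 primary chromosome lengths (bp).
HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

#' hg19 chromosome lengths, optionally scaled down
#'
#' Chromosome lengths of the GRCh37/hg19 assembly. `scale < 1` shrinks every
#' chromosome proportionally (rounded to whole windows of `round_to` bp),
#' giving a genome with the same relative chromosome sizes that runs through
#' the whole pipeline in seconds — the default simulation genome uses
#' `scale = 0.1`.
#'
#' @param scale Proportional scaling factor in (0, 1].
#' @param include_y Keep chromosome Y (default `FALSE`; dosage calling
#'   excludes chrY).
#' @param round_to Round scaled lengths to a multiple of this many bp.
#' @return Named numeric vector of lengths.
#' @export
hg19_chrom_lengths <- function(scale = 1, include_y = FALSE,
                               round_to = 20000) {
  stopifnot(scale > 0, scale <= 1)
  len <- HG19_LENGTHS
  if (!include_y) len <- len[names(len) != "chrY"]
  if (scale < 1)
    len <- setNames(pmax(round_to, round(len * scale / round_to) * round_to),
                    names(len))
  len
}

#' Default annotated simulation grid
#'
#' A 20-kb window grid over the scaled hg19 genome with a deterministic
#' synthetic GC landscape ([simulate_grid_gc()]). This is the grid every
#' simulation-based example and test runs on.
#'
#' @param scale Genome scaling factor (default 0.1).
#' @param window_size Window width in bp.
#' @param gc_seed Seed of the synthetic GC landscape (fixed by default so the
#'   grid is identical across sessions).
#' @return An annotated `window_grid`.
#' @export
default_grid <- function(scale = 0.1, window_size = 20000L,
                         gc_seed = 20170707L) {
  grid <- make_window_grid(hg19_chrom_lengths(scale = scale,
                                              round_to = window_size),
                           window_size = window_size,
                           genome_id = sprintf("hg19-scaled-%.2g", scale))
  simulate_grid_gc(grid, seed = gc_seed)
}
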