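# Bundled study fixtures: the six Coriell cell lines with confirmed
# karyotypes used to validate WGA-based CNV detection (four aneuploidies,
# one microdeletion, one unbalanced translocation represented by its
# terminal deletion + duplication dosage footprint), the per-kit reported
# call strings for those lines, and a miniature BAM/FASTA emitter for
# exercising the read-counting filters.

#' Confirmed cell-line karyotype fixtures
#'
#' The six Coriell lines plus a euploid bulk reference, as
#' [karyotype_spec()]s with event coordinates resolved from the bundled
#' band table (scaled to the simulation genome). The unbalanced
#' translocation line GM01183 is represented by its dosage footprint:
#' a terminal 4p deletion plus a terminal 12p duplication.
#'
#' @param scale Genome scaling factor matching the grid in use.
#' @param bands Band table already scaled to the genome (default: bundled
#'   synthetic table scaled by `scale`).
#' @return A tibble with columns `name`, `confirmed` (karyotype string),
#'   `sex` (reporting sex, XO samples report as XX females), and `spec`
#'   (list column of `karyotype_spec`).
#' @export
cell_line_fixtures <- function(scale = 0.1,
                               bands = read_cytoband(scale = scale)) {
  band_iv <- function(label) resolve_band_interval(label, bands, "chr")
  ev <- function(label, cn) {
    iv <- band_iv(label)
    tibble(chrom = iv$chrom, start_bp = iv$start, end_bp = iv$end,
           copy_number = as.integer(cn))
  }
  len <- hg19_chrom_lengths(scale = scale)
  whole <- function(chrom, cn)
    tibble(chrom = chrom, start_bp = 0, end_bp = len[[chrom]],
           copy_number = as.integer(cn))

  tibble(
    name = c("GM00857", "GM05875", "GM04592", "GM01359", "GM03330",
             "GM01183", "bulk"),
    confirmed = c("45,XO",
                  "46,XX,del(16p12.1-p11.2)",
                  "47,XX,+21",
                  "47,XY,+18",
                  "47,XY,+13",
                  "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)",
                  "46,XX"),
    sex = c("XX", "XX", "XX", "XY", "XY", "XY", "XX"),
    spec = list(
      karyotype_spec("XO"),
      karyotype_spec("XX", ev("16p12.1-p11.2", 1)),
      karyotype_spec("XX", whole("chr21", 3)),
      karyotype_spec("XY", whole("chr18", 3)),
      karyotype_spec("XY", whole("chr13", 3)),
      karyotype_spec("XY", bind_rows(ev("4p16.3-p16.2", 1),
                                     ev("12p13.33-p12.1", 3))),
      karyotype_spec("XX")
    )
  )
}

#' Reported per-kit CNV calls for the validation cell lines
#'
#' The karyotype-style call strings reported for each cell line and WGA
#' chemistry in the kit-comparison experiment, alongside the confirmed
#' karyotypes — the worked example for [concordance()]. `NA` marks runs for
#' which no interpretable result was reported.
#'
#' @return A tibble: `cell_line`, `confirmed`, one column per kit.
#' @export
validation_call_table <- function() {
  tibble(
    cell_line = c("GM00857", "GM05875", "GM04592", "GM01359", "GM03330",
                  "GM01183", "bulk"),
    confirmed = c("45,XO",
                  "46,XX,del(16p12.1-p11.2)",
                  "47,XX,+21",
                  "47,XY,+18",
                  "47,XY,+13",
                  "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)",
                  "46,XX"),
    MALBAC = c("45,XO", "46,XX,del(16p12.1-p11.2)", "47,XX,+21",
               "47,XY,+18", "47,XY,+13",
               "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)", "46,XX"),
    PicoPLEX = c("45,XO", "46,XX,del(16p12.1-p11.2)", "47,XX,+21",
                 "47,XY,+18", "47,XY,+13",
                 "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)", "46,XX"),
    GenomePlex = c("45,XO", "46,XX,del(16p12.1-p11.2)",
                   "46,XX,+21,del(1p31.1-p22.3)",
                   "47,XY,+18,dup(6q15-q16.1)", "47,XY,+13",
                   "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)", "46,XX"),
    MDA = c("+21,-22", NA, "-22", NA, NA, NA, "46,XX")
  )
}

#' Write a miniature FASTA + BAM fixture with hand-placeable reads
#'
#' Emits a small reference FASTA covering the grid and a coordinate-sorted
#' BAM whose reads are placed exactly as specified, so filtered window
#' counts are computable by hand. Intended for testing the read-counting
#' filters.
#'
#' @param grid A small `window_grid`.
#' @param placements Data frame with columns `chrom`, `pos` (1-based
#'   leftmost), `mapq`, `length` (reference-aligned bp), `strand`
#'   (`"+"`/`"-"`); optional `unmapped` (logical).
#' @param dir Output directory.
#' @param basename Stem of the emitted `basename.fa` / `basename.bam`.
#' @return List with `fasta` and `bam` paths.
#' @export
make_fixture_bam <- function(grid, placements, dir = tempdir(),
                             basename = "fixture") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    abort("make_fixture_bam() needs the Rsamtools package.")
  placements <- as_tibble(placements)
  if (!"unmapped" %in% names(placements)) placements$unmapped <- FALSE
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  lens <- tapply(grid$end, grid$chrom, max)
  fasta <- file.path(dir, paste0(basename, ".fa"))
  con <- file(fasta, "wt")
  for (chrom in names(lens)) {
    writeLines(paste0(">", chrom), con)
    writeLines(strrep("ACGT", ceiling(lens[[chrom]] / 4)), con)
  }
  close(con)

  sam <- file.path(dir, paste0(basename, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  ord <- order(match(placements$chrom, names(lens)), placements$pos)
  placements <- placements[ord, ]
  recs <- vapply(seq_len(nrow(placements)), function(i) {
    p <- placements[i, ]
    flag <- 0L
    if (isTRUE(p$unmapped)) flag <- bitwOr(flag, 4L)
    if (identical(p$strand, "-")) flag <- bitwOr(flag, 16L)
    seq <- strrep("A", p$length)
    paste(sprintf("read%03d", i), flag,
          if (isTRUE(p$unmapped)) "*" else p$chrom,
          if (isTRUE(p$unmapped)) 0L else p$pos,
          if (isTRUE(p$unmapped)) 0L else p$mapq,
          if (isTRUE(p$unmapped)) "*" else paste0(p$length, "M"),
          "*", 0L, 0L, seq, strrep("I", p$length), sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, basename), overwrite = TRUE,
                          indexDestination = TRUE)
  list(fasta = fasta, bam = bam)
}
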