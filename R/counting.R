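# Per-window read counting from single-end BAM with the pipeline's read
# filters: primary alignments only, MAPQ >= 10, aligned (reference) length
# >= 35 bp, PCR-duplicate removal. Filter order is fixed: unmapped/secondary
# -> low MAPQ -> short -> duplicate; each read is counted once under the
# first rule it fails.

new_window_counts <- function(count, grid, sample_id = "sample",
                              kit = "none", sample_type = "bulk",
                              total_filtered_reads = sum(count)) {
  out <- tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                count = count)
  attr(out, "sample_id") <- sample_id
  attr(out, "kit") <- kit
  attr(out, "sample_type") <- sample_type
  attr(out, "total_filtered_reads") <- total_filtered_reads
  attr(out, "grid_checksum") <- grid_checksum(grid)
  class(out) <- c("window_counts", class(tibble()))
  out
}

#' Count filtered reads per window from a BAM file
#'
#' Applies the read filters in order (unmapped or non-primary, MAPQ below
#' `mapq_min`, reference-aligned length below `len_min`, PCR duplicate) and
#' assigns each kept read to the window containing its leftmost aligned base.
#' Duplicates are groups of reads with identical (chromosome, leftmost
#' position, strand); the highest-MAPQ member is kept, ties broken by read
#' name. Unusable windows still accumulate counts — window filtering happens
#' downstream in normalization.
#'
#' @param bam Path to a coordinate-sorted single-end BAM.
#' @param grid A `window_grid` whose chromosome names match the BAM header.
#' @param mapq_min Minimum mapping quality (default 10).
#' @param len_min Minimum reference-aligned length in bp (default 35).
#' @param dedup Remove PCR duplicates (default `TRUE`).
#' @param sample_id,kit,sample_type Metadata recorded on the result.
#'
#' @return A `window_counts` tibble (`chrom`, `start`, `end`, `count`) with a
#'   `filter_stats` attribute; retrieve it with [filter_stats()].
#' @export
count_reads <- function(bam, grid, mapq_min = 10L, len_min = 35L,
                        dedup = TRUE, sample_id = basename(bam),
                        kit = "none", sample_type = "single_cell") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    abort("count_reads() needs the Rsamtools package.")
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  bam_chroms <- names(hdr$targets)
  unmatched <- setdiff(unique(grid$chrom), bam_chroms)
  if (length(unmatched))
    abort(paste0("grid chromosome(s) absent from BAM header: ",
                 paste(unmatched, collapse = ", ")))
  so <- grep("^SO:", unlist(hdr$text["@HD"]), value = TRUE)
  if (dedup && (!length(so) || so != "SO:coordinate"))
    abort("BAM must be coordinate-sorted when dedup = TRUE.")

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- length(b$pos)

  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) != 0L | bitwAnd(flag, 256L) != 0L |
    bitwAnd(flag, 2048L) != 0L
  mapq <- b$mapq
  mapq[is.na(mapq)] <- 0L
  low_mapq <- !unmapped & mapq < mapq_min
  ref_len <- cigar_ref_width(b$cigar)
  short <- !unmapped & !low_mapq & ref_len < len_min

  keep <- !(unmapped | low_mapq | short)
  n_duplicate <- 0L
  if (dedup && any(keep)) {
    ki <- which(keep)
    key <- paste(b$rname[ki], b$pos[ki], b$strand[ki], sep = "\r")
    ord <- order(key, -mapq[ki], b$qname[ki], method = "radix")
    dup <- duplicated(key[ord])
    keep[ki[ord][dup]] <- FALSE
    n_duplicate <- sum(dup)
  }

  stats <- list(
    n_total = n_total,
    n_unmapped = sum(unmapped),
    n_low_mapq = sum(low_mapq),
    n_short = sum(short),
    n_duplicate = n_duplicate,
    n_kept = sum(keep)
  )

  count <- integer(nrow(grid))
  if (any(keep)) {
    chroms <- as.character(b$rname[keep])
    pos0 <- b$pos[keep] - 1L
    for (chrom in unique(chroms)) {
      gi <- which(grid$chrom == chrom)
      ci <- which(chroms == chrom)
      w <- findInterval(pos0[ci], grid$start[gi])
      w <- w[w >= 1 & pos0[ci] < max(grid$end[gi])]
      tab <- tabulate(w, nbins = length(gi))
      count[gi] <- count[gi] + tab
    }
  }

  out <- new_window_counts(count, grid, sample_id = sample_id, kit = kit,
                           sample_type = sample_type,
                           total_filtered_reads = stats$n_kept)
  attr(out, "filter_stats") <- stats
  out
}

# Reference-consuming width of a CIGAR string (sum of M/D/N/=/X op lengths).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(ops, nchar(ops))
    len <- as.integer(substring(ops, 1L, nchar(ops) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read-filtering statistics of a count table
#'
#' @param wc A `window_counts` produced by [count_reads()].
#' @return A one-row tibble with columns `n_total`, `n_unmapped`,
#'   `n_low_mapq`, `n_short`, `n_duplicate`, `n_kept`.
#' @export
filter_stats <- function(wc) {
  s <- attr(wc, "filter_stats")
  if (is.null(s)) abort("no filter statistics recorded on this object.")
  as_tibble(s)
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("# window_counts: %s (%s, %s), %s filtered reads in %d windows\n",
              attr(x, "sample_id"), attr(x, "kit"), attr(x, "sample_type"),
              format(attr(x, "total_filtered_reads"), big.mark = ","),
              nrow(x)))
  NextMethod()
}

#' Aggregate window counts to a larger window size
#'
#' Sums counts over consecutive runs of `factor` windows per chromosome,
#' mirroring [aggregate_grid()].
#'
#' @param wc A `window_counts`.
#' @param factor Positive integer aggregation factor.
#' @param grid The grid the counts live on (only used to carry the checksum
#'   of the aggregated grid); if supplied, must match `wc`.
#' @return A `window_counts` on the aggregated grid.
#' @export
aggregate_counts <- function(wc, factor, grid = NULL) {
  if (factor < 1) abort("`factor` must be >= 1.")
  factor <- as.integer(factor)
  if (factor == 1L) return(wc)
  gid <- aggregation_groups(wc$chrom, factor)
  firsts <- which(!duplicated(gid))
  lasts <- c(firsts[-1] - 1L, length(gid))
  cnt <- unname(rowsum(as.numeric(wc$count), gid, reorder = FALSE)[, 1])
  if (all(is.finite(cnt)) && max(cnt) <= .Machine$integer.max)
    cnt <- as.integer(cnt)
  out <- tibble(chrom = wc$chrom[firsts], start = wc$start[firsts],
                end = wc$end[lasts], count = cnt)
  for (a in c("sample_id", "kit", "sample_type", "total_filtered_reads"))
    attr(out, a) <- attr(wc, a)
  attr(out, "grid_checksum") <-
    if (!is.null(grid)) grid_checksum(aggregate_grid(grid, factor)) else NA_character_
  class(out) <- c("window_counts", class(tibble()))
  out
}
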