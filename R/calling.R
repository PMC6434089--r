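# Threshold-based CNV calling on CBS segments: a segment calls as a gain
# when its mean log2 ratio exceeds +0.37 (ratio ~1.29, mosaic-tolerant CN
# ~2.6) and as a loss below -0.51 (ratio ~0.70, CN ~1.4); inequalities are
# strict. Adjacent same-direction passing segments merge before the event
# size filter (default > 4 Mbp), since segmentation may split one biological
# event.

#' CNV-calling configuration
#'
#' @param loss_log2 Loss threshold on the segment mean log2 ratio
#'   (strictly below; default -0.51).
#' @param gain_log2 Gain threshold (strictly above; default 0.37).
#' @param min_size_bp Minimum event size in bp (strictly above;
#'   default 4e6). On a proportionally scaled simulation genome, scale this
#'   threshold by the same factor.
#' @param whole_chrom_fraction Fraction of a chromosome a call must cover to
#'   be reported as a whole-chromosome aneuploidy (default 0.8; acrocentric
#'   short arms keep real calls below 1.0).
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(loss_log2 = -0.51, gain_log2 = 0.37,
                           min_size_bp = 4e6, whole_chrom_fraction = 0.8) {
  if (!(loss_log2 < 0 && gain_log2 > 0))
    abort("need loss_log2 < 0 < gain_log2.")
  if (min_size_bp <= 0) abort("`min_size_bp` must be positive.")
  structure(list(loss_log2 = loss_log2, gain_log2 = gain_log2,
                 min_size_bp = min_size_bp,
                 whole_chrom_fraction = whole_chrom_fraction),
            class = "calling_config")
}

#' Call CNVs from a segmentation
#'
#' @param segments A `cbs_fit` or its segment tibble ([tidy()] output).
#' @param config A [calling_config()].
#' @param exclude_y Drop chrY segments before calling (default `TRUE`;
#'   single-copy chrY against a female control is dosage, not CNV).
#' @return A tibble of class `cnv_calls`: `chrom`, `start_bp`, `end_bp`,
#'   `kind` ("gain"/"loss"), `mean_log2_ratio`, `size_bp`.
#' @export
call_cnvs <- function(segments, config = calling_config(), exclude_y = TRUE) {
  segs <- if (inherits(segments, "cbs_fit")) segments$segments else segments
  if (exclude_y) segs <- segs[!is_chry(segs$chrom), ]
  if (!nrow(segs)) return(empty_calls())

  segs <- segs %>%
    mutate(.row = dplyr::row_number(),
           kind = dplyr::case_when(
      .data$mean_log2_ratio > config$gain_log2 ~ "gain",
      .data$mean_log2_ratio < config$loss_log2 ~ "loss",
      TRUE ~ NA_character_
    ))

  pass <- segs[!is.na(segs$kind), ]
  if (!nrow(pass)) return(empty_calls())

  # merge runs of adjacent (same chromosome, consecutive in the segment
  # table) same-direction passing segments before the size filter
  run <- cumsum(c(TRUE, !(pass$chrom[-1] == pass$chrom[-nrow(pass)] &
                            pass$kind[-1] == pass$kind[-nrow(pass)] &
                            diff(pass$.row) == 1)))
  calls <- pass %>%
    mutate(.run = run) %>%
    group_by(.data$.run) %>%
    summarise(chrom = .data$chrom[1],
              start_bp = min(.data$start_bp),
              end_bp = max(.data$end_bp),
              mean_log2_ratio = stats::weighted.mean(.data$mean_log2_ratio,
                                                     .data$n_windows),
              kind = .data$kind[1],
              .groups = "drop") %>%
    mutate(size_bp = .data$end_bp - .data$start_bp) %>%
    filter(.data$size_bp > config$min_size_bp) %>%
    dplyr::select("chrom", "start_bp", "end_bp", "kind", "mean_log2_ratio",
                  "size_bp")
  structure(as_tibble(calls), class = c("cnv_calls", class(tibble())))
}

empty_calls <- function() {
  structure(tibble(chrom = character(), start_bp = numeric(),
                   end_bp = numeric(), kind = character(),
                   mean_log2_ratio = numeric(), size_bp = numeric()),
            class = c("cnv_calls", class(tibble())))
}

#' Write calls as BED
#'
#' Three coordinate columns plus name (`gain`/`loss`) and the mean log2
#' ratio as score.
#'
#' @param calls A `cnv_calls` tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  df <- data.frame(calls$chrom, format(calls$start_bp, scientific = FALSE,
                                       trim = TRUE),
                   format(calls$end_bp, scientific = FALSE, trim = TRUE),
                   calls$kind, sprintf("%.4f", calls$mean_log2_ratio))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
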