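# End-to-end orchestration: counts -> GC correction -> control
# normalization -> QC gate -> CBS -> threshold calling -> karyotype string.

#' Run the full CNV-detection pipeline
#'
#' Takes per-window counts for a sample and a matched control (tibbles from
#' [count_reads()], [read_counts()] or [simulate_counts()]), GC-corrects
#' both, normalizes, applies the QC gate (MAPD at the QC window size and
#' coverage uniformity), segments by CBS, calls CNVs, and renders the
#' karyotype string. When QC fails and `force = FALSE` the pipeline stops
#' after QC and returns a result with `qc_fail = TRUE` and no calls.
#'
#' @param sample,control `window_counts` on `grid`.
#' @param grid Annotated `window_grid`.
#' @param sex Declared sample sex for karyotype rendering (control is XX).
#' @param cbs A [cbs_config()].
#' @param calling A [calling_config()]; on a proportionally scaled genome,
#'   scale `min_size_bp` accordingly.
#' @param qc_factor,mapd_max,coverage_min QC gate parameters (defaults:
#'   100-kb MAPD <= 0.4, coverage fraction >= 0.90).
#' @param span GC-correction span.
#' @param bands Optional band table for event labels.
#' @param force Proceed to calling even when QC fails (the report still
#'   records the failure).
#' @return A list of class `cnv_analysis`: `qc` (`qc_report`), `profile`,
#'   `fit` (`cbs_fit` or `NULL`), `calls`, `karyotype`, `qc_fail`,
#'   `thresholds` (the exact gate/calling thresholds used). [glance()]
#'   summarises it in one row.
#' @export
run_cnv_pipeline <- function(sample, control, grid, sex = "XX",
                             cbs = cbs_config(), calling = calling_config(),
                             qc_factor = 5L, mapd_max = 0.4,
                             coverage_min = 0.9, span = 0.3, bands = NULL,
                             force = FALSE) {
  qc <- qc_report(sample, control, grid, qc_factor = qc_factor,
                  mapd_max = mapd_max, coverage_min = coverage_min,
                  span = span)
  qc_fail <- !(qc$qc_pass_mapd && qc$qc_pass_coverage)

  profile <- normalize_to_control(gc_correct(sample, grid, span = span),
                                  gc_correct(control, grid, span = span),
                                  grid)
  thresholds <- list(loss_log2 = calling$loss_log2,
                     gain_log2 = calling$gain_log2,
                     min_size_bp = calling$min_size_bp,
                     mapd_max = mapd_max, coverage_min = coverage_min)

  if (qc_fail && !force) {
    return(structure(list(qc = qc, profile = profile, fit = NULL,
                          calls = empty_calls(), karyotype = NA_character_,
                          qc_fail = TRUE, thresholds = thresholds,
                          sex = sex),
                     class = "cnv_analysis"))
  }

  fit <- segment_cbs(profile, cbs)
  calls <- call_cnvs(fit, calling)
  chrom_lengths <- tapply(grid$end, grid$chrom, max)
  karyotype <- render_karyotype(calls, sex = sex,
                                chrom_lengths = chrom_lengths,
                                bands = bands,
                                whole_chrom_fraction =
                                  calling$whole_chrom_fraction)
  structure(list(qc = qc, profile = profile, fit = fit, calls = calls,
                 karyotype = karyotype, qc_fail = qc_fail,
                 thresholds = thresholds, sex = sex),
            class = "cnv_analysis")
}

#' @export
print.cnv_analysis <- function(x, ...) {
  cat("# cnv_analysis\n")
  print(x$qc)
  if (x$qc_fail && is.null(x$fit)) {
    cat("  QC failed; no calls made (use force = TRUE to override).\n")
  } else {
    cat(sprintf("  karyotype: %s\n", x$karyotype))
    if (nrow(x$calls)) print(x$calls) else cat("  no CNV calls.\n")
  }
  invisible(x)
}

#' @rdname run_cnv_pipeline
#' @param x A `cnv_analysis`.
#' @param ... Unused.
#' @export
glance.cnv_analysis <- function(x, ...) {
  tibble(karyotype = x$karyotype,
         n_calls = nrow(x$calls),
         qc_fail = x$qc_fail,
         mapd_qc = x$qc$mapd_qc,
         coverage_fraction = x$qc$coverage_fraction_at_20pct,
         n_segments = if (is.null(x$fit)) NA_integer_ else nrow(x$fit$segments))
}

#' Genome-wide copy-number plot
#'
#' Scatter of per-window log2 normalized ratios along the genome,
#' chromosomes in alternating colours, with segment means overlaid and the
#' gain/loss calling thresholds as dashed lines. Chromosome Y is excluded
#' by default.
#'
#' @param profile A `normalized_profile`.
#' @param segments Optional `cbs_fit` or segment tibble to overlay.
#' @param thresholds Optional numeric `c(loss, gain)` log2 thresholds to
#'   draw (default the standard -0.51 / 0.37).
#' @param exclude_y Drop chrY windows.
#' @return A ggplot object.
#' @export
plot_genome <- function(profile, segments = NULL,
                        thresholds = c(-0.51, 0.37), exclude_y = TRUE) {
  df <- as_tibble(profile) %>% filter(!.data$mask)
  if (exclude_y) df <- df %>% filter(!is_chry(.data$chrom))
  chroms <- unique(df$chrom)
  offs <- setNames(cumsum(c(0, head(tapply(df$end, factor(df$chrom, chroms),
                                           max), -1))), chroms)
  df <- df %>%
    mutate(pos = (.data$start + .data$end) / 2 + offs[.data$chrom],
           col = factor(match(.data$chrom, chroms) %% 2))

  p <- ggplot(df, aes(x = .data$pos, y = .data$log2_ratio)) +
    geom_point(aes(colour = .data$col), size = 0.3, alpha = 0.6,
               show.legend = FALSE) +
    scale_colour_manual(values = c("grey35", "steelblue")) +
    geom_hline(yintercept = thresholds, linetype = "dashed",
               colour = "firebrick", linewidth = 0.3) +
    labs(x = NULL, y = "log2 normalized ratio") +
    scale_x_continuous(breaks = offs + tapply(df$end, factor(df$chrom,
                                                             chroms),
                                              max) / 2,
                       labels = chrom_core(chroms)) +
    theme_minimal() +
    theme(panel.grid.minor = element_blank(),
          axis.text.x = element_text(size = 6))

  if (!is.null(segments)) {
    segs <- if (inherits(segments, "cbs_fit")) segments$segments else segments
    if (exclude_y) segs <- segs[!is_chry(segs$chrom), ]
    segs <- segs[segs$chrom %in% chroms, ]
    if (nrow(segs)) {
      segs$x0 <- segs$start_bp + offs[segs$chrom]
      segs$x1 <- segs$end_bp + offs[segs$chrom]
      p <- p + geom_segment(data = segs,
                            aes(x = .data$x0, xend = .data$x1,
                                y = .data$mean_log2_ratio,
                                yend = .data$mean_log2_ratio),
                            colour = "orange", linewidth = 0.9)
    }
  }
  p
}

#' @rdname segment_cbs
#' @param object A `cbs_fit`.
#' @export
autoplot.cbs_fit <- function(object, ...) {
  plot_genome(object$profile, object)
}

#' @rdname run_cnv_pipeline
#' @param object A `cnv_analysis`.
#' @export
autoplot.cnv_analysis <- function(object, ...) {
  plot_genome(object$profile, object$fit,
              thresholds = c(object$thresholds$loss_log2,
                             object$thresholds$gain_log2))
}
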