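seg_row <- function(chrom, start_bp, end_bp, mean, n = 50L) {
  tibble::tibble(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 start_window = 1L, end_window = n, n_windows = n,
                 mean_log2_ratio = mean)
}

test_that("calling thresholds are strict and direction-correct", {
  # +0.40 over 5 Mbp: gain
  calls <- call_cnvs(seg_row("chr1", 0, 5e6, 0.40))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "gain")
  expect_equal(calls$size_bp, 5e6)
  # +0.30 over 5 Mbp: below the gain threshold, no call
  expect_equal(nrow(call_cnvs(seg_row("chr1", 0, 5e6, 0.30))), 0L)
  # -0.90 over 3.5 Mbp: passes the ratio threshold but fails the size filter
  expect_equal(nrow(call_cnvs(seg_row("chr1", 0, 3.5e6, -0.90))), 0L)
  # -0.60 over 6 Mbp: loss
  calls2 <- call_cnvs(seg_row("chr2", 1e6, 7e6, -0.60))
  expect_equal(calls2$kind, "loss")
  # boundary values are strict: exactly 0.37 / -0.51 never call
  expect_equal(nrow(call_cnvs(seg_row("chr1", 0, 5e6, 0.37))), 0L)
  expect_equal(nrow(call_cnvs(seg_row("chr1", 0, 5e6, -0.51))), 0L)
  # exactly min_size_bp is strict too
  expect_equal(nrow(call_cnvs(seg_row("chr1", 0, 4e6, 0.5))), 0L)
})

test_that("adjacent same-direction passing segments merge before sizing", {
  # two 2.5-Mbp gain segments, each below the 4-Mbp size filter alone
  segs <- dplyr::bind_rows(seg_row("chr3", 0, 2.5e6, 0.45, n = 25L),
                           seg_row("chr3", 2.5e6, 5e6, 0.55, n = 25L))
  calls <- call_cnvs(segs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start_bp, 0)
  expect_equal(calls$end_bp, 5e6)
  expect_equal(calls$mean_log2_ratio, 0.5)   # window-weighted mean
  # a non-passing segment in between blocks the merge
  segs2 <- dplyr::bind_rows(seg_row("chr3", 0, 2.5e6, 0.45),
                            seg_row("chr3", 2.5e6, 3e6, 0.0),
                            seg_row("chr3", 3e6, 5.5e6, 0.55))
  expect_equal(nrow(call_cnvs(segs2)), 0L)
  # opposite directions never merge
  segs3 <- dplyr::bind_rows(seg_row("chr3", 0, 2.5e6, 0.45),
                            seg_row("chr3", 2.5e6, 5e6, -0.8))
  expect_equal(nrow(call_cnvs(segs3)), 0L)
})

test_that("calls are monotone in the thresholds", {
  segs <- dplyr::bind_rows(seg_row("chr1", 0, 6e6, 0.40),
                           seg_row("chr2", 0, 6e6, 0.70),
                           seg_row("chr5", 0, 6e6, -0.55),
                           seg_row("chr7", 0, 5e6, -1.2))
  stricter <- call_cnvs(segs, calling_config(loss_log2 = -1.0,
                                             gain_log2 = 0.58))
  looser <- call_cnvs(segs, calling_config(loss_log2 = -0.51,
                                           gain_log2 = 0.37))
  expect_true(all(stricter$chrom %in% looser$chrom))
  expect_equal(nrow(stricter), 2L)
  expect_equal(nrow(looser), 4L)
})

test_that("chrY segments are excluded by default", {
  segs <- seg_row("chrY", 0, 5e6, -2)
  expect_equal(nrow(call_cnvs(segs)), 0L)
  expect_equal(nrow(call_cnvs(segs, exclude_y = FALSE)), 1L)
})

test_that("render_karyotype produces the standard strings", {
  len <- study_lengths()
  bands <- study_bands()
  gain21 <- tibble::tibble(chrom = "chr21", start_bp = 0,
                           end_bp = len[["chr21"]], kind = "gain",
                           mean_log2_ratio = 0.55,
                           size_bp = len[["chr21"]])
  expect_equal(render_karyotype(gain21, "XX", len, bands), "47,XX,+21")
  expect_equal(render_karyotype(gain21[0, ], "XX", len, bands), "46,XX")
  expect_equal(render_karyotype(gain21[0, ], "XY", len, bands), "46,XY")

  xo <- tibble::tibble(chrom = "chrX", start_bp = 0, end_bp = len[["chrX"]],
                       kind = "loss", mean_log2_ratio = -0.9,
                       size_bp = len[["chrX"]])
  expect_equal(render_karyotype(xo, "XX", len, bands), "45,XO")
  # against an XX control a male sample shows a whole-chrX loss: absorbed
  # into the XY sex token, not reported as an event
  expect_equal(render_karyotype(xo, "XY", len, bands), "46,XY")

  iv1 <- resolve_band_interval("4p16.3-p16.2", bands, "chr")
  iv2 <- resolve_band_interval("12p13.33-p12.1", bands, "chr")
  part <- tibble::tibble(
    chrom = c("chr12", "chr4"),
    start_bp = c(iv2$start, iv1$start), end_bp = c(iv2$end, iv1$end),
    kind = c("gain", "loss"), mean_log2_ratio = c(0.5, -0.9),
    size_bp = c(iv2$end - iv2$start, iv1$end - iv1$start))
  expect_equal(render_karyotype(part, "XY", len, bands),
               "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)")
  # without a band table, Mb labels are used
  expect_match(render_karyotype(part[1, ], "XY", len),
               "46,XY,dup\\(12:.*Mb\\)")
})

test_that("parse_karyotype inverts render_karyotype", {
  len <- study_lengths()
  bands <- study_bands()
  ev <- parse_karyotype("47,XX,+21", len, bands)
  expect_equal(ev$chrom, "chr21")
  expect_equal(ev$kind, "gain")
  expect_true(ev$whole)
  expect_equal(attr(ev, "sex"), "XX")

  ev2 <- parse_karyotype("45,XO", len, bands)
  expect_equal(ev2$chrom, "chrX")
  expect_equal(ev2$kind, "loss")
  expect_equal(attr(ev2, "sex"), "XO")

  ev3 <- parse_karyotype("46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)",
                         len, bands)
  expect_equal(ev3$kind, c("loss", "gain"))
  iv <- resolve_band_interval("4p16.3-p16.2", bands, "chr")
  expect_equal(ev3$start_bp[1], iv$start)
  expect_equal(ev3$end_bp[1], iv$end)

  expect_equal(nrow(parse_karyotype(NA, len, bands)), 0L)
  expect_equal(nrow(parse_karyotype("46,XX", len, bands)), 0L)
  # unicode minus from printed tables
  ev4 <- parse_karyotype("+21,−22", len, bands)
  expect_equal(ev4$kind, c("gain", "loss"))
  expect_error(parse_karyotype("47,XX,+99", len, bands), "unknown chromosome")

  # the renderer's coordinate fallback (no band coverage) round-trips too
  ev5 <- parse_karyotype("46,XY,dup(10:25.8-27.2Mb)", len, bands)
  expect_equal(ev5$chrom, "chr10")
  expect_equal(ev5$start_bp, 25.8e6)
  expect_equal(ev5$end_bp, 27.2e6)
  expect_equal(ev5$kind, "gain")

  # full round trip through the renderer
  for (s in c("47,XX,+21", "45,XO",
              "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)")) {
    ev <- parse_karyotype(s, len, bands)
    calls <- tibble::tibble(chrom = ev$chrom, start_bp = ev$start_bp,
                            end_bp = ev$end_bp, kind = ev$kind,
                            mean_log2_ratio = ifelse(ev$kind == "gain",
                                                     0.58, -1),
                            size_bp = ev$end_bp - ev$start_bp)
    sex <- switch(attr(ev, "sex"), XO = "XX", attr(ev, "sex"))
    expect_equal(render_karyotype(calls, sex, len, bands), s)
  }
})

test_that("concordance fragmentation matching unions split calls", {
  len <- study_lengths()
  bands <- study_bands()
  # a trisomy 21 detected as two dup segments with a small gap between them
  frag <- tibble::tibble(
    chrom = "chr21", kind = "gain",
    start_bp = c(0, 0.55 * len[["chr21"]]),
    end_bp = c(0.5 * len[["chr21"]], len[["chr21"]]))
  # default matching: neither call alone covers 80% -> 2 FP + 1 FN
  strict <- concordance(frag, "47,XX,+21", len, bands)
  expect_equal(strict$n_false_positive, 2L)
  expect_equal(strict$n_false_negative, 1L)
  # fragmentation-tolerant: the union covers 95% -> recovered, no FP
  loose <- concordance(frag, "47,XX,+21", len, bands,
                       allow_fragmentation = TRUE)
  expect_equal(loose, tibble::tibble(n_true_positive = 1L,
                                     n_false_positive = 0L,
                                     n_false_negative = 0L))
  # a call matching no confirmed event stays a false positive
  frag2 <- dplyr::bind_rows(frag, tibble::tibble(
    chrom = "chr4", kind = "gain", start_bp = 0, end_bp = 2e6))
  loose2 <- concordance(frag2, "47,XX,+21", len, bands,
                        allow_fragmentation = TRUE)
  expect_equal(loose2$n_false_positive, 1L)
  # a union that covers too little of the event still fails to match
  sparse <- tibble::tibble(
    chrom = "chr21", kind = "gain",
    start_bp = c(0, 0.9 * len[["chr21"]]),
    end_bp = c(0.3 * len[["chr21"]], len[["chr21"]]))
  got <- concordance(sparse, "47,XX,+21", len, bands,
                     allow_fragmentation = TRUE)
  expect_equal(got$n_true_positive, 0L)
  expect_equal(got$n_false_positive, 2L)
})

test_that("concordance scores identity and the hand-worked MDA case", {
  len <- study_lengths()
  bands <- study_bands()
  s <- "46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)"
  expect_equal(concordance(s, s, len, bands),
               tibble::tibble(n_true_positive = 2L, n_false_positive = 0L,
                              n_false_negative = 0L))
  # MDA on the 45,XO line reported "+21,-22": nothing matches
  got <- concordance("+21,-22", "45,XO", len, bands)
  expect_equal(got$n_true_positive, 0L)
  expect_equal(got$n_false_positive, 2L)
  expect_equal(got$n_false_negative, 1L)
  # empty vs empty
  expect_equal(concordance("46,XX", "46,XX", len, bands)$n_false_positive, 0L)
  # direction must match: a deletion does not confirm a duplication
  got2 <- concordance("dup(16p12.1-p11.2)", "46,XX,del(16p12.1-p11.2)",
                      len, bands)
  expect_equal(got2$n_true_positive, 0L)
})

test_that("the validation table reproduces the per-kit concordance totals", {
  len <- study_lengths()
  bands <- study_bands()
  tab <- validation_call_table()
  totals <- function(kit) {
    rows <- lapply(seq_len(nrow(tab)), function(i)
      concordance(tab[[kit]][i], tab$confirmed[i], len, bands))
    dplyr::summarise_all(dplyr::bind_rows(rows), sum)
  }
  # MALBAC and PicoPLEX: every confirmed event recovered, no false calls
  for (kit in c("MALBAC", "PicoPLEX")) {
    t <- totals(kit)
    expect_equal(t$n_true_positive, 7L)
    expect_equal(t$n_false_positive, 0L)
    expect_equal(t$n_false_negative, 0L)
  }
  # GenomePlex: all events recovered plus exactly two false positives
  tg <- totals("GenomePlex")
  expect_equal(tg$n_true_positive, 7L)
  expect_equal(tg$n_false_positive, 2L)
  expect_equal(tg$n_false_negative, 0L)
  # MDA: no confirmed event recovered anywhere
  tm <- totals("MDA")
  expect_equal(tm$n_true_positive, 0L)
  expect_equal(tm$n_false_positive, 3L)
  expect_equal(tm$n_false_negative, 7L)
})

test_that("write_calls_bed emits plain BED", {
  calls <- call_cnvs(seg_row("chr1", 0, 5e6, 0.40))
  path <- tempfile(fileext = ".bed")
  write_calls_bed(calls, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1L)
  expect_match(lines, "^chr1\t0\t5000000\tgain\t0\\.4000$")
})
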