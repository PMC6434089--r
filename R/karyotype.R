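# Karyotype-style reporting of CNV calls and concordance scoring against
# confirmed karyotypes.
#
# The rendered string is a simplified ISCN dialect: modal autosome count,
# sex designation, then whole-chromosome events as +N / -N and partial
# events as del(...) / dup(...) with cytogenetic band labels when a band
# table is available (Mb coordinates otherwise). Calls are interpreted
# relative to the control's sex: against the default XX control a male
# sample shows a whole-chrX loss, which the renderer absorbs into the XY sex
# designation rather than reporting as an event; a whole-chrX loss in a
# declared-female sample renders as XO.

#' Read a cytogenetic band table (UCSC cytoBand format)
#'
#' Five tab-separated columns: chrom, start, end, band, stain. `scale`
#' shrinks the coordinates proportionally for use with a scaled simulation
#' genome.
#'
#' @param path File path; default is the bundled synthetic approximation of
#'   the hg19 ideogram (see [cytoband_synthetic()]).
#' @param scale Coordinate scaling factor.
#' @return A tibble `chrom`, `start`, `end`, `band`, `stain`.
#' @export
read_cytoband <- function(path = cytoband_synthetic(), scale = 1) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "band", "stain"),
                   stringsAsFactors = FALSE)
  df$start <- df$start * scale
  df$end <- df$end * scale
  as_tibble(df)
}

#' Path to the bundled synthetic cytogenetic band table
#'
#' A synthetic approximation of the hg19 ideogram (band boundaries are
#' plausible but not the reference UCSC coordinates) covering the
#' chromosomes used by the bundled cell-line fixtures. Fixture event
#' coordinates and band-label rendering both derive from this same table,
#' so labels round-trip exactly.
#'
#' @return File path of the table.
#' @export
cytoband_synthetic <- function() {
  system.file("extdata", "cytoband_synthetic.txt", package = "wgacnv",
              mustWork = TRUE)
}

# Label for the band containing position `pos` on `chrom`.
band_at <- function(bands, chrom, pos) {
  b <- bands[bands$chrom == chrom & bands$start <= pos & pos < bands$end, ]
  if (!nrow(b)) {
    b <- bands[bands$chrom == chrom, ]
    if (!nrow(b)) return(NA_character_)
    return(b$band[which.min(pmax(b$start - pos, pos - b$end, 0))])
  }
  b$band[1]
}

# "16p12.1-p11.2"-style label of an interval (single-band intervals collapse
# to one band).
interval_band_label <- function(chrom, start, end, bands) {
  core <- chrom_core(chrom)
  b1 <- band_at(bands, chrom, start)
  b2 <- band_at(bands, chrom, max(start, end - 1))
  if (is.na(b1) || is.na(b2)) return(NA_character_)
  if (b1 == b2) paste0(core, b1) else paste0(core, b1, "-", b2)
}

#' Render CNV calls as a karyotype-style string
#'
#' @param calls A `cnv_calls` tibble.
#' @param sex Declared sex of the sample, `"XX"` or `"XY"` (the control is
#'   assumed XX; see Details in the package vignette).
#' @param chrom_lengths Named vector of chromosome lengths on the calling
#'   genome.
#' @param bands Optional band table ([read_cytoband()], scaled to the same
#'   genome); without it partial events are labelled with Mb coordinates.
#' @param whole_chrom_fraction Coverage fraction above which a call counts
#'   as a whole-chromosome event.
#' @return A single string such as `"47,XX,+21"` or
#'   `"46,XY,del(4p16.3-p16.2),dup(12p13.33-p12.1)"`.
#' @export
render_karyotype <- function(calls, sex = c("XX", "XY"), chrom_lengths,
                             bands = NULL, whole_chrom_fraction = 0.8) {
  sex <- match.arg(sex)
  if (nrow(calls)) {
    missing <- setdiff(unique(calls$chrom), names(chrom_lengths))
    if (length(missing))
      abort(paste0("no chromosome length for: ",
                   paste(missing, collapse = ", ")))
  }
  cov <- if (nrow(calls))
    (calls$end_bp - calls$start_bp) / chrom_lengths[calls$chrom] else numeric(0)
  whole <- cov >= whole_chrom_fraction

  x_lost <- any(whole & is_chrx(calls$chrom) & calls$kind == "loss")
  auto_whole <- calls[whole & is_autosome(calls$chrom), , drop = FALSE]
  partial <- calls[!whole, , drop = FALSE]

  modal <- 46L + sum(auto_whole$kind == "gain") -
    sum(auto_whole$kind == "loss") - as.integer(sex == "XX" && x_lost)
  sex_token <- if (sex == "XY") "XY" else if (x_lost) "XO" else "XX"

  tokens <- character(0)
  if (nrow(auto_whole)) {
    ord <- order(chrom_rank(auto_whole$chrom))
    tokens <- c(tokens, paste0(ifelse(auto_whole$kind[ord] == "gain",
                                      "+", "-"),
                               chrom_core(auto_whole$chrom[ord])))
  }
  if (nrow(partial)) {
    ord <- order(chrom_rank(partial$chrom), partial$start_bp)
    lab <- vapply(seq_len(nrow(partial)), function(k) {
      i <- ord[k]
      bl <- if (!is.null(bands))
        interval_band_label(partial$chrom[i], partial$start_bp[i],
                            partial$end_bp[i], bands) else NA_character_
      if (is.na(bl))
        bl <- sprintf("%s:%.1f-%.1fMb", chrom_core(partial$chrom[i]),
                      partial$start_bp[i] / 1e6, partial$end_bp[i] / 1e6)
      paste0(ifelse(partial$kind[i] == "loss", "del(", "dup("), bl, ")")
    }, character(1))
    tokens <- c(tokens, lab)
  }
  if (sex_token == "XO")
    return(paste(c(sprintf("%d,XO", modal), tokens), collapse = ","))
  paste(c(sprintf("%d,%s", modal, sex_token), tokens), collapse = ",")
}

chrom_rank <- function(chrom) {
  core <- chrom_core(chrom)
  r <- suppressWarnings(as.integer(core))
  r[core == "X"] <- 23L
  r[core == "Y"] <- 24L
  r
}

#' Parse a karyotype-style string into an event table
#'
#' Understands the simplified dialect [render_karyotype()] emits (and the
#' equivalent reporting style of clinical CNV summaries): an optional modal
#' number, a sex token (`XX`/`XY`/`XO`), whole-chromosome events `+N` / `-N`,
#' and partial events `del(16p12.1-p11.2)` / `dup(12p13.33-p12.1)` whose
#' coordinates are resolved from a band table. The renderer's coordinate
#' fallback (`dup(10:25.8-27.2Mb)`, emitted when the band table does not
#' cover a chromosome) round-trips too. `XO` is returned as a
#' whole-chrX loss event (relative to an XX control).
#'
#' @param string Karyotype string. `NA` or `"NA"` yields zero events.
#' @param chrom_lengths Named chromosome lengths of the target genome.
#' @param bands Band table on the same genome ([read_cytoband()]).
#' @param chrom_prefix Prefix of chromosome names in `chrom_lengths`
#'   (`"chr"` or `""`), detected automatically by default.
#' @return A tibble `chrom`, `start_bp`, `end_bp`, `kind`, `whole` (plus
#'   attribute `sex` when a sex token is present).
#' @export
parse_karyotype <- function(string, chrom_lengths,
                            bands = read_cytoband(), chrom_prefix = NULL) {
  if (is.null(chrom_prefix))
    chrom_prefix <- if (any(startsWith(names(chrom_lengths), "chr")))
      "chr" else ""
  empty <- tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), kind = character(), whole = logical())
  if (is.na(string) || toupper(trimws(string)) == "NA") return(empty)
  s <- gsub("\u2212", "-", string)  # printed minus sign
  tokens <- trimws(strsplit(s, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]

  rows <- list()
  sex <- NA_character_
  for (tk in tokens) {
    if (grepl("^[0-9]+$", tk)) next
    up <- toupper(tk)
    if (up %in% c("XX", "XY")) { sex <- up; next }
    if (up %in% c("XO", "X0")) {
      sex <- "XO"
      chrom <- paste0(chrom_prefix, "X")
      rows[[length(rows) + 1L]] <- tibble(chrom = chrom, start_bp = 0,
                                          end_bp = chrom_lengths[[chrom]],
                                          kind = "loss", whole = TRUE)
      next
    }
    if (grepl("^[+-]", tk)) {
      core <- sub("^[+-]", "", tk)
      chrom <- paste0(chrom_prefix, core)
      if (!chrom %in% names(chrom_lengths))
        abort(paste0("unknown chromosome in karyotype token: ", tk))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, start_bp = 0, end_bp = chrom_lengths[[chrom]],
        kind = if (startsWith(tk, "+")) "gain" else "loss", whole = TRUE)
      next
    }
    m <- stringr::str_match(tk, "^(del|dup)\\((.+)\\)$")
    if (!is.na(m[1, 1])) {
      iv <- resolve_band_interval(m[1, 3], bands, chrom_prefix)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = iv$chrom, start_bp = iv$start, end_bp = iv$end,
        kind = if (m[1, 2] == "del") "loss" else "gain", whole = FALSE)
      next
    }
    abort(paste0("cannot parse karyotype token: ", tk))
  }
  out <- if (length(rows)) bind_rows(rows) else empty
  attr(out, "sex") <- sex
  out
}

# "16p12.1-p11.2" or "16p11.2" -> chrom + union interval of the named bands.
# Also accepts the renderer's coordinate fallback "10:25.8-27.2Mb", used
# when the band table does not cover the call's chromosome.
resolve_band_interval <- function(label, bands, chrom_prefix) {
  mc <- stringr::str_match(
    label, "^([0-9]+|X|Y):([0-9.]+)-([0-9.]+)Mb$")
  if (!is.na(mc[1, 1]))
    return(list(chrom = paste0(chrom_prefix, mc[1, 2]),
                start = as.numeric(mc[1, 3]) * 1e6,
                end = as.numeric(mc[1, 4]) * 1e6))
  m <- stringr::str_match(label, "^([0-9]+|X|Y)([pq][0-9.]*)(?:-([pq][0-9.]*))?$")
  if (is.na(m[1, 1])) abort(paste0("cannot parse band interval: ", label))
  chrom <- paste0(chrom_prefix, m[1, 2])
  b1 <- band_rows(bands, chrom, m[1, 3])
  b2 <- if (!is.na(m[1, 4])) band_rows(bands, chrom, m[1, 4]) else b1
  list(chrom = chrom, start = min(b1$start, b2$start),
       end = max(b1$end, b2$end))
}

band_rows <- function(bands, chrom, band) {
  core <- sub("^chr", "", chrom)
  b <- bands[sub("^chr", "", bands$chrom) == core &
               (bands$band == band |
                  startsWith(bands$band, paste0(band, "."))), ]
  if (!nrow(b)) abort(paste0("band not in table: ", chrom, band))
  b
}

#' Score detected CNV calls against a confirmed event set
#'
#' A detected call matches a confirmed event when both have the same
#' direction and either (a) the confirmed event is whole-chromosome and the
#' call covers at least `whole_chrom_fraction` of that chromosome, or (b)
#' their reciprocal overlap reaches `reciprocal_overlap`. Matching is
#' greedy, one detected call per confirmed event. Unmatched detected calls
#' are false positives; unmatched confirmed events false negatives.
#'
#' With `allow_fragmentation = TRUE` a confirmed event may instead be
#' matched by the *union* of several same-direction calls: every candidate
#' call must individually overlap the event by at least
#' `reciprocal_overlap` of the call's own length, and their summed overlap
#' must reach the same coverage threshold a single call would need
#' (`whole_chrom_fraction` of a whole-chromosome event,
#' `reciprocal_overlap` of a partial one). Fragments of an event matched by
#' another call (for example the residual dup segments flanking a
#' whole-chromosome call of the same trisomy) are absorbed by that match
#' instead of counting as extra false positives. This is the usual
#' fragmentation-tolerant matching of CNV benchmarks: segmentation may
#' split one biological event into adjacent calls without that counting as
#' both false positives and a false negative. Calls matching no event are
#' false positives either way.
#'
#' @param detected `cnv_calls` tibble, a [parse_karyotype()] event table, or
#'   a karyotype string.
#' @param confirmed A [parse_karyotype()] event table, karyotype string, or
#'   [karyotype_spec()].
#' @param chrom_lengths Named chromosome lengths.
#' @param bands Band table used when either side is given as a string.
#' @param reciprocal_overlap Minimum reciprocal overlap for partial events.
#' @param whole_chrom_fraction Coverage defining a whole-chromosome call.
#' @param allow_fragmentation Let several same-direction calls jointly match
#'   one confirmed event (see Details). Default `FALSE`.
#' @return A one-row tibble: `n_true_positive`, `n_false_positive`,
#'   `n_false_negative`.
#' @export
concordance <- function(detected, confirmed, chrom_lengths,
                        bands = read_cytoband(), reciprocal_overlap = 0.5,
                        whole_chrom_fraction = 0.8,
                        allow_fragmentation = FALSE) {
  det <- as_event_table(detected, chrom_lengths, bands, whole_chrom_fraction)
  conf <- as_event_table(confirmed, chrom_lengths, bands,
                         whole_chrom_fraction)

  used <- rep(FALSE, nrow(det))
  tp <- 0L
  if (nrow(conf)) for (i in seq_len(nrow(conf))) {
    cand <- which(!used & det$kind == conf$kind[i] &
                    chrom_core(det$chrom) == chrom_core(conf$chrom[i]))
    hit <- NA_integer_
    for (j in cand) {
      ok <- if (conf$whole[i]) {
        det$whole[j] ||
          (det$end_bp[j] - det$start_bp[j]) >=
            whole_chrom_fraction * (conf$end_bp[i] - conf$start_bp[i])
      } else {
        ov <- min(det$end_bp[j], conf$end_bp[i]) -
          max(det$start_bp[j], conf$start_bp[i])
        ov > 0 &&
          ov >= reciprocal_overlap * (det$end_bp[j] - det$start_bp[j]) &&
          ov >= reciprocal_overlap * (conf$end_bp[i] - conf$start_bp[i])
      }
      if (ok) { hit <- j; break }
    }
    frag <- integer(0)
    if (allow_fragmentation && length(cand)) {
      # calls mostly (reciprocal_overlap of their own length) inside the
      # event are treated as fragments of it
      ov <- pmin(det$end_bp[cand], conf$end_bp[i]) -
        pmax(det$start_bp[cand], conf$start_bp[i])
      frag <- cand[ov > 0 &
                     ov >= reciprocal_overlap *
                       (det$end_bp[cand] - det$start_bp[cand])]
    }
    if (!is.na(hit)) {
      # co-fragments of a matched event are absorbed by it rather than
      # counted as extra false positives
      used[c(hit, frag)] <- TRUE
      tp <- tp + 1L
      next
    }
    if (allow_fragmentation) {
      keep <- frag
      if (length(keep) >= 2L) {
        # coverage of the union (clipped intervals may share a band edge)
        a <- pmax(det$start_bp[keep], conf$start_bp[i])
        b <- pmin(det$end_bp[keep], conf$end_bp[i])
        o <- order(a)
        covered <- 0
        hi <- -Inf
        for (k in o) {
          covered <- covered + max(0, b[k] - max(a[k], hi))
          hi <- max(hi, b[k])
        }
        need <- (if (conf$whole[i]) whole_chrom_fraction else
          reciprocal_overlap) * (conf$end_bp[i] - conf$start_bp[i])
        if (covered >= need) { used[keep] <- TRUE; tp <- tp + 1L }
      }
    }
  }
  tibble(n_true_positive = tp,
         n_false_positive = nrow(det) - sum(used),
         n_false_negative = nrow(conf) - tp)
}

as_event_table <- function(x, chrom_lengths, bands, whole_chrom_fraction) {
  if (is.character(x) && length(x) == 1)
    return(parse_karyotype(x, chrom_lengths, bands))
  if (inherits(x, "karyotype_spec")) return(spec_events(x, chrom_lengths))
  df <- as_tibble(x)
  if (!"whole" %in% names(df))
    df$whole <- (df$end_bp - df$start_bp) >=
      whole_chrom_fraction * chrom_lengths[df$chrom]
  df[, c("chrom", "start_bp", "end_bp", "kind", "whole")]
}
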