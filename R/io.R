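# Plain-text (TSV) serialization of grids, count tables, normalized profiles
# and segment tables. Every file starts with '#key=value' metadata lines; the
# count reader refuses tables whose grid checksum does not match the grid it
# is asked to align to.

write_meta_tsv <- function(df, path, meta, digits = 10) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
  })
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_meta_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  df <- read.delim(text = body, sep = "\t", stringsAsFactors = FALSE)
  list(meta = meta, data = as_tibble(df))
}

#' Serialize / restore a window grid as TSV
#'
#' Six data columns (`chrom`, `start`, `end`, `gc`, `n_fraction`, `usable`)
#' preceded by `#`-prefixed metadata (window size, genome id, checksum).
#'
#' @param grid A `window_grid`.
#' @param path Output/input file path.
#' @return `write_grid()` the path, invisibly; `read_grid()` the grid.
#' @export
write_grid <- function(grid, path) {
  meta <- list(window_size = grid_window_size(grid),
               genome_id = attr(grid, "genome_id"),
               checksum = grid_checksum(grid))
  df <- as_tibble(grid)
  df$usable <- as.integer(df$usable)
  write_meta_tsv(df, path, meta)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  r <- read_meta_tsv(path)
  df <- r$data
  df$usable <- as.logical(df$usable)
  g <- new_window_grid(df, window_size = as.integer(r$meta$window_size),
                       genome_id = r$meta$genome_id)
  if (!is.null(r$meta$checksum) && grid_checksum(g) != r$meta$checksum)
    abort("grid checksum mismatch: file does not match its recorded checksum.")
  g
}

#' Serialize / restore a per-window count table as TSV
#'
#' Columns `chrom`, `start`, `end`, `count` with metadata header recording
#' sample id, kit, sample type, total filtered reads and the checksum of the
#' grid the counts are aligned to. `read_counts()` refuses a file whose grid
#' checksum differs from `grid` — counts must never be silently re-interpreted
#' on a different grid.
#'
#' @param wc A `window_counts`.
#' @param path File path.
#' @param grid The `window_grid` to validate against on read.
#' @return `write_counts()` the path, invisibly; `read_counts()` the counts.
#' @export
write_counts <- function(wc, path) {
  meta <- list(sample_id = attr(wc, "sample_id"), kit = attr(wc, "kit"),
               sample_type = attr(wc, "sample_type"),
               total_filtered_reads = attr(wc, "total_filtered_reads"),
               grid_checksum = attr(wc, "grid_checksum"))
  write_meta_tsv(as_tibble(wc), path, meta)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, grid) {
  r <- read_meta_tsv(path)
  if (!identical(r$meta$grid_checksum, grid_checksum(grid)))
    abort("grid checksum mismatch: counts were produced on a different grid.")
  out <- new_window_counts(r$data$count, grid,
                           sample_id = r$meta$sample_id,
                           kit = r$meta$kit,
                           sample_type = r$meta$sample_type,
                           total_filtered_reads =
                             as.numeric(r$meta$total_filtered_reads))
  out
}

#' Serialize a normalized profile / segment table as TSV
#'
#' @param profile A `normalized_profile`; `segments` a segment tibble from
#'   [segment_cbs()].
#' @param path File path.
#' @param segments Segment tibble.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  meta <- list(sample_id = attr(profile, "sample_id") %||% "sample",
               grid_checksum = attr(profile, "grid_checksum") %||% "")
  df <- as_tibble(profile)[, c("chrom", "start", "end", "gc", "ratio",
                               "log2_ratio", "mask")]
  df$mask <- as.integer(df$mask)
  write_meta_tsv(df, path, meta)
}

#' @rdname write_profile
#' @export
write_segments <- function(segments, path) {
  meta <- list(seed = attr(segments, "seed") %||% "",
               alpha = attr(segments, "alpha") %||% "")
  write_meta_tsv(as_tibble(segments), path, meta)
}

#' Write read-filter statistics as key=value text
#'
#' @param stats A `filter_stats()` row or the attribute list itself.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_filter_stats <- function(stats, path) {
  stats <- as.list(stats)
  writeLines(sprintf("%s=%s", names(stats), unlist(stats)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
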