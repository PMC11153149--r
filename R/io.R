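# Readers/writers.  Internal coordinates are 0-based half-open everywhere;
# BED/bedGraph files are 0-based half-open, junction-table and catalog TSVs
# carry 1-based positions and are converted on read.  All parsers reject
# malformed input with the offending line number rather than repairing it.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first token of each
#'   FASTA header; sequences restricted to the A/C/G/T/N alphabet.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
  af <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0)) {
    stopf("sequence '%s' contains letters outside A/C/G/T/N",
          names(genome)[which(bad > 0)[1L]])
  }
  genome
}

#' Write a genome FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

JUNCTION_COLS <- c("library_id", "chrom", "junction_pos", "strand",
                   "bait_id", "read_id")

#' Parse a junction-table TSV
#'
#' Project dialect: comment lines `#key=value` carry library metadata
#' (`#germline_reads=<int>` is required), then a tab-separated header line
#' `library_id chrom junction_pos strand bait_id read_id`, then one row per
#' junction.  Positions in the file are 1-based and converted to 0-based
#' internally.
#'
#' @param path TSV file.
#' @return A [junction_library()] with row order preserved.
#' @export
parse_junction_table <- function(path) {
  lines <- readLines(path)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0L) meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
    i <- i + 1L
  }
  if (is.null(meta$germline_reads)) {
    stopf("%s: missing '#germline_reads=<int>' header before line %d", path, i)
  }
  germ <- suppressWarnings(as.integer(meta$germline_reads))
  if (is.na(germ)) stopf("%s: non-integer germline_reads header", path)
  if (i > length(lines)) stopf("%s: missing header line", path)
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  miss <- setdiff(JUNCTION_COLS, header)
  if (length(miss)) {
    stopf("%s line %d: missing column(s) %s", path, i, paste(miss, collapse = ", "))
  }
  body <- lines[-seq_len(i)]
  body_ln <- i + seq_along(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    j <- which(nf != length(header))[1L]
    stopf("%s line %d: expected %d fields, got %d", path, body_ln[j],
          length(header), nf[j])
  }
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE,
              dimnames = list(NULL, header))
  pos <- suppressWarnings(as.integer(m[, "junction_pos"]))
  if (anyNA(pos) && length(body)) {
    j <- which(is.na(pos))[1L]
    stopf("%s line %d: non-integer junction_pos '%s'", path, body_ln[j],
          m[j, "junction_pos"])
  }
  strand <- m[, "strand"]
  if (!all(strand %in% c("+", "-"))) {
    j <- which(!strand %in% c("+", "-"))[1L]
    stopf("%s line %d: strand must be '+' or '-', got '%s'", path, body_ln[j],
          strand[j])
  }
  records <- data.frame(chrom = unname(m[, "chrom"]),
                        junction_pos = pos - 1L,
                        prey_orientation = unname(strand),
                        bait_id = unname(m[, "bait_id"]),
                        read_id = unname(m[, "read_id"]))
  lib_id <- meta$library_id %||%
    (if (length(body)) m[1L, "library_id"] else "library")
  rep_id <- meta$repeat_id %||% NA
  junction_library(records, germ, lib_id, repeat_id = rep_id)
}

#' Write a junction-table TSV
#'
#' Inverse of [parse_junction_table()]: positions are written 1-based.
#' @param lib A [junction_library()].
#' @param path Output file.
#' @export
write_junction_table <- function(lib, path) {
  stopifnot(inherits(lib, "junction_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#germline_reads=%d", lib$germline_read_count),
               sprintf("#library_id=%s", lib$library_id),
               if (!is.na(lib$repeat_id)) sprintf("#repeat_id=%s", lib$repeat_id),
               paste(JUNCTION_COLS, collapse = "\t")), con)
  r <- lib$records
  if (nrow(r)) {
    writeLines(paste(lib$library_id, r$chrom, r$junction_pos + 1L,
                     r$prey_orientation, r$bait_id, r$read_id, sep = "\t"), con)
  }
  invisible(path)
}

#' Write called peaks as BED6 plus a statistics sidecar TSV
#'
#' The BED score is `round(-10 * log10(summit raw P))`, capped at 1000; the
#' sidecar `<path-sans-ext>_stats.tsv` carries the full statistics.
#'
#' @param peaks `data.frame` of peaks sorted by (chrom, start) with columns
#'   `chrom`, `start`, `end`, `summit_pos`, `summit_raw_p`, `summit_adj_p`,
#'   and optionally `name` and `support`.
#' @param path Output BED file.
#' @return Invisibly, the sidecar path.
#' @export
write_peaks_bed <- function(peaks, path) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 1L) {
    o <- order(peaks$chrom, peaks$start)
    if (!identical(o, seq_len(nrow(peaks)))) {
      stopf("peaks must be sorted by (chrom, start) before writing")
    }
  }
  name <- peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  score <- round(-10 * log10(peaks$summit_raw_p))
  score[!is.finite(score) | score > 1000] <- 1000
  score[score < 0] <- 0
  bed <- if (nrow(peaks)) {
    paste(peaks$chrom, peaks$start, peaks$end, name, score, ".", sep = "\t")
  } else character(0)
  writeLines(bed, path)
  stats_path <- paste0(tools::file_path_sans_ext(path), "_stats.tsv")
  sidecar <- data.frame(name = name, chrom = peaks$chrom, start = peaks$start,
                        end = peaks$end, summit_pos = peaks$summit_pos,
                        summit_raw_p = peaks$summit_raw_p,
                        summit_adj_p = peaks$summit_adj_p,
                        support = peaks$support %||% rep(NA_integer_, nrow(peaks)))
  utils::write.table(sidecar, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stats_path)
}

#' Parse a BED file of intervals
#'
#' @param path BED3+ file (0-based half-open).
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
parse_bed <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  lines <- lines[keep]; ln <- which(keep)
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    j <- which(lengths(fields) < 3L)[1L]
    stopf("%s line %d: fewer than 3 BED fields", path, ln[j])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    j <- which(is.na(start) | is.na(end))[1L]
    stopf("%s line %d: non-integer coordinates", path, ln[j])
  }
  if (any(end <= start)) {
    j <- which(end <= start)[1L]
    stopf("%s line %d: end must exceed start", path, ln[j])
  }
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L), start = start, end = end)
  nf <- min(lengths(fields))
  if (nf >= 4L) out$name <- vapply(fields, `[[`, "", 4L)
  if (nf >= 5L) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (nf >= 6L) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals as BED
#' @param df `data.frame` with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  for (nm in c("name", "score", "strand")) {
    if (!is.null(df[[nm]])) cols <- c(cols, list(df[[nm]])) else break
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Construct a step-function signal track
#'
#' @param df `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and numeric `value`; intervals on one chromosome must not overlap.
#'   Uncovered bases have value 0.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(df) {
  df <- as.data.frame(df)[, c("chrom", "start", "end", "value")]
  if (any(df$end <= df$start)) stopf("signal intervals must have end > start")
  if (!is.numeric(df$value) || anyNA(df$value)) stopf("signal values must be numeric")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  by_chrom <- split(df[, c("start", "end", "value")], df$chrom)
  for (chrom in names(by_chrom)) {
    b <- by_chrom[[chrom]]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stopf("overlapping intervals on chromosome '%s'", chrom)
    }
  }
  structure(list(by_chrom = by_chrom), class = "signal_track")
}

#' Parse a bedGraph signal track
#'
#' @param path bedGraph file (0-based half-open, numeric values).
#' @return A [signal_track()].  Overlapping intervals within the file are an
#'   error (reported with a line number).
#' @export
parse_signal_track <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  lines <- lines[keep]; ln <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    j <- which(lengths(fields) != 4L)[1L]
    stopf("%s line %d: bedGraph rows need 4 fields", path, ln[j])
  }
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
                   end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
                   value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    j <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))[1L]
    stopf("%s line %d: non-numeric bedGraph fields", path, ln[j])
  }
  for (chrom in unique(df$chrom)) {
    b <- df[df$chrom == chrom, , drop = FALSE]
    o <- order(b$start)
    if (nrow(b) > 1L) {
      ov <- which(b$start[o][-1L] < b$end[o][-nrow(b)])
      if (length(ov)) {
        stopf("%s line %d: overlapping intervals on '%s'",
              path, ln[df$chrom == chrom][o][ov[1L] + 1L], chrom)
      }
    }
  }
  signal_track(df)
}

#' Write a signal track as bedGraph
#' @param track A [signal_track()].
#' @param path Output file.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  rows <- character(0)
  for (chrom in names(track$by_chrom)) {
    b <- track$by_chrom[[chrom]]
    rows <- c(rows, paste(chrom, b$start, b$end, b$value, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

## Max and mean of a step-function track over [start, end); uncovered = 0.
track_query <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "signal_track"))
  if (end <= start) stopf("track query needs end > start")
  b <- track$by_chrom[[chrom]]
  len <- end - start
  if (is.null(b) || nrow(b) == 0L) return(c(max = 0, mean = 0))
  hit <- b$end > start & b$start < end
  if (!any(hit)) return(c(max = 0, mean = 0))
  h <- b[hit, , drop = FALSE]
  cover <- pmin(h$end, end) - pmax(h$start, start)
  mx <- max(h$value)
  if (sum(cover) < len) mx <- max(mx, 0)
  c(max = mx, mean = sum(h$value * cover) / len)
}

#' Maximum signal over an interval
#' @param track A [signal_track()].
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Numeric max (0 where uncovered).
#' @export
track_max <- function(track, chrom, start, end) {
  unname(track_query(track, chrom, start, end)["max"])
}

#' Mean signal over an interval (uncovered bases count as 0)
#' @inheritParams track_max
#' @return Numeric mean.
#' @export
track_mean <- function(track, chrom, start, end) {
  unname(track_query(track, chrom, start, end)["mean"])
}

#' Parse a JASPAR-format position count matrix
#'
#' Accepts the bracketed JASPAR layout (`A [ 87 167 ... ]`) or four plain
#' numeric rows, in A/C/G/T order.
#'
#' @param path Motif file.
#' @return A 4 x width numeric matrix with rownames A, C, G, T.
#' @export
parse_motif_matrix <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")
  rows <- lines[keep]; ln <- which(keep)
  if (length(rows) != 4L) {
    stopf("%s: expected 4 matrix rows, found %d", path, length(rows))
  }
  labels <- toupper(sub("^\\s*([ACGTacgt])[:\\s\\[].*$", "\\1", rows))
  if (!all(labels %in% c("A", "C", "G", "T"))) labels <- c("A", "C", "G", "T")
  vals <- lapply(seq_along(rows), function(i) {
    txt <- gsub("^\\s*[ACGTacgt]?\\s*\\[?|\\]\\s*$", "", rows[i])
    v <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
    if (anyNA(v)) stopf("%s line %d: non-numeric motif counts", path, ln[i])
    v
  })
  w <- lengths(vals)
  if (length(unique(w)) != 1L) {
    stopf("%s line %d: motif rows have unequal lengths", path, ln[which(w != w[1L])[1L]])
  }
  m <- do.call(rbind, vals)
  rownames(m) <- labels
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(m < 0)) stopf("%s: negative motif counts", path)
  m
}

#' Parse a segment/RSS catalog TSV
#'
#' Columns: `segment_id`, `chrom`, `rss_cleavage_pos` (1-based in the file),
#' `orientation`, `rss_kind` (12/23), `strength`, `domain_label`.
#' @param path TSV file.
#' @return `data.frame` with 0-based `rss_cleavage_pos`.
#' @export
parse_segment_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("segment_id", "chrom", "rss_cleavage_pos", "orientation")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  check_orientation(df$orientation)
  df$rss_cleavage_pos <- as.integer(df$rss_cleavage_pos) - 1L
  df
}

#' Write a segment/RSS catalog TSV (positions written 1-based)
#' @param catalog `data.frame` with 0-based `rss_cleavage_pos`.
#' @param path Output file.
#' @export
write_segment_catalog <- function(catalog, path) {
  out <- catalog
  out$rss_cleavage_pos <- out$rss_cleavage_pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
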