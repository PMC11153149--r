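# Annotation of robust interaction peaks (+/- 1 kb) with underlying
# CTCF-binding elements (CBEs), E2A binding and transcription, yielding the
# C/E/T/U labels.

#' Log-odds weight matrix from a position count matrix
#'
#' Column-wise log2 odds against a uniform background, with a pseudocount of
#' 1% of the column total: `log2(((c + eps) / (tot + 4 eps)) / 0.25)`.
#'
#' @param pcm 4 x width count matrix (rows A/C/G/T, nonnegative).
#' @return 4 x width numeric log-odds matrix (bits).
#' @export
pwm_log_odds <- function(pcm) {
  if (nrow(pcm) != 4L) stopf("count matrix must have 4 rows (A/C/G/T)")
  tot <- colSums(pcm)
  if (any(tot <= 0)) stopf("zero-total column in count matrix")
  eps <- 0.01 * tot
  freq <- sweep(pcm, 2L, eps, "+")
  freq <- sweep(freq, 2L, tot + 4 * eps, "/")
  log2(freq / 0.25)
}

#' Scan a genome with a position count matrix
#'
#' Scores every placement on both strands with the log-odds matrix of
#' [pwm_log_odds()] and reports placements scoring above the threshold.
#' Placements containing N are skipped.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character).
#' @param pcm 4 x width position count matrix.
#' @param threshold Score threshold (bits); hits satisfy `score > threshold`.
#' @return `data.frame` with `chrom`, `start` (0-based), `end`, `strand`,
#'   `score`; motif width as attribute `"width"`.
#' @export
pwm_scan <- function(genome, pcm, threshold) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  w <- pwm_log_odds(pcm)
  width <- ncol(w)
  if (width < 4L) stopf("motif width must be >= 4")
  w_rc <- w[4:1, width:1, drop = FALSE]  # minus-strand scoring matrix
  out <- list()
  for (chrom in names(genome)) {
    ch <- chrom_chars(genome, chrom)
    L <- length(ch)
    if (L < width) next
    base <- match(ch, c("A", "C", "G", "T"))
    n_pos <- L - width + 1L
    sc_f <- sc_r <- numeric(n_pos)
    for (i in seq_len(width)) {
      b <- base[seq_len(n_pos) + i - 1L]
      sc_f <- sc_f + w[cbind(b, i)]
      sc_r <- sc_r + w_rc[cbind(b, i)]
    }
    hit_f <- which(!is.na(sc_f) & sc_f > threshold)
    hit_r <- which(!is.na(sc_r) & sc_r > threshold)
    df <- rbind(
      if (length(hit_f)) data.frame(chrom = chrom, start = hit_f - 1L,
                                    strand = "+", score = sc_f[hit_f]),
      if (length(hit_r)) data.frame(chrom = chrom, start = hit_r - 1L,
                                    strand = "-", score = sc_r[hit_r]))
    if (!is.null(df)) out[[chrom]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), start = integer(), strand = character(),
               score = numeric())
  }
  res$end <- res$start + width
  res <- res[order(res$chrom, res$start, res$strand),
             c("chrom", "start", "end", "strand", "score"), drop = FALSE]
  rownames(res) <- NULL
  attr(res, "width") <- width
  res
}

## Number of ChIP repeats whose peak set overlaps each interval.
count_chip_support <- function(chrom, start, end, chip_peak_sets) {
  support <- integer(length(start))
  for (peaks in chip_peak_sets) {
    hit <- logical(length(start))
    for (cr in unique(chrom)) {
      sel <- chrom == cr
      pk <- peaks[peaks$chrom == cr, , drop = FALSE]
      if (!nrow(pk)) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(start[sel] + 1L, end[sel]),
        IRanges::IRanges(pk$start + 1L, pk$end))
      hit[sel] <- ov > 0L
    }
    support <- support + hit
  }
  support
}

#' Reliable CBEs from motif hits and CTCF ChIP repeats
#'
#' A CBE is reliable when its motif score exceeds `score_threshold` and it
#' overlaps a ChIP peak in at least `min_repeats` repeats.  Orientation is
#' reported as rightward (+ strand) or leftward (- strand).
#'
#' @param hits Motif hits from [pwm_scan()].
#' @param chip_peak_sets List (>= 2) of per-repeat peak `data.frame`s with
#'   `chrom`, `start`, `end`.
#' @param score_threshold Motif score cutoff (default 13).
#' @param min_repeats Minimum supporting ChIP repeats (default 2).
#' @return `data.frame` of reliable CBEs with `orientation` and
#'   `chip_support` columns.
#' @export
reliable_cbes <- function(hits, chip_peak_sets, score_threshold = 13,
                          min_repeats = 2L) {
  if (length(chip_peak_sets) < 2L) stopf("need >= 2 ChIP repeats")
  support <- count_chip_support(hits$chrom, hits$start, hits$end,
                                chip_peak_sets)
  keep <- hits$score > score_threshold & support >= min_repeats
  out <- hits[keep, , drop = FALSE]
  out$orientation <- ifelse(out$strand == "+", "rightward", "leftward")
  out$chip_support <- support[keep]
  rownames(out) <- NULL
  out
}

#' Annotate robust interaction peaks with underlying features
#'
#' Each peak region +/- `flank` bp is queried for reliable CBEs (label C,
#' with orientations), maximum E2A ChIP signal >= 0.5 (label E), and
#' transcription -- a GRO-seq repeat supports transcription when its window
#' maximum is >= 40 or its window mean is >= 10, and at least 2 supporting
#' repeats give label T.  Peaks with none of these are labelled U (unknown).
#'
#' @param peaks Robust peak `data.frame` (`chrom`, `start`, `end`).
#' @param cbes Reliable CBEs from [reliable_cbes()].
#' @param e2a_track E2A ChIP [signal_track()].
#' @param gro_tracks List of per-repeat GRO-seq [signal_track()]s.
#' @param flank Window extension in bp (default 1000).
#' @param e2a_min,gro_max_min,gro_mean_min,txn_min_repeats Thresholds of the
#'   E and T rules.
#' @return `data.frame`: one row per peak with `cbe_count`,
#'   `cbe_orientations`, `e2a_max`, `txn_support`, `transcription` and a
#'   comma-separated `labels` column (`"U"` when featureless).
#' @export
annotate_peaks <- function(peaks, cbes, e2a_track, gro_tracks, flank = 1000L,
                           e2a_min = 0.5, gro_max_min = 40, gro_mean_min = 10,
                           txn_min_repeats = 2L) {
  if (flank < 0) stopf("flank must be >= 0")
  n <- nrow(peaks)
  win_s <- pmax(0L, peaks$start - as.integer(flank))
  win_e <- peaks$end + as.integer(flank)
  cbe_count <- integer(n); cbe_orient <- character(n)
  e2a_max <- numeric(n); txn_support <- integer(n)
  for (i in seq_len(n)) {
    sel <- cbes$chrom == peaks$chrom[i] & cbes$end > win_s[i] &
      cbes$start < win_e[i]
    cbe_count[i] <- sum(sel)
    cbe_orient[i] <- paste(cbes$orientation[sel], collapse = ",")
    e2a_max[i] <- track_max(e2a_track, peaks$chrom[i], win_s[i], win_e[i])
    txn_support[i] <- sum(vapply(gro_tracks, function(trk) {
      q <- track_query(trk, peaks$chrom[i], win_s[i], win_e[i])
      q["max"] >= gro_max_min || q["mean"] >= gro_mean_min
    }, logical(1L)))
  }
  has_c <- cbe_count >= 1L
  has_e <- e2a_max >= e2a_min
  has_t <- txn_support >= txn_min_repeats
  labels <- vapply(seq_len(n), function(i) {
    l <- c(if (has_c[i]) "C", if (has_e[i]) "E", if (has_t[i]) "T")
    if (length(l)) paste(l, collapse = ",") else "U"
  }, character(1L))
  out <- peaks
  out$cbe_count <- cbe_count
  out$cbe_orientations <- cbe_orient
  out$e2a_max <- e2a_max
  out$txn_support <- txn_support
  out$transcription <- has_t
  out$labels <- labels
  out
}
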