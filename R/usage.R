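# Library normalization, per-segment usage quantification, and the
# comparison statistics and binned profiles used to contrast libraries.

#' Down-sample a library to a fixed total read count
#'
#' To compare absolute V(D)J recombination levels, each library is
#' down-sampled to a fixed number of total reads (junctions + germline
#' reads).  Junction records and germline pseudo-reads are sampled jointly
#' from one urn, uniformly without replacement; the output total is exact and
#' deterministic given the seed.
#'
#' @param lib A [junction_library()].
#' @param total_reads Target total (default 500000).
#' @param seed Integer seed.
#' @param allow_smaller If the library holds fewer than `total_reads` reads,
#'   pass it through unchanged with a warning instead of erroring.
#' @return A [junction_library()] with exactly `total_reads` reads (record
#'   order preserved).
#' @export
downsample_library <- function(lib, total_reads = 500000L, seed,
                               allow_smaller = FALSE) {
  stopifnot(inherits(lib, "junction_library"))
  total_reads <- as.integer(total_reads)
  if (total_reads <= 0L) stopf("total_reads must be > 0")
  tot <- total_reads(lib)
  if (tot < total_reads) {
    if (allow_smaller) {
      warnf("library %s has %d < %d reads; passing through unchanged",
            lib$library_id, tot, total_reads)
      return(lib)
    }
    stopf("library %s has %d reads, fewer than target %d",
          lib$library_id, tot, total_reads)
  }
  n_rec <- nrow(lib$records)
  keep <- withr::with_seed(seed, sample.int(tot, total_reads))
  kept_rec <- sort(keep[keep <= n_rec])
  records <- lib$records[kept_rec, , drop = FALSE]
  rownames(records) <- NULL
  junction_library(records, total_reads - length(kept_rec), lib$library_id,
                   bait = lib$bait, repeat_id = lib$repeat_id)
}

#' Per-segment usage table
#'
#' Counts on-target junctions per catalog segment (after down-sampling) and
#' expresses each segment's usage as a percentage of the total on-target
#' count.  Zero-count segments are retained.
#'
#' @param on_target On-target records from [split_on_off_target()] (must
#'   carry `segment_id`).
#' @param catalog Segment catalog `data.frame` with `segment_id`.
#' @return `data.frame` with `segment_id`, `absolute_count`,
#'   `relative_percent`; total count as attribute `"total"`.
#' @export
segment_usage <- function(on_target, catalog) {
  ids <- catalog$segment_id
  unknown <- setdiff(unique(on_target$segment_id), ids)
  if (length(unknown)) {
    stopf("record assigned to unknown segment '%s'", unknown[1L])
  }
  counts <- table(factor(on_target$segment_id, levels = ids))
  total <- sum(counts)
  out <- data.frame(segment_id = ids, absolute_count = as.integer(counts),
                    relative_percent = if (total > 0)
                      100 * as.integer(counts) / total else NA_real_)
  attr(out, "total") <- total
  out
}

#' Pearson correlation between usage vectors
#'
#' Product-moment correlation with the two-sided parametric P value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, as used
#' to compare segment-usage patterns between samples.
#'
#' @param u,v Equal-length numeric vectors (n >= 3, non-constant).
#' @return `list(r, p, n)`.
#' @export
pearson_usage <- function(u, v) {
  n <- length(u)
  if (length(v) != n) stopf("usage vectors differ in length")
  if (n < 3L) stopf("need n >= 3")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stopf("correlation undefined for a constant vector")
  }
  du <- u - mean(u); dv <- v - mean(v)
  r <- sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Welch's unpaired two-sided t-test
#'
#' Compares total rearrangement levels between two groups without assuming
#' equal variances (Welch statistic, Welch-Satterthwaite degrees of freedom).
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 and positive
#'   variance in at least one group.
#' @return `list(t, df, p)`.
#' @export
welch_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs n >= 2")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va + vb == 0) stopf("degenerate variance: both groups constant")
  se2 <- va / na + vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}

#' Binned mean +/- s.e.m. signal profile across repeats
#'
#' The plotting region is divided into `nbins` equal half-open bins (the last
#' bin absorbs the remainder); within each bin the per-repeat value is the
#' maximum signal, and repeats are merged as mean +/- s.e.m. of those maxima.
#'
#' @param tracks List of [signal_track()]s, one per biological repeat.
#' @param chrom,start,end Plotting region (0-based half-open, length >=
#'   `nbins`).
#' @param nbins Number of bins (1000 for full-locus profiles, 200 for
#'   zoom-ins).
#' @return `data.frame` with `bin`, `start`, `end`, `mean`, `sem`;
#'   `n_repeats` as an attribute.
#' @export
binned_profile <- function(tracks, chrom, start, end, nbins = 1000L) {
  nbins <- as.integer(nbins)
  if (nbins <= 0L) stopf("nbins must be > 0")
  len <- end - start
  if (len < nbins) stopf("region length %d shorter than nbins %d", len, nbins)
  width <- len %/% nbins
  bs <- start + (seq_len(nbins) - 1L) * width
  be <- c(bs[-1L], end)  # last bin absorbs the remainder
  vals <- vapply(tracks, function(trk) {
    vapply(seq_len(nbins), function(i) track_max(trk, chrom, bs[i], be[i]),
           numeric(1L))
  }, numeric(nbins))
  vals <- matrix(vals, nrow = nbins)
  out <- data.frame(bin = seq_len(nbins), start = bs, end = be,
                    mean = rowMeans(vals),
                    sem = apply(vals, 1L, sem))
  attr(out, "n_repeats") <- length(tracks)
  out
}
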