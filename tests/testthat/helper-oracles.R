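# Independent oracles and small fixture builders.  The oracles deliberately
# avoid the package's vectorized code paths: plain substring arithmetic and
# direct pmf summation.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

## Hamming distance between equal-length strings by per-character comparison.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

## Score one 39-base window (already in site orientation): NULL if no CAC,
## else c(spacer, mismatches), evaluating both spacers, tie to 12.
oracle_score_window <- function(win) {
  if (substr(win, 1L, 3L) != "CAC") return(NULL)
  mh <- oracle_hamming(substr(win, 4L, 7L), "AGTG")
  m12 <- mh + oracle_hamming(substr(win, 20L, 28L), "ACAAAAACC")
  m23 <- mh + oracle_hamming(substr(win, 31L, 39L), "ACAAAAACC")
  if (m12 <= m23) c(12L, m12) else c(23L, m23)
}

## Exhaustive per-position / per-orientation scan of one sequence string.
## Returns a data.frame comparable to scan_unannotated_rss() for one chrom.
oracle_scan <- function(s, chrom = "chr", max_mm = 4L) {
  L <- nchar(s)
  rows <- list()
  for (p in 0:(L - 1L)) {
    if (p + 39L <= L) {
      r <- oracle_score_window(substr(s, p + 1L, p + 39L))
      if (!is.null(r) && r[2L] <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, cleavage_pos = p, orientation = "+",
          spacer_class = r[1L], mismatches = r[2L])
      }
    }
    if (p >= 38L) {
      r <- oracle_score_window(oracle_revcomp(substr(s, p - 37L, p + 1L)))
      if (!is.null(r) && r[2L] <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, cleavage_pos = p, orientation = "-",
          spacer_class = r[1L], mismatches = r[2L])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), cleavage_pos = integer(),
                      orientation = character(), spacer_class = integer(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$cleavage_pos, out$orientation), ]
  rownames(out) <- NULL
  out
}

## Upper-tail Poisson probability by direct pmf summation (term recurrence
## from exp(-lambda); truncated far into the upper tail).
oracle_poisson_upper <- function(k, lambda) {
  kmax <- k + max(400L, as.integer(10 * lambda))
  term <- exp(-lambda)
  total <- 0
  for (j in 0:kmax) {
    if (j >= k) total <- total + term
    term <- term * lambda / (j + 1)
  }
  total
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## Tiny junction library builder.
make_lib <- function(pos, orient, germline = 10L, chrom = "chr1",
                     id = "libA", repeat_id = 1L) {
  junction_library(
    data.frame(chrom = chrom, junction_pos = as.integer(pos),
               prey_orientation = orient, bait_id = "bait",
               read_id = sprintf("r%d", seq_along(pos))),
    germline, id, repeat_id = repeat_id)
}

## Minimal peak data.frame for robustness-rule tests.
peak_df <- function(start, end, p = 1e-8) {
  data.frame(chrom = "chr1", start = as.integer(start), end = as.integer(end),
             summit_pos = as.integer((start + end) %/% 2L), summit_raw_p = p,
             summit_adj_p = p, n_sites = 3L)
}

empty_peak_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit_pos = integer(), summit_raw_p = numeric(),
             summit_adj_p = numeric(), n_sites = integer())
}
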