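# Cryptic-RSS analysis of RAG off-target junctions: heptamer/nonamer
# mismatch scoring against the consensus RSS, genome-wide detection of
# unannotated bona fide RSSs, on/off-target splitting, 15-bp collapsing of
# coding-end junctions onto CAC cleavage sites, and deletional/inversional
# orientation classification.
#
# Coordinate convention: the cleavage position of an RSS (or bare CAC) is the
# first base of the heptamer read in the site's orientation -- the base
# adjacent to the coding flank.  For a "+" site the heptamer occupies
# [pos, pos + 7) on the forward strand; for a "-" site it occupies
# [pos - 6, pos + 1) and reads heptamer-to-nonamer leftward.

IDEAL_HEPTAMER_TAIL <- c("A", "G", "T", "G")   # heptamer positions 4-7
IDEAL_NONAMER <- c("A", "C", "A", "A", "A", "A", "A", "C", "C")
RSS_WINDOW <- 39L  # heptamer (7) + 23-spacer + nonamer (9)

#' Mismatch count of a window against the consensus RSS
#'
#' A candidate window is scored only if it starts with the invariant CAC;
#' otherwise no call is made.  The mismatch count is the Hamming distance of
#' heptamer positions 4-7 to AGTG plus that of the 9 bases following a 12- or
#' 23-bp spacer to the consensus nonamer ACAAAAACC (13 compared positions).
#' Both spacer lengths are evaluated and the smaller count returned; ties go
#' to the 12-spacer.
#'
#' @param window Nucleotide string of at least 39 bases starting at the
#'   putative heptamer.
#' @param orientation `"+"` to read the window as given, `"-"` to score its
#'   reverse complement.
#' @return `NULL` (no call) or `list(spacer, mismatches)`.
#' @export
mismatch_to_ideal_rss <- function(window, orientation = "+") {
  check_orientation(orientation)
  if (nchar(window) < RSS_WINDOW) {
    stopf("window too short: need %d bases, got %d", RSS_WINDOW, nchar(window))
  }
  if (orientation == "-") window <- revcomp(window)
  ch <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (!(ch[1L] == "C" && ch[2L] == "A" && ch[3L] == "C")) return(NULL)
  mh <- sum(ch[4:7] != IDEAL_HEPTAMER_TAIL)
  m12 <- mh + sum(ch[20:28] != IDEAL_NONAMER)
  m23 <- mh + sum(ch[31:39] != IDEAL_NONAMER)
  if (m12 <= m23) list(spacer = 12L, mismatches = as.integer(m12))
  else list(spacer = 23L, mismatches = as.integer(m23))
}

## Vectorized one-strand scan over a character vector of bases; returns
## 0-based window start positions (in the given strand's coordinates),
## best spacer and mismatch count for every CAC-gated window with
## mismatches <= max_mismatch.
scan_strand <- function(ch, max_mismatch) {
  L <- length(ch)
  empty <- data.frame(pos = integer(), spacer_class = integer(),
                      mismatches = integer())
  if (L < RSS_WINDOW) return(empty)
  idx <- seq_len(L - RSS_WINDOW + 1L)
  cand <- idx[ch[idx] == "C" & ch[idx + 1L] == "A" & ch[idx + 2L] == "C"]
  if (!length(cand)) return(empty)
  mh <- integer(length(cand))
  for (k in 0:3) mh <- mh + (ch[cand + 3L + k] != IDEAL_HEPTAMER_TAIL[k + 1L])
  m12 <- mh; m23 <- mh
  for (k in 0:8) {
    m12 <- m12 + (ch[cand + 19L + k] != IDEAL_NONAMER[k + 1L])
    m23 <- m23 + (ch[cand + 30L + k] != IDEAL_NONAMER[k + 1L])
  }
  best <- pmin(m12, m23)
  keep <- best <= max_mismatch
  data.frame(pos = cand[keep] - 1L,
             spacer_class = ifelse(m12[keep] <= m23[keep], 12L, 23L),
             mismatches = as.integer(best[keep]))
}

#' Scan a genome for unannotated bona fide RSSs
#'
#' Reports every position and orientation whose window scores at most
#' `max_mismatch` mismatches to the consensus RSS (CAC gate plus 13 compared
#' heptamer/nonamer positions, see [mismatch_to_ideal_rss()]).  These sites
#' behave as bona fide RSSs and are eliminated from cryptic-RSS analyses.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param max_mismatch Maximum mismatches for a site to be called (default 4).
#' @return `data.frame` with `chrom`, `cleavage_pos` (0-based first heptamer
#'   base in site orientation), `orientation`, `spacer_class`, `mismatches`,
#'   sorted by (chrom, cleavage_pos, orientation).
#' @export
scan_unannotated_rss <- function(genome, max_mismatch = 4L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- list()
  for (chrom in names(genome)) {
    ch <- chrom_chars(genome, chrom)
    L <- length(ch)
    fwd <- scan_strand(ch, max_mismatch)
    rc <- rev(chartr("ACGTN", "TGCAN", ch))
    rev_hits <- scan_strand(rc, max_mismatch)
    hits <- rbind(
      if (nrow(fwd)) data.frame(chrom = chrom, cleavage_pos = fwd$pos,
                                orientation = "+",
                                spacer_class = fwd$spacer_class,
                                mismatches = fwd$mismatches),
      if (nrow(rev_hits)) data.frame(chrom = chrom,
                                     cleavage_pos = L - 1L - rev_hits$pos,
                                     orientation = "-",
                                     spacer_class = rev_hits$spacer_class,
                                     mismatches = rev_hits$mismatches))
    if (!is.null(hits)) out[[chrom]] <- hits
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), cleavage_pos = integer(),
                      orientation = character(), spacer_class = integer(),
                      mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$cleavage_pos, res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Distance from each record to the nearest catalog site with matching chrom
## and orientation.  Returns list(dist, idx) into `sites`.
nearest_site <- function(records, sites) {
  n <- nrow(records)
  dist <- rep(Inf, n); idx <- rep(NA_integer_, n)
  if (!nrow(sites)) return(list(dist = dist, idx = idx))
  key_r <- paste(records$chrom, records$prey_orientation)
  key_s <- paste(sites$chrom, sites$orientation)
  for (key in unique(key_r)) {
    ri <- which(key_r == key)
    si <- which(key_s == key)
    if (!length(si)) next
    o <- si[order(sites$pos[si])]
    pos <- sites$pos[o]
    p <- records$junction_pos[ri]
    left <- findInterval(p, pos)
    d_left <- ifelse(left >= 1L, p - pos[pmax(left, 1L)], Inf)
    right <- pmin(left + 1L, length(pos))
    d_right <- ifelse(left < length(pos), pos[right] - p, Inf)
    use_left <- d_left <= d_right   # exact tie -> leftmost site
    dist[ri] <- pmin(d_left, d_right)
    idx[ri] <- ifelse(use_left, o[pmax(left, 1L)], o[right])
  }
  list(dist = dist, idx = idx)
}

#' Split a junction library into on-target, cryptic and removed junctions
#'
#' A junction is on-target if it lies within `tolerance` bp of an annotated
#' catalog RSS cleavage site with consistent orientation; junctions within
#' `tolerance` of an unannotated bona fide site (at most 4 mismatches to
#' consensus) are removed from cryptic analyses; everything else is a cryptic
#' (RAG off-target) junction.  The three outputs partition the input.
#'
#' @param lib A [junction_library()].
#' @param annotated Segment catalog `data.frame` with `segment_id`, `chrom`,
#'   `rss_cleavage_pos`, `orientation`.
#' @param unannotated `data.frame` of unannotated bona fide sites with
#'   `chrom`, `cleavage_pos`, `orientation` (e.g. from
#'   [scan_unannotated_rss()], minus the annotated set).
#' @param tolerance Assignment tolerance in bp (default 50; coding-end
#'   resection spreads junctions around the cleavage site).
#' @return `list(on_target, cryptic, removed)`; `on_target` gains a
#'   `segment_id` column.
#' @export
split_on_off_target <- function(lib, annotated, unannotated, tolerance = 50L) {
  stopifnot(inherits(lib, "junction_library"))
  if (tolerance < 0) stopf("tolerance must be >= 0")
  records <- lib$records
  ann <- data.frame(chrom = annotated$chrom, pos = annotated$rss_cleavage_pos,
                    orientation = annotated$orientation,
                    segment_id = annotated$segment_id)
  una <- if (!is.null(unannotated) && nrow(unannotated)) {
    data.frame(chrom = unannotated$chrom, pos = unannotated$cleavage_pos,
               orientation = unannotated$orientation)
  } else data.frame(chrom = character(), pos = integer(), orientation = character())
  na <- nearest_site(records, ann)
  nu <- nearest_site(records, una)
  on <- na$dist <= tolerance
  removed <- !on & nu$dist <= tolerance
  cryptic <- !on & !removed
  on_target <- records[on, , drop = FALSE]
  on_target$segment_id <- ann$segment_id[na$idx[on]]
  rownames(on_target) <- NULL
  out_cry <- records[cryptic, , drop = FALSE]; rownames(out_cry) <- NULL
  out_rm <- records[removed, , drop = FALSE]; rownames(out_rm) <- NULL
  list(on_target = on_target, cryptic = out_cry, removed = out_rm)
}

#' Collapse cryptic junctions onto CAC cleavage sites
#'
#' Coding-end junctions are processed and spread over several bp beyond the
#' cleavage site, so junctions within `radius` bp of a catalog CAC site (with
#' matching orientation) are collapsed into one peak mapped to that cleavage
#' site.  A junction near two sites goes to the nearer one (exact tie: the
#' leftmost coordinate).  Junctions not within `radius` of any CAC are
#' reported separately as unassigned; total junction count is conserved.
#'
#' @param cryptic `data.frame` of cryptic junction records.
#' @param cac_catalog `data.frame` with `chrom`, `pos` (CAC cleavage
#'   coordinate, 0-based), `orientation`.
#' @param radius Collapse radius in bp (default 15).
#' @return `list(peaks, unassigned)`: `peaks` has one row per CAC with >= 1
#'   member (`chrom`, `cac_pos`, `orientation`, `junction_count`,
#'   `member_offsets` list column).
#' @export
collapse_cryptic <- function(cryptic, cac_catalog, radius = 15L) {
  if (radius <= 0) stopf("radius must be > 0")
  sites <- data.frame(chrom = cac_catalog$chrom, pos = cac_catalog$pos,
                      orientation = cac_catalog$orientation)
  nn <- nearest_site(cryptic, sites)
  assigned <- nn$dist <= radius
  peaks <- data.frame(chrom = character(), cac_pos = integer(),
                      orientation = character(), junction_count = integer())
  peaks$member_offsets <- list()
  if (any(assigned)) {
    ai <- nn$idx[assigned]
    offs <- abs(cryptic$junction_pos[assigned] - sites$pos[ai])
    grp <- split(offs, ai)
    gi <- as.integer(names(grp))
    peaks <- data.frame(chrom = sites$chrom[gi], cac_pos = sites$pos[gi],
                        orientation = sites$orientation[gi],
                        junction_count = lengths(grp))
    peaks$member_offsets <- unname(grp)
    peaks <- peaks[order(peaks$chrom, peaks$cac_pos, peaks$orientation), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
  }
  unassigned <- cryptic[!assigned, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(peaks = peaks, unassigned = unassigned)
}

#' Classify junction orientation as deletional or inversional
#'
#' A junction is deletional when the prey cryptic RSS is in convergent
#' orientation with the bait RSS (opposite strand sign; intervening DNA is
#' excised) and inversional when prey and bait share the same orientation
#' (intervening DNA is inverted).  Vectorized; invariant under a global
#' strand flip.
#'
#' @param bait_orientation `"+"`/`"-"` (recycled).
#' @param prey_orientation `"+"`/`"-"`.
#' @return Character vector of `"deletional"`/`"inversional"`.
#' @export
classify_orientation <- function(bait_orientation, prey_orientation) {
  check_orientation(bait_orientation, "bait_orientation")
  check_orientation(prey_orientation, "prey_orientation")
  ifelse(prey_orientation == bait_orientation, "inversional", "deletional")
}

#' Per-region deletional/inversional junction fractions across repeats
#'
#' For each named region the percentage of deletional and inversional cryptic
#' junctions is computed per biological repeat, then summarized as
#' mean +/- s.e.m. across repeats.  Regions with no junctions in any repeat
#' are flagged empty rather than reported as 0/0.
#'
#' @param records Cryptic junction `data.frame` with `chrom`, `junction_pos`,
#'   `prey_orientation` and `repeat_id`.
#' @param regions `data.frame` with `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param bait_orientation Orientation of the bait RSS.
#' @param known_chroms Chromosomes regions may refer to (defaults to those
#'   present in `records`).
#' @return `data.frame`, one row per region, with per-repeat counts attached
#'   as attribute `"per_repeat"`.
#' @export
orientation_fractions <- function(records, regions, bait_orientation,
                                  known_chroms = unique(records$chrom)) {
  if (!all(regions$chrom %in% known_chroms)) {
    bad <- setdiff(regions$chrom, known_chroms)[1L]
    stopf("region on unknown chromosome '%s'", bad)
  }
  cls <- classify_orientation(bait_orientation, records$prey_orientation)
  repeats <- sort(unique(records$repeat_id))
  if (!length(repeats)) repeats <- NA
  per_repeat <- list()
  out <- data.frame(name = regions$name, n_junctions = 0L,
                    pct_deletional_mean = NA_real_, pct_deletional_sem = NA_real_,
                    pct_inversional_mean = NA_real_, pct_inversional_sem = NA_real_,
                    n_repeats = 0L, empty = TRUE)
  for (i in seq_len(nrow(regions))) {
    sel <- records$chrom == regions$chrom[i] &
      records$junction_pos >= regions$start[i] &
      records$junction_pos < regions$end[i]
    pr <- data.frame(repeat_id = repeats, n = 0L, pct_deletional = NA_real_,
                     pct_inversional = NA_real_)
    for (j in seq_along(repeats)) {
      rs <- sel & records$repeat_id %in% repeats[j]
      n <- sum(rs)
      pr$n[j] <- n
      if (n > 0L) {
        pr$pct_deletional[j] <- 100 * sum(cls[rs] == "deletional") / n
        pr$pct_inversional[j] <- 100 * sum(cls[rs] == "inversional") / n
      }
    }
    with_data <- !is.na(pr$pct_deletional)
    out$n_junctions[i] <- sum(pr$n)
    out$n_repeats[i] <- sum(with_data)
    out$empty[i] <- !any(with_data)
    if (any(with_data)) {
      out$pct_deletional_mean[i] <- mean(pr$pct_deletional[with_data])
      out$pct_deletional_sem[i] <- sem(pr$pct_deletional[with_data])
      out$pct_inversional_mean[i] <- mean(pr$pct_inversional[with_data])
      out$pct_inversional_sem[i] <- sem(pr$pct_inversional[with_data])
    }
    per_repeat[[regions$name[i]]] <- pr
  }
  attr(out, "per_repeat") <- per_repeat
  out
}
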