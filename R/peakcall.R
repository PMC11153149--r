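# Restriction-site-anchored interaction peak calling for 3C-HTGTS profiles.
# Junction signals are collapsed onto CATG (NlaIII) cutting sites, libraries
# are bait-filtered, region-restricted and normalized to the smallest
# library, and sites with signal are tested against a Poisson background
# whose rate is the moving 101-site median of counts (a conservative
# over-estimate).  Summits are called at Bonferroni-adjusted P < 0.05,
# extended to flanking raw-P local maxima >= 0.05, merged, and peaks
# supported by >50% of repeats are reported as robust.

#' Build a restriction map from a genome
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param motif Recognition motif (default `"CATG"`, NlaIII; palindromic, so
#'   one strand suffices).
#' @return A `restriction_map`: list of sorted 0-based motif start positions
#'   per chromosome.
#' @export
build_restriction_map <- function(genome, motif = "CATG") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  sites <- lapply(seq_along(genome), function(i) {
    as.integer(Biostrings::start(
      Biostrings::matchPattern(motif, genome[[i]]))) - 1L
  })
  names(sites) <- names(genome)
  restriction_map(sites)
}

#' Construct a restriction map from positions
#' @param sites Named list of integer vectors of 0-based site positions
#'   (one element per chromosome); must be strictly increasing.
#' @return A `restriction_map`.
#' @export
restriction_map <- function(sites) {
  for (chrom in names(sites)) {
    p <- sites[[chrom]]
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      stopf("restriction sites on '%s' must be strictly increasing", chrom)
    }
    sites[[chrom]] <- as.integer(p)
  }
  structure(sites, class = "restriction_map")
}

#' Collapse junctions to restriction sites
#'
#' Each junction is assigned to its nearest cutting site when within
#' `max_dist` bp (exact tie between two sites: the leftmost), and discarded
#' otherwise.  Assigned + discarded = total.
#'
#' @param records Junction `data.frame` with `chrom`, `junction_pos`.
#' @param map A `restriction_map`.
#' @param max_dist Maximum junction-to-site distance in bp (default 10).
#' @return `list(site_counts, n_discarded)`; `site_counts` has one row per
#'   site with >= 1 assigned junction (`chrom`, `site_pos`, `count`).
#' @export
collapse_to_sites <- function(records, map, max_dist = 10L) {
  stopifnot(inherits(map, "restriction_map"))
  out <- list(); n_disc <- 0L
  for (chrom in unique(records$chrom)) {
    sites <- map[[chrom]]
    if (is.null(sites) || !length(sites)) {
      stopf("restriction map has no sites on chromosome '%s'", chrom)
    }
    p <- records$junction_pos[records$chrom == chrom]
    left <- findInterval(p, sites)
    d_left <- ifelse(left >= 1L, p - sites[pmax(left, 1L)], Inf)
    right <- pmin(left + 1L, length(sites))
    d_right <- ifelse(left < length(sites), sites[right] - p, Inf)
    use_left <- d_left <= d_right
    dist <- pmin(d_left, d_right)
    site <- ifelse(use_left, sites[pmax(left, 1L)], sites[right])
    keep <- dist <= max_dist
    n_disc <- n_disc + sum(!keep)
    if (any(keep)) {
      tab <- table(site[keep])
      out[[chrom]] <- data.frame(chrom = chrom,
                                 site_pos = as.integer(names(tab)),
                                 count = as.integer(tab))
    }
  }
  counts <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), site_pos = integer(), count = integer())
  }
  counts <- counts[order(counts$chrom, counts$site_pos), , drop = FALSE]
  rownames(counts) <- NULL
  list(site_counts = counts, n_discarded = n_disc)
}

#' Preprocess a set of 3C-HTGTS libraries for peak calling
#'
#' Removes junctions inside the bait self-ligation exclusion interval and
#' outside the analysis region, then down-samples every library (uniformly,
#' without replacement) to the minimum retained junction count across the
#' set -- the smallest-library normalization.
#'
#' @param libs List of [junction_library()]s.
#' @param bait A [bait_spec()].
#' @param region `list(chrom, start, end)` analysis region (0-based
#'   half-open).
#' @param seed Integer seed for the down-sampling.
#' @return List of normalized [junction_library()]s (identical junction
#'   totals).
#' @export
preprocess_3c <- function(libs, bait, region, seed) {
  if (!length(libs)) stopf("need at least one library")
  filtered <- lapply(libs, function(lib) {
    r <- lib$records
    in_excl <- r$chrom == bait$chrom & r$junction_pos >= bait$exclusion_start &
      r$junction_pos < bait$exclusion_end
    in_region <- r$chrom == region$chrom & r$junction_pos >= region$start &
      r$junction_pos < region$end
    keep <- !in_excl & in_region
    if (!any(keep)) stopf("library %s retains no junctions", lib$library_id)
    r2 <- r[keep, , drop = FALSE]; rownames(r2) <- NULL
    junction_library(r2, lib$germline_read_count, lib$library_id,
                     bait = lib$bait, repeat_id = lib$repeat_id)
  })
  n_min <- min(vapply(filtered, function(l) nrow(l$records), integer(1L)))
  withr::with_seed(seed, lapply(filtered, function(lib) {
    keep <- sort(sample.int(nrow(lib$records), n_min))
    r <- lib$records[keep, , drop = FALSE]; rownames(r) <- NULL
    junction_library(r, lib$germline_read_count, lib$library_id,
                     bait = lib$bait, repeat_id = lib$repeat_id)
  }))
}

#' Moving-median Poisson rate over tested sites
#'
#' For each signal-bearing site, the background rate is the median count over
#' a window of up to 50 tested sites on each side plus the centre (101 sites;
#' truncated at the array edges, where an even window takes the lower-middle
#' value).  Counts are >= 1 at tested sites, so the rate is always >= 1.
#'
#' @param counts Integer counts at tested sites, ordered by position.
#' @param window Window size in sites (odd, default 101).
#' @return Numeric vector of rates, same length as `counts`.
#' @export
rolling_median_lambda <- function(counts, window = 101L) {
  n <- length(counts)
  if (n == 0L) stopf("empty site list")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stopf("window must be odd and >= 1")
  half <- (window - 1L) %/% 2L
  lambda <- numeric(n)
  if (n >= window) {
    interior <- (half + 1L):(n - half)
    lambda[interior] <- stats::runmed(counts, window)[interior]
    edge <- c(seq_len(half), (n - half + 1L):n)
  } else {
    edge <- seq_len(n)
  }
  for (i in edge) {
    lambda[i] <- lower_median(counts[max(1L, i - half):min(n, i + half)])
  }
  lambda
}

#' Upper-tail Poisson P value
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)` -- the enrichment test applied at
#' each signal-bearing site against its moving-median background rate.
#'
#' @param k Observed count (>= 0).
#' @param lambda Background rate (> 0).  Vectorized.
#' @return P values in (0, 1]; monotone non-increasing in `k`.
#' @export
poisson_upper_p <- function(k, lambda) {
  if (any(lambda <= 0)) stopf("lambda must be > 0")
  if (any(k < 0)) stopf("k must be >= 0")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Per-site statistics for one library
#'
#' @param site_counts `data.frame` from [collapse_to_sites()] (one
#'   chromosome).
#' @param window Moving-median window (default 101 sites).
#' @return `data.frame` adding `lambda`, `raw_p`, `adj_p` (Bonferroni over
#'   the tested sites).
#' @export
site_stats <- function(site_counts, window = 101L) {
  if (!nrow(site_counts)) stopf("empty site list")
  if (length(unique(site_counts$chrom)) > 1L) {
    stopf("site_stats() expects sites of a single chromosome")
  }
  out <- site_counts[order(site_counts$site_pos), , drop = FALSE]
  out$lambda <- rolling_median_lambda(out$count, window)
  out$raw_p <- poisson_upper_p(out$count, out$lambda)
  out$adj_p <- pmin(1, nrow(out) * out$raw_p)
  rownames(out) <- NULL
  out
}

## A tested site is an extension stop if its raw P is >= p_floor and is a
## strict local maximum of raw P (at the array boundary: exceeds the single
## inner neighbour).
is_stop_site <- function(p, p_floor) {
  n <- length(p)
  left_ok <- c(TRUE, p[-1L] > p[-n])
  right_ok <- c(p[-n] > p[-1L], TRUE)
  p >= p_floor & left_ok & right_ok
}

#' Call interaction peaks in one repeat
#'
#' Summits are tested sites with Bonferroni-adjusted P below `alpha`.  From
#' each summit the peak range is determined by progressively extending both
#' sides to the first tested site whose raw P is a local maximum and at least
#' `p_floor`; the stop sites are included in the span.  If no stop is met the
#' region ends at the first/last tested site.  Overlapping regions are merged
#' and only the best (lowest raw P) summit is kept.
#'
#' @param stats `data.frame` from [site_stats()].
#' @param alpha Summit threshold on adjusted P (default 0.05).
#' @param p_floor Raw-P floor for extension stops (default 0.05).
#' @return `data.frame` of peaks: `chrom`, `start`, `end` (half-open span of
#'   the stop sites), `summit_pos`, `summit_raw_p`, `summit_adj_p`,
#'   `n_sites`.
#' @export
call_peaks_single <- function(stats, alpha = 0.05, p_floor = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit_pos = integer(), summit_raw_p = numeric(),
                      summit_adj_p = numeric(), n_sites = integer())
  out <- empty
  for (chrom in unique(stats$chrom)) {
    s <- stats[stats$chrom == chrom, , drop = FALSE]
    s <- s[order(s$site_pos), , drop = FALSE]
    n <- nrow(s)
    summits <- which(s$adj_p < alpha)
    if (!length(summits)) next
    stop_ok <- is_stop_site(s$raw_p, p_floor)
    lo <- hi <- integer(length(summits))
    for (k in seq_along(summits)) {
      i <- summits[k]
      L <- i - 1L
      while (L >= 1L && !stop_ok[L]) L <- L - 1L
      if (L < 1L) L <- 1L
      R <- i + 1L
      while (R <= n && !stop_ok[R]) R <- R + 1L
      if (R > n) R <- n
      lo[k] <- min(L, i); hi[k] <- max(R, i)
    }
    regions <- merge_intervals(s$site_pos[lo], s$site_pos[hi] + 1L)
    for (m in seq_len(nrow(regions))) {
      mem <- regions$members[[m]]
      best <- mem[which.min(s$raw_p[summits[mem]])]
      li <- min(lo[mem]); hi_i <- max(hi[mem])
      out <- rbind(out, data.frame(
        chrom = chrom, start = s$site_pos[li], end = s$site_pos[hi_i] + 1L,
        summit_pos = s$site_pos[summits[best]],
        summit_raw_p = s$raw_p[summits[best]],
        summit_adj_p = s$adj_p[summits[best]],
        n_sites = hi_i - li + 1L))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Robust peaks across biological repeats
#'
#' Overlapping peak regions from all repeats are merged; each merged region's
#' support is the number of repeats contributing at least one overlapping
#' region.  Regions supported by more than half of the repeats are kept
#' (>= 2 of 2-3 repeats, >= 3 of 4-5 repeats), reporting the best (lowest
#' raw P) summit among the supporting repeats.
#'
#' @param peak_lists List (length 2-5) of per-repeat peak `data.frame`s from
#'   [call_peaks_single()].
#' @return `data.frame` of robust peaks with a `support` column.
#' @export
robust_peaks <- function(peak_lists) {
  n_rep <- length(peak_lists)
  if (n_rep < 2L || n_rep > 5L) stopf("robust_peaks() needs 2-5 repeats")
  need <- if (n_rep <= 3L) 2L else 3L
  pooled <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    p <- peak_lists[[i]]
    if (nrow(p)) cbind(p, repeat_idx = i) else NULL
  }))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit_pos = integer(), summit_raw_p = numeric(),
                      summit_adj_p = numeric(), support = integer())
  if (is.null(pooled) || !nrow(pooled)) return(empty)
  out <- empty
  for (chrom in unique(pooled$chrom)) {
    pc <- pooled[pooled$chrom == chrom, , drop = FALSE]
    regions <- merge_intervals(pc$start, pc$end)
    for (m in seq_len(nrow(regions))) {
      mem <- regions$members[[m]]
      support <- length(unique(pc$repeat_idx[mem]))
      if (support < need) next
      best <- mem[which.min(pc$summit_raw_p[mem])]
      out <- rbind(out, data.frame(
        chrom = chrom, start = regions$start[m], end = regions$end[m],
        summit_pos = pc$summit_pos[best],
        summit_raw_p = pc$summit_raw_p[best],
        summit_adj_p = pc$summit_adj_p[best], support = support))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end 3C-HTGTS peak calling
#'
#' Convenience wrapper: preprocess the library set (bait filter, region
#' restriction, smallest-library normalization), collapse junctions to
#' cutting sites, compute per-site Poisson statistics, call per-repeat peaks
#' and intersect them into robust peaks.
#'
#' @inheritParams preprocess_3c
#' @param map A `restriction_map`.
#' @param max_dist Junction-to-site collapse distance (default 10 bp).
#' @param window Moving-median window (default 101 sites).
#' @param alpha Summit threshold on adjusted P (default 0.05).
#' @return `list(per_repeat, robust, stats)`.
#' @export
call_3c_peaks <- function(libs, map, bait, region, seed, max_dist = 10L,
                          window = 101L, alpha = 0.05) {
  norm <- preprocess_3c(libs, bait, region, seed)
  stats_list <- lapply(norm, function(lib) {
    cs <- collapse_to_sites(lib$records, map, max_dist)
    site_stats(cs$site_counts, window)
  })
  per_repeat <- lapply(stats_list, call_peaks_single, alpha = alpha)
  robust <- if (length(per_repeat) >= 2L) robust_peaks(per_repeat) else NULL
  list(per_repeat = per_repeat, robust = robust, stats = stats_list)
}
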