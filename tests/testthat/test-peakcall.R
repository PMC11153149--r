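test_that("junctions collapse to the nearest cutting site within 10 bp", {
  map <- restriction_map(list(chr1 = c(100L, 120L, 1000L)))
  rec <- make_lib(pos = c(103L, 1011L, 110L, 120L, 500L),
                  orient = rep("+", 5L))$records
  cs <- collapse_to_sites(rec, map, max_dist = 10L)
  ## 3 bp away -> assigned; 11 bp -> discarded; 10-bp tie -> leftmost;
  ## exact hit -> assigned; 380 bp -> discarded
  expect_identical(cs$site_counts$site_pos, c(100L, 120L))
  expect_identical(cs$site_counts$count, c(2L, 1L))
  expect_identical(cs$n_discarded, 2L)
  expect_identical(sum(cs$site_counts$count) + cs$n_discarded, nrow(rec))

  expect_error(collapse_to_sites(make_lib(1L, "+", chrom = "chrX")$records,
                                 map), "no sites")
})

test_that("3C preprocessing removes bait/self-ligation and region-external
           junctions and normalizes to the smallest library", {
  bait <- bait_spec("b", "chr1", 5000L, "+", 4950L, 5050L)
  region <- list(chrom = "chr1", start = 1000L, end = 100000L)
  mk <- function(n, id) {
    make_lib(pos = c(rep(5000L, 10L),      # inside exclusion -> removed
                     rep(200L, 5L),        # left of region -> removed
                     2000L + seq_len(n)),  # retained
             orient = rep("+", 15L + n), id = id)
  }
  libs <- list(mk(600L, "L1"), mk(550L, "L2"), mk(520L, "L3"))
  norm <- preprocess_3c(libs, bait, region, seed = 4L)
  expect_identical(vapply(norm, function(l) nrow(l$records), integer(1L)),
                   rep(520L, 3L))
  expect_true(all(norm[[1L]]$records$junction_pos >= 1000L))
  expect_false(any(norm[[1L]]$records$junction_pos == 5000L))
  ## deterministic given the seed
  norm2 <- preprocess_3c(libs, bait, region, seed = 4L)
  expect_identical(norm[[2L]]$records, norm2[[2L]]$records)

  empty_region <- list(chrom = "chr9", start = 0L, end = 10L)
  expect_error(preprocess_3c(libs, bait, empty_region, seed = 1L),
               "retains no junctions")
})

test_that("moving-median background matches direct truncated-window medians", {
  expect_equal(rolling_median_lambda(rep(7L, 300L), 101L), rep(7, 300L))
  ## window truncation at the edges of a short array
  expect_equal(rolling_median_lambda(c(1, 2, 100, 2, 1), 101L)[3L], 2)
  ## median robustness: a single outlier keeps lambda at the background
  expect_equal(rolling_median_lambda(c(1, 1, 100, 1), 101L)[3L], 1)
  ## direct-oracle comparison (lower-middle rule on even windows) against
  ## the runmed-accelerated implementation
  withr::with_seed(5L, {
    x <- rpois(400L, 6) + 1L
    direct <- vapply(seq_along(x), function(i) {
      w <- x[max(1L, i - 50L):min(length(x), i + 50L)]
      sort(w)[(length(w) + 1L) %/% 2L]
    }, numeric(1L))
    expect_equal(rolling_median_lambda(x, 101L), direct)
  })
  expect_error(rolling_median_lambda(numeric(0)), "empty")
  expect_error(rolling_median_lambda(1:5, 100L), "odd")
})

test_that("Poisson upper-tail probabilities are exact and monotone", {
  expect_equal(poisson_upper_p(0L, 3.7), 1)
  expect_equal(poisson_upper_p(5L, 1), 1 - exp(-1) * 65 / 24,
               tolerance = 1e-12)
  expect_equal(poisson_upper_p(5L, 1), oracle_poisson_upper(5L, 1),
               tolerance = 1e-12)
  k <- 0:30
  p <- poisson_upper_p(k, 4)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(poisson_upper_p(1L, 0), "lambda")
  expect_error(poisson_upper_p(-1L, 1), ">= 0")
})

test_that("peak calling walks to raw-P local maxima and merges overlaps", {
  mk_stats <- function(counts, lambda = 2) {
    df <- data.frame(chrom = "chr1", site_pos = 100L * seq_along(counts),
                     count = counts)
    df$lambda <- lambda
    df$raw_p <- poisson_upper_p(counts, lambda)
    df$adj_p <- pmin(1, nrow(df) * df$raw_p)
    df
  }

  ## no significant site -> no peaks
  expect_identical(nrow(call_peaks_single(mk_stats(c(2L, 3L, 2L, 1L, 2L)))), 0L)

  ## a significant site flanked by high-raw-P local maxima: the peak spans
  ## exactly those three sites with the summit at the significant site
  st <- mk_stats(c(5L, 1L, 20L, 1L, 5L, 2L, 2L))
  pk <- call_peaks_single(st)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$start, 200L)
  expect_identical(pk$end, 401L)
  expect_identical(pk$summit_pos, 300L)
  expect_identical(pk$n_sites, 3L)

  ## two summits with overlapping extension walks merge into one region
  ## keeping the lower-raw-P summit; a walk that never meets a stop ends at
  ## the array boundary
  st2 <- mk_stats(c(2L, 30L, 3L, 35L, 2L, 1L, 1L))
  pk2 <- call_peaks_single(st2)
  expect_identical(nrow(pk2), 1L)
  expect_identical(pk2$summit_pos, 400L)
  expect_identical(pk2$start, 100L)
  expect_identical(pk2$end, 701L)

  expect_error(call_peaks_single(st, alpha = 1.5), "alpha")
})

test_that("robust peaks enforce the >50% repeat-support rule", {
  a <- peak_df(100L, 200L, p = 1e-9)
  b <- peak_df(150L, 260L, p = 1e-12)
  far <- peak_df(5000L, 5100L)

  ## 3 repeats, region present in 2 -> kept with support 2, best summit kept
  r3 <- robust_peaks(list(a, b, far))
  kept <- r3[r3$start == 100L, ]
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$support, 2L)
  expect_identical(kept$end, 260L)
  expect_equal(kept$summit_raw_p, 1e-12)
  ## the far region is supported by one repeat only -> dropped
  expect_false(5000L %in% r3$start)

  ## 4 repeats, present in 2 -> dropped; present in 3 -> kept
  expect_identical(nrow(robust_peaks(list(a, b, empty_peak_df(),
                                          empty_peak_df()))), 0L)
  r4 <- robust_peaks(list(a, b, peak_df(120L, 210L), empty_peak_df()))
  expect_identical(r4$support, 3L)

  ## 2 repeats, present in 1 -> dropped
  expect_identical(nrow(robust_peaks(list(a, empty_peak_df()))), 0L)

  expect_error(robust_peaks(list(a)), "2-5")
  expect_error(robust_peaks(list(a, b, a, b, a, b)), "2-5")
})
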