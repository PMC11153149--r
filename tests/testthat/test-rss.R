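ideal12 <- function(spacer = paste(rep("T", 12L), collapse = "")) {
  paste0("CACAGTG", spacer, "ACAAAAACC")
}

test_that("mismatch scoring matches the consensus-RSS definition", {
  win12 <- paste0(ideal12(), paste(rep("G", 11L), collapse = ""))
  expect_equal(mismatch_to_ideal_rss(win12), list(spacer = 12L, mismatches = 0L))

  win23 <- paste0("CACAGTG", paste(rep("T", 23L), collapse = ""), "ACAAAAACC")
  expect_equal(mismatch_to_ideal_rss(win23), list(spacer = 23L, mismatches = 0L))

  ## heptamer position 4 plus nonamer positions 8-9 differ -> 3 mismatches
  win3 <- paste0("CACTGTG", paste(rep("T", 12L), collapse = ""), "ACAAAAAGG",
                 paste(rep("G", 11L), collapse = ""))
  got <- mismatch_to_ideal_rss(win3)
  expect_equal(got, list(spacer = 12L, mismatches = 3L))
  expect_equal(unname(oracle_score_window(win3)), c(12L, 3L))

  ## no CAC gate -> no call
  expect_null(mismatch_to_ideal_rss(paste0("G", substr(win12, 2L, 39L))))
  ## reverse-complement reading
  expect_equal(mismatch_to_ideal_rss(oracle_revcomp(win12), "-"),
               list(spacer = 12L, mismatches = 0L))
  expect_error(mismatch_to_ideal_rss("CACAGTG"), "too short")
})

test_that("scanner finds planted RSSs at the stated coordinates", {
  ## poly-G background: no CAC gate on either strand away from the plant
  bg <- paste(rep("G", 2000L), collapse = "")
  w <- ideal12()  # 28 bases: heptamer + 12-spacer + nonamer
  s <- paste0(substr(bg, 1L, 1000L), w, substr(bg, 1029L, 2000L))
  hits <- scan_unannotated_rss(c(chrA = s))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$cleavage_pos, 1000L)
  expect_identical(hits$orientation, "+")
  expect_identical(hits$spacer_class, 12L)
  expect_identical(hits$mismatches, 0L)

  ## same RSS planted as reverse complement: "-" site, cleavage at the
  ## forward coordinate of the heptamer's first base (the rightmost base of
  ## the planted 28-mer)
  s2 <- paste0(substr(bg, 1L, 1473L), oracle_revcomp(w), substr(bg, 1502L, 2000L))
  hits2 <- scan_unannotated_rss(c(chrA = s2))
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$orientation, "-")
  expect_identical(hits2$cleavage_pos, 1500L)
})

test_that("scanner equals the exhaustive brute-force oracle on random
           sequences", {
  withr::with_seed(101L, {
    for (i in 1:5) {
      s <- random_seq(3000L)
      got <- scan_unannotated_rss(c(chr = s), 4L)
      want <- oracle_scan(s, "chr", 4L)
      expect_equal(got, want)
    }
  })
})

test_that("on/off-target splitting partitions the library", {
  annotated <- data.frame(segment_id = c("V1", "V2"), chrom = "chr1",
                          rss_cleavage_pos = c(1000L, 5000L),
                          orientation = c("+", "+"))
  unannotated <- data.frame(chrom = "chr1", cleavage_pos = 3000L,
                            orientation = "+")
  lib <- make_lib(pos = c(1000L, 990L, 3005L, 7000L, 5010L, 1000L),
                  orient = c("+", "+", "+", "+", "+", "-"))
  sp <- split_on_off_target(lib, annotated, unannotated, tolerance = 50L)
  ## exact-position junction and within-tolerance junction are on-target
  expect_identical(sp$on_target$junction_pos, c(1000L, 990L, 5010L))
  expect_identical(sp$on_target$segment_id, c("V1", "V1", "V2"))
  ## 5 bp from the unannotated strong RSS -> removed
  expect_identical(sp$removed$junction_pos, 3005L)
  ## far junction and orientation-inconsistent junction are cryptic
  expect_setequal(sp$cryptic$junction_pos, c(7000L, 1000L))
  expect_identical(nrow(sp$on_target) + nrow(sp$cryptic) + nrow(sp$removed),
                   nrow(lib$records))
})

test_that("cryptic junctions collapse onto CAC sites within 15 bp", {
  cac <- data.frame(chrom = "chr1", pos = c(100L, 500L, 520L),
                    orientation = "+")
  rec <- make_lib(pos = c(100L, 105L, 112L, 130L, 510L, 560L),
                  orient = rep("+", 6L))$records
  cc <- collapse_cryptic(rec, cac, radius = 15L)
  ## offsets 0/5/12 collapse onto the CAC at 100
  p100 <- cc$peaks[cc$peaks$cac_pos == 100L, ]
  expect_identical(p100$junction_count, 3L)
  expect_setequal(p100$member_offsets[[1L]], c(0L, 5L, 12L))
  ## exact 10-bp tie between the CACs at 500 and 520 -> leftmost site
  expect_identical(cc$peaks$cac_pos[cc$peaks$junction_count == 1L], 500L)
  expect_false(520L %in% cc$peaks$cac_pos)
  ## 30 bp and 40 bp away are not collapsed
  expect_setequal(cc$unassigned$junction_pos, c(130L, 560L))
  expect_identical(sum(cc$peaks$junction_count) + nrow(cc$unassigned),
                   as.integer(nrow(rec)))
  ## orientation must match the CAC side
  rec2 <- make_lib(pos = 100L, orient = "-")$records
  cc2 <- collapse_cryptic(rec2, cac, radius = 15L)
  expect_identical(nrow(cc2$peaks), 0L)
})

test_that("orientation classification follows the convergent/same rule and
           is strand-flip symmetric", {
  expect_identical(classify_orientation("+", "-"), "deletional")
  expect_identical(classify_orientation("+", "+"), "inversional")
  expect_identical(classify_orientation("-", "+"), "deletional")
  expect_identical(classify_orientation("-", "-"), "inversional")
  combos <- expand.grid(b = c("+", "-"), p = c("+", "-"),
                        stringsAsFactors = FALSE)
  flip <- function(x) ifelse(x == "+", "-", "+")
  expect_identical(classify_orientation(combos$b, combos$p),
                   classify_orientation(flip(combos$b), flip(combos$p)))
  expect_error(classify_orientation(".", "+"), "orientation")
})

test_that("orientation fractions summarize per region across repeats", {
  rec <- rbind(
    make_lib(pos = 1:30, orient = rep("-", 30L), repeat_id = 1L)$records,
    make_lib(pos = 31:40, orient = rep("+", 10L), repeat_id = 1L)$records)
  rec$repeat_id <- 1L
  regions <- data.frame(name = c("A", "B"), chrom = "chr1",
                        start = c(0L, 5000L), end = c(100L, 6000L))
  out <- orientation_fractions(rec, regions, bait_orientation = "+")
  expect_equal(out$pct_deletional_mean[1L], 75)
  expect_equal(out$pct_inversional_mean[1L], 25)
  expect_false(out$empty[1L])
  expect_true(out$empty[2L])
  expect_true(is.na(out$pct_deletional_mean[2L]))
  bad <- data.frame(name = "X", chrom = "chrZ", start = 0L, end = 10L)
  expect_error(orientation_fractions(rec, bad, "+"), "unknown chromosome")
})
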