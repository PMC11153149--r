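test_that("synthetic loci are deterministic and closed under the RSS filter", {
  cfg <- sim_config(locus_length = 60000L, n_cryptic_pairs = 40L)
  loc <- make_synthetic_locus(cfg, seed = 11L)
  loc2 <- make_synthetic_locus(cfg, seed = 11L)
  expect_identical(as.character(loc$genome), as.character(loc2$genome))
  loc3 <- make_synthetic_locus(cfg, seed = 12L)
  expect_false(identical(as.character(loc$genome), as.character(loc3$genome)))

  ## byte-identical FASTA output for identical seeds
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(loc$genome, f1)
  write_genome_fasta(loc2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  ## the scanner returns exactly the planted bona fide set
  hits <- scan_unannotated_rss(loc$genome, 4L)
  planted <- sort(c(loc$segments$rss_cleavage_pos,
                    loc$unannotated_rss$cleavage_pos))
  expect_identical(hits$cleavage_pos, planted)
  expect_true(all(hits$orientation == "+"))

  ## every restriction-map position carries CATG
  s <- as.character(loc$genome[[1L]])
  pos <- loc$restriction_map[[cfg$chrom_name]]
  expect_true(all(substring(s, pos + 1L, pos + 4L) == "CATG"))

  ## planted cryptic sites carry a CAC in their stated orientation
  cac <- loc$cryptic_sites
  fwd <- cac$pos[cac$orientation == "+"]
  rev <- cac$pos[cac$orientation == "-"]
  expect_true(all(substring(s, fwd + 1L, fwd + 3L) == "CAC"))
  expect_true(all(substring(s, rev - 1L, rev + 1L) == "GTG"))
})

test_that("V(D)J simulation preserves totals and draws usage by strength", {
  cfg <- sim_config(mode = "diffusion", locus_length = 120000L,
                    n_segments = 2L, segment_strengths = c(3, 1),
                    n_total_reads = 150000L, junction_rate = 0.8,
                    cryptic_rate = 0.2)
  loc <- make_synthetic_locus(cfg, seed = 21L)
  lib <- simulate_vdj_library(loc, cfg, seed = 22L)
  expect_identical(total_reads(lib), 150000L)
  expect_identical(nrow(lib$records), 120000L)

  sp <- split_on_off_target(lib, loc$segments, loc$unannotated_rss, 50L)
  usage <- segment_usage(sp$on_target, loc$segments)
  ## 3:1 strengths at ~96,000 on-target draws: goodness of fit at alpha 0.01
  gof <- chisq.test(usage$absolute_count, p = c(3, 1) / 4)
  expect_gt(gof$p.value, 0.01)
  expect_equal(usage$relative_percent[1L], 75, tolerance = 1)

  ## determinism
  lib2 <- simulate_vdj_library(loc, cfg, seed = 22L)
  expect_identical(lib$records, lib2$records)
})

test_that("scanning-mode cryptic junctions are convergent and bounded by the
           impediment", {
  cfg <- sim_config(mode = "scanning", locus_length = 120000L,
                    n_total_reads = 30000L, junction_rate = 0.5,
                    cryptic_rate = 0.4)
  loc <- make_synthetic_locus(cfg, seed = 41L)
  lib <- simulate_vdj_library(loc, cfg, seed = 42L)
  sp <- split_on_off_target(lib, loc$segments, loc$unannotated_rss, 50L)
  cls <- classify_orientation(loc$bait$orientation, sp$cryptic$prey_orientation)
  expect_true(all(cls == "deletional"))
  expect_true(all(sp$cryptic$junction_pos >= cfg$scan_impediment_pos))
  expect_true(all(sp$cryptic$junction_pos <= loc$bait$cleavage_pos))

  bad <- cfg; bad$scan_impediment_pos <- 500000L
  expect_error(simulate_vdj_library(loc, bad, seed = 1L),
               "impediment position outside locus")
})

test_that("3C simulation conserves totals and scales anchors over background", {
  map <- restriction_map(list(chrS = as.integer(seq(0L, by = 200L,
                                                    length.out = 800L))))
  bait <- bait_spec("b", "chrS", 0L, "+", 0L, 50L)
  cfg <- sim_config(n_total_reads = 16000L, decay_exponent = 0,
                    selfligation_rate = 0.05,
                    anchors = data.frame(site_index = 400L, enrichment = 8))
  lib <- simulate_3c_library(map, bait, cfg, seed = 51L)
  expect_identical(nrow(lib$records), 16000L)
  ## the self-ligation spike sits inside the exclusion interval
  expect_identical(sum(lib$records$junction_pos < 50L &
                         lib$records$junction_pos != 0L), 800L)

  ## over replicates the anchor's mean count is ~8x its local background
  counts <- vapply(1:40, function(s) {
    l <- simulate_3c_library(map, bait, cfg, seed = 100L + s)
    cs <- collapse_to_sites(l$records, map)$site_counts
    anchor <- cs$count[cs$site_pos == 200L * 399L]
    bgs <- cs$count[cs$site_pos %in% (200L * c(390:398, 400:408))]
    c(anchor = sum(anchor), bg = mean(bgs))
  }, numeric(2L))
  expect_equal(mean(counts["anchor", ]) / mean(counts["bg", ]), 8,
               tolerance = 0.15)

  bad <- cfg; bad$anchors$site_index <- 5000L
  expect_error(simulate_3c_library(map, bait, bad, seed = 1L), "out of range")
  small <- restriction_map(list(chrS = c(0L, 10L)))
  expect_error(simulate_3c_library(small, bait, cfg, seed = 1L), ">= 500")
})

test_that("homogeneous 3C backgrounds follow the decay-free Poisson law", {
  ## with decay 0 and no anchors, site counts are exchangeable multinomial
  ## allocations: mean ~ n/sites, variance close to Poisson
  map <- restriction_map(list(chrS = as.integer(seq(0L, by = 100L,
                                                    length.out = 600L))))
  bait <- bait_spec("b", "chrS", 0L, "+", 0L, 10L)
  cfg <- sim_config(n_total_reads = 12000L, decay_exponent = 0,
                    selfligation_rate = 0)
  l <- simulate_3c_library(map, bait, cfg, seed = 61L)
  cs <- collapse_to_sites(l$records, map)$site_counts
  expect_equal(sum(cs$count), 12000L)
  expect_equal(mean(cs$count) * nrow(cs) / 600L, 20, tolerance = 0.01)

  ## power-law decay: distant sites receive fewer junctions
  cfg2 <- sim_config(n_total_reads = 50000L, decay_exponent = 1,
                     selfligation_rate = 0)
  l2 <- simulate_3c_library(map, bait, cfg2, seed = 62L)
  p <- l2$records$junction_pos
  expect_gt(sum(p < 10000L), 5 * sum(p >= 50000L))
})
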