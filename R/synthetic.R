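# Seeded synthetic-data generators.  They emulate the statistical structure
# the analysis assumes -- a kappa-like locus with an array of V-like segments
# upstream of a recombination centre (RC), planted cryptic CAC sites with
# scanning- or diffusion-mode accessibility, CATG restriction sites with a
# distance-decaying bait contact background, and annotation features -- so
# that every downstream stage can be tested against planted truth.

#' Synthetic CTCF-like position count matrix
#'
#' A sharp width-19 count matrix (997 counts on the consensus base, 1
#' elsewhere) used to plant and detect CBE features on synthetic loci.  It is
#' a synthetic stand-in, not the JASPAR MA0139.1 record.
#'
#' @return 4 x 19 count matrix with rownames A/C/G/T; consensus string as
#'   attribute `"consensus"`.
#' @export
synthetic_ctcf_pcm <- function() {
  consensus <- "CCAGCAGGGGGCAGCTGTT"
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  m <- matrix(1, nrow = 4L, ncol = length(cons), dimnames = list(bases, NULL))
  m[cbind(match(cons, bases), seq_along(cons))] <- 997
  attr(m, "consensus") <- consensus
  m
}

## Consensus 39-mer comparison template in site orientation: NA at free
## (spacer) positions.
rss_consensus_template <- function() {
  cons <- rep(NA_character_, 39L)
  cons[1:3] <- c("C", "A", "C")
  cons[4:7] <- IDEAL_HEPTAMER_TAIL
  cons[20:28] <- IDEAL_NONAMER
  cons[31:39] <- IDEAL_NONAMER
  cons
}

next_base <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[b]

#' Generate a synthetic locus
#'
#' Draws a random background sequence and plants, without overlap: CATG
#' restriction sites on a regular grid, bona fide consensus RSSs at segment
#' positions, unannotated bona fide RSSs (2 mismatches, not in the segment
#' catalog), bare cryptic CAC sites as convergent pairs, and CBE motif
#' sequences at CBE features.  Any accidental background window that would
#' pass the 4-mismatch bona fide filter is rewritten, so
#' [scan_unannotated_rss()] on the emitted genome returns exactly the planted
#' bona fide sites.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same (config, seed) pair yields a
#'   byte-identical genome.
#' @return An object of class `synthetic_locus`: list with `genome`,
#'   `segments`, `unannotated_rss`, `cryptic_sites`, `restriction_map`,
#'   `features`, `bait`, `config`.
#' @export
make_synthetic_locus <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    L <- config$locus_length
    chrom <- config$chrom_name
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    protected <- logical(L)
    footprints <- data.frame(start = integer(), end = integer())

    overlaps_any <- function(s, e, margin = 0L) {
      any(footprints$start < e + margin & s - margin < footprints$end)
    }
    reserve <- function(s, e, protect = TRUE) {
      if (s < 0L || e > L) stopf("planted element outside locus [%d, %d)", s, e)
      if (overlaps_any(s, e)) stopf("planted elements overlapping at [%d, %d)", s, e)
      footprints[nrow(footprints) + 1L, ] <<- c(s, e)
      if (protect) protected[(s + 1L):e] <<- TRUE
      invisible(NULL)
    }
    write_seq <- function(s, what) {  # 0-based start
      ch[(s + 1L):(s + nchar(what))] <<- strsplit(what, "", fixed = TRUE)[[1L]]
    }

    bait_pos <- as.integer(round(0.9 * L))
    bait <- bait_spec("RC_bait", chrom, bait_pos, "-",
                      bait_pos - 75L, bait_pos + 75L)
    reserve(bait_pos - 75L, bait_pos + 75L, protect = FALSE)

    ## bona fide segment RSSs (12RSS, "+": convergent with the "-" bait)
    seg_lo <- as.integer(round(0.30 * L)); seg_hi <- as.integer(round(0.80 * L))
    seg_pos <- as.integer(round(seq(seg_lo, seg_hi,
                                    length.out = config$n_segments)))
    spacer12 <- function() paste(sample(c("A", "G", "T"), 12L, TRUE), collapse = "")
    for (p in seg_pos) {
      reserve(p - 10L, p + 38L)
      write_seq(p, paste0("CACAGTG", spacer12(), paste(IDEAL_NONAMER, collapse = "")))
    }
    thirds <- stats::quantile(seg_pos, c(1 / 3, 2 / 3))
    segments <- data.frame(
      segment_id = sprintf("V%02d", seq_along(seg_pos)), chrom = chrom,
      rss_cleavage_pos = seg_pos, orientation = "+", rss_kind = 12L,
      strength = config$segment_strengths,
      domain_label = ifelse(seg_pos <= thirds[1L], "distal",
                            ifelse(seg_pos <= thirds[2L], "middle", "proximal")))

    ## unannotated bona fide RSSs (2 nonamer mismatches), between segments
    una_pos <- integer(0)
    if (config$n_unannotated_rss > 0L) {
      una_pos <- as.integer(round(seq(seg_lo + 1500L, seg_hi - 1500L,
                                      length.out = config$n_unannotated_rss + 2L)))
      una_pos <- una_pos[c(-1L, -length(una_pos))]
      for (p in una_pos) {
        reserve(p - 10L, p + 38L)
        write_seq(p, paste0("CACAGTG", spacer12(), "ACAAAAAGG"))
      }
    }
    unannotated <- data.frame(chrom = character(0), cleavage_pos = integer(0),
                              orientation = character(0))
    if (length(una_pos)) {
      unannotated <- data.frame(chrom = chrom, cleavage_pos = una_pos,
                                orientation = "+", spacer_class = 12L,
                                mismatches = 2L)
    }

    ## annotation features; CBE features get motif-matching sequence
    features <- config$features %||%
      data.frame(type = character(), pos = integer(), strand = character())
    pcm <- synthetic_ctcf_pcm()
    consensus <- attr(pcm, "consensus")
    for (i in seq_len(nrow(features))) {
      p <- as.integer(features$pos[i])
      if (features$type[i] == "CBE") {
        reserve(p, p + nchar(consensus))
        write_seq(p, if ((features$strand[i] %||% "+") == "-")
          revcomp(consensus) else consensus)
      } else {
        reserve(p - 50L, p + 50L, protect = FALSE)
      }
    }

    ## cryptic CAC sites, planted as convergent +/- pairs 40 bp apart
    cry_lo <- as.integer(round(0.05 * L)); cry_hi <- bait_pos - 2000L
    cpos <- integer(0); corient <- character(0); cpair <- integer(0)
    tries <- 0L
    while (length(cpair) < 2L * config$n_cryptic_pairs) {
      tries <- tries + 1L
      if (tries > 50L * config$n_cryptic_pairs) {
        stopf("could not place cryptic CAC pairs without overlap")
      }
      q <- sample(cry_lo:cry_hi, 1L)
      if (overlaps_any(q - 5L, q + 48L, margin = 60L)) next
      reserve(q, q + 3L)            # "+" CAC at cleavage q
      reserve(q + 38L, q + 41L)     # "-" CAC at cleavage q + 40
      write_seq(q, "CAC")
      write_seq(q + 38L, "GTG")
      k <- length(cpair) %/% 2L + 1L
      cpos <- c(cpos, q, q + 40L)
      corient <- c(corient, "+", "-")
      cpair <- c(cpair, k, k)
    }
    cryptic <- data.frame(chrom = chrom, pos = cpos, orientation = corient,
                          pair_id = cpair)
    cryptic <- cryptic[order(cryptic$pos), , drop = FALSE]
    rownames(cryptic) <- NULL

    ## CATG restriction-site grid (skipping planted footprints)
    grid <- seq(100L, L - 104L, by = config$catg_spacing)
    for (g in grid) {
      if (!overlaps_any(g, g + 4L)) write_seq(g, "CATG")
    }

    ## rewrite accidental windows that pass the bona fide filter
    expected_key <- c(paste(segments$rss_cleavage_pos, "+"),
                      if (nrow(unannotated)) paste(unannotated$cleavage_pos, "+"))
    cons39 <- rss_consensus_template()
    for (iter in seq_len(25L)) {
      genome <- Biostrings::DNAStringSet(structure(paste(ch, collapse = ""),
                                                   names = chrom))
      hits <- scan_unannotated_rss(genome, 4L)
      extr <- hits[!paste(hits$cleavage_pos, hits$orientation) %in% expected_key, ,
                   drop = FALSE]
      if (!nrow(extr)) break
      if (iter == 25L) stopf("failed to rewrite accidental bona fide RSSs")
      for (j in seq_len(nrow(extr))) {
        c0 <- extr$cleavage_pos[j]; ori <- extr$orientation[j]
        fwd_pos <- function(k0) if (ori == "+") c0 + k0 else c0 - k0
        win <- vapply(0:38, function(k0) {
          b <- ch[fwd_pos(k0) + 1L]
          if (ori == "+") b else chartr("ACGTN", "TGCAN", b)
        }, character(1L))
        cand <- which(!is.na(cons39) & win == cons39)  # 1-based window offset
        cand <- cand[!protected[fwd_pos(cand - 1L) + 1L]]
        ## prefer breaking the CAC gate (one edit kills both spacer variants)
        gate <- cand[cand <= 3L]
        pick <- if (length(gate)) gate[1L] else cand
        for (k in pick[seq_len(min(2L, length(pick)))]) {
          fp <- fwd_pos(k - 1L)
          cur <- ch[fp + 1L]
          ch[fp + 1L] <- next_base(cur)
        }
      }
    }

    genome <- Biostrings::DNAStringSet(structure(paste(ch, collapse = ""),
                                                 names = chrom))
    structure(list(genome = genome, segments = segments,
                   unannotated_rss = unannotated, cryptic_sites = cryptic,
                   restriction_map = build_restriction_map(genome),
                   features = features, bait = bait, config = config),
              class = "synthetic_locus")
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_locus> %s (%d bp): %d segments, %d cryptic ",
                     "CACs, %d restriction sites, %d features\n"),
              x$config$chrom_name, x$config$locus_length, nrow(x$segments),
              nrow(x$cryptic_sites), length(x$restriction_map[[1L]]),
              nrow(x$features)))
  invisible(x)
}

#' Simulate an HTGTS-V(D)J-seq junction library
#'
#' On-target junctions are drawn multinomially over segments with probability
#' proportional to segment strength; cryptic junctions are drawn over planted
#' CAC sites with mode-dependent accessibility -- scanning mode allows only
#' convergent-orientation CACs between the RC and the impediment with
#' exponentially decaying intensity, diffusion mode allows both orientations
#' within a radius of the RC (eligibility assessed per convergent CAC pair so
#' the generator's orientation symmetry is exact).  Junction positions are
#' jittered by a coding-end resection offset uniform on [0, 15) bp toward the
#' coding flank; remaining reads are germline.
#'
#' @param locus A `synthetic_locus`.
#' @param config A [sim_config()] (defaults to the locus config).
#' @param seed Integer seed.
#' @param library_id,repeat_id Library labels.
#' @return A [junction_library()].
#' @export
simulate_vdj_library <- function(locus, config = locus$config, seed,
                                 library_id = "sim_vdj", repeat_id = 1L) {
  stopifnot(inherits(locus, "synthetic_locus"))
  L <- config$locus_length
  bait <- locus$bait
  withr::with_seed(seed, {
    n_total <- config$n_total_reads
    if (n_total <= 0L) stopf("n_total_reads must be > 0")
    n_junc <- as.integer(round(n_total * config$junction_rate))
    n_cry <- as.integer(round(n_junc * config$cryptic_rate))
    n_on <- n_junc - n_cry
    segs <- locus$segments
    if (!nrow(segs)) stopf("segment catalog is empty")

    resect <- function(cleave, orient, n) {
      off <- sample.int(15L, n, replace = TRUE) - 1L
      ifelse(orient == "+", cleave - off, cleave + off)
    }

    si <- sample.int(nrow(segs), n_on, replace = TRUE, prob = segs$strength)
    on_df <- data.frame(chrom = segs$chrom[si],
                        junction_pos = resect(segs$rss_cleavage_pos[si],
                                              segs$orientation[si], n_on),
                        prey_orientation = segs$orientation[si])

    cac <- locus$cryptic_sites
    cac$pair_mid <- stats::ave(cac$pos, cac$pair_id)
    if (config$mode == "scanning") {
      imp <- config$scan_impediment_pos
      if (imp < 0L || imp >= L) stopf("impediment position outside locus")
      lo <- min(bait$cleavage_pos, imp); hi <- max(bait$cleavage_pos, imp)
      ## 15-bp buffer: resection jitter must not carry a junction past the
      ## impediment
      elig <- cac$orientation != bait$orientation &
        cac$pos >= lo + 15L & cac$pos <= hi - 15L
      wgt <- exp(-abs(cac$pos - bait$cleavage_pos) / config$scan_decay_bp)
    } else {
      elig <- abs(cac$pair_mid - bait$cleavage_pos) <= config$diffusion_radius
      wgt <- rep(1, nrow(cac))
    }
    if (n_cry > 0L && !any(elig)) stopf("no eligible cryptic CAC sites")
    ei <- which(elig)
    ci <- ei[sample.int(length(ei), n_cry, replace = TRUE, prob = wgt[ei])]
    cry_df <- data.frame(chrom = cac$chrom[ci],
                         junction_pos = resect(cac$pos[ci],
                                               cac$orientation[ci], n_cry),
                         prey_orientation = cac$orientation[ci])

    records <- rbind(on_df, cry_df)
    records$bait_id <- bait$bait_id
    records$read_id <- sprintf("r%07d", seq_len(nrow(records)))
    junction_library(records, n_total - n_junc, library_id, bait = bait,
                     repeat_id = repeat_id)
  })
}

#' Simulate a 3C-HTGTS junction library
#'
#' Per-site rates follow a power-law contact decay
#' `lambda(d) = (1 + d)^-decay_exponent` in distance from the bait, scaled to
#' the requested library size and multiplied by planted anchor enrichment
#' factors; junction counts are the multinomial allocation of the library
#' total over sites.  A self-ligation spike is placed inside the bait
#' exclusion interval.  Junction positions sit exactly at restriction-site
#' coordinates unless `jitter_3c > 0`.
#'
#' @param map A `restriction_map` with at least 500 sites on the bait
#'   chromosome.
#' @param bait A [bait_spec()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param library_id,repeat_id Library labels.
#' @return A [junction_library()] with `config$n_total_reads` junctions.
#' @export
simulate_3c_library <- function(map, bait, config, seed,
                                library_id = "sim_3c", repeat_id = 1L) {
  stopifnot(inherits(map, "restriction_map"))
  sites <- map[[bait$chrom]]
  if (is.null(sites)) stopf("map has no sites on bait chromosome '%s'", bait$chrom)
  if (length(sites) < 500L) {
    stopf("need >= 500 restriction sites in region, got %d", length(sites))
  }
  anchors <- config$anchors
  if (nrow(anchors) &&
      (any(anchors$site_index < 1L) || any(anchors$site_index > length(sites)))) {
    stopf("anchor site index out of range")
  }
  withr::with_seed(seed, {
    d <- abs(sites - bait$cleavage_pos)
    lam <- (1 + d)^(-config$decay_exponent)
    if (nrow(anchors)) {
      lam[anchors$site_index] <- lam[anchors$site_index] * anchors$enrichment
    }
    n <- config$n_total_reads
    n_self <- as.integer(round(config$selfligation_rate * n))
    counts <- as.integer(stats::rmultinom(1L, n - n_self, lam / sum(lam)))
    pos <- rep(sites, counts)
    if (config$jitter_3c > 0L) {
      pos <- pos + sample(seq(-config$jitter_3c, config$jitter_3c),
                          length(pos), replace = TRUE)
      pos <- pmax(0L, pos)
    }
    if (n_self > 0L) {
      spike <- (bait$exclusion_start + bait$exclusion_end) %/% 2L
      pos <- c(rep(spike, n_self), pos)
    }
    records <- data.frame(chrom = bait$chrom, junction_pos = pos,
                          prey_orientation = sample(c("+", "-"), length(pos),
                                                    replace = TRUE),
                          bait_id = bait$bait_id,
                          read_id = sprintf("r%07d", seq_along(pos)))
    junction_library(records, 0L, library_id, bait = bait,
                     repeat_id = repeat_id)
  })
}

#' Simulate annotation tracks for a synthetic locus
#'
#' Planted CBE features receive ChIP peaks in at least the first two repeats
#' (later repeats with probability 0.8); planted E2A features receive track
#' maxima of 1.5 (>= the 0.5 call threshold); planted transcription features
#' receive GRO maxima of 45 (>= 40) in at least two repeats.  Away from
#' features the tracks carry sub-threshold noise (E2A < 0.2, GRO < 5), plus
#' repeat-specific random ChIP noise peaks.
#'
#' @param locus A `synthetic_locus`.
#' @param seed Integer seed.
#' @param n_repeats Number of ChIP / GRO repeats (default 3).
#' @return `list(chip_peaks, e2a, gro)`: per-repeat peak `data.frame`s, an
#'   E2A [signal_track()], and per-repeat GRO [signal_track()]s.
#' @export
simulate_tracks <- function(locus, seed, n_repeats = 3L) {
  stopifnot(inherits(locus, "synthetic_locus"))
  config <- locus$config
  L <- config$locus_length; chrom <- config$chrom_name
  features <- locus$features
  if (any(features$pos < 0L | features$pos >= L)) {
    stopf("feature coordinates outside locus")
  }
  withr::with_seed(seed, {
    binw <- 100L
    bs <- seq(0L, L - binw, by = binw)
    paint <- function(baseline_max, windows, value) {
      v <- stats::runif(length(bs), 0, baseline_max)
      for (i in seq_len(nrow(windows))) {
        sel <- bs + binw > windows$start[i] & bs < windows$end[i]
        v[sel] <- value
      }
      signal_track(data.frame(chrom = chrom, start = bs, end = bs + binw,
                              value = v))
    }
    feat_win <- function(type, pad) {
      f <- features[features$type == type, , drop = FALSE]
      data.frame(start = f$pos - pad, end = f$pos + pad)
    }

    cbe <- features[features$type == "CBE", , drop = FALSE]
    chip_peaks <- lapply(seq_len(n_repeats), function(r) {
      keep <- if (r <= 2L) rep(TRUE, nrow(cbe)) else
        stats::runif(nrow(cbe)) < 0.8
      planted <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0))
      if (any(keep)) {
        planted <- data.frame(chrom = chrom, start = cbe$pos[keep] - 200L,
                              end = cbe$pos[keep] + 220L)
      }
      noise_pos <- sample.int(L - 400L, 5L)
      rbind(planted, data.frame(chrom = chrom, start = noise_pos,
                                end = noise_pos + 400L))
    })

    e2a <- paint(0.2, feat_win("E2A", 100L), 1.5)
    txn <- feat_win("TXN", 300L)
    gro <- lapply(seq_len(n_repeats), function(r) {
      keep <- if (r <= 2L) rep(TRUE, nrow(txn)) else
        stats::runif(nrow(txn)) < 0.8
      paint(5, txn[keep, , drop = FALSE], 45)
    })
    list(chip_peaks = chip_peaks, e2a = e2a, gro = gro)
  })
}
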