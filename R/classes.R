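#' Bait specification
#'
#' Describes the fixed bait of a bait-anchored junction library: the cleavage
#' position of the bait RSS (HTGTS-V(D)J-seq) or the bait restriction fragment
#' (3C-HTGTS), its orientation, and the self-ligation exclusion interval whose
#' junctions are removed before normalization.
#'
#' @param bait_id Character label for the bait.
#' @param chrom Chromosome the bait lies on.
#' @param cleavage_pos Bait cleavage coordinate (0-based).
#' @param orientation `"+"` or `"-"`; direction the bait RSS reads
#'   heptamer-to-nonamer on the forward strand.
#' @param exclusion_start,exclusion_end Self-ligation exclusion interval
#'   (0-based half-open) on the bait chromosome; junctions inside it are
#'   removed during 3C preprocessing.
#' @return An object of class `bait_spec`.
#' @export
bait_spec <- function(bait_id, chrom, cleavage_pos, orientation,
                      exclusion_start, exclusion_end) {
  check_orientation(orientation, "bait orientation")
  if (exclusion_end <= exclusion_start) {
    stopf("bait exclusion interval must be nonempty (got [%s, %s))",
          exclusion_start, exclusion_end)
  }
  if (cleavage_pos < 0) stopf("bait cleavage_pos must be >= 0")
  structure(list(bait_id = as.character(bait_id), chrom = as.character(chrom),
                 cleavage_pos = as.integer(cleavage_pos),
                 orientation = orientation,
                 exclusion_start = as.integer(exclusion_start),
                 exclusion_end = as.integer(exclusion_end)),
            class = "bait_spec")
}

#' @export
print.bait_spec <- function(x, ...) {
  cat(sprintf("<bait_spec> %s %s:%d (%s), exclusion [%d, %d)\n", x$bait_id,
              x$chrom, x$cleavage_pos, x$orientation,
              x$exclusion_start, x$exclusion_end))
  invisible(x)
}

#' Junction library
#'
#' One sequencing library's bait-anchored junctions plus its germline read
#' count.  Germline (unjoined bait-side) reads carry no position information
#' and only their total matters for normalization, so they are stored as a
#' count rather than as records.
#'
#' @param records `data.frame` with columns `chrom`, `junction_pos`
#'   (0-based), `prey_orientation` (`"+"`/`"-"`), `bait_id`, `read_id`.
#' @param germline_read_count Nonnegative number of germline reads.
#' @param library_id Character label.
#' @param bait Optional [bait_spec()].
#' @param repeat_id Biological repeat label (integer or character).
#' @return An object of class `junction_library`.
#' @export
junction_library <- function(records, germline_read_count, library_id,
                             bait = NULL, repeat_id = NA) {
  req <- c("chrom", "junction_pos", "prey_orientation", "bait_id", "read_id")
  miss <- setdiff(req, names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[, req]
  records$junction_pos <- as.integer(records$junction_pos)
  if (any(is.na(records$junction_pos)) || any(records$junction_pos < 0)) {
    stopf("junction_pos must be nonnegative integers")
  }
  check_orientation(records$prey_orientation, "prey_orientation")
  germline_read_count <- as.integer(germline_read_count)
  if (is.na(germline_read_count) || germline_read_count < 0) {
    stopf("germline_read_count must be a nonnegative integer")
  }
  structure(list(records = records,
                 germline_read_count = germline_read_count,
                 library_id = as.character(library_id),
                 bait = bait, repeat_id = repeat_id),
            class = "junction_library")
}

#' Total reads of a junction library (junctions + germline reads)
#' @param lib A [junction_library()].
#' @return Integer total read count.
#' @export
total_reads <- function(lib) {
  stopifnot(inherits(lib, "junction_library"))
  nrow(lib$records) + lib$germline_read_count
}

#' @export
print.junction_library <- function(x, ...) {
  cat(sprintf("<junction_library> %s: %d junctions + %d germline reads (repeat %s)\n",
              x$library_id, nrow(x$records), x$germline_read_count,
              as.character(x$repeat_id)))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic locus and library generators.  The generator
#' emulates a kappa-like light-chain locus: an array of V segments bearing
#' 12RSSs upstream of a recombination centre (RC, the bait), an impediment
#' element between them (scanning mode), planted cryptic CAC sites, planted
#' CATG restriction sites and annotation features.
#'
#' @param mode `"scanning"` (loop-extrusion presentation: convergent-only
#'   cryptic joins between the RC and the impediment, intensity decaying with
#'   distance) or `"diffusion"` (both orientations within a radius of the RC).
#' @param locus_length Locus length in bp (>= 50 kb).
#' @param chrom_name Chromosome name of the synthetic locus.
#' @param catg_spacing Mean spacing (bp) of planted CATG restriction sites.
#' @param n_segments Number of bona fide V-like segments.
#' @param segment_strengths Nonnegative utilization weights, recycled to
#'   `n_segments`.
#' @param n_unannotated_rss Number of planted unannotated bona fide RSSs
#'   (2 mismatches to consensus; not in the segment catalog).
#' @param n_cryptic_pairs Number of planted convergent cryptic CAC pairs.
#' @param n_total_reads Total reads per simulated library
#'   (junctions + germline for V(D)J; junctions for 3C).
#' @param junction_rate Fraction of V(D)J reads that are junctions.
#' @param cryptic_rate Fraction of junctions that are RAG off-targets.
#' @param scan_impediment_pos Impediment coordinate (bp); scanning-mode
#'   cryptic joins do not pass it.  Default: 20% of the locus.
#' @param scan_decay_bp Length scale (bp) of the exponential decay of
#'   scanning intensity with distance from the RC.
#' @param diffusion_radius Radius (bp) of diffusion-mode accessibility.
#' @param decay_exponent Exponent of the 3C power-law background
#'   `lambda(d) ~ (1 + d)^-decay_exponent`; 0 gives a homogeneous background.
#' @param anchors `data.frame(site_index, enrichment)`: planted 3C anchor
#'   enrichments (factors >= 1) at restriction-site indices.
#' @param selfligation_rate Fraction of 3C junctions placed as a
#'   self-ligation spike inside the bait exclusion interval.
#' @param jitter_3c Maximum absolute jitter (bp, <= 3) of 3C junction
#'   positions around restriction sites.
#' @param features `data.frame(type, pos, strand)` of planted annotation
#'   features; `type` in `"CBE"`, `"E2A"`, `"TXN"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = c("scanning", "diffusion"),
                       locus_length = 200000L,
                       chrom_name = "chrSim",
                       catg_spacing = 150L,
                       n_segments = 8L,
                       segment_strengths = 1,
                       n_unannotated_rss = 2L,
                       n_cryptic_pairs = 150L,
                       n_total_reads = 600000L,
                       junction_rate = 0.25,
                       cryptic_rate = 0.05,
                       scan_impediment_pos = NULL,
                       scan_decay_bp = 20000,
                       diffusion_radius = 25000,
                       decay_exponent = 1,
                       anchors = data.frame(site_index = integer(),
                                            enrichment = numeric()),
                       selfligation_rate = 0.05,
                       jitter_3c = 0L,
                       features = NULL) {
  mode <- match.arg(mode)
  locus_length <- as.integer(locus_length)
  if (locus_length < 50000L) stopf("locus_length must be >= 50 kb")
  if (is.null(scan_impediment_pos)) {
    scan_impediment_pos <- as.integer(round(0.2 * locus_length))
  }
  for (p in c(junction_rate, cryptic_rate, selfligation_rate)) {
    if (p < 0 || p > 1) stopf("rates must lie in [0, 1]")
  }
  if (nrow(anchors)) {
    if (!all(c("site_index", "enrichment") %in% names(anchors))) {
      stopf("anchors needs columns site_index and enrichment")
    }
    if (any(anchors$enrichment < 1)) stopf("anchor enrichment factors must be >= 1")
  }
  if (jitter_3c > 3L) stopf("jitter_3c must be <= 3 bp")
  segment_strengths <- rep_len(segment_strengths, n_segments)
  if (any(segment_strengths < 0)) stopf("segment strengths must be >= 0")
  structure(list(mode = mode, locus_length = locus_length,
                 chrom_name = chrom_name, catg_spacing = as.integer(catg_spacing),
                 n_segments = as.integer(n_segments),
                 segment_strengths = segment_strengths,
                 n_unannotated_rss = as.integer(n_unannotated_rss),
                 n_cryptic_pairs = as.integer(n_cryptic_pairs),
                 n_total_reads = as.integer(n_total_reads),
                 junction_rate = junction_rate, cryptic_rate = cryptic_rate,
                 scan_impediment_pos = as.integer(scan_impediment_pos),
                 scan_decay_bp = scan_decay_bp,
                 diffusion_radius = diffusion_radius,
                 decay_exponent = decay_exponent, anchors = anchors,
                 selfligation_rate = selfligation_rate,
                 jitter_3c = as.integer(jitter_3c),
                 features = features),
            class = "sim_config")
}
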