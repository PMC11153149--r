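---
title: "Methods: junction analysis for HTGTS-V(D)J-seq and 3C-HTGTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction analysis for HTGTS-V(D)J-seq and 3C-HTGTS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `vdjscan`, in the spirit of the methods sections of the
established differential-expression and ordination packages: what each stage
assumes, which knobs matter, and what the synthetic-data tests do and do not
establish about real libraries.

## Background and coordinate conventions

V(D)J recombination assembles antigen-receptor genes by RAG cleavage at
recombination signal sequences (RSSs): a conserved heptamer (consensus
`CACAGTG`), a 12- or 23-bp spacer, and a nonamer (consensus `ACAAAAACC`).
RAG loaded at a recombination centre (RC) captures partner RSSs either by
cohesin-mediated loop extrusion ("scanning", which presents chromatin
linearly and favours convergent joins that stop at impediments such as CBEs)
or by 3D diffusion (orientation-agnostic, distance-limited).  Bait-anchored
junction sequencing reads this out: HTGTS-V(D)J-seq recovers every junction
to a fixed RSS bait; 3C-HTGTS recovers restriction-fragment contacts of a
fixed bait fragment.

All internal coordinates are 0-based half-open.  BED and bedGraph files keep
their native 0-based half-open convention; the project junction-table and
catalog TSVs carry 1-based positions and are converted on read.  The
*cleavage position* of an RSS or bare CAC is the first base of the heptamer
read in the site's orientation — the base adjacent to the coding flank.
No universal base-level convention exists for where "the CAC cleavage site"
sits, so one convention had to be fixed; it is used consistently by the
scanner, the generator and the collapser.

## Cryptic-RSS analysis

`mismatch_to_ideal_rss()` scores a 39-base window: no call unless it starts
with `CAC` (the invariant cleavage triplet); otherwise the mismatch count is
the Hamming distance of heptamer positions 4–7 to `AGTG` plus the 9 bases
after a 12- or 23-bp spacer to `ACAAAAACC` — 13 compared positions, 0–13
mismatches.  Both spacer lengths are always evaluated and the smaller count
kept; ties are resolved toward the 12-spacer.  The tie rule is a package
convention (the filter definition names both spacers without ordering
them); it only affects the reported spacer class, never whether a site
passes the ≤ 4-mismatch filter.

`scan_unannotated_rss()` applies this at every position and orientation.
Sites at ≤ 4 mismatches behave as bona fide RSSs even when not associated
with annotated segments, and junctions near them are *removed* from cryptic
analyses rather than counted as off-targets.  Removal is applied at the
junction level before collapsing (the conservative reading of site-level
elimination); the alternative — dropping whole collapsed peaks — would only
differ when a peak mixes removed and genuine cryptic junctions, which the
50-bp assignment tolerance makes rare.

On-target assignment uses a 50-bp tolerance (configurable): coding-end
resection spreads junctions around the cleavage site, and the upstream
alignment pipeline's exact assignment rule is not part of this package.  A
junction must also match the catalog RSS's orientation, since the recovered
prey orientation is the orientation of the RSS that was cleaved.

`collapse_cryptic()` assigns each cryptic junction to the nearest
same-orientation CAC within 15 bp (exact ties to the leftmost site — a
deterministic, position-stable rule), maps the peak to the CAC cleavage
coordinate, and reports junctions near no CAC separately so counts are
always conserved.

Orientation classification is purely binary: prey convergent with the bait
RSS → deletional, same orientation → inversional.  Divergent prey
(opposite strand, facing away) therefore classify as deletional; the
scanning/diffusion contrast rests only on the convergent/same dichotomy.

## Usage quantification

Down-sampling to a fixed total (default 500,000 reads) treats junction
records and germline pseudo-reads as one urn and samples without
replacement, so the junction/germline split is hypergeometric and relative
per-segment usage is unchanged in expectation.  Germline reads are carried
as a count, not as records: only their total enters any downstream rule.

`pearson_usage()` reports the product-moment *r* with the two-sided
parametric *p* from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom;
`welch_test()` uses the Welch statistic with Welch–Satterthwaite degrees of
freedom.  Both are deliberately plain direct-formula implementations so the
test suite can verify them against R's `cor.test()`/`t.test()` as
independent oracles to 1e-12.  s.e.m. uses the $n-1$ sample standard
deviation over biological repeats and is defined as 0 for a single repeat.

`binned_profile()` divides the plotting region into 1,000 (or 200) equal
half-open bins — integer bin width, the last bin absorbing the remainder —
and takes the per-repeat *maximum* per bin before averaging across repeats,
which preserves narrow peaks that per-bin means would dilute.

## 3C-HTGTS peak calling

3C-HTGTS junctions concentrate at restriction sites, so signals are first
collapsed onto CATG (NlaIII) sites; junctions more than 10 bp from any site
are discarded (equidistant ties go to the leftmost site).  Preprocessing
removes junctions in the bait self-ligation exclusion interval (the high
peaks upstream of the bait dominated by circularization), restricts to the
locus region, and down-samples every library to the smallest retained
junction count — the same smallest-library convention used for the original
libraries' fixed normalization total.

Only signal-bearing sites (count ≥ 1) are tested.  The background rate at
each site is the median count over a window of 101 tested sites (50 each
side), a deliberately conservative over-estimate of the local Poisson rate:
enriched neighbours inflate the median, never deflate it, biasing the
caller against false positives.  At array edges the window truncates; an
even-sized truncated window takes the *lower* middle value, keeping λ
integral and again conservative.  Since tested counts are ≥ 1, λ ≥ 1
always.  The interior of the window is computed with `stats::runmed`; edges
directly.

The site test is the upper-tail Poisson probability P(X ≥ k) — the standard
enrichment convention.  Multiplicity is corrected by Bonferroni with m =
the number of tested sites in the region of that library (junctions are
restricted to the region first, so per-region correction is the natural
scope).  Summits require adjusted P < 0.05.  The peak range extends from
the summit outward to the first tested site that is a strict local maximum
of raw P *and* has raw P ≥ 0.05; those stop sites are included in the span
(reaching a stop site reads as arriving at it).  At the array boundary a
stop needs only to exceed its single inner neighbour, and a walk that never
meets a stop ends at the last tested site, so the walk always terminates.
Overlapping regions merge, keeping the lowest-raw-P summit (ties to the
leftmost).  Robust peaks across 2–5 repeats require support from more than
half the repeats — ≥ 2 of 2–3, ≥ 3 of 4–5 — with the best summit among
supporting repeats reported.

## Peak annotation

Each robust peak ± 1 kb (half-open arithmetic, clipped at position 0) is
annotated with: reliable CBEs (log-odds motif score > 13 *and* CTCF ChIP
peaks in ≥ 2 repeats; orientations reported rightward/leftward), E2A
binding (window maximum ≥ 0.5), and transcription.  The transcription rule
applies the max/mean disjunction per repeat — a repeat supports
transcription when its window maximum is ≥ 40 *or* its window mean is ≥ 10
— and requires ≥ 2 supporting repeats; this is the most direct reading of
the rule's phrasing.  Window means count uncovered bases as 0 (whole-window
average; configurable in principle but fixed here).  Peaks with no feature
are labelled U.

The motif scanner is a generic log-odds PWM scorer with a pseudocount of
1 % of each column total: $\sum_i \log_2\frac{(c_{i,b}+\varepsilon_i)/
(T_i+4\varepsilon_i)}{0.25}$.  The "> 13" default threshold is retained as
the configurable cutoff, with the caveat that it is calibrated to the
FIMO/JASPAR scale of the original analysis and a generic scanner's scale is
not guaranteed identical.  The shipped motif
(`inst/extdata/synthetic_ctcf.jaspar`, `synthetic_ctcf_pcm()`) is a sharp
*synthetic* CTCF-like matrix used to plant and recover CBE features on
synthetic loci; analyses of real data should supply the actual JASPAR
record.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
any particular locus:

- **Locus.** Random sequence (default 200 kb) with planted CATG sites on a
  ~150-bp grid (plus whatever CATGs occur by chance — the restriction map is
  computed from the final sequence, so it is exact by construction), eight
  consensus 12RSS segments in the middle 30–80 % of the locus, two
  unannotated bona fide RSSs at 2 mismatches, and bare cryptic CAC sites.
  Any accidental background window passing the ≤ 4-mismatch filter is
  rewritten (preferring a single edit that destroys the CAC gate), so the
  planted catalog is *exactly* the scanner's expected output and oracle
  equality tests are possible.  Planted elements may not overlap; explicit
  placements that collide raise an error.
- **Bait/RC.** At 90 % of the locus, orientation `-`, so the `+` segment
  RSSs are convergent (deletional-configured).  The self-ligation exclusion
  interval is bait ± 75 bp.
- **Cryptic sites** are planted as convergent `+`/`-` pairs 40 bp apart.
  Diffusion-mode eligibility is assessed at the pair midpoint, which makes
  the generator's orientation symmetry exactly 0.5 — required for the
  exact-binomial check of the diffusion readout.  Scanning mode admits only
  convergent CACs between the RC and the impediment (default at 20 % of the
  locus), with exponential intensity decay (length scale 20 kb); a 15-bp
  buffer inside the impediment guarantees that resection jitter never
  carries a junction past it.  The scanning decay form and diffusion radius
  are simulation knobs, not claims about chromatin physics.
- **Junction positions** are jittered by a resection offset uniform on
  [0, 15) bp toward the coding flank — chosen to exercise the 15-bp
  collapsing rule exactly at its boundary.
- **3C libraries** allocate a fixed junction total multinomially over sites
  with weights $(1+d)^{-\gamma}$ times planted anchor enrichments (γ = 0
  gives the homogeneous backgrounds used for calibration runs), plus a
  self-ligation spike inside the exclusion interval.  Conditioning the
  Poisson site counts on the library total is what fixed-size sequencing
  does to independent Poisson signals.
- **Tracks.** Planted CBE features receive motif-consensus sequence (written
  by the locus builder, since the genome is immutable afterwards) and ChIP
  peaks in ≥ 2 repeats; E2A features receive maxima of 1.5; transcription
  features receive GRO maxima of 45 in ≥ 2 repeats; elsewhere the tracks
  carry sub-threshold noise (E2A < 0.2, GRO < 5).

What passing these tests shows — and does not.  The synthetic libraries
have exact catalogs, independent junctions, and noiseless threshold
separations.  Real libraries have alignment artefacts, duplicate junctions,
copy-number structure, and RSS-strength variation that the `strength`
weights only caricature.  The tests therefore establish the *correctness of
the computations* (filters, collapsing, normalization, the peak caller's
error control, the annotation rules), not the biological calibration of any
threshold.

## Problem sizes and seeds

The acceptance checks run at fixed sizes chosen to make their statistical
tolerances meaningful on a single CPU in about a minute: the Poisson oracle
grid over k ∈ [0, 50] × 6 rates; the scanner oracle on 100 random 10-kb
sequences; the null false-positive control on 200 replicates of 5,000
tested sites at λ₀ = 20 (family-wise error under Bonferroni bounds the
expected replicate-positive fraction by 0.05, tested against 0.10); anchor
recovery on 100 replicates with 20 planted 8× anchors; orientation readouts
at 10,000 cryptic junctions against the exact binomial 99 % interval.  All
randomness flows through explicit seeds via `withr::with_seed`, so every
reported number is reproducible bit-for-bit.

## Known limitations

- The significance model is purely local-median Poisson: no distance-decay
  correction within the window, no dispersion estimation.  A strongly
  sloped background inside 101 sites will inflate λ asymmetrically.
- Bonferroni over tested sites is conservative by design; weaker anchors
  than the calibration's 8× may be missed.
- The RSS filter scores only the 13 consensus-critical positions; it is not
  a recombination-efficiency model (RIC scores are out of scope), so
  "unannotated bona fide" means sequence-similar, not functionally
  validated.
- The junction-table TSV dialect is a project definition for portability,
  not a description of any public deposit's schema.
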