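---
title: "Detecting introgressed regions in congenic genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgressed regions in congenic genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

A congenic inbred line is expected to be genetically identical to its
recipient strain everywhere except a deliberately (or accidentally)
introgressed donor segment. When such an individual is whole-genome
sequenced and its reads are called against the recipient-strain reference,
almost every true variant it carries should be homozygous-reference. A
*heterozygous* non-reference SNP is therefore informative: a dense cluster
of heterozygous calls marks a chromosomal segment where one haplotype is
donor-derived. This signature is how cryptic modifier regions are found in
nominally congenic colonies — for example a protective ~37 Mb variant region
on mouse chromosome 13 segregating in a B6.Y^POS^ sex-reversal colony.

introscan packages the full desk analysis around that signature:

1. **Filter** raw SNP calls on the caller's internal status check and a
   per-site quality score.
2. **Scan**: per-window heterozygous-SNP density, run-based segment calling,
   triage of small artifact clusters, and detection of variant-devoid gaps
   inside called segments.
3. **Compare**: classify segment SNPs as private or shared against a
   multi-strain genotype panel, rank strains by similarity, and export
   Circos-style track tables.
4. **Test**: exact contingency tests on genotype-by-phenotype tables,
   Welch's t, and relative qPCR quantification by the delta-delta-Ct method.
5. **Simulate**: generate every input above with planted truth, so the whole
   pipeline is validated by recovery.

## The discovery model

Let the filtered heterozygous non-reference calls on a chromosome have
positions $x_1 < x_2 < \dots$. The genome is tiled with fixed windows of
width $w$ (default 1 Mb) anchored at bp 1; window $i$ covers
$[(i-1)w + 1,\; iw]$ and the last partial window is kept. The per-window
count vector is the density track; counts always sum to the number of input
calls (a conservation property the tests assert).

A **segment** is a maximal run of windows with count
$\ge$ `min_snps_per_window`, in which up to `max_gap_windows` consecutive
below-threshold windows may be bridged. Runs spanning fewer than
`min_segment_windows` windows are classified `artifact_candidate`, the rest
`introgressed`. Segment boundaries are then trimmed from window edges to the
first and last supporting SNP, which is why a segment can be reported with
sub-window resolution (e.g. 38.2–75.7 Mb) from a 1 Mb grid.

### Parameters and defaults

| parameter             | default | units   | why                                                                 |
|-----------------------|---------|---------|---------------------------------------------------------------------|
| `mq_threshold`        | 200     | score   | calls with score `< 200` are removed, `>= 200` retained (strict less-than boundary); the conventional high-confidence cutoff for GATK-style site scores |
| `window_size`         | 1e6     | bp      | the standard megabase binning for genome-wide SNP-density summaries |
| `min_snps_per_window` | 5       | count   | a window is a "significant cluster" only above the size of scattered error clusters (1–5 sites, further thinned by filtering), and far below a real introgressed density of tens of sites per Mb |
| `max_gap_windows`     | 5       | windows | introgressed regions are mosaics: internal recipient-homozygous blocks and multi-Mb variant-devoid stretches must not split one region. A bridge of 5 keeps a segment with an internal gap of up to ~5 Mb intact while never joining clusters further apart |
| `min_segment_windows` | 3       | windows | runs of 1–2 hot windows are artifact candidates, not regions        |

No published description of this analysis quantifies "significant cluster",
so `min_snps_per_window` and `min_segment_windows` are this package's own
calibration, exposed as parameters. `max_gap_windows = 5` is likewise a
design choice: a smaller bridge (e.g. 2) suffices for typical
recipient-homozygous blocks but would cut a region in two at a 4.5 Mb
variant-devoid gap, which contradicts how such regions are reported — as one
segment containing the gap.

The quality filter retains a call only if it passed the caller status check
**and** its score meets the threshold; the two removal counts are reported
separately. Note that "mapping quality" here is whatever per-site score the
upstream caller emitted (GATK-era reports plot the same 200–1000 range
variously as mapping quality or base-quality score); the filter is agnostic
about which field it is, and the VCF reader takes it from `INFO/MQ`. Calls
lacking the annotation are kept by the reader (flagged `NA`, with a warning)
but fail the quality criterion in the filter — the conservative choice.

### Variant-devoid gaps

Within a called segment, maximal intervals of width at least `min_gap_bp`
(default 1 Mb) containing zero heterozygous calls are reported, widest
first. These matter biologically: a candidate gene inside a called region
that sits in a multi-Mb devoid gap is *not* covered by donor sequence and
drops out of the candidate list.

## Strain comparison

Against a panel of strain genotypes (a sites-by-strains 0/1 matrix of
non-reference-allele carriage), a segment SNP is **shared** if at least one
panel strain carries the alternate allele and **private** otherwise —
private and shared always partition the sites. Sites absent from the panel's
catalogue count as carried by no strain (that is what calling privacy
against an available catalogue means); their count is logged so users can
audit it. Strain **similarity** is the fraction of segment sites whose
alternate allele the strain carries, ranked descending with a deterministic
tie-break on strain label (C-locale order). Whether published "similarity"
figures used this per-SNP sharing fraction or some other metric is not
stated anywhere we know of; the sharing fraction is the definition
implemented here.

Marker-based genotyping (`genotype_region()`) calls a region genotype from a
set of diagnostic SNPs (typically nine spread across the region): all-het
gives `int/+`, all-hom-alt `int/int`, all-hom-ref `+/+`, and any mixed
pattern is reported `discordant`. Discordance is deliberately *not* resolved
by majority: real colonies contain recombinants, and silently resolving them
would hide exactly the animals one needs to inspect.

## Statistics

**Exact contingency tests.** For 2x2 tables the two-sided p-value sums
hypergeometric probabilities of all tables with the observed margins whose
point probability does not exceed the observed one (the point-probability
convention of common statistical software). For larger R x C tables the
Freeman–Halton extension enumerates every margin-fixed table recursively
with the same criterion. Ties in point probability are accepted with a
relative tolerance of 1e-7, the standard guard against floating-point
ordering. Tables whose total exceeds 200, or whose enumeration would exceed
~2e6 tables, are rejected with advice to use `monte_carlo_exact()`, which
resamples margin-fixed tables (Patefield's algorithm) and reports the
(k+1)/(N+1)-corrected proportion with a binomial confidence interval.
Gonad-category tables are tested as full R x C (categories O/Ot/ot/oT/T;
never-observed categories are dropped as empty columns).

**Welch's t** (unequal variances, Welch–Satterthwaite df, two-sided) is used
for between-group comparisons of expression quantities. The degenerate case
of two zero-variance samples returns p = 1 when the means agree.

**Delta-delta-Ct.** Per sample, dCt = Ct(target) − Ct(reference); per group,
ddCt = mean dCt(group) − mean dCt(calibrator); fold change = 2^(−ddCt).
Averaging happens on the cycle (log) scale before exponentiating — the
standard relative-quantification procedure — so the calibrator group is
exactly 1 by construction, and the estimator is an exact inverse of the
simulator in the zero-noise limit. Per-sample relative quantities
2^(−(dCt − mean dCt(calibrator))) are returned for plotting and Welch
testing. Samples missing either gene are excluded with a warning.

No multiple-testing correction is applied anywhere: the pipeline reports the
same per-test p-values a modifier-locus study would report.

## What the simulator emulates — and what it does not

`generate_congenic_callset()` plants a truth mosaic (default: heterozygous
blocks spanning 38.2–75.7 Mb of a 120 Mb chromosome, interleaved with two
recipient-homozygous blocks, one 4.5 Mb variant-devoid gap containing the
51.8 Mb position, and a 60–70 Mb private-site region) and emits:

* heterozygous calls at homogeneous-Poisson positions inside heterozygous
  blocks, none inside devoid gaps. The literature never states the per-Mb
  density of donor SNPs in such regions, so the default `het_site_rate` of
  **50 sites/Mb** was chosen once as a realistic post-filtering density for
  a divergent inter-strain segment at ~13x coverage (raw inter-strain
  divergence is severalfold higher; status and quality filtering at a strict
  threshold discards much of it). The positional model is homogeneous
  Poisson because no positional structure beyond the mosaic is described.
* artifact clusters: Poisson-many per genome (default 20), each 1–5 sites
  within 10 kb, uniformly placed outside the planted mosaic, emulating the
  small scattered clusters attributed to sequence context, sequencing error
  and drift.
* a two-component quality model: mapping quality ~ N(620, 140) for
  introgression-origin calls vs N(150, 80) for artifacts (both truncated to
  [0, 1000], the score range such callers print), with status-check pass
  probabilities 0.98 vs 0.5. This makes the `MQ < 200` filter meaningful:
  most artifact sites fail it, most true sites survive.

The panel generator gives each strain the alternate allele of each
non-private site independently with a per-strain probability; the default
profile makes a BALB/c-like strain the closest relative (0.90), the
reference's sibling strain C57BL/6N the outlier (0.05), other C57-lineage
strains low (0.20), wild-derived strains intermediate (0.35) and classical
inbreds high (0.60). Sites in the private region are carried by no strain.
The cohort generator draws phenotypic sex (default: 72.5% female for
non-carriers — the familiar 70–75% XY-female rate of the sensitized
background — vs 45% for carriers) and an O/Ot/ot/oT/T gonad category per
animal. The qPCR generator writes each sample's target Ct as its own
reference Ct plus an offset minus log2(relative expression), with
independent Gaussian cycle noise.

Deliberately **not** modeled: reads, alignment, base-level error and its
sequence-context correlation; linkage disequilibrium and recombination
within blocks; pedigrees; allele-frequency structure among panel strains
(strains are independent given the profile); qPCR efficiency differences.
Passing recovery tests therefore demonstrate that the *analysis logic* is
correct under the stated generative model — not that the pipeline is robust
to alignment artifacts or population structure in real call sets.

## Determinism and numerical choices

A single integer seed is fanned out into named sub-streams (one per
generator), so each synthetic output is individually reproducible and
generators never perturb the caller's RNG state. Every file writer orders
rows deterministically (C-locale radix sort) and run manifests record
parameters, package version, seed and input checksums but no timestamps, so
repeated runs with one seed are byte-identical — a property the test suite
asserts file-by-file. Window grids are anchored at bp 1; positions are
1-based inclusive everywhere in memory, and only BED output is 0-based
half-open. Ties: the first (lowest-start) maximal private span is reported;
devoid gaps sort by width then start; similarity ties break on strain label.

## Problem sizes used in validation

The packaged validation study is desk-scale, chosen so the full suite runs
in minutes while keeping every estimate's sampling error far below the
tolerances asserted: a 2-chromosome (~277 Mb) genome with ~1,500 planted
calls per run; 100 seeds for segment-recovery, artifact-triage and qPCR
Monte-Carlo checks; 2,000 simulated null cohorts of 500 animals per
genotype for the type-I-error check (the cohort size was chosen *a priori*
by an exact calculation of the conditional test's discreteness — at 500 per
arm the true two-sided rejection rate at alpha 0.05 is ~0.046, inside the
asserted 5% +/- 1.5% band; at 60 per arm the exact test is conservative
enough, ~0.035, to sit on the edge of it).

## Known limitations

* Segmentation is threshold/run-based, not an HMM or changepoint model; it
  is transparent and easily calibrated but has no per-boundary uncertainty.
* Privacy is relative to the supplied panel: a "private" SNP is only as
  private as the catalogue is complete.
* The exact-test enumerator is exponential in table size by design; large
  tables must use the Monte-Carlo estimator.
* Copy-number or structural variation (abnormal coverage) is out of scope;
  so are multi-sample VCFs, indels, and phasing.
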