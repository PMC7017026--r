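# introscan

Detection and characterization of introgressed (donor-derived) chromosomal
regions in congenic inbred-strain genomes from whole-genome SNP calls.

## Why

A congenic line should be homozygous for the recipient-strain reference
everywhere outside the introgressed material, so a dense cluster of
**heterozygous non-reference SNPs** in a single individual's call set is the
diagnostic signature of a cryptic donor segment — the way unexpected modifier
regions are discovered in nominally congenic colonies (e.g. a protective
~37 Mb variant region on mouse chromosome 13 in a B6.Y^POS^ sex-reversal
colony). introscan is for geneticists who have such a call set and want the
complete desk analysis around that signature, plus a synthetic-data module
that makes every step testable by planted-truth recovery.

## What it computes

* **Quality filtering** — retain calls passing the caller status check with
  per-site quality ≥ *t* (default 200; a call at 199 is removed, at 200
  retained).
* **Windowed density and segment calling** — per-window counts
  $c_i = \#\{x : (i-1)w < x \le iw\}$ on a fixed grid ($w$ = 1 Mb);
  segments are maximal runs with $c_i \ge$ 5, bridging ≤ 5 below-threshold
  windows (introgressed regions are mosaics containing
  recipient-homozygous blocks and variant-devoid gaps); short runs are
  triaged as artifact candidates; boundaries are trimmed to the first/last
  supporting SNP.
* **Variant-devoid gaps** — maximal intervals ≥ 1 Mb inside a segment with
  zero heterozygous calls.
* **Private vs shared SNPs** — against a strain × site genotype panel, a
  site is *shared* iff ≥ 1 strain carries the alternate allele, else
  *private*; per-strain similarity = fraction of segment sites carried;
  10-Mb sliding-span localization of the private-SNP cluster.
* **Marker genotyping** — region genotype (`+/+`, `int/+`, `int/int`) from
  diagnostic SNPs; mixed patterns are reported `discordant`, never resolved.
* **Statistics** — two-sided exact tests (2×2 hypergeometric summation;
  R×C by Freeman–Halton full enumeration; Monte-Carlo fallback for large
  tables), Welch's *t* (Welch–Satterthwaite df), and delta-delta-Ct qPCR
  quantification: fold change $= 2^{-\Delta\Delta C_t}$ with
  $\Delta C_t = C_t^{target} - C_t^{reference}$ averaged on the cycle scale.
* **Simulation** — congenic call sets with a planted heterozygous mosaic,
  devoid gaps, private-site region, quality-degraded artifact clusters; a
  36-strain panel; phenotype cohorts; qPCR Ct tables — all with truth
  records and byte-identical reproducibility under one seed.

File formats: single-sample VCF v4.2 in/out, BED (0-based half-open) out,
tab-delimited panels/cohorts/Ct tables/tracks. See the methods vignette
(`vignettes/introgression-scan.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(introscan)
demo <- run_demo("demo_out", seed = 1)   # simulate -> discover -> compare -> stats

subset(demo$discover$segments, classification == "introgressed")
#>   chrom    start      end n_supporting_snps n_windows classification mean_mq n_calls
#> 1 chr13 38235780 75652888              1458        38   introgressed 624.855    1458

head(demo$compare$similarity, 3)
#>    strain  fraction rank
#> 1 BALB/cJ 0.6090535    1
#> 2   I/LnJ 0.4272977    2
#> 3  KK/HiJ 0.4218107    3

demo$discover$gaps[1, ]
#>   chrom    start      end width_bp
#> 1 chr13 49513462 54051375  4537914

demo$stats$report
#>               test                      comparison  statistic       df      p_value
#> 1     fisher_exact                  genotype_x_sex         NA       NA 4.959803e-06
#> 2     fisher_exact       genotype_x_gonad_category         NA       NA 1.434453e-07
#> 3          welch_t rel_quantity:carrier_vs_control -9.1927160 5.643947 1.322511e-04
#> 4 ddct_fold_change              carrier_vs_control  0.5132878       NA           NA
```

Reading the output: the discover stage recovered the planted mosaic
(38.2–75.7 Mb of chr13) as **one** introgressed segment of 37.4 Mb supported
by 1,458 heterozygous SNPs, despite its internal homozygous blocks and the
4.5 Mb variant-devoid gap — which the gap scan then reports (49.5–54.1 Mb,
spanning the 51.8 Mb locus position). The comparison stage ranks the
BALB/c-like donor first among 36 strains; the private-SNP span maximizer
localizes the planted 60–70 Mb private cluster
(`demo$compare$max_private_span$start` = 60000001). The stats stage finds the
planted genotype effects on sex ratio and gonad category (exact tests), and
estimates the planted 2-fold expression reduction as fold change 0.51 with a
significant Welch test.

The same stages run from a shell:

```sh
Rscript inst/cli/introscan.R demo --out demo_out --seed 1
Rscript inst/cli/introscan.R discover --vcf demo_out/inputs/congenic.vcf --out scan_out
```

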