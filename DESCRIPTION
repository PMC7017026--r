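Package: introscan
Title: Detection and Characterization of Introgressed Regions in Congenic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discover and characterize donor-derived (introgressed)
    chromosomal regions in congenic inbred-strain genomes from whole-genome SNP
    calls. Provides quality filtering of variant calls, windowed
    heterozygous-SNP density tracks, run-based segment calling with artifact
    triage, detection of variant-devoid gaps inside called segments,
    private/shared SNP classification against a multi-strain genotype panel
    with strain-similarity ranking, marker-based region genotyping, and the
    downstream statistics typical of modifier-locus studies: exact contingency
    tests (2x2 and RxC by full enumeration, with a Monte-Carlo fallback),
    Welch's t-test, and relative qPCR quantification by the delta-delta-Ct
    method. A synthetic-data module generates congenic call sets with planted
    introgression truth, strain panels, phenotype cohorts, and qPCR tables for
    end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
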