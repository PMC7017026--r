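## Pipeline orchestration: discover -> compare -> stats, with a config
## object, a run manifest, and a one-command synthetic demo.

#' Pipeline configuration
#'
#' Collects the input paths, parameters and seed driving the pipeline
#' stages. Referenced paths are checked at run time by the stage that needs
#' them.
#'
#' @param vcf single-sample VCF of the congenic individual.
#' @param panel optional strain-panel table ([read_strain_panel()] format).
#' @param cohort optional cohort table (columns `animal`, `genotype`, `sex`,
#'   `gonad`).
#' @param qpcr optional Ct table (columns `sample`, `group`, `gene`, `ct`).
#' @param features optional BED file of feature intervals to annotate.
#' @param out_dir output directory (created if absent).
#' @param scan a [scan_params()].
#' @param chromosome_lengths optional named vector; when absent, each
#'   chromosome's length is taken as the last call position rounded up to a
#'   whole window (documented approximation: trailing empty windows carry no
#'   information for segment calling).
#' @param min_gap_bp minimum devoid-gap width (bp) reported by discover.
#' @param calibrator_group calibrator for the qPCR stage (default: last
#'   group in the Ct table).
#' @param target_gene,reference_gene gene labels in the Ct table.
#' @param seed integer seed for any stage needing randomness.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, panel = NULL, cohort = NULL, qpcr = NULL,
                            features = NULL, out_dir = ".",
                            scan = scan_params(), chromosome_lengths = NULL,
                            min_gap_bp = 1e6, calibrator_group = NULL,
                            target_gene = "target", reference_gene = "reference",
                            seed = 1L) {
  structure(list(vcf = vcf, panel = panel, cohort = cohort, qpcr = qpcr,
                 features = features, out_dir = out_dir, scan = scan,
                 chromosome_lengths = chromosome_lengths,
                 min_gap_bp = min_gap_bp, calibrator_group = calibrator_group,
                 target_gene = target_gene, reference_gene = reference_gene,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_manifest <- function(config, stage, inputs, path) {
  existing <- inputs[file.exists(unlist(inputs))]
  manifest <- list(
    stage = stage,
    package = "introscan",
    version = as.character(utils::packageVersion("introscan")),
    seed = config$seed,
    parameters = c(unclass(config$scan), list(min_gap_bp = config$min_gap_bp)),
    inputs = lapply(existing, function(p) unname(tools::md5sum(p))))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Run the discovery stage
#'
#' Reads the VCF, applies the quality filters, keeps heterozygous
#' non-reference calls, computes per-chromosome 1-Mb (by default) density
#' tracks, calls segments with artifact triage, and locates variant-devoid
#' gaps inside introgressed segments. Writes `segments.bed`, `density.tsv`,
#' `artifact_report.tsv`, `devoid_gaps.tsv` and `manifest_discover.yaml`
#' into the output directory. All outputs are deterministic for a given
#' config.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `calls`, `het_calls`, `tracks`, `segments`,
#'   `gaps`, `removed`.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- read_vcf(config$vcf)
  filt <- apply_quality_filters(calls, config$scan)
  het <- select_het_nonref(filt$calls)

  lens <- config$chromosome_lengths
  if (is.null(lens)) {
    w <- config$scan$window_size
    lens <- vapply(split(het$pos, het$chrom),
                   function(p) ceiling(max(p) / w) * w, 0)
  }
  empty_seg <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_supporting_snps = numeric(),
                          n_windows = integer(), classification = character(),
                          stringsAsFactors = FALSE)
  if (nrow(het) == 0L) {
    warnf("run_discover: no heterozygous calls after filtering; no segments called")
    tracks <- list(); segments <- empty_seg
  } else {
    chroms <- sort(unique(het$chrom), method = "radix")
    tracks <- lapply(chroms, function(ch)
      window_density(het, ch, lens[[ch]], config$scan))
    names(tracks) <- chroms
    segments <- do.call(rbind, lapply(tracks, function(tr)
      call_segments(tr, config$scan, het)))
    if (is.null(segments)) segments <- empty_seg
    rownames(segments) <- NULL
  }
  segments <- flag_artifact_clusters(segments, het)

  intro <- segments[segments$classification == "introgressed", , drop = FALSE]
  gaps <- do.call(rbind, lapply(seq_len(nrow(intro)), function(i)
    find_devoid_gaps(intro[i, ], het, config$min_gap_bp)))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       width_bp = numeric(), stringsAsFactors = FALSE)
  rownames(gaps) <- NULL

  density <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(chrom = tr$chromosome, start = tr$start, end = tr$end,
               count = tr$counts, stringsAsFactors = FALSE)))
  if (is.null(density))
    density <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), count = integer())
  rownames(density) <- NULL

  out <- function(f) file.path(config$out_dir, f)
  write_bed(segments, out("segments.bed"))
  write_tsv(density, out("density.tsv"))
  write_tsv(segments[segments$classification == "artifact_candidate", ,
                     drop = FALSE], out("artifact_report.tsv"))
  write_tsv(gaps, out("devoid_gaps.tsv"))
  if (!is.null(config$features)) {
    feats <- read_bed(config$features)
    write_tsv(annotate_intervals(segments, feats, gaps),
              out("feature_overlaps.tsv"))
  }
  write_manifest(config, "discover", list(vcf = config$vcf),
                 out("manifest_discover.yaml"))
  invisible(list(calls = calls, het_calls = het, tracks = tracks,
                 segments = segments, gaps = gaps, removed = filt$removed))
}

#' Run the strain-comparison stage
#'
#' Classifies the het calls of the largest introgressed segment as
#' private/shared against the strain panel, ranks strains by similarity, and
#' writes the label-split density track (Circos-style columns: chrom, start,
#' end, count, private_count, shared_count), `provenance.tsv`,
#' `similarity.tsv` and `manifest_compare.yaml`.
#'
#' @param config a [pipeline_config()] with `panel` set.
#' @param discover output of [run_discover()].
#' @return (invisibly) list with `provenance`, `similarity`, `track`,
#'   `max_private_span`.
#' @export
run_compare <- function(config, discover) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(config$panel))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_strain_panel(config$panel)
  intro <- discover$segments[discover$segments$classification == "introgressed", ,
                             drop = FALSE]
  if (nrow(intro) == 0L) stopf("run_compare: no introgressed segment to compare")
  seg <- intro[which.max(intro$end - intro$start), , drop = FALSE]
  if (!seg$chrom %in% unique(panel$sites$chrom))
    stopf("panel/segment chromosome mismatch: segment on %s, panel covers %s",
          seg$chrom, paste(unique(panel$sites$chrom), collapse = ", "))
  het <- discover$het_calls
  sites <- het[het$chrom == seg$chrom & het$pos >= seg$start & het$pos <= seg$end, ,
               drop = FALSE]
  prov <- classify_private(sites, panel)
  sim <- strain_similarity(sites, panel)
  tr <- discover$tracks[[seg$chrom]]
  track <- windowed_private_density(sites, prov$label, seg$chrom,
                                    tr$chromosome_length, config$scan)
  span <- max_private_span(track)

  out <- function(f) file.path(config$out_dir, f)
  write_tsv(prov, out("provenance.tsv"))
  write_tsv(sim, out("similarity.tsv"))
  write_tsv(data.frame(chrom = track$chromosome, start = track$start,
                       end = track$end, count = track$counts,
                       private_count = track$private,
                       shared_count = track$shared, stringsAsFactors = FALSE),
            out("private_shared_track.tsv"))
  write_manifest(config, "compare", list(panel = config$panel),
                 out("manifest_compare.yaml"))
  invisible(list(provenance = prov, similarity = sim, track = track,
                 max_private_span = span, segment = seg))
}

#' Run the statistics stage
#'
#' Exact tests on the genotype x phenotypic-sex (2x2) and genotype x
#' gonad-category (R x C, Freeman-Halton) tables of the cohort, and, when a
#' Ct table is supplied, delta-delta-Ct fold changes plus Welch's t on the
#' per-sample relative quantities. Writes one consolidated
#' `stats_report.tsv`.
#'
#' @param config a [pipeline_config()] with `cohort` and/or `qpcr` set.
#' @return (invisibly) list with `report` plus the underlying objects.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); extras <- list()
  if (!is.null(config$cohort)) {
    cohort <- read_tsv(config$cohort)
    if ("sex" %in% names(cohort)) {
      ft <- fisher_exact(cohort_contingency(cohort, "sex"))
      rows[[length(rows) + 1L]] <- data.frame(
        test = "fisher_exact", comparison = "genotype_x_sex",
        statistic = NA_real_, df = NA_real_, p_value = ft$p_value)
    }
    if ("gonad" %in% names(cohort)) {
      ft <- fisher_exact(cohort_contingency(cohort, "gonad"))
      rows[[length(rows) + 1L]] <- data.frame(
        test = "fisher_exact", comparison = "genotype_x_gonad_category",
        statistic = NA_real_, df = NA_real_, p_value = ft$p_value)
    }
    extras$cohort <- cohort
  }
  if (!is.null(config$qpcr)) {
    ct <- read_tsv(config$qpcr)
    calib <- config$calibrator_group
    if (is.null(calib)) calib <- utils::tail(unique(ct$group), 1L)
    dd <- ddct_fold_change(ct, config$target_gene, config$reference_gene, calib)
    for (g in setdiff(dd$groups$group, calib)) {
      wt <- welch_t(dd$samples$rel_quantity[dd$samples$group == g],
                    dd$samples$rel_quantity[dd$samples$group == calib])
      rows[[length(rows) + 1L]] <- data.frame(
        test = "welch_t", comparison = sprintf("rel_quantity:%s_vs_%s", g, calib),
        statistic = wt$t, df = wt$df, p_value = wt$p_value)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "ddct_fold_change", comparison = sprintf("%s_vs_%s", g, calib),
        statistic = dd$groups$fold_change[dd$groups$group == g],
        df = NA_real_, p_value = NA_real_)
    }
    extras$ddct <- dd
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(), comparison = character(),
               statistic = numeric(), df = numeric(), p_value = numeric())
  write_tsv(report, file.path(config$out_dir, "stats_report.tsv"))
  write_manifest(config, "stats",
                 list(cohort = config$cohort, qpcr = config$qpcr)[
                   !vapply(list(config$cohort, config$qpcr), is.null, TRUE)],
                 file.path(config$out_dir, "manifest_stats.yaml"))
  invisible(c(list(report = report), extras))
}

#' One-command synthetic demo: simulate, discover, compare, test
#'
#' Generates a full synthetic study at the default scale (a congenic genome
#' with the default planted mosaic, a 36-strain panel, a two-genotype
#' phenotype cohort and a two-group Ct table), writes the inputs under
#' `out_dir/inputs`, then runs every pipeline stage on them.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return (invisibly) list with `truth`, `site_truth` and the three stage
#'   results (`discover`, `compare`, `stats`).
#' @export
run_demo <- function(out_dir, seed = 1L) {
  inputs <- file.path(out_dir, "inputs")
  dir.create(inputs, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulation_config(seed = seed)
  truth <- introgression_truth()
  sim <- generate_congenic_callset(cfg, truth)
  pan <- generate_strain_panel(cfg, sim, truth)
  cohort <- generate_cohort(cohort_config(seed = seed))
  ct <- generate_qpcr(qpcr_config(seed = seed))

  p <- function(f) file.path(inputs, f)
  write_vcf(sim$calls, p("congenic.vcf"), sample_name = "congenic_stud",
            contig_lengths = cfg$chromosome_lengths)
  write_strain_panel(pan$panel, p("panel.tsv"))
  write_tsv(cohort, p("cohort.tsv"))
  write_tsv(ct, p("qpcr.tsv"))
  write_tsv(sim$truth, p("truth_calls.tsv"))
  write_tsv(pan$site_truth, p("truth_sites.tsv"))

  config <- pipeline_config(
    vcf = p("congenic.vcf"), panel = p("panel.tsv"), cohort = p("cohort.tsv"),
    qpcr = p("qpcr.tsv"), out_dir = out_dir,
    chromosome_lengths = cfg$chromosome_lengths,
    calibrator_group = "control", seed = seed)
  disc <- run_discover(config)
  comp <- run_compare(config, disc)
  stat <- run_stats(config)
  invisible(list(truth = truth, callset = sim, panel = pan,
                 discover = disc, compare = comp, stats = stat,
                 config = config))
}
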