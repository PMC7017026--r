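## Synthetic congenic genomes, strain panels, phenotype cohorts and qPCR
## tables, each with a full planted-truth record for recovery testing.

#' Default 36-strain comparison panel
#'
#' Classical inbred and wild-derived laboratory mouse strains used as the
#' default genotype-panel labels.
#'
#' @return character vector of 36 strain names.
#' @export
default_panel_strains <- function() {
  c("129P2/OlaHsd", "129S1/SvImJ", "129S5/SvEvBrd", "A/J", "AKR/J",
    "BALB/cJ", "BTBR T+ Itpr3tf/J", "BUB/BnJ", "C3H/HeH", "C3H/HeJ",
    "C57BL/10J", "C57BL/6NJ", "C57BR/cdJ", "C57L/J", "C58/J",
    "CAST/EiJ", "CBA/J", "DBA/1J", "DBA/2J", "FVB/NJ",
    "I/LnJ", "KK/HiJ", "LEWES/EiJ", "LP/J", "MOLF/EiJ",
    "NOD/ShiLtJ", "NZB/B1NJ", "NZO/HlLtJ", "NZW/LacJ", "PWK/PhJ",
    "RF/J", "SEA/GnJ", "SPRET/EiJ", "ST/bJ", "WSB/EiJ", "ZALENDE/EiJ")
}

#' Default per-strain allele-sharing probabilities
#'
#' Probability that a given panel strain carries the non-reference allele at
#' a (non-private) introgressed site. The defaults emulate the sharing
#' structure reported for donor-derived regions on an otherwise B6
#' background: a BALB/c-like donor shares most alleles, the C57BL/6N sibling
#' strain of the reference shares almost none, the remaining C57 lineage is
#' low, wild-derived strains intermediate, and other classical inbreds high.
#'
#' @param strains character vector of strain labels.
#' @return named numeric vector of probabilities in [0, 1].
#' @export
default_sharing_profile <- function(strains = default_panel_strains()) {
  p <- rep(0.6, length(strains))
  names(p) <- strains
  wild <- c("CAST/EiJ", "LEWES/EiJ", "MOLF/EiJ", "PWK/PhJ", "SPRET/EiJ",
            "WSB/EiJ", "ZALENDE/EiJ")
  c57 <- c("C57BL/10J", "C57BR/cdJ", "C57L/J", "C58/J")
  p[names(p) %in% wild] <- 0.35
  p[names(p) %in% c57] <- 0.20
  p["C57BL/6NJ"] <- 0.05
  p["BALB/cJ"] <- 0.90
  p[!is.na(names(p))]
}

#' Planted introgression truth
#'
#' Describes the donor-derived mosaic planted on one chromosome of a
#' synthetic congenic genome: alternating heterozygous and
#' reference-homozygous blocks, optional variant-devoid gaps inside
#' heterozygous blocks, and the interval in which panel-private alleles are
#' concentrated. Defaults reproduce the published geometry of the protective
#' chromosome-13 variant region: a mosaic spanning 38.2-75.7 Mb with two
#' internal reference-homozygous blocks, a 4.5 Mb variant-devoid gap
#' containing the 51.8 Mb position of the Gadd45g locus, and private sites
#' concentrated between 60 and 70 Mb.
#'
#' @param chromosome chromosome label.
#' @param blocks data.frame with columns `start`, `end` (1-based inclusive
#'   bp) and `state` (`"heterozygous"` or `"reference_homozygous"`),
#'   non-overlapping and sorted.
#' @param devoid_gaps data.frame with columns `start`, `end`; each gap must
#'   lie inside a heterozygous block and will carry zero variants.
#' @param private_site_region length-2 numeric (start, end) bp interval in
#'   which introgressed alleles are carried by no panel strain.
#' @return object of class `introgression_truth`.
#' @export
introgression_truth <- function(
    chromosome = "chr13",
    blocks = data.frame(
      start = c(38200001, 43000001, 44500001, 56500001, 58000001),
      end   = c(43000000, 44500000, 56500000, 58000000, 75700000),
      state = c("heterozygous", "reference_homozygous", "heterozygous",
                "reference_homozygous", "heterozygous")
    ),
    devoid_gaps = data.frame(start = 49550001, end = 54050000),
    private_site_region = c(60000001, 70000000)) {
  stopifnot(is.data.frame(blocks),
            all(c("start", "end", "state") %in% names(blocks)),
            nrow(blocks) >= 1L)
  if (!all(blocks$state %in% c("heterozygous", "reference_homozygous")))
    stopf("block state must be 'heterozygous' or 'reference_homozygous'")
  if (any(blocks$start > blocks$end)) stopf("block start > end")
  o <- order(blocks$start)
  blocks <- blocks[o, , drop = FALSE]
  if (nrow(blocks) > 1L && any(blocks$start[-1] <= blocks$end[-nrow(blocks)]))
    stopf("truth blocks overlap")
  if (!is.null(devoid_gaps) && nrow(devoid_gaps)) {
    het <- blocks[blocks$state == "heterozygous", , drop = FALSE]
    inside <- vapply(seq_len(nrow(devoid_gaps)), function(i) {
      any(devoid_gaps$start[i] >= het$start & devoid_gaps$end[i] <= het$end)
    }, logical(1))
    if (!all(inside)) stopf("every devoid gap must lie inside a heterozygous block")
  } else {
    devoid_gaps <- data.frame(start = numeric(), end = numeric())
  }
  structure(
    list(chromosome = chromosome, blocks = blocks, devoid_gaps = devoid_gaps,
         private_site_region = as.numeric(private_site_region),
         region_start = min(blocks$start), region_end = max(blocks$end)),
    class = "introgression_truth")
}

#' Simulation configuration for the congenic call-set generator
#'
#' @param chromosome_lengths named numeric vector of chromosome lengths (bp).
#'   The default carries the GRCm38 lengths of chromosomes 4 and 13: the
#'   chromosome carrying the planted mosaic plus one background chromosome on
#'   which only artifact clusters can occur.
#' @param het_site_rate heterozygous sites per Mb inside heterozygous blocks
#'   (homogeneous Poisson intensity). The field's reports never quantify this
#'   density, so the default (50/Mb) is a realistic post-filtering density for
#'   a divergent inter-strain segment; see the methods vignette.
#' @param artifact_cluster_rate expected number of false-positive SNP
#'   clusters per genome (Poisson).
#' @param artifact_cluster_size length-2 integer (min, max) sites per
#'   artifact cluster, drawn uniformly.
#' @param quality list of quality-model parameters: `true_mq_mean`,
#'   `true_mq_sd`, `artifact_mq_mean`, `artifact_mq_sd` for the two-component
#'   Gaussian mapping-quality mixture (truncated to `mq_range`), and
#'   `true_pass_prob` / `artifact_pass_prob` for the caller status check.
#' @param panel_strains character vector of panel strain labels.
#' @param sharing_profile named probability vector over `panel_strains`.
#' @param seed master integer seed; identical configuration + seed gives
#'   byte-identical outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(
    chromosome_lengths = c(chr4 = 156508116, chr13 = 120421639),
    het_site_rate = 50,
    artifact_cluster_rate = 20,
    artifact_cluster_size = c(1L, 5L),
    quality = list(true_mq_mean = 620, true_mq_sd = 140,
                   artifact_mq_mean = 150, artifact_mq_sd = 80,
                   mq_range = c(0, 1000),
                   true_pass_prob = 0.98, artifact_pass_prob = 0.5),
    panel_strains = default_panel_strains(),
    sharing_profile = default_sharing_profile(panel_strains),
    seed = 1L) {
  stopifnot(length(chromosome_lengths) >= 1L, !is.null(names(chromosome_lengths)),
            all(chromosome_lengths >= 1))
  if (het_site_rate < 0 || artifact_cluster_rate < 0)
    stopf("rates must be non-negative")
  stopifnot(length(artifact_cluster_size) == 2L,
            artifact_cluster_size[1] >= 1,
            artifact_cluster_size[1] <= artifact_cluster_size[2])
  probs <- c(quality$true_pass_prob, quality$artifact_pass_prob, sharing_profile)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  extra <- setdiff(names(sharing_profile), panel_strains)
  if (length(extra))
    stopf("unknown strain label in sharing_profile: %s", paste(extra, collapse = ", "))
  miss <- setdiff(panel_strains, names(sharing_profile))
  if (length(miss))
    stopf("sharing_profile missing strains: %s", paste(miss, collapse = ", "))
  structure(
    list(chromosome_lengths = chromosome_lengths, het_site_rate = het_site_rate,
         artifact_cluster_rate = artifact_cluster_rate,
         artifact_cluster_size = as.integer(artifact_cluster_size),
         quality = quality, panel_strains = panel_strains,
         sharing_profile = sharing_profile[panel_strains],
         seed = as.integer(seed)),
    class = "simulation_config")
}

# truncated-normal draw by clamping to the admissible score range; the
# mixture separation, not the tail shape, is what the downstream MQ filter
# exercises
rmq <- function(n, mean, sd, range) pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])

draw_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Generate a synthetic congenic variant call set with planted truth
#'
#' Emits heterozygous SNP calls at homogeneous-Poisson positions inside the
#' heterozygous blocks of `truth` (none inside its devoid gaps), plus small
#' scattered artifact clusters elsewhere in the genome, mimicking the
#' genome-wide call set of a congenic individual that is reference-homozygous
#' outside the introgressed mosaic. Every call carries a mapping quality
#' drawn from a two-component mixture (high for introgression-origin calls,
#' degraded for artifacts) and a caller status flag, so the downstream
#' quality filters are meaningful. The returned truth record labels every
#' call with exactly one origin.
#'
#' @param config a [simulation_config()].
#' @param truth an [introgression_truth()].
#' @return list with elements `calls` (a [variant_calls()] data.frame) and
#'   `truth` (data.frame `chrom`, `pos`, `origin` with origin
#'   `"introgression"` or `"artifact"`, keyed identically to `calls`).
#' @export
generate_congenic_callset <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "introgression_truth"))
  len <- config$chromosome_lengths
  if (!truth$chromosome %in% names(len))
    stopf("truth chromosome '%s' not in config chromosome_lengths", truth$chromosome)
  if (truth$region_end > len[[truth$chromosome]] || truth$region_start < 1)
    stopf("truth blocks outside chromosome '%s' bounds [1, %d]",
          truth$chromosome, len[[truth$chromosome]])

  # introgressed heterozygous sites
  het_pos <- with_stream_seed(config$seed, "het_sites", {
    hb <- truth$blocks[truth$blocks$state == "heterozygous", , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(hb)), function(i) {
      L <- hb$end[i] - hb$start[i] + 1
      n <- stats::rpois(1L, config$het_site_rate * L / 1e6)
      sort(unique(hb$start[i] + floor(stats::runif(n) * L)))
    }))
    g <- truth$devoid_gaps
    if (nrow(g)) {
      in_gap <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(g)))
        in_gap <- in_gap | (pos >= g$start[i] & pos <= g$end[i])
      pos <- pos[!in_gap]
    }
    pos
  })
  n_het <- length(het_pos)
  het <- with_stream_seed(config$seed, "het_quality", {
    al <- draw_alleles(n_het)
    q <- config$quality
    data.frame(chrom = rep(truth$chromosome, n_het), pos = het_pos,
               ref = al$ref, alt = al$alt, genotype = rep("het", n_het),
               mapping_quality = rmq(n_het, q$true_mq_mean, q$true_mq_sd, q$mq_range),
               status_pass = stats::runif(n_het) < q$true_pass_prob,
               origin = rep("introgression", n_het),
               stringsAsFactors = FALSE)
  })

  # artifact clusters: small, tight, quality-degraded, scattered anywhere
  # outside the planted mosaic
  art <- with_stream_seed(config$seed, "artifacts", {
    n_cl <- stats::rpois(1L, config$artifact_cluster_rate)
    q <- config$quality
    rows <- vector("list", n_cl)
    if (n_cl > 0L) {
      chroms <- sample(names(len), n_cl, replace = TRUE, prob = len / sum(len))
      for (k in seq_len(n_cl)) {
        ch <- chroms[k]
        center <- 1 + floor(stats::runif(1) * len[[ch]])
        if (ch == truth$chromosome &&
            center >= truth$region_start && center <= truth$region_end)
          next  # clusters are planted outside the introgressed mosaic
        size <- sample(seq(config$artifact_cluster_size[1],
                           config$artifact_cluster_size[2]), 1L)
        pos <- sort(unique(pmin(pmax(center + floor(stats::runif(size) * 1e4), 1),
                                len[[ch]])))
        m <- length(pos)
        al <- draw_alleles(m)
        rows[[k]] <- data.frame(
          chrom = rep(ch, m), pos = pos, ref = al$ref, alt = al$alt,
          genotype = rep("het", m),
          mapping_quality = rmq(m, q$artifact_mq_mean, q$artifact_mq_sd, q$mq_range),
          status_pass = stats::runif(m) < q$artifact_pass_prob,
          origin = rep("artifact", m), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })

  all <- rbind(het, art)
  if (is.null(all)) all <- het
  # deterministic order; on position collision keep the introgression call
  all <- all[order_radix(all$chrom, all$pos, match(all$origin, c("introgression", "artifact"))), ,
             drop = FALSE]
  dup <- duplicated(paste(all$chrom, all$pos))
  all <- all[!dup, , drop = FALSE]
  rownames(all) <- NULL
  calls <- all[, c("chrom", "pos", "ref", "alt", "genotype",
                   "mapping_quality", "status_pass")]
  validate_calls(calls)
  list(calls = calls, truth = all[, c("chrom", "pos", "origin")])
}

#' Generate a synthetic strain genotype panel over the introgressed sites
#'
#' For every introgression-origin site of a synthetic call set, each panel
#' strain carries the non-reference allele with its `sharing_profile`
#' probability, except sites inside the truth's `private_site_region`, which
#' are carried by no strain (the planted region-private alleles). The truth
#' record labels every site `private`/`shared` according to the realized
#' panel.
#'
#' @param config a [simulation_config()].
#' @param callset output of [generate_congenic_callset()].
#' @param truth the [introgression_truth()] used for the call set.
#' @return list with elements `panel` (a [strain_panel()]) and `site_truth`
#'   (data.frame `chrom`, `pos`, `in_private_region`, `label`).
#' @export
generate_strain_panel <- function(config, callset, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "introgression_truth"),
            is.list(callset), !is.null(callset$calls), !is.null(callset$truth))
  keep <- callset$truth$origin == "introgression"
  sites <- callset$calls[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  strains <- config$panel_strains
  pr <- truth$private_site_region
  in_priv <- sites$pos >= pr[1] & sites$pos <= pr[2] &
    sites$chrom == truth$chromosome
  alleles <- with_stream_seed(config$seed, "panel", {
    m <- vapply(strains, function(s)
      stats::rbinom(nrow(sites), 1L, config$sharing_profile[[s]]), integer(nrow(sites)))
    if (nrow(sites) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, strains))
    m[in_priv, ] <- 0L
    m
  })
  panel <- strain_panel(strains, sites, alleles)
  site_truth <- data.frame(
    chrom = sites$chrom, pos = sites$pos, in_private_region = in_priv,
    label = ifelse(rowSums(alleles) == 0L, "private", "shared"),
    stringsAsFactors = FALSE)
  list(panel = panel, site_truth = site_truth)
}

#' Cohort simulation configuration
#'
#' Genotype-dependent phenotypic-sex and gonad-category probabilities.
#' Defaults emulate the published colony behaviour: ~72.5% of
#' non-carrier XY animals score as phenotypic females at weaning, carriers of
#' one copy of the protective region substantially less; fetal gonads are
#' scored on the ordinal ovary-to-testis scale O / Ot / ot / oT / T with no
#' normal testes in any group.
#'
#' @param n_per_genotype named integer vector, animals per genotype.
#' @param p_female named numeric vector, probability of female phenotypic sex
#'   per genotype.
#' @param gonad_category_probs named list (per genotype) of probability
#'   vectors over the categories `O`, `Ot`, `ot`, `oT`, `T`, each summing
#'   to 1.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_genotype = c("+/+" = 60L, "int/+" = 60L),
    p_female = c("+/+" = 0.725, "int/+" = 0.45),
    gonad_category_probs = list(
      "+/+"   = c(O = 0.55, Ot = 0.30, ot = 0.12, oT = 0.03, T = 0),
      "int/+" = c(O = 0.20, Ot = 0.30, ot = 0.30, oT = 0.20, T = 0)),
    seed = 1L) {
  g <- names(n_per_genotype)
  stopifnot(!is.null(g), all(n_per_genotype >= 0),
            setequal(g, names(p_female)), setequal(g, names(gonad_category_probs)))
  if (any(p_female < 0 | p_female > 1)) stopf("p_female must lie in [0, 1]")
  for (gt in g) {
    p <- gonad_category_probs[[gt]]
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("gonad_category_probs['%s'] must be 5 probabilities summing to 1", gt)
  }
  structure(list(n_per_genotype = n_per_genotype, p_female = p_female[g],
                 gonad_category_probs = gonad_category_probs[g],
                 seed = as.integer(seed)),
            class = "cohort_config")
}

GONAD_CATEGORIES <- c("O", "Ot", "ot", "oT", "T")

#' Simulate a phenotype cohort
#'
#' Independent Bernoulli (phenotypic sex) and categorical (gonad score) draws
#' per animal, by genotype.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `animal`, `genotype`, `sex` (`"F"`/`"M"`)
#'   and `gonad` (one of O, Ot, ot, oT, T).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_stream_seed(config$seed, "cohort", {
    out <- lapply(names(config$n_per_genotype), function(gt) {
      n <- config$n_per_genotype[[gt]]
      if (n == 0L) return(NULL)
      data.frame(
        animal = sprintf("%s_%04d", gsub("[^A-Za-z0-9]+", "", gt), seq_len(n)),
        genotype = rep(gt, n),
        sex = ifelse(stats::runif(n) < config$p_female[[gt]], "F", "M"),
        gonad = sample(GONAD_CATEGORIES, n, replace = TRUE,
                       prob = config$gonad_category_probs[[gt]]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
}

#' qPCR simulation configuration
#'
#' @param groups character group labels; the last group is the calibrator,
#'   every other group expresses the target at `true_fold_change` times the
#'   calibrator level.
#' @param n_replicates biological replicates per group (>= 2).
#' @param true_fold_change target-gene expression ratio vs the calibrator
#'   (> 0; e.g. 0.5 for a planted 2-fold reduction).
#' @param ct_noise_sd Gaussian cycle noise added independently to each Ct.
#' @param reference_gene_ct_mean mean Ct of the endogenous-control gene.
#' @param target_ct_offset baseline target-minus-reference Ct in the
#'   calibrator group (cycles).
#' @param seed integer seed.
#' @return object of class `qpcr_config`.
#' @export
qpcr_config <- function(groups = c("carrier", "control"),
                        n_replicates = 5L,
                        true_fold_change = 0.5,
                        ct_noise_sd = 0.2,
                        reference_gene_ct_mean = 20,
                        target_ct_offset = 5,
                        seed = 1L) {
  stopifnot(length(groups) >= 2L, n_replicates >= 2L)
  if (true_fold_change <= 0) stopf("true_fold_change must be > 0")
  if (ct_noise_sd < 0) stopf("ct_noise_sd must be >= 0")
  structure(list(groups = groups, n_replicates = as.integer(n_replicates),
                 true_fold_change = true_fold_change, ct_noise_sd = ct_noise_sd,
                 reference_gene_ct_mean = reference_gene_ct_mean,
                 target_ct_offset = target_ct_offset, seed = as.integer(seed)),
            class = "qpcr_config")
}

#' Simulate a qPCR Ct table
#'
#' For each sample, the reference-gene Ct is drawn around
#' `reference_gene_ct_mean` and the target-gene Ct is the same sample's
#' reference Ct plus `target_ct_offset` minus log2(relative expression), each
#' with independent Gaussian cycle noise. In the zero-noise limit the
#' delta-delta-Ct estimator recovers the planted fold change exactly.
#'
#' @param config a [qpcr_config()].
#' @return data.frame with columns `sample`, `group`, `gene`
#'   (`"target"`/`"reference"`) and `ct`.
#' @export
generate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_config"))
  calibrator <- config$groups[length(config$groups)]
  with_stream_seed(config$seed, "qpcr", {
    rows <- lapply(config$groups, function(g) {
      expr <- if (g == calibrator) 1 else config$true_fold_change
      n <- config$n_replicates
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), seq_len(n))
      ref_ct <- config$reference_gene_ct_mean + stats::rnorm(n, 0, config$ct_noise_sd)
      tgt_ct <- ref_ct + config$target_ct_offset - log2(expr) +
        stats::rnorm(n, 0, config$ct_noise_sd)
      data.frame(sample = rep(id, 2L), group = rep(g, 2L * n),
                 gene = rep(c("reference", "target"), each = n),
                 ct = c(ref_ct, tgt_ct), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
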