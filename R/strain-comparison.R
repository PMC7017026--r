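## Private/shared SNP provenance against a strain panel, strain-similarity
## ranking, label-split density tracks and marker-based region genotyping.

#' Classify segment SNPs as private or shared against a strain panel
#'
#' A site is `shared` if at least one panel strain carries the non-reference
#' allele, otherwise `private` (found uniquely in the query region). Sites
#' absent from the panel's catalogue are treated as carried by no strain —
#' the situation when calling privacy against an available catalogue — and
#' their count is reported with a message so users can audit it. An empty
#' panel classifies every site private, with a warning.
#'
#' @param sites data.frame with columns `chrom`, `pos` (the query sites,
#'   typically het calls inside a called segment).
#' @param panel a [strain_panel()].
#' @return data.frame `chrom`, `pos`, `label` (`"private"`/`"shared"`),
#'   `n_sharing`, `in_panel`, and `sharing_strains` (`";"`-collapsed labels).
#' @export
classify_private <- function(sites, panel) {
  stopifnot(inherits(panel, "strain_panel"),
            all(c("chrom", "pos") %in% names(sites)))
  n <- nrow(sites)
  if (length(panel$strains) == 0L)
    warnf("classify_private: empty panel; every site is classified private")
  idx <- match(paste(sites$chrom, sites$pos),
               paste(panel$sites$chrom, panel$sites$pos))
  if (any(is.na(idx)) && n > 0L)
    message(sprintf("classify_private: %d site(s) absent from panel catalogue (treated as carried by no strain)",
                    sum(is.na(idx))))
  carriers <- function(i) {
    if (is.na(i) || length(panel$strains) == 0L) character(0)
    else panel$strains[panel$alleles[i, ] == 1L]
  }
  who <- lapply(idx, carriers)
  n_sharing <- lengths(who)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             label = ifelse(n_sharing >= 1L, "shared", "private"),
             n_sharing = n_sharing, in_panel = !is.na(idx),
             sharing_strains = vapply(who, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Rank panel strains by similarity to the query region
#'
#' Similarity of a strain is the fraction of query sites whose non-reference
#' allele the strain carries (sites absent from the panel count as not
#' carried). Ranking is descending with a deterministic tie-break on strain
#' label (C-locale order).
#'
#' @param sites data.frame with columns `chrom`, `pos`; at least one site.
#' @param panel a [strain_panel()].
#' @return data.frame `strain`, `fraction`, `rank`, ordered by rank.
#' @export
strain_similarity <- function(sites, panel) {
  stopifnot(inherits(panel, "strain_panel"), nrow(sites) >= 1L)
  idx <- match(paste(sites$chrom, sites$pos),
               paste(panel$sites$chrom, panel$sites$pos))
  hitmat <- panel$alleles[idx[!is.na(idx)], , drop = FALSE]
  frac <- if (length(panel$strains)) colSums(hitmat) / nrow(sites) else numeric(0)
  out <- data.frame(strain = panel$strains, fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  out <- out[order_radix(-out$fraction, out$strain), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Label-split windowed density (private vs shared)
#'
#' Computes aligned per-window counts of private and shared sites on one
#' chromosome; each label class conserves its site count.
#'
#' @param sites data.frame `chrom`, `pos` on one chromosome.
#' @param labels character vector (`"private"`/`"shared"`), one per site,
#'   e.g. the `label` column of [classify_private()].
#' @param chromosome chromosome label.
#' @param chromosome_length chromosome length in bp.
#' @param params a [scan_params()] (window size).
#' @return a [window_density()] track whose `counts` is the total and which
#'   carries aligned `private` and `shared` count vectors.
#' @export
windowed_private_density <- function(sites, labels, chromosome,
                                     chromosome_length, params = scan_params()) {
  stopifnot(length(labels) == nrow(sites), all(labels %in% c("private", "shared")))
  as_calls <- function(keep) {
    n <- sum(keep)
    variant_calls(sites$chrom[keep], sites$pos[keep], rep("A", n), rep("G", n),
                  rep("het", n), rep(1000, n), rep(TRUE, n))
  }
  priv <- window_density(as_calls(labels == "private"), chromosome,
                         chromosome_length, params)
  shar <- window_density(as_calls(labels == "shared"), chromosome,
                         chromosome_length, params)
  track <- priv
  track$counts <- priv$counts + shar$counts
  track$private <- priv$counts
  track$shared <- shar$counts
  track
}

#' Start of the span maximizing private-SNP count
#'
#' Slides a fixed-width span (default 10 Mb) in window-sized steps (default
#' 1 Mb) across a label-split track and returns the first span with the
#' maximal private-site count — the "where do the region-private variants
#' cluster" summary.
#'
#' @param track a [windowed_private_density()] track.
#' @param span_windows span width in windows (default 10).
#' @return list with `start` (1-based bp of the span's first window),
#'   `end`, and `count` (private sites inside the span).
#' @export
max_private_span <- function(track, span_windows = 10L) {
  stopifnot(inherits(track, "window_track"), !is.null(track$private))
  k <- min(span_windows, length(track$private))
  sums <- stats::filter(track$private, rep(1, k), sides = 1)
  sums <- as.numeric(sums[k:length(track$private)])  # span starting at window i sums i..i+k-1
  best <- which.max(sums)  # first maximum: deterministic tie-break
  list(start = track$start[best], end = track$end[best + k - 1L],
       count = sums[best])
}

#' Genotype individuals at the region's diagnostic marker SNPs
#'
#' Derives a region genotype per animal from its per-marker calls: all
#' markers heterozygous gives `int/+` (one introgressed copy), all
#' homozygous-alt `int/int`, all homozygous-ref `+/+`. Any mixed pattern is
#' reported as `discordant` (a possible recombinant) and never silently
#' resolved to a majority call. Missing marker calls are ignored; an animal
#' with no informative call is `discordant`.
#'
#' @param marker_calls data.frame with columns `animal`, `marker`,
#'   `genotype` (one of het/hom_ref/hom_alt/missing).
#' @param markers optional character vector of known marker ids; calls at
#'   markers outside it are an error.
#' @return data.frame `animal`, `n_markers`, `region_genotype`.
#' @export
genotype_region <- function(marker_calls, markers = NULL) {
  stopifnot(all(c("animal", "marker", "genotype") %in% names(marker_calls)),
            nrow(marker_calls) >= 1L)
  if (!all(marker_calls$genotype %in% GENOTYPE_LEVELS))
    stopf("genotype must be one of: %s", paste(GENOTYPE_LEVELS, collapse = ", "))
  if (!is.null(markers)) {
    bad <- setdiff(unique(marker_calls$marker), markers)
    if (length(bad)) stopf("unknown marker id: %s", paste(bad, collapse = ", "))
  }
  per <- split(marker_calls$genotype, marker_calls$animal)
  call_one <- function(g) {
    g <- g[g != "missing"]
    if (!length(g)) return("discordant")
    u <- unique(g)
    if (length(u) > 1L) return("discordant")
    switch(u, het = "int/+", hom_alt = "int/int", hom_ref = "+/+")
  }
  data.frame(animal = names(per),
             n_markers = lengths(per),
             region_genotype = vapply(per, call_one, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pick evenly spaced diagnostic marker sites across a segment
#'
#' Convenience for building a marker set (default nine loci) spanning a
#' called region, for downstream colony genotyping.
#'
#' @param calls het calls supporting the segment.
#' @param segment one-row segment data.frame.
#' @param n number of markers.
#' @return data.frame `marker`, `chrom`, `pos`, `ref`, `alt`.
#' @export
select_markers <- function(calls, segment, n = 9L) {
  validate_calls(calls)
  sel <- calls$chrom == segment$chrom &
    calls$pos >= segment$start & calls$pos <= segment$end
  cand <- calls[sel, , drop = FALSE]
  cand <- cand[order(cand$pos), , drop = FALSE]
  if (nrow(cand) < n) stopf("segment has only %d candidate sites (< %d)", nrow(cand), n)
  pick <- cand[round(seq(1, nrow(cand), length.out = n)), , drop = FALSE]
  data.frame(marker = sprintf("M%02d", seq_len(n)), chrom = pick$chrom,
             pos = pick$pos, ref = pick$ref, alt = pick$alt,
             stringsAsFactors = FALSE)
}
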