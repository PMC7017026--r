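## File formats: minimal single-sample VCF v4.2, BED (0-based half-open) and
## tab-delimited strain panels / cohort / Ct tables. All in-memory positions
## are 1-based inclusive; only BED output switches convention.

GT_MAP <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
            "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
            "1/1" = "hom_alt", "1|1" = "hom_alt",
            "./." = "missing", "." = "missing", ".|." = "missing")

#' Read a single-sample VCF into a variant-call table
#'
#' Parses a (plain-text) VCF v4.2 via \pkg{vcfR} and maps it onto the
#' package's call table: GT to zygosity, INFO `MQ` to `mapping_quality`, and
#' FILTER to `status_pass` (`PASS` and `.` pass, anything else fails). Only
#' biallelic SNP records (single-base REF and ALT) enter the pipeline; others
#' are dropped with a message giving the count. Records lacking the `MQ`
#' annotation are retained with `mapping_quality = NA` and a warning.
#'
#' @param path VCF file path.
#' @param chrom,start,end optional region filter (1-based inclusive).
#' @return a [variant_calls()] data.frame.
#' @export
read_vcf <- function(path, chrom = NULL, start = NULL, end = NULL) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  gt <- vcf@gt
  if (nrow(fix) == 0L) return(empty_calls())
  if (is.null(gt) || ncol(gt) < 2L)
    stopf("VCF has no sample genotype column: %s", path)
  if (ncol(gt) > 2L)
    stopf("multi-sample VCF not supported (%d samples): %s", ncol(gt) - 1L, path)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & ref %in% BASES & alt %in% BASES
  if (any(!snp))
    message(sprintf("read_vcf: dropped %d non-SNP record(s)", sum(!snp)))

  gt_raw <- unname(vcfR::extract.gt(vcf, element = "GT")[, 1L])
  geno <- unname(GT_MAP[gt_raw])
  geno[is.na(geno)] <- "missing"
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "MQ")))
  if (any(is.na(mq[snp])))
    warnf("read_vcf: %d record(s) lack INFO/MQ; retained with NA mapping_quality",
          sum(is.na(mq[snp])))
  filt <- fix[, "FILTER"]
  pass <- !is.na(filt) & filt %in% c("PASS", ".")

  calls <- variant_calls(fix[snp, "CHROM"], as.numeric(fix[snp, "POS"]),
                         ref[snp], alt[snp], geno[snp], mq[snp], pass[snp])
  if (!is.null(chrom)) {
    keep <- calls$chrom == chrom
    if (!is.null(start)) keep <- keep & calls$pos >= start
    if (!is.null(end)) keep <- keep & calls$pos <= end
    calls <- calls[keep, , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls
}

#' Write a variant-call table as minimal VCF v4.2
#'
#' One sample, GT-only FORMAT, mapping quality as INFO `MQ`, FILTER `PASS`
#' or `FAIL` from `status_pass`. Records are written sorted by
#' (chromosome, position) so output is deterministic.
#'
#' @param calls a [variant_calls()] data.frame.
#' @param path output path.
#' @param sample_name sample column header.
#' @param contig_lengths optional named vector written as contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE", contig_lengths = NULL) {
  validate_calls(calls)
  calls <- calls[order_radix(calls$chrom, calls$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=introscan",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Per-site mapping quality\">",
    "##FILTER=<ID=FAIL,Description=\"Failed caller internal status check\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  gt_code <- c(het = "0/1", hom_ref = "0/0", hom_alt = "1/1", missing = "./.")
  info <- ifelse(is.na(calls$mapping_quality), ".",
                 sprintf("MQ=%.10g", calls$mapping_quality))
  body <- sprintf("%s\t%.0f\t.\t%s\t%s\t.\t%s\t%s\tGT\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  ifelse(calls$status_pass, "PASS", "FAIL"),
                  info, gt_code[calls$genotype])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genomic segments as BED
#'
#' Output is BED with 0-based half-open coordinates (internal coordinates are
#' 1-based inclusive, so `start - 1` and `end` are written), the name column
#' carrying the segment classification and the score column the supporting
#' SNP count. Rows are ordered by (chromosome, start).
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `classification` and (optionally) `n_supporting_snps`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  if (nrow(segments) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", "classification") %in% names(segments)),
            all(segments$start < segments$end | segments$start == segments$end))
  segments <- segments[order_radix(segments$chrom, segments$start), , drop = FALSE]
  n <- if ("n_supporting_snps" %in% names(segments)) segments$n_supporting_snps
       else rep(0, nrow(segments))
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%.0f",
                     segments$chrom, segments$start - 1, segments$end,
                     segments$classification, n),
             path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED3+ file (chrom, start, end, optional name, optional score).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), plus
#'   `name` and `score` when present.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, fill = FALSE)
  if (ncol(x) < 3L) stopf("BED file needs at least 3 columns: %s", path)
  out <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]) + 1,
                    end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) out$name <- as.character(x[[4]])
  if (ncol(x) >= 5L) out$score <- as.numeric(x[[5]])
  out
}

#' Strain genotype panel
#'
#' A strain-by-site presence/absence catalogue of the non-reference allele:
#' `sites` is one row per (chromosome, position, ref, alt) and `alleles` a
#' sites x strains 0/1 matrix.
#'
#' @param strains ordered character strain labels.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, no
#'   duplicate (chrom, pos).
#' @param alleles integer 0/1 matrix, `nrow(sites)` x `length(strains)`.
#' @return object of class `strain_panel`.
#' @export
strain_panel <- function(strains, sites, alleles) {
  stopifnot(is.character(strains),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != nrow(sites) || ncol(alleles) != length(strains))
    stopf("alleles matrix must be %d sites x %d strains", nrow(sites), length(strains))
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stopf("duplicate (chromosome, position) site in panel")
  if (nrow(alleles) && any(!alleles %in% c(0L, 1L)))
    stopf("panel alleles must be 0/1")
  colnames(alleles) <- strains
  rownames(sites) <- NULL
  structure(list(strains = strains, sites = sites, alleles = alleles),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("strain_panel: %d strains x %d sites\n",
              length(x$strains), nrow(x$sites)))
  invisible(x)
}

#' Write a strain panel as tab-delimited text
#'
#' One row per site; columns `chrom`, `pos`, `ref`, `alt`, then one 0/1
#' column per strain.
#'
#' @param panel a [strain_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strain_panel <- function(panel, path) {
  stopifnot(inherits(panel, "strain_panel"))
  tab <- cbind(panel$sites, as.data.frame(panel$alleles, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a strain panel from tab-delimited text
#'
#' @param path file written by [write_strain_panel()] (or equivalent): header
#'   row, then one row per site with `chrom`, `pos`, `ref`, `alt` and one
#'   column per strain. Ragged rows and duplicate sites are errors.
#' @return a [strain_panel()].
#' @export
read_strain_panel <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           fill = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stopf("panel file must start with columns: %s", paste(need, collapse = ", "))
  strains <- setdiff(names(tab), need)
  strain_panel(strains, tab[, need, drop = FALSE],
               as.matrix(tab[, strains, drop = FALSE]))
}

#' Write/read small delimited tables (cohorts, Ct tables, tracks, reports)
#'
#' Plain tab-delimited text with a header row; the common interchange format
#' for every non-VCF/BED table the pipeline touches.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
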