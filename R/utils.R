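## Internal helpers: seed sub-streams, validation, deterministic ordering.

GENOTYPE_LEVELS <- c("het", "hom_ref", "hom_alt", "missing")
BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-stream seed
#'
#' A single user-facing integer seed is fanned out into named sub-streams
#' (one per generator) so that each synthetic output is reproducible on its
#' own, independent of how many other generators ran before it.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer seed in [0, 2^31).
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  # small deterministic hash of the stream name, folded with the master seed
  h <- sum(codes * seq_along(codes)) %% 97561L
  as.integer((abs(as.numeric(seed)) * 48271 + h * 131 + 7) %% 2147483647)
}

# Evaluate `code` under a stream-derived seed, restoring the caller's RNG
# state afterwards (no hidden global state leaks out of the generators).
with_stream_seed <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

# locale-independent ordering (radix = C collation), used everywhere a
# deterministic on-disk ordering is promised
order_radix <- function(...) order(..., method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Assemble a set of variant calls
#'
#' The exchange container used throughout the package: one row per called SNP
#' site with 1-based position, single-base REF/ALT alleles, zygosity,
#' a per-site quality score and the caller's internal status flag.
#'
#' @param chrom character chromosome labels.
#' @param pos integer 1-based positions.
#' @param ref,alt single-base alleles (A/C/G/T).
#' @param genotype one of `"het"`, `"hom_ref"`, `"hom_alt"`, `"missing"`.
#' @param mapping_quality non-negative per-site quality score (NA allowed for
#'   calls read from files lacking the annotation).
#' @param status_pass logical; did the call pass the caller's internal check.
#' @return data.frame with the seven columns above, ordered by
#'   (chromosome, position).
#' @export
variant_calls <- function(chrom, pos, ref, alt, genotype,
                          mapping_quality, status_pass) {
  calls <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    genotype = as.character(genotype),
    mapping_quality = as.numeric(mapping_quality),
    status_pass = as.logical(status_pass),
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
  calls[order_radix(calls$chrom, calls$pos), , drop = FALSE]
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  need <- c("chrom", "pos", "ref", "alt", "genotype",
            "mapping_quality", "status_pass")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stopf("call set lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  if (any(calls$pos < 1)) stopf("positions must be >= 1 (1-based coordinates)")
  if (!all(calls$genotype %in% GENOTYPE_LEVELS))
    stopf("genotype must be one of: %s", paste(GENOTYPE_LEVELS, collapse = ", "))
  if (!all(calls$ref %in% BASES) || !all(calls$alt %in% BASES))
    stopf("only single-base A/C/G/T alleles are supported (SNPs)")
  bad_het <- calls$genotype == "het" & calls$ref == calls$alt
  if (any(bad_het)) stopf("heterozygous call with REF == ALT at row %d", which(bad_het)[1])
  if (any(!is.na(calls$mapping_quality) & calls$mapping_quality < 0))
    stopf("mapping_quality must be non-negative")
  invisible(calls)
}

empty_calls <- function() {
  variant_calls(character(), numeric(), character(), character(),
                character(), numeric(), logical())
}
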