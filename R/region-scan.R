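## Discovery core: quality filtering, windowed heterozygous-SNP density,
## run-based segment calling with artifact triage, variant-devoid gaps and
## feature-interval annotation.

#' Scan parameters
#'
#' @param mq_threshold minimum per-site quality score retained by
#'   [apply_quality_filters()]; calls with a score strictly below it are
#'   removed (default 200, the conventional high-confidence cutoff for
#'   GATK-style scores on inbred resequencing data).
#' @param window_size density window width in bp (default 1 Mb). Windows form
#'   a fixed grid anchored at bp 1; the last partial window is included.
#' @param min_snps_per_window per-window call count at or above which a
#'   window counts as a "significant cluster" (default 5: comfortably above
#'   what scattered error clusters of 1-5 sites leave after quality
#'   filtering, and far below a real introgressed density of tens per Mb).
#' @param max_gap_windows number of consecutive below-threshold windows
#'   bridged inside one segment (default 5). Introgressed mosaics contain
#'   reference-homozygous blocks and can contain multi-Mb variant-devoid
#'   gaps; a bridge of 5 windows keeps a region with an internal gap of up to
#'   ~5 Mb intact as a single segment while never joining clusters separated
#'   by more than that.
#' @param min_segment_windows runs spanning fewer windows than this are
#'   classified `artifact_candidate` rather than `introgressed` (default 3).
#' @return object of class `scan_params`.
#' @export
scan_params <- function(mq_threshold = 200, window_size = 1e6,
                        min_snps_per_window = 5, max_gap_windows = 5,
                        min_segment_windows = 3) {
  stopifnot(mq_threshold >= 0, window_size >= 1, min_snps_per_window >= 0,
            max_gap_windows >= 0, min_segment_windows >= 0)
  structure(list(mq_threshold = mq_threshold, window_size = window_size,
                 min_snps_per_window = min_snps_per_window,
                 max_gap_windows = max_gap_windows,
                 min_segment_windows = min_segment_windows),
            class = "scan_params")
}

#' Quality-filter a call set
#'
#' Retains calls that passed the caller's internal status check AND have
#' mapping quality at or above `mq_threshold`; a call with score 199 is
#' removed at the default threshold of 200, a call at exactly 200 retained.
#' Calls with missing mapping quality fail the quality criterion
#' (conservative).
#'
#' @param calls a [variant_calls()] data.frame.
#' @param params a [scan_params()].
#' @return list with `calls` (the retained subset) and `removed`, a named
#'   count per criterion (`failed_status`, `low_mapping_quality`; a call
#'   failing both is counted under both).
#' @export
apply_quality_filters <- function(calls, params = scan_params()) {
  validate_calls(calls)
  mq_ok <- !is.na(calls$mapping_quality) & calls$mapping_quality >= params$mq_threshold
  keep <- calls$status_pass & mq_ok
  list(calls = calls[keep, , drop = FALSE],
       removed = c(failed_status = sum(!calls$status_pass),
                   low_mapping_quality = sum(!mq_ok)))
}

#' Select heterozygous non-reference calls
#'
#' The diagnostic signature of a non-recipient segment on an inbred
#' background is the heterozygous state; everything else is dropped.
#'
#' @param calls a [variant_calls()] data.frame.
#' @return the het subset.
#' @export
select_het_nonref <- function(calls) {
  validate_calls(calls)
  calls[calls$genotype == "het", , drop = FALSE]
}

#' Per-window SNP density on one chromosome
#'
#' Window `i` (1-based) covers bp `[(i-1)*w + 1, i*w]` on a fixed grid
#' anchored at bp 1; the final partial window is included. Window counts
#' always sum to the number of input calls on the chromosome.
#'
#' @param calls calls (any chromosomes; the `chromosome` subset is used).
#' @param chromosome chromosome label.
#' @param chromosome_length chromosome length in bp.
#' @param params a [scan_params()] (only `window_size` is used).
#' @return object of class `window_track`: list with `chromosome`,
#'   `window_size`, `chromosome_length`, `counts` (one per window), and
#'   `start`/`end` vectors of 1-based window bounds.
#' @export
window_density <- function(calls, chromosome, chromosome_length,
                           params = scan_params()) {
  validate_calls(calls)
  w <- params$window_size
  pos <- calls$pos[calls$chrom == chromosome]
  if (length(pos) && max(pos) > chromosome_length)
    stopf("call position %d beyond chromosome length %d", max(pos), chromosome_length)
  n_win <- as.integer(ceiling(chromosome_length / w))
  counts <- tabulate((pos - 1) %/% w + 1, nbins = n_win)
  start <- (seq_len(n_win) - 1) * w + 1
  structure(list(chromosome = chromosome, window_size = w,
                 chromosome_length = chromosome_length, counts = counts,
                 start = start, end = pmin(start + w - 1, chromosome_length)),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("window_track: %s, %d windows of %g bp, %d calls\n",
              x$chromosome, length(x$counts), x$window_size, sum(x$counts)))
  invisible(x)
}

#' Call candidate introgressed segments from a density track
#'
#' Finds maximal runs of windows whose count reaches
#' `min_snps_per_window`, bridging up to `max_gap_windows` consecutive
#' below-threshold windows inside a run (introgressed regions are mosaics:
#' internal reference-homozygous blocks and variant-devoid gaps must not
#' split them). Runs spanning fewer than `min_segment_windows` windows are
#' classified `artifact_candidate`, the rest `introgressed`. When `calls`
#' are supplied, segment boundaries are trimmed from window edges to the
#' first/last supporting SNP, giving sub-window boundary resolution.
#'
#' @param track a [window_density()] track.
#' @param params a [scan_params()].
#' @param calls optional calls on the track's chromosome used for boundary
#'   trimming and support counts.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `n_supporting_snps`, `n_windows`, `classification`.
#' @export
call_segments <- function(track, params = scan_params(), calls = NULL) {
  stopifnot(inherits(track, "window_track"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_supporting_snps = numeric(), n_windows = integer(),
                      classification = character(), stringsAsFactors = FALSE)
  hot <- which(track$counts >= params$min_snps_per_window)
  if (!length(hot)) return(empty)
  grp <- cumsum(c(1L, diff(hot) - 1L > params$max_gap_windows))
  pos <- if (!is.null(calls)) sort(calls$pos[calls$chrom == track$chromosome])
  segs <- lapply(split(hot, grp), function(idx) {
    w1 <- min(idx); w2 <- max(idx)
    start <- track$start[w1]
    end <- track$end[w2]
    n <- sum(track$counts[w1:w2])
    if (!is.null(pos)) {
      inside <- pos[pos >= start & pos <= end]
      if (length(inside)) {
        start <- min(inside); end <- max(inside); n <- length(inside)
      }
    }
    data.frame(chrom = track$chromosome, start = start, end = end,
               n_supporting_snps = n, n_windows = w2 - w1 + 1L,
               classification = if (w2 - w1 + 1L < params$min_segment_windows)
                 "artifact_candidate" else "introgressed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out[order_radix(out$chrom, out$start), , drop = FALSE]
}

#' Annotate called segments for artifact triage
#'
#' Adds the mean mapping quality and supporting-call count of each segment,
#' the quantities used to triage `artifact_candidate` clusters (small,
#' scattered, quality-degraded) against genuine introgressed segments.
#'
#' @param segments output of [call_segments()] (possibly several chromosomes
#'   row-bound).
#' @param calls the calls the segments were derived from.
#' @return `segments` with additional columns `mean_mq` and `n_calls`.
#' @export
flag_artifact_clusters <- function(segments, calls) {
  validate_calls(calls)
  if (nrow(segments) == 0L) {
    segments$mean_mq <- numeric(0)
    segments$n_calls <- integer(0)
    return(segments)
  }
  ann <- t(vapply(seq_len(nrow(segments)), function(i) {
    sel <- calls$chrom == segments$chrom[i] &
      calls$pos >= segments$start[i] & calls$pos <= segments$end[i]
    c(mean(calls$mapping_quality[sel], na.rm = TRUE), sum(sel))
  }, numeric(2)))
  segments$mean_mq <- ann[, 1]
  segments$n_calls <- as.integer(ann[, 2])
  segments
}

#' Find variant-devoid gaps inside a segment
#'
#' Maximal intervals inside the segment, of width at least `min_gap_bp`,
#' containing zero heterozygous non-reference calls — the pattern seen where
#' a called introgressed region contains a multi-Mb stretch with no
#' non-recipient variants at all.
#'
#' @param segment one-row data.frame with `chrom`, `start`, `end`.
#' @param calls het calls (restricted to the segment's chromosome; positions
#'   outside the segment are ignored).
#' @param min_gap_bp minimum reported gap width in bp (default 1 Mb).
#' @return data.frame `chrom`, `start`, `end`, `width_bp`, sorted by width
#'   descending (ties by start).
#' @export
find_devoid_gaps <- function(segment, calls, min_gap_bp = 1e6) {
  stopifnot(nrow(segment) == 1L)
  validate_calls(calls)
  s <- segment$start; e <- segment$end
  pos <- sort(calls$pos[calls$chrom == segment$chrom & calls$pos >= s & calls$pos <= e])
  bounds <- c(s - 1, pos, e + 1)
  gs <- bounds[-length(bounds)] + 1
  ge <- bounds[-1] - 1
  width <- ge - gs + 1
  keep <- width >= min_gap_bp
  out <- data.frame(chrom = rep(segment$chrom, sum(keep)), start = gs[keep],
                    end = ge[keep], width_bp = width[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$width_bp, out$start), , drop = FALSE]
}

#' Overlap features with segments and devoid gaps
#'
#' For each feature interval (e.g. gene or marker from a BED file, 1-based
#' inclusive after [read_bed()]), reports whether it overlaps any called
#' segment and whether it falls wholly inside any variant-devoid gap. Both
#' inputs must share one coordinate convention and assembly; a mismatch is
#' not detectable.
#'
#' @param segments data.frame `chrom`, `start`, `end` (1-based inclusive).
#' @param features data.frame `chrom`, `start`, `end`, optional `name`.
#' @param gaps optional data.frame of devoid gaps (`chrom`, `start`, `end`).
#' @return `features` with logical columns `overlaps_segment` and `in_gap`.
#' @export
annotate_intervals <- function(segments, features, gaps = NULL) {
  hit <- function(query, subject, type) {
    out <- rep(FALSE, nrow(query))
    if (is.null(subject) || nrow(subject) == 0L || nrow(query) == 0L) return(out)
    for (ch in unique(query$chrom)) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      if (!length(si)) next
      q <- IRanges::IRanges(query$start[qi], query$end[qi])
      s <- IRanges::IRanges(subject$start[si], subject$end[si])
      out[qi] <- IRanges::overlapsAny(q, s, type = type)
    }
    out
  }
  features$overlaps_segment <- hit(features, segments, "any")
  features$in_gap <- hit(features, gaps, "within")
  features
}
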