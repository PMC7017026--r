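## Downstream statistics: exact contingency tests (2x2 hypergeometric tail
## summation; RxC Freeman-Halton full enumeration; Monte-Carlo fallback),
## Welch's t-test and delta-delta-Ct relative quantification.

# log point probability of a table under fixed margins (multivariate
# hypergeometric): sum(lfact(row)) + sum(lfact(col)) - lfact(n) - sum(lfact(cells))
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

validate_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("contingency table needs at least 2 rows and 2 columns")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("contingency table must hold non-negative integer counts")
  if (sum(tab) == 0) stopf("contingency table total must be > 0")
  storage.mode(tab) <- "double"
  tab
}

#' Two-sided exact test of independence for a contingency table
#'
#' For a 2x2 table, the exact conditional test: the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed the observed table's
#' (the point-probability two-sided convention used by common statistical
#' software). For larger R x C tables, the Freeman-Halton extension: full
#' recursive enumeration of every table with the observed margins, summing
#' probabilities by the same criterion.
#'
#' @param tab integer matrix of counts (rows e.g. genotypes, columns e.g.
#'   phenotypic sexes or gonad categories); at least 2x2. Tables whose total
#'   exceeds 200 (or whose enumeration would exceed ~2e6 tables) are
#'   rejected with an error advising [monte_carlo_exact()].
#' @return list with `p_value`, `point_probability`, and `method`.
#' @export
fisher_exact <- function(tab) {
  tab <- validate_table(tab)
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    r <- rowSums(tab); cs <- colSums(tab)
    supp <- max(0, cs[1] - r[2]):min(r[1], cs[1])
    probs <- stats::dhyper(supp, r[1], r[2], cs[1])
    p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], cs[1])
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p_value = min(p, 1), point_probability = p_obs,
                method = "2x2 exact (hypergeometric tail summation)"))
  }
  n <- sum(tab)
  r <- rowSums(tab); cs <- colSums(tab)
  n_free <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  bound <- prod(pmin(rep(max(r), n_free), max(cs)) + 1)
  if (n > 200 || bound > 2e6)
    stopf("table too large for full enumeration; use monte_carlo_exact()")
  log_obs <- log_table_prob(tab)
  tol <- 1e-7
  lr <- sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(n)
  p <- 0
  R <- nrow(tab); C <- ncol(tab)
  cells <- matrix(0, R, C)
  # enumerate rows 1..R-1 left to right; last row and last column determined
  recurse <- function(i, j, col_rem, row_rem, lcells) {
    if (i == R) {
      # last row forced to the remaining column totals
      lp <- lr - lcells - sum(lfactorial(col_rem))
      if (lp <= log_obs + tol) p <<- p + exp(lp)
      return(invisible())
    }
    if (j == C) {
      # last cell of the row forced
      v <- row_rem
      if (v > col_rem[C]) return(invisible())
      recurse(i + 1L, 1L, col_rem - c(rep(0, C - 1L), v),
              r[i + 1L], lcells + lfactorial(v))
      return(invisible())
    }
    later_cap <- sum(r[(i + 1L):R])  # what rows below can still absorb in column j
    lo <- max(0, col_rem[j] - later_cap)
    hi <- min(row_rem, col_rem[j])
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      cr <- col_rem; cr[j] <- cr[j] - v
      recurse(i, j + 1L, cr, row_rem - v, lcells + lfactorial(v))
    }
  }
  recurse(1L, 1L, cs, r[1], 0)
  list(p_value = min(p, 1), point_probability = exp(log_obs),
       method = "RxC exact (Freeman-Halton full enumeration)")
}

#' Monte-Carlo estimate of the exact two-sided p-value
#'
#' Resamples tables with the observed margins (Patefield's algorithm via
#' [stats::r2dtable()]) and estimates the proportion whose point probability
#' does not exceed the observed table's, with the (k + 1)/(N + 1) correction
#' so the estimate is never exactly zero. The fallback for tables too large
#' for [fisher_exact()]'s full enumeration.
#'
#' @param tab integer matrix of counts, at least 2x2.
#' @param n_draws number of resampled tables (>= 1000).
#' @param seed integer seed (reproducible estimates).
#' @return list with `p_value`, `conf_int` (95% binomial CI on the
#'   uncorrected proportion), `n_draws`, `method`.
#' @export
monte_carlo_exact <- function(tab, n_draws = 10000L, seed = 1L) {
  tab <- validate_table(tab)
  if (n_draws < 1000L) stopf("n_draws must be >= 1000")
  log_obs <- log_table_prob(tab)
  k <- with_stream_seed(seed, "monte_carlo_exact", {
    draws <- stats::r2dtable(n_draws, rowSums(tab), colSums(tab))
    sum(vapply(draws, log_table_prob, 0) <= log_obs + 1e-7)
  })
  ci <- stats::binom.test(k, n_draws)$conf.int
  list(p_value = (k + 1) / (n_draws + 1), conf_int = as.numeric(ci),
       n_draws = n_draws, method = "margin-fixed Monte-Carlo exact test")
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used for between-genotype expression
#' comparisons. Requires n >= 2 per sample; if both samples have zero
#' variance the test degenerates (p = 1 for equal means, p = 0 otherwise).
#'
#' @param sample_a,sample_b numeric vectors.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("welch_t needs at least 2 observations per sample")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    eq <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    return(list(t = if (eq) 0 else sign(mean(sample_a) - mean(sample_b)) * Inf,
                df = NA_real_, p_value = if (eq) 1 else 0))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, delta-Ct = Ct(target) - Ct(reference); per group,
#' delta-delta-Ct = mean delta-Ct(group) - mean delta-Ct(calibrator); fold
#' change = 2^(-delta-delta-Ct), so the calibrator group is 1 by
#' construction. Averaging happens on the cycle (log) scale before
#' exponentiating, the standard relative-quantification procedure.
#' Per-sample relative quantities 2^(-(delta-Ct - mean delta-Ct(calibrator)))
#' are returned for plotting and between-group testing with [welch_t()].
#'
#' @param data data.frame with columns `sample`, `group`, `gene`, `ct` (one
#'   row per sample x gene). Samples missing either gene are excluded with a
#'   warning.
#' @param target_gene,reference_gene gene labels in `data$gene`.
#' @param calibrator_group group whose mean delta-Ct anchors the comparison.
#' @return list with `groups` (data.frame `group`, `n`, `mean_dct`, `ddct`,
#'   `fold_change`) and `samples` (data.frame `sample`, `group`, `dct`,
#'   `rel_quantity`).
#' @export
ddct_fold_change <- function(data, target_gene = "target",
                             reference_gene = "reference",
                             calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(data)))
  if (any(!is.finite(data$ct)) || any(data$ct <= 0))
    stopf("Ct values must be finite and positive")
  tgt <- data[data$gene == target_gene, ]
  ref <- data[data$gene == reference_gene, ]
  common <- intersect(tgt$sample, ref$sample)
  dropped <- setdiff(unique(data$sample), common)
  if (length(dropped))
    warnf("ddct_fold_change: excluded %d sample(s) missing a gene: %s",
          length(dropped), paste(dropped, collapse = ", "))
  ti <- match(common, tgt$sample)
  ri <- match(common, ref$sample)
  samples <- data.frame(sample = common, group = tgt$group[ti],
                        dct = tgt$ct[ti] - ref$ct[ri],
                        stringsAsFactors = FALSE)
  if (!calibrator_group %in% samples$group)
    stopf("calibrator group '%s' has no complete samples", calibrator_group)
  mean_cal <- mean(samples$dct[samples$group == calibrator_group])
  samples$rel_quantity <- 2^(-(samples$dct - mean_cal))
  grp <- unique(samples$group)
  mean_dct <- vapply(grp, function(g) mean(samples$dct[samples$group == g]), 0)
  groups <- data.frame(group = grp,
                       n = as.integer(table(samples$group)[grp]),
                       mean_dct = mean_dct,
                       ddct = mean_dct - mean_cal,
                       fold_change = 2^(-(mean_dct - mean_cal)),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(groups = groups, samples = samples)
}

#' Build a genotype-by-phenotype contingency table from a cohort
#'
#' @param cohort data.frame with columns `genotype` and the phenotype column.
#' @param phenotype `"sex"` or `"gonad"`; gonad tables keep the ordinal
#'   category order O, Ot, ot, oT, T and drop all-zero columns (categories
#'   never observed) with a message.
#' @return integer matrix of counts.
#' @export
cohort_contingency <- function(cohort, phenotype = c("sex", "gonad")) {
  phenotype <- match.arg(phenotype)
  stopifnot(all(c("genotype", phenotype) %in% names(cohort)))
  lev <- if (phenotype == "gonad") GONAD_CATEGORIES else sort(unique(cohort$sex))
  tab <- table(factor(cohort$genotype), factor(cohort[[phenotype]], levels = lev))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  zero_col <- colSums(m) == 0L
  if (any(zero_col)) {
    message(sprintf("cohort_contingency: dropped empty column(s): %s",
                    paste(colnames(m)[zero_col], collapse = ", ")))
    m <- m[, !zero_col, drop = FALSE]
  }
  zero_row <- rowSums(m) == 0L
  if (any(zero_row)) {
    warnf("cohort_contingency: dropped empty row(s): %s",
          paste(rownames(m)[zero_row], collapse = ", "))
    m <- m[!zero_row, , drop = FALSE]
  }
  m
}
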