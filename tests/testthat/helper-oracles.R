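# Independent oracles and small fixture builders used across the suite.

# brute-force per-window counting by explicit interval membership
oracle_window_counts <- function(pos, chrom_len, w) {
  n_win <- ceiling(chrom_len / w)
  vapply(seq_len(n_win), function(i) {
    lo <- (i - 1) * w + 1
    hi <- min(i * w, chrom_len)
    sum(pos >= lo & pos <= hi)
  }, 0L)
}

# quadratic all-pairs interval overlap
oracle_overlaps <- function(features, subjects, within = FALSE) {
  vapply(seq_len(nrow(features)), function(i) {
    any(vapply(seq_len(nrow(subjects)), function(j) {
      if (features$chrom[i] != subjects$chrom[j]) return(FALSE)
      if (within)
        features$start[i] >= subjects$start[j] && features$end[i] <= subjects$end[j]
      else
        features$start[i] <= subjects$end[j] && features$end[i] >= subjects$start[j]
    }, logical(1)))
  }, logical(1))
}

# brute-force devoid-gap scan over sorted positions
oracle_gaps <- function(start, end, pos, min_gap) {
  pos <- sort(pos[pos >= start & pos <= end])
  edges <- c(start - 1, pos, end + 1)
  out <- data.frame(start = numeric(), end = numeric(), width = numeric())
  for (i in seq_len(length(edges) - 1)) {
    g0 <- edges[i] + 1
    g1 <- edges[i + 1] - 1
    if (g1 - g0 + 1 >= min_gap)
      out <- rbind(out, data.frame(start = g0, end = g1, width = g1 - g0 + 1))
  }
  out[order(-out$width, out$start), , drop = FALSE]
}

# exhaustive two-sided exact p for a 2xC table: enumerate every first row
# compatible with the margins; conditional probability from binomial
# coefficients (product over columns of choose(c_j, x_j), normalized)
oracle_exact_p <- function(tab) {
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  grid <- expand.grid(lapply(cs, function(cj) 0:cj))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  logw <- apply(grid, 1, function(x) sum(lchoose(cs, x)))
  w <- exp(logw - max(logw))
  p_all <- w / sum(w)
  obs <- which(apply(grid, 1, function(x) all(x == tab[1, ])))
  sum(p_all[p_all <= p_all[obs] * (1 + 1e-7)])
}

# textbook Welch formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small hand-built call set
make_calls <- function(pos, chrom = "chr13", genotype = "het",
                       mq = 600, pass = TRUE) {
  n <- length(pos)
  variant_calls(rep(chrom, n), pos, rep("A", n), rep("G", n),
                rep(genotype, length.out = n),
                rep(mq, length.out = n), rep(pass, length.out = n))
}

# tiny deterministic strain panel
make_panel <- function(strains = c("S1", "S2", "S3"),
                       pos = c(100, 200, 300), alleles = NULL) {
  sites <- data.frame(chrom = "chr13", pos = pos,
                      ref = rep("A", length(pos)), alt = rep("G", length(pos)),
                      stringsAsFactors = FALSE)
  if (is.null(alleles))
    alleles <- matrix(0L, nrow(sites), length(strains))
  strain_panel(strains, sites, alleles)
}
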