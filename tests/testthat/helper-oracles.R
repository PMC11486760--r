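# Independent oracles used across the suite. Each recomputes the target
# quantity by direct enumeration or textbook formulas, sharing no code
# with the implementation it checks.

# Exhaustive best circular split: scan every arc [i, j) with a plain
# double loop, computing the pooled-variance t from subset means/vars.
brute_force_best_split <- function(z, min_seg = 1L) {
  n <- length(z)
  m <- if (n >= 2 * min_seg) min_seg else 1L
  best <- list(i = NA, j = NA, statistic = 0)
  for (i in 0:(n - m)) {
    for (j in (i + m):min(n, i + n - m)) {
      arc <- z[(i + 1):j]
      comp <- z[-((i + 1):j)]
      na <- length(arc); nb <- length(comp)
      sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) /
        (n - 2)
      stat <- if (sp2 <= 0) {
        if (abs(mean(arc) - mean(comp)) < 1e-12) 0 else Inf
      } else abs(mean(arc) - mean(comp)) / sqrt(sp2 * (1 / na + 1 / nb))
      if (stat > best$statistic) best <- list(i = i, j = j, statistic = stat)
    }
  }
  best
}

# An arc starting at 0 and the arc that is its complement describe the
# same circular partition; map (0, j) onto (j, n) so representations of
# one split compare equal.
canonical_split <- function(i, j, n) {
  if (!is.na(i) && i == 0) c(j, n) else c(i, j)
}

# Two-sided Fisher p by margin-fixed hypergeometric enumeration: sum the
# point probabilities of all tables no more probable than the observed.
fisher_enumeration_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the pairwise-comparison U statistic with half credit for ties.
auc_pairwise <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Small toy-build grid shared by fixtures.
toy_grid <- function(lengths = c(2e6, 1e6), bin_width = 2e5) {
  make_bins(toy_genome(lengths, lengths / 2), bin_width)
}

# Deterministic diploid-ish profile on a grid.
flat_profile <- function(grid, value = 100, id = "flat") {
  coverage_profile(id, grid, rep(value, nrow(grid$bins)))
}

# Write a tiny FASTQ file; quals is a list of integer vectors.
write_fastq <- function(path, ids, seqs, quals) {
  lines <- unlist(mapply(function(id, s, q) {
    c(paste0("@", id), s, "+", intToUtf8(q + 33L, multiple = FALSE))
  }, ids, seqs, quals, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}
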