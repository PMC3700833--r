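# Independent oracles used across the test files. These deliberately take
# different computational routes from the package implementation.

# Audic-Claverie conditional pmf, written literally from the closed form
# (choose() in linear space, no logs): p(k|x) with r = n_b/n_a.
ac_pmf_literal <- function(k, x, n_a, n_b) {
  r <- n_b / n_a
  choose(x + k, k) * r^k / (1 + r)^(x + k + 1)
}

# Two-sided AC p-value by literal term-by-term summation.
ac_pvalue_bruteforce <- function(x, y, n_a, n_b) {
  p_lo <- sum(ac_pmf_literal(0:y, x, n_a, n_b))
  # upper tail: extend until terms are negligible
  kmax <- y
  repeat {
    kmax <- kmax + 50
    if (ac_pmf_literal(kmax, x, n_a, n_b) < 1e-30 || kmax > 1e6) break
  }
  p_hi <- sum(ac_pmf_literal(y:kmax, x, n_a, n_b))
  min(1, 2 * min(p_lo, min(p_hi, 1)))
}

# Brute-force tag classifier: enumerate all reference substrings by hand.
# Mirrors the priority rule but via naive scans, for bundles <= ~50 seqs.
classify_oracle <- function(tag, bundle) {
  mt <- bundle$mirna
  hit <- which(mt$seq == tag)
  if (length(hit) > 0) {
    j <- hit[order(mt$id[hit])][1]
    return(list(category = "miRNA", mirna = mt$id[j]))
  }
  for (j in order(mt$id)) {
    hp <- bundle$hairpin[[mt$hairpin_id[j]]]
    arm <- substr(hp, mt$arm_start[j], mt$arm_end[j])
    if (grepl(tag, arm, fixed = TRUE))
      return(list(category = "miRNA", mirna = mt$id[j]))
  }
  for (cl in c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA")) {
    for (s in bundle$ncrna$seq[bundle$ncrna$class == cl]) {
      if (grepl(tag, s, fixed = TRUE))
        return(list(category = cl, mirna = NA_character_))
    }
  }
  for (s in bundle$genome) {
    if (grepl(tag, s, fixed = TRUE))
      return(list(category = "genome_only", mirna = NA_character_))
  }
  list(category = "unmatched", mirna = NA_character_)
}

# All-pairs Duncan oracle: explicit enumeration of every range comparison
# plus the containment-protection closure. Returns a k x k logical matrix
# over groups sorted by decreasing mean: TRUE = significantly different.
duncan_oracle_matrix <- function(values, groups, alpha) {
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  k <- length(means)
  n <- if (length(unique(ns)) > 1) k / sum(1 / ns) else ns[1]
  fit <- stats::lm(v ~ g, data = data.frame(v = values, g = factor(groups)))
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  sig0 <- matrix(FALSE, k, k)
  if (mse > 0) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- j - i + 1
        alpha_p <- 1 - (1 - alpha)^(p - 1)
        Rp <- stats::qtukey(1 - alpha_p, p, dfe) * sqrt(mse / n)
        sig0[i, j] <- (m[i] - m[j]) > Rp
      }
    }
  }
  # containment closure: a pair is separated only if every enclosing range
  # is also raw-significant
  sep <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      enclosing_ok <- TRUE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if (!sig0[a, b]) enclosing_ok <- FALSE
        }
      }
      sep[i, j] <- enclosing_ok
    }
  }
  list(sep = sep, order = ord, groups = names(m))
}

# do two groups share at least one letter?
letters_shared <- function(letters_df, g1, g2) {
  l1 <- strsplit(letters_df$letters[letters_df$group == g1], "")[[1]]
  l2 <- strsplit(letters_df$letters[letters_df$group == g2], "")[[1]]
  length(intersect(l1, l2)) > 0
}

# tiny simulation config used throughout the unit tests
tiny_config <- function(...) {
  sim_config(n_mirnas = 30, library_sizes = c(a = 2e4, b = 2e4), ...)
}
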