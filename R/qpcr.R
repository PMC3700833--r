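# qRT-PCR relative quantification and group comparison.
#
# Relative expression uses the 2^-ddCt method against a reference assay
# (e.g. 5S rRNA): per replicate, dCt = Ct_target - Ct_reference, ddCt =
# dCt - mean dCt of the calibrator group, value = 2^-ddCt. Group means are
# compared by one-way ANOVA and Duncan's multiple range test, with the
# usual letter convention (groups sharing a letter are not significantly
# different; lowercase at alpha = 0.05, uppercase at alpha = 0.01).

#' Relative expression by the 2^-ddCt method
#'
#' Computed per biological replicate and then summarized: each replicate's
#' dCt (target minus reference Ct) is centred on the calibrator group's mean
#' dCt, and the relative level is 2 to the negative of that quantity. The
#' calibrator group goes through the same formula as every other group, so
#' its mean is exactly 1 only in the zero-noise limit. The standard error is
#' the sample SD of replicate values divided by sqrt(n).
#'
#' @param ct_table A `ct_table` (see [as_ct_table()] / [read_ct_table()]).
#' @param calibrator Group label used as the calibrator.
#' @return Object of class `rel_expression`: list with `values` (per
#'   replicate: `group`, `replicate`, `dct`, `ddct`, `value`), `summary`
#'   (per group: `n`, `mean`, `se`), and `calibrator`.
#' @export
ddct <- function(ct_table, calibrator) {
  ct_table <- as_ct_table(as.data.frame(ct_table))
  if (!calibrator %in% ct_table$group)
    stopf("calibrator group '%s' not present in the Ct table", calibrator)
  tgt <- ct_table[ct_table$assay == "target", ]
  ref <- ct_table[ct_table$assay == "reference", ]
  key <- function(d) paste(d$group, d$replicate, sep = "\r")
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    miss <- tgt[is.na(m), ][1, ]
    stopf("missing reference Ct for group %s replicate %s",
          miss$group, miss$replicate)
  }
  dct <- tgt$ct - ref$ct[m]
  vals <- data.frame(group = tgt$group, replicate = tgt$replicate,
                     dct = dct, stringsAsFactors = FALSE)
  cal_mean <- mean(vals$dct[vals$group == calibrator])
  vals$ddct <- vals$dct - cal_mean
  vals$value <- 2^(-vals$ddct)
  groups <- unique(vals$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- vals$value[vals$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  structure(list(values = vals, summary = summ, calibrator = calibrator),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat(sprintf("Relative expression (2^-ddCt, calibrator = %s):\n",
              x$calibrator))
  s <- x$summary
  s$mean <- signif(s$mean, 4)
  s$se <- signif(s$se, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA on replicate relative-expression values
#'
#' Standard fixed-effects one-way ANOVA on the per-replicate 2^-ddCt
#' values. With identical groups (zero between- and within-group variance)
#' the F statistic is reported as 0 with P = 1.
#'
#' @param rel A [ddct()] result (or a data frame with `group` and `value`).
#' @return List with `f`, `p`, `df_between`, `df_error`, `mse`.
#' @export
anova_oneway <- function(rel) {
  vals <- if (inherits(rel, "rel_expression")) rel$values else rel
  stopifnot(all(c("group", "value") %in% names(vals)))
  g <- factor(vals$group)
  if (nlevels(g) < 2) stopf("ANOVA needs at least 2 groups")
  if (any(tabulate(g) < 2)) stopf("every group needs at least 2 replicates")
  fit <- stats::lm(value ~ g, data = data.frame(value = vals$value, g = g))
  an <- suppressWarnings(stats::anova(fit))
  mse <- an["Residuals", "Mean Sq"]
  msb <- an["g", "Mean Sq"]
  # guard the degenerate all-equal case against floating-point residue
  eps <- 1e-20 * (mean(vals$value^2) + .Machine$double.xmin)
  if (mse <= eps && msb <= eps) {
    f <- 0; p <- 1; mse <- 0
  } else {
    f <- an["g", "F value"]
    p <- an["g", "Pr(>F)"]
  }
  list(f = f, p = p, df_between = an["g", "Df"],
       df_error = an["Residuals", "Df"], mse = mse)
}

# least significant range for spans 2..k at Duncan's protection level
duncan_ranges <- function(alpha, k, df_error, mse, n_per_group) {
  p <- 2:k
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  q <- stats::qtukey(1 - alpha_p, p, df_error)
  stats::setNames(q * sqrt(mse / n_per_group), p)
}

#' Duncan's multiple range test with letter groupings
#'
#' Post-ANOVA stepwise comparison: group means are sorted and every range
#' spanning p means is tested against the least significant range
#' `R_p = q(alpha_p, p, df_error) * sqrt(MSE / n)`, where `q` is the
#' studentized-range quantile and `alpha_p = 1 - (1 - alpha)^(p-1)` is
#' Duncan's protection level. A range declared non-significant protects all
#' ranges it contains (they are not tested further). Letters are then
#' assigned so that two groups share a letter iff they were not separated.
#' With unbalanced groups the harmonic mean of the group sizes is used,
#' with a warning.
#'
#' @param rel A [ddct()] result (or data frame with `group`, `value`).
#' @param alpha Protection level of the test.
#' @return Data frame of class `duncan_letters`, sorted by descending mean:
#'   `group`, `n`, `mean`, `letters`.
#' @export
duncan_mrt <- function(rel, alpha = 0.05) {
  vals <- if (inherits(rel, "rel_expression")) rel$values else rel
  an <- anova_oneway(vals)
  means <- tapply(vals$value, vals$group, mean)
  ns <- tapply(vals$value, vals$group, length)
  if (length(unique(ns)) > 1) {
    warning("unbalanced groups: using the harmonic mean group size")
    n <- length(ns) / sum(1 / ns)
  } else n <- ns[1]
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  sep <- matrix(FALSE, k, k)  # sep[i,j]: groups i..j (sorted) separated
  if (an$mse > 0) {
    R <- duncan_ranges(alpha, k, an$df_error, an$mse, n)
    # stepwise: test the full range; recurse into sub-ranges only when the
    # enclosing range is significant
    test_range <- function(i, j) {
      if (j <= i) return(invisible())
      span <- j - i + 1
      if (m[i] - m[j] > R[as.character(span)]) {
        sep[i, j] <<- TRUE
        test_range(i, j - 1)
        test_range(i + 1, j)
      }
    }
    test_range(1, k)
  }
  # The untested/non-significant relation is containment-closed, so for each
  # start a the non-separated span is contiguous; letters go to the maximal
  # homogeneous intervals.
  bmax <- vapply(seq_len(k), function(a) {
    b <- a
    while (b < k && !sep[a, b + 1L]) b <- b + 1L
    b
  }, integer(1))
  intervals <- list()
  for (a in seq_len(k)) {
    if (a == 1L || bmax[a] > bmax[a - 1L])
      intervals[[length(intervals) + 1]] <- c(a, bmax[a])
  }
  lets <- rep("", k)
  for (ii in seq_along(intervals)) {
    rng <- intervals[[ii]][1]:intervals[[ii]][2]
    lets[rng] <- paste0(lets[rng], letters[ii])
  }
  out <- data.frame(group = names(m), n = as.vector(ns[ord]),
                    mean = as.vector(m), letters = lets,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("duncan_letters", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Full qPCR group comparison
#'
#' Runs [ddct()], [anova_oneway()], and [duncan_mrt()] at both
#' conventional levels, attaching lowercase letters for alpha = 0.05 and
#' uppercase letters for alpha = 0.01.
#'
#' @param ct_table A `ct_table`.
#' @param calibrator Calibrator group label.
#' @return List of class `qpcr_result`: `rel` (the [ddct()] object),
#'   `anova`, and `table` (per group: mean, se, letters_0.05, letters_0.01).
#' @export
qpcr_compare <- function(ct_table, calibrator) {
  rel <- ddct(ct_table, calibrator)
  an <- anova_oneway(rel)
  l05 <- duncan_mrt(rel, alpha = 0.05)
  l01 <- duncan_mrt(rel, alpha = 0.01)
  tab <- merge(rel$summary, l05[, c("group", "letters")], by = "group")
  names(tab)[names(tab) == "letters"] <- "letters_0.05"
  tab <- merge(tab, l01[, c("group", "letters")], by = "group")
  names(tab)[names(tab) == "letters"] <- "letters_0.01"
  tab$letters_0.01 <- toupper(tab$letters_0.01)
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  structure(list(rel = rel, anova = an, table = tab),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qPCR relative expression (calibrator = %s)\n",
              x$rel$calibrator))
  cat(sprintf("  one-way ANOVA: F = %.4g, P = %.4g\n", x$anova$f, x$anova$p))
  tab <- x$table
  tab$mean <- signif(tab$mean, 4)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
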