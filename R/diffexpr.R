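# Two-library digital differential expression.
#
# Normalization is reads-per-million of clean reads:
#   NE = 10^6 * count / total, with NE = 0.01 imputed for zero counts so
# log2 ratios stay finite. Rows with NE < 1 in both libraries are removed.
# Significance uses the Audic-Claverie exact test: conditional on observing
# x reads in library A (total N_a), the count y in library B (total N_b)
# follows
#   p(y|x) = (N_b/N_a)^y * (x+y)! / (x! y! (1 + N_b/N_a)^(x+y+1)),
# i.e. a negative binomial with size x+1 and success probability
# N_a/(N_a+N_b). The two-sided P-value doubles the smaller tail and is
# clipped to [0, 1]. The test always runs on raw integer counts; the 0.01
# imputation affects only the log2 ratio.

#' Reads-per-million normalized expression
#'
#' `NE = 10^6 * raw / total`; a raw count of zero is imputed to `NE = 0.01`
#' so that log2 expression ratios remain finite.
#'
#' @param raw Non-negative integer read count(s).
#' @param total Positive clean-read total of the library.
#' @return Normalized expression value(s).
#' @examples
#' normalized_expression(1177256, 14545100)  # ~ 8.09e4 reads per million
#' normalized_expression(0, 14545100)        # imputed to 0.01
#' @export
normalized_expression <- function(raw, total) {
  if (any(total <= 0)) stopf("clean-read total must be positive")
  if (any(raw < 0)) stopf("counts must be non-negative")
  ne <- 1e6 * raw / total
  ne[raw == 0] <- 0.01
  ne
}

#' Low-expression filter
#'
#' Removes rows whose normalized expression is below 1 read per million in
#' both libraries (evaluated after zero imputation); one adequately
#' expressed library suffices to retain a row.
#'
#' @param rows Data frame with columns `ne_a` and `ne_b`.
#' @return The retained rows.
#' @export
low_expression_filter <- function(rows) {
  stopifnot(all(c("ne_a", "ne_b") %in% names(rows)))
  rows[!(rows$ne_a < 1 & rows$ne_b < 1), , drop = FALSE]
}

# log p(k|x) for k = 0..kmax under the Audic-Claverie conditional law
ac_log_pmf <- function(kvec, x, log_r, log_1r) {
  lgamma(x + kvec + 1) - lgamma(x + 1) - lgamma(kvec + 1) +
    kvec * log_r - (x + kvec + 1) * log_1r
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Audic-Claverie exact P-value for a two-library count comparison
#'
#' Tests whether a transcript's counts in two sequencing libraries of known
#' sizes are compatible with equal underlying concentration. Conditional on
#' the count `x` in library A, the null law of the count `y` in library B is
#' the negative binomial given in the details; the reported P-value is
#' two-sided, doubling the smaller of the lower and upper tails at `y` and
#' clipping at 1. Computation is in log space and exact.
#'
#' @param x,y Observed counts in libraries A and B (non-negative integers;
#'   vectorized, recycled to common length).
#' @param n_a,n_b Library totals (clean reads), strictly positive.
#' @return Two-sided P-value(s) in \[0, 1\].
#' @export
exact_pvalue <- function(x, y, n_a, n_b) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(n_a <= 0) || any(n_b <= 0)) stopf("library totals must be positive")
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n_a <- rep_len(n_a, k); n_b <- rep_len(n_b, k)
  vapply(seq_len(k), function(i) {
    r <- n_b[i] / n_a[i]
    log_r <- log(n_b[i]) - log(n_a[i])
    log_1r <- log1p(r)
    # lower tail P(Y <= y): exact log-space sum over 0..y
    p_lo <- exp(log_sum_exp(ac_log_pmf(0:y[i], x[i], log_r, log_1r)))
    # upper tail P(Y >= y): summed upward from y until the remainder is
    # negligible (terms decay geometrically beyond the null mode)
    mu <- (x[i] + 1) * r
    hi_end <- ceiling(max(y[i], mu) + 20 * sqrt(mu * (1 + r) + 1) + 100)
    p_hi <- exp(log_sum_exp(ac_log_pmf(y[i]:hi_end, x[i], log_r, log_1r)))
    # floor at the smallest normal double: the probability is never truly 0,
    # merely below what doubles can hold
    max(min(1, 2 * min(p_lo, min(p_hi, 1))), .Machine$double.xmin)
  }, numeric(1))
}

#' Call differential expression between two libraries
#'
#' The full two-library procedure: reads-per-million normalization with zero
#' imputation, dual-library low-expression filtering, log2 expression ratio
#' (library B over library A, A being the control condition), the
#' Audic-Claverie exact P-value on raw counts, and threshold calling: a row
#' is significant when `|log2 ratio| >= lfc_min` and `P <= alpha` (both
#' inclusive). Significance labels are `"**"` for P <= 0.01, `"*"`
#' otherwise when significant, `""` when not. A Benjamini-Hochberg FDR
#' column is provided as supplementary output but plays no part in calling.
#'
#' @param counts A [count_table()] (library A = control).
#' @param alpha P-value threshold (inclusive).
#' @param lfc_min Minimum |log2 ratio| (inclusive).
#' @return Data frame of class `de_result`, one row per retained miRNA:
#'   `mirna`, `raw_a`, `raw_b`, `ne_a`, `ne_b`, `log2_ratio`, `fold_change`
#'   (magnitude, >= 1), `direction` (`up`/`down`/`equal` relative to the
#'   control), `p_value`, `bh_fdr`, `significant`, `sig_label`.
#' @export
call_de <- function(counts, alpha = 0.05, lfc_min = 1) {
  stopifnot(inherits(counts, "count_table"))
  df <- counts$counts
  rows <- data.frame(
    mirna = df$mirna, raw_a = df$count_a, raw_b = df$count_b,
    ne_a = normalized_expression(df$count_a, counts$totals["a"]),
    ne_b = normalized_expression(df$count_b, counts$totals["b"]),
    stringsAsFactors = FALSE
  )
  rows <- low_expression_filter(rows)
  if (nrow(rows) == 0) {
    res <- cbind(rows, log2_ratio = numeric(0), fold_change = numeric(0),
                 direction = character(0), p_value = numeric(0),
                 bh_fdr = numeric(0), significant = logical(0),
                 sig_label = character(0))
    class(res) <- c("de_result", "data.frame")
    return(res)
  }
  rows$log2_ratio <- log2(rows$ne_b / rows$ne_a)
  rows$fold_change <- 2^abs(rows$log2_ratio)
  rows$p_value <- exact_pvalue(rows$raw_a, rows$raw_b,
                               counts$totals["a"], counts$totals["b"])
  rows$bh_fdr <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- abs(rows$log2_ratio) >= lfc_min & rows$p_value <= alpha
  rows$direction <- ifelse(!rows$significant, "equal",
                           ifelse(rows$log2_ratio > 0, "up", "down"))
  rows$sig_label <- ifelse(!rows$significant, "",
                           ifelse(rows$p_value <= 0.01, "**", "*"))
  rows <- rows[order(-rows$fold_change * rows$significant, rows$p_value), ]
  rownames(rows) <- NULL
  attr(rows, "alpha") <- alpha
  attr(rows, "lfc_min") <- lfc_min
  attr(rows, "totals") <- counts$totals
  class(rows) <- c("de_result", "data.frame")
  rows
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Two-library differential expression: %d miRNAs tested\n",
              nrow(x)))
  cat(sprintf("  thresholds: |log2 ratio| >= %g, P <= %g\n",
              attr(x, "lfc_min"), attr(x, "alpha")))
  cat(sprintf("  significant: %d (%d up, %d down)\n",
              sum(x$significant), sum(x$direction == "up"),
              sum(x$direction == "down")))
  df <- as.data.frame(x)
  top <- utils::head(df[df$significant, c("mirna", "fold_change", "p_value",
                                          "direction", "sig_label")], 8)
  if (nrow(top)) {
    top$fold_change <- signif(top$fold_change, 4)
    print(top)
  }
  invisible(x)
}

#' @export
summary.de_result <- function(object, fold_floor = 4, ...) {
  de_report(object, fold_floor = fold_floor)
}

#' Summarize a differential-expression result
#'
#' Tabulates up/down/equal calls, lists the significant rows whose
#' fold-change magnitude exceeds `fold_floor` (Table-style, sorted by
#' descending fold-change with values displayed to 4 significant figures),
#' and reports the extreme fold-change per direction.
#'
#' @param results A `de_result` (or a data frame with `fold_change`,
#'   `direction`, `significant` columns, e.g. a published table).
#' @param fold_floor Fold-change magnitude floor for the highlighted list.
#' @return Object of class `de_report`: list with `n_up`, `n_down`,
#'   `n_equal`, `over_floor` (data frame), `max_up`, `max_down` (NA when a
#'   direction is absent).
#' @export
de_report <- function(results, fold_floor = 4) {
  stopifnot(is.data.frame(results))
  results <- as.data.frame(results)
  if (!"significant" %in% names(results))
    results$significant <- results$direction %in% c("up", "down")
  sig <- results[results$significant, , drop = FALSE]
  over <- sig[sig$fold_change > fold_floor, , drop = FALSE]
  over <- over[order(-over$fold_change), , drop = FALSE]
  rownames(over) <- NULL
  maxdir <- function(d) {
    v <- sig$fold_change[sig$direction == d]
    if (length(v) == 0) NA_real_ else max(v)
  }
  structure(list(
    n_up = sum(results$direction == "up"),
    n_down = sum(results$direction == "down"),
    n_equal = sum(!results$significant),
    fold_floor = fold_floor,
    over_floor = over,
    max_up = maxdir("up"),
    max_down = maxdir("down")
  ), class = "de_report")
}

#' @export
print.de_report <- function(x, ...) {
  cat(sprintf("DE summary: %d up, %d down, %d equal\n",
              x$n_up, x$n_down, x$n_equal))
  cat(sprintf("  %d miRNAs change more than %g-fold\n",
              nrow(x$over_floor), x$fold_floor))
  cat(sprintf("  largest fold-change: up %s, down %s\n",
              ifelse(is.na(x$max_up), "-", signif(x$max_up, 5)),
              ifelse(is.na(x$max_down), "-", signif(x$max_down, 5))))
  if (nrow(x$over_floor)) {
    show <- x$over_floor[, intersect(c("mirna", "fold_change", "p_value",
                                       "direction", "sig_label"),
                                     names(x$over_floor))]
    show$fold_change <- signif(show$fold_change, 5)
    print(show)
  }
  invisible(x)
}

#' Write a DE report TSV
#'
#' Columns mirror a published fold-change table: miR-name, fold-change
#' (4 significant figures), P-value, regulated, sig-label, plus the
#' normalized expressions, log2 ratio, and BH FDR.
#'
#' @param results A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(results, path) {
  stopifnot(inherits(results, "de_result"))
  out <- data.frame(
    `miR-name` = results$mirna,
    `fold-change` = signif(results$fold_change, 4),
    `P-value` = results$p_value,
    regulated = results$direction,
    `sig-label` = results$sig_label,
    ne_a = results$ne_a, ne_b = results$ne_b,
    log2_ratio = results$log2_ratio, bh_fdr = results$bh_fdr,
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a published-style DE table
#'
#' Accepts a TSV with columns `miR-name`/`mirna`, `fold-change`/
#' `fold_change`, `P-value`/`p_value`, `regulated`/`direction`, and an
#' optional significance-label column, as printed in fold-change tables.
#'
#' @param path Path to the TSV.
#' @return Data frame with standardized column names `mirna`,
#'   `fold_change`, `p_value`, `direction`, `sig_label`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ren <- c("miR-name" = "mirna", "fold-change" = "fold_change",
           "P-value" = "p_value", "regulated" = "direction",
           "sig-label" = "sig_label", "Sig-lable" = "sig_label")
  for (i in seq_along(ren)) {
    j <- which(names(df) == names(ren)[i])
    if (length(j)) names(df)[j] <- ren[i]
  }
  need <- c("mirna", "fold_change", "p_value", "direction")
  if (!all(need %in% names(df)))
    stopf("DE table must provide columns %s", paste(need, collapse = ", "))
  df
}
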