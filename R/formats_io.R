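#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is converted to DNA `T`, so all
#' downstream exact matching works over a single DNA alphabet. Identifiers
#' must be unique; duplicated identifiers and empty files are hard errors —
#' records are never silently dropped.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param class_tag_rule How to interpret identifiers: `"none"` keeps the
#'   full first word of the header as the name; `"pipe"` expects
#'   `classname|id` headers (used for ncRNA bundles) and returns the class
#'   in the `"class"` attribute.
#' @return Named character vector of DNA sequences. With
#'   `class_tag_rule = "pipe"`, attribute `class` holds the per-record class.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1", "ACGU"), fa)
#' read_fasta(fa)  # U is stored as T
#' @export
read_fasta <- function(path, class_tag_rule = c("none", "pipe")) {
  class_tag_rule <- match.arg(class_tag_rule)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA file is empty: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_seq(as.character(set), what = basename(path))
  cls <- NULL
  if (class_tag_rule == "pipe") {
    if (!all(grepl("|", ids, fixed = TRUE)))
      stopf("class-tagged FASTA requires 'classname|id' headers: %s", path)
    cls <- sub("\\|.*$", "", ids)
    ids <- sub("^[^|]*\\|", "", ids)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stopf("duplicate FASTA identifier: %s", dup[1])
  names(seqs) <- ids
  if (!is.null(cls)) attr(seqs, "class_tag") <- cls
  seqs
}

#' Write sequences as FASTA
#'
#' One sequence per line (no wrapping), so that `write_fasta()` followed by
#' [read_fasta()] is a byte-identical round trip for normalized input.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param class_tags Optional character vector of per-record class tags,
#'   emitted as `classname|id` headers.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, class_tags = NULL) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stopf("all sequences must be named")
  ids <- names(seqs)
  if (!is.null(class_tags)) ids <- paste0(class_tags, "|", ids)
  writeLines(paste0(">", ids, "\n", unname(seqs)), path, sep = "\n")
  invisible(path)
}

#' Construct a two-library count table
#'
#' The container for per-miRNA read counts in two libraries, with the
#' per-library clean-read totals that act as normalization denominators.
#' Library A is the control condition (the immature, 42-d ovary in the
#' motivating study); library B the treatment (mature, 162-d).
#'
#' @param counts Data frame with columns `mirna`, `count_a`, `count_b`
#'   (non-negative integers, unique `mirna`).
#' @param totals Length-2 numeric vector `c(a, b)` of positive clean-read
#'   totals; each library's column sum must not exceed its total.
#' @return Object of class `count_table`: a list with elements `counts`
#'   (data frame) and `totals` (named numeric).
#' @export
count_table <- function(counts, totals) {
  stopifnot(is.data.frame(counts))
  need <- c("mirna", "count_a", "count_b")
  if (!all(need %in% names(counts)))
    stopf("counts must have columns %s", paste(need, collapse = ", "))
  counts <- counts[, need]
  if (anyDuplicated(counts$mirna))
    stopf("duplicate miRNA identifier in count table: %s",
          counts$mirna[duplicated(counts$mirna)][1])
  if (!is_count(counts$count_a) || !is_count(counts$count_b))
    stopf("counts must be non-negative integers")
  if (length(totals) != 2L || !all(is.finite(totals)) || any(totals <= 0))
    stopf("totals must be two strictly positive numbers")
  totals <- c(a = unname(totals[1]), b = unname(totals[2]))
  if (sum(counts$count_a) > totals["a"] || sum(counts$count_b) > totals["b"])
    stopf("per-library count sum exceeds the stated clean-read total")
  structure(list(counts = counts, totals = totals), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Two-library count table: %d miRNAs\n", nrow(x$counts)))
  cat(sprintf("  clean-read totals: A = %s, B = %s\n",
              format(x$totals["a"], big.mark = ","),
              format(x$totals["b"], big.mark = ",")))
  print(utils::head(x$counts, 6))
  if (nrow(x$counts) > 6) cat("  ...\n")
  invisible(x)
}

#' Read a two-library count table from TSV
#'
#' The format is a TSV with header `mirna<TAB>count_a<TAB>count_b`, preceded
#' by two comment lines carrying the clean-read totals:
#' ```
#' # total_a: 14545100
#' # total_b: 14774864
#' ```
#' A missing totals line, a negative count, or counts summing above a total
#' is an error.
#'
#' @param path Path to the TSV file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  hdr <- readLines(path, n = 10L)
  get_total <- function(key) {
    ln <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (length(ln) != 1L)
      stopf("count table %s is missing its '# %s:' totals line", path, key)
    as.numeric(sub(".*:\\s*", "", ln))
  }
  totals <- c(get_total("total_a"), get_total("total_b"))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$count_a < 0) || any(df$count_b < 0))
    stopf("negative count in %s", path)
  count_table(df, totals)
}

#' Write a two-library count table to TSV
#'
#' Inverse of [read_count_table()]; the round trip is lossless.
#'
#' @param ct A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# total_a: %.0f", ct$totals["a"]),
               sprintf("# total_b: %.0f", ct$totals["b"])), con)
  utils::write.table(ct$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `group`, `replicate`, `assay` (one of `target`,
#' `reference`), `ct`. Every (group, replicate) pair must carry both a
#' target and a reference Ct.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stopf("Ct table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_ct_table(df)
}

#' Validate a data frame as a Ct table
#'
#' @param df Data frame with columns `group`, `replicate`, `assay`, `ct`.
#' @return The validated data frame, classed `ct_table`.
#' @export
as_ct_table <- function(df) {
  need <- c("group", "replicate", "assay", "ct")
  if (!all(need %in% names(df)))
    stopf("Ct table must have columns %s", paste(need, collapse = ", "))
  if (!all(df$assay %in% c("target", "reference")))
    stopf("assay must be 'target' or 'reference'")
  if (!is.numeric(df$ct) || anyNA(df$ct))
    stopf("ct must be numeric and complete")
  key <- interaction(df$group, df$replicate, drop = TRUE)
  for (k in levels(key)) {
    a <- df$assay[key == k]
    if (!("target" %in% a) || !("reference" %in% a))
      stopf("record %s lacks a target or reference Ct", k)
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a Ct table to TSV
#' @param df A `ct_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
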