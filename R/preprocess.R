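#' Trim the 3' adapter from reads
#'
#' The insert is the read prefix before the leftmost full-adapter match; if
#' the adapter is only partially present (truncated at the read's 3' end), a
#' terminal exact prefix-overlap of at least `min_overlap` bases also
#' delimits the insert. Reads with no detectable adapter, and reads that are
#' pure adapter (empty insert), are rejected — rejects are data, not errors.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Non-empty adapter sequence.
#' @param min_overlap Minimum exact adapter-prefix overlap at the read end.
#' @return Character vector of inserts, with `NA` where no adapter was
#'   found and `""` for empty inserts (pure adapter reads).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  adapter <- normalize_seq(adapter, "adapter")
  pos <- unname(stringi::stri_locate_first_fixed(reads, adapter)[, "start"])
  out <- ifelse(is.na(pos), NA_character_, substr(reads, 1, ifelse(is.na(pos), 0, pos - 1)))
  todo <- which(is.na(pos))
  if (length(todo) > 0 && nchar(adapter) - 1L >= min_overlap) {
    # truncated adapter at the 3' end: longest adapter prefix that suffixes
    # the read, down to min_overlap
    for (k in seq(nchar(adapter) - 1L, min_overlap)) {
      if (length(todo) == 0) break
      ap <- substr(adapter, 1, k)
      hit <- endsWith(reads[todo], ap)
      if (any(hit)) {
        idx <- todo[hit]
        out[idx] <- substr(reads[idx], 1, nchar(reads[idx]) - k)
        todo <- todo[!hit]
      }
    }
  }
  out
}

#' Clean, filter, and collapse a FASTQ library to unique tags
#'
#' Applies, in a fixed order, the read-level and tag-level filters of a
#' small-RNA pipeline: (1) mean-Phred quality floor, (2) 3' adapter
#' trimming (no adapter, or an empty insert, rejects the read), (3) insert
#' length selection, (4) collapsing identical inserts to unique tags, and
#' (5) removal of single-read tags. The reject ledger is exact:
#' `raw_total = clean_total + sum(rejects)` always holds.
#'
#' @param fastq Path to a FASTQ file (Phred+33).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len Insert length window (inclusive).
#' @param quality_floor Minimum mean Phred score per read.
#' @param drop_singletons Drop unique tags seen only once (the
#'   "single-read sequences" filter). Set `FALSE` to keep them.
#' @param keep_no_adapter Keep full-length reads when no adapter is found
#'   instead of rejecting them.
#' @param min_overlap Passed to [trim_adapter()].
#' @return Object of class `clean_library`: list with `tags` (named integer
#'   vector, sequence -> count), `raw_total`, `clean_total`, and `rejects`
#'   (counts for `low_quality`, `empty_or_no_adapter`, `out_of_length`,
#'   `single_read`).
#' @export
clean_and_collapse <- function(fastq, adapter, min_len = 18L, max_len = 30L,
                               quality_floor = 20, drop_singletons = TRUE,
                               keep_no_adapter = FALSE, min_overlap = 6L) {
  fq <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                     with.qualities = TRUE)
  if (length(fq) == 0L) stopf("FASTQ stream is empty: %s", fastq)
  reads <- as.character(fq)
  quals <- as.character(S4Vectors::mcols(fq)$qualities)
  raw_total <- length(reads)
  rejects <- c(low_quality = 0L, empty_or_no_adapter = 0L,
               out_of_length = 0L, single_read = 0L)

  # 1. quality floor on mean Phred
  mean_q <- vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                   USE.NAMES = FALSE)
  ok <- mean_q >= quality_floor
  rejects["low_quality"] <- sum(!ok)
  reads <- reads[ok]

  # 2. adapter trimming
  ins <- trim_adapter(reads, adapter, min_overlap)
  if (keep_no_adapter) ins[is.na(ins)] <- reads[is.na(ins)]
  bad <- is.na(ins) | ins == ""
  rejects["empty_or_no_adapter"] <- sum(bad)
  ins <- ins[!bad]

  # 3. length window
  len <- nchar(ins)
  inwin <- len >= min_len & len <= max_len
  rejects["out_of_length"] <- sum(!inwin)
  ins <- ins[inwin]

  # 4. collapse to unique tags; 5. singleton filter
  tags <- table(ins)
  tags <- stats::setNames(as.integer(tags), names(tags))
  if (drop_singletons) {
    singles <- tags == 1L
    rejects["single_read"] <- sum(tags[singles])
    tags <- tags[!singles]
  }
  clean_total <- sum(tags)
  stopifnot(raw_total == clean_total + sum(rejects))
  structure(list(tags = tags, raw_total = raw_total,
                 clean_total = clean_total, rejects = rejects),
            class = "clean_library")
}

#' @export
print.clean_library <- function(x, ...) {
  cat(sprintf("Clean small-RNA library: %s raw -> %s clean reads (%d unique tags)\n",
              format(x$raw_total, big.mark = ","),
              format(x$clean_total, big.mark = ","), length(x$tags)))
  rej <- x$rejects[x$rejects > 0]
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Build a clean library directly from tag counts
#'
#' Convenience constructor used when tags have already been collapsed (for
#' example, when reading a published tag table instead of raw FASTQ).
#'
#' @param tags Named integer vector, sequence -> read count.
#' @param rejects Optional named reject counts.
#' @return A `clean_library`.
#' @export
as_clean_library <- function(tags, rejects = NULL) {
  if (is.null(rejects))
    rejects <- c(low_quality = 0L, empty_or_no_adapter = 0L,
                 out_of_length = 0L, single_read = 0L)
  if (!is_count(tags)) stopf("tag counts must be non-negative integers")
  structure(list(tags = stats::setNames(as.integer(tags), names(tags)),
                 raw_total = sum(tags) + sum(rejects),
                 clean_total = sum(tags), rejects = rejects),
            class = "clean_library")
}

#' Length distribution of a clean library
#'
#' The per-length share of clean reads over the analysis window, reported
#' both by read abundance and by distinct sequence count (the two panels of
#' a standard small-RNA length profile, where Dicer products put the mode
#' at 22 nt).
#'
#' @param lib A `clean_library` with `clean_total > 0`.
#' @param min_len,max_len Length window to tabulate.
#' @return Data frame with columns `length`, `reads`, `read_fraction`,
#'   `distinct`, `distinct_fraction`; each fraction column sums to 1.
#' @export
length_distribution <- function(lib, min_len = 18L, max_len = 30L) {
  stopifnot(inherits(lib, "clean_library"))
  if (lib$clean_total <= 0) stopf("library has no clean reads")
  len <- nchar(names(lib$tags))
  lv <- min_len:max_len
  reads <- vapply(lv, function(L) sum(lib$tags[len == L]), numeric(1))
  distinct <- vapply(lv, function(L) sum(len == L), numeric(1))
  data.frame(length = lv, reads = reads,
             read_fraction = reads / sum(reads),
             distinct = distinct,
             distinct_fraction = distinct / sum(distinct))
}

#' Write a tag table to TSV
#'
#' Columns `tag`, `length`, `count`, mirroring the collapsed unique-tag
#' output of the preprocessing stage.
#'
#' @param lib A `clean_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(lib, path) {
  stopifnot(inherits(lib, "clean_library"))
  df <- data.frame(tag = names(lib$tags), length = nchar(names(lib$tags)),
                   count = unname(lib$tags))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag table written by [write_tag_table()]
#' @param path Path to the TSV.
#' @return A `clean_library` (with an empty reject ledger).
#' @export
read_tag_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tag", "count") %in% names(df)))
    stopf("tag table must have columns tag, count")
  as_clean_library(stats::setNames(df$count, df$tag))
}
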