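# Exact-match hierarchical annotation of collapsed small-RNA tags.
#
# A tag gets exactly one category, resolved by fixed priority:
#   miRNA (identical to a mature/star sequence, or an exact hairpin substring
#   lying inside an annotated arm)  >  ncRNA class (exact substring of an
#   rRNA/tRNA/snRNA/scRNA/snoRNA record)  >  genome_only (exact substring of
#   a genome record)  >  unmatched.
# The priority form makes the category totals a partition of the clean reads,
# and is equivalent to map-then-discard ordering when only perfect matches
# are retained.

CATEGORIES <- c("miRNA", "rRNA", "tRNA", "snRNA", "scRNA", "snoRNA",
                "genome_only", "unmatched")

# which tags occur as exact substrings of any sequence in `refs`
# (vectorized fixed search over a '#'-joined subject; '#' cannot occur in DNA)
tags_in_refs <- function(tags, refs) {
  if (length(refs) == 0 || length(tags) == 0)
    return(logical(length(tags)))
  subject <- paste(refs, collapse = "#")
  stringi::stri_detect_fixed(subject, tags)
}

#' Classify unique tags against a reference bundle
#'
#' Assigns each tag one category by the fixed priority miRNA > ncRNA class >
#' genome_only > unmatched, using exact matching only (perfect matches are
#' the retention rule for conserved miRNAs). A tag counts as miRNA if it is
#' identical to a mature or star sequence, or an exact substring of a
#' hairpin confined to an annotated arm. Ties between miRNA identifiers
#' sharing a sequence resolve to the lexicographically smallest identifier,
#' with a warning.
#'
#' @param tags Character vector of tag sequences (typically 18–30 nt).
#' @param bundle A `reference_bundle` (see [build_reference()] or
#'   [read_reference_bundle()]).
#' @return Data frame with one row per tag: `tag`, `category`, `mirna`
#'   (identifier or `NA`), `is_star`.
#' @export
classify_tags <- function(tags, bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  n <- length(tags)
  category <- rep("unmatched", n)
  mirna <- rep(NA_character_, n)
  is_star <- rep(NA, n)

  mt <- bundle$mirna
  # identity to a mature/star sequence; duplicate sequences resolve to the
  # lexicographically smallest identifier
  if (anyDuplicated(mt$seq)) {
    ord <- order(mt$seq, mt$id)
    first <- !duplicated(mt$seq[ord])
    dupseq <- unique(mt$seq[duplicated(mt$seq)])
    warning(sprintf("%d arm sequence(s) map to multiple identifiers; using the lexicographically smallest", length(dupseq)))
    lut <- mt[ord, ][first, ]
  } else lut <- mt
  hit <- match(tags, lut$seq)
  sel <- !is.na(hit)
  category[sel] <- "miRNA"
  mirna[sel] <- lut$id[hit[sel]]
  is_star[sel] <- lut$is_star[hit[sel]]

  # hairpin substring within an annotated arm
  rest <- which(category == "unmatched")
  if (length(rest) > 0 && length(bundle$hairpin) > 0) {
    in_hp <- tags_in_refs(tags[rest], bundle$hairpin)
    for (i in rest[in_hp]) {
      tg <- tags[i]
      cand <- NULL
      for (j in seq_len(nrow(mt))) {
        hp <- bundle$hairpin[[mt$hairpin_id[j]]]
        p <- stringi::stri_locate_first_fixed(hp, tg)[1, "start"]
        if (!is.na(p) && p >= mt$arm_start[j] &&
            p + nchar(tg) - 1L <= mt$arm_end[j]) {
          cand <- c(cand, j)
        }
      }
      if (length(cand) > 0) {
        j <- cand[order(mt$id[cand])][1]
        if (length(cand) > 1)
          warning(sprintf("tag %s matches multiple miRNA arms; assigned to %s",
                          tg, mt$id[j]))
        category[i] <- "miRNA"
        mirna[i] <- mt$id[j]
        is_star[i] <- mt$is_star[j]
      }
    }
  }

  # ncRNA classes, in the bundle's class order
  for (cl in c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA")) {
    rest <- which(category == "unmatched")
    if (length(rest) == 0) break
    refs <- bundle$ncrna$seq[bundle$ncrna$class == cl]
    hit <- tags_in_refs(tags[rest], refs)
    category[rest[hit]] <- cl
  }

  # genome
  rest <- which(category == "unmatched")
  if (length(rest) > 0) {
    hit <- tags_in_refs(tags[rest], bundle$genome)
    category[rest[hit]] <- "genome_only"
  }

  data.frame(tag = tags, category = category, mirna = mirna,
             is_star = is_star, stringsAsFactors = FALSE)
}

#' Annotate and quantify two clean libraries
#'
#' Classifies the union of tags from both libraries, accumulates per-category
#' read totals per library (a partition of each library's clean reads), and
#' builds the per-miRNA count table. A miRNA's count is the sum of the counts
#' of all tags assigned to it; the co-expressed set comprises miRNAs with a
#' positive count in both libraries.
#'
#' @param lib_a,lib_b `clean_library` objects (A = control condition).
#' @param bundle A `reference_bundle`.
#' @return Object of class `annotation`: list with `assignments` (the
#'   [classify_tags()] table), `category_totals` (category x library matrix
#'   of read counts), `mirna_counts` (a [count_table()]), and `clean_totals`.
#' @export
quantify_mirnas <- function(lib_a, lib_b, bundle) {
  stopifnot(inherits(lib_a, "clean_library"),
            inherits(lib_b, "clean_library"))
  if (nrow(bundle$mirna) == 0) stopf("reference bundle has no miRNAs")
  tags <- union(names(lib_a$tags), names(lib_b$tags))
  if (length(tags) == 0) stopf("no tags to annotate")
  asg <- classify_tags(tags, bundle)
  ca <- unname(lib_a$tags[match(tags, names(lib_a$tags))])
  cb <- unname(lib_b$tags[match(tags, names(lib_b$tags))])
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L

  cat_tot <- rbind(
    a = vapply(CATEGORIES, function(k) sum(ca[asg$category == k]), numeric(1)),
    b = vapply(CATEGORIES, function(k) sum(cb[asg$category == k]), numeric(1))
  )
  sel <- asg$category == "miRNA"
  agg_a <- tapply(ca[sel], asg$mirna[sel], sum)
  agg_b <- tapply(cb[sel], asg$mirna[sel], sum)
  ids <- sort(names(agg_a))
  mirna_counts <- count_table(
    data.frame(mirna = ids, count_a = as.integer(agg_a[ids]),
               count_b = as.integer(agg_b[ids]), stringsAsFactors = FALSE),
    totals = c(max(lib_a$clean_total, 1), max(lib_b$clean_total, 1))
  )
  structure(list(assignments = asg, category_totals = t(cat_tot),
                 mirna_counts = mirna_counts,
                 clean_totals = c(a = lib_a$clean_total,
                                  b = lib_b$clean_total)),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("Small-RNA annotation summary (reads per category):\n")
  print(x$category_totals)
  n_co <- sum(x$mirna_counts$counts$count_a > 0 &
              x$mirna_counts$counts$count_b > 0)
  cat(sprintf("  %d miRNAs detected, %d co-expressed in both libraries\n",
              nrow(x$mirna_counts$counts), n_co))
  invisible(x)
}

#' Per-category percentages of clean reads
#'
#' Percentages are computed per library against its clean-read total and
#' rounded half-up to two decimals, the convention used for reporting
#' genome-mapped proportions such as 66.14%. The genome-mapped percentage
#' counts everything except unmatched tags.
#'
#' @param result An `annotation` from [quantify_mirnas()], or a matrix of
#'   category read totals (categories x libraries) with a `clean_totals`
#'   attribute.
#' @return Data frame: `category`, `pct_a`, `pct_b`, with an extra
#'   `genome_mapped` row.
#' @export
category_proportions <- function(result) {
  stopifnot(inherits(result, "annotation"))
  tot <- result$clean_totals
  if (any(tot <= 0)) stopf("clean-read totals must be positive")
  m <- result$category_totals
  pct <- sweep(m, 2, tot, "/") * 100
  mapped <- 100 * (tot - m["unmatched", ]) / tot
  out <- data.frame(category = c(rownames(m), "genome_mapped"),
                    pct_a = round_half_up(c(pct[, "a"], mapped["a"]), 2),
                    pct_b = round_half_up(c(pct[, "b"], mapped["b"]), 2),
                    row.names = NULL)
  out
}

#' Genome-mapped percentage from raw numbers
#'
#' The reporting arithmetic in isolation: `100 * mapped / total`, rounded
#' half-up to two decimals (9,619,834 of 14,545,100 reads gives 66.14).
#'
#' @param mapped Number of genome-mapped clean reads.
#' @param total Clean-read total (> 0).
#' @return Percentage rounded to two decimals.
#' @export
genome_mapped_pct <- function(mapped, total) {
  if (any(total <= 0)) stopf("clean-read total must be positive")
  round_half_up(100 * mapped / total, 2)
}

#' Mature/star arm abundance report
#'
#' Pairs mature and star rows of the annotated count table by base
#' identifier and flags duplexes whose star arm out-reads the mature arm in
#' both libraries (the miR-140-like inversion). Star arms observed without
#' their mature counterpart are reported as orphans.
#'
#' @param result An `annotation` from [quantify_mirnas()].
#' @return Data frame of class `arm_report`: `base_id`, `mature_a`,
#'   `mature_b`, `star_a`, `star_b`, `star_dominant`, `orphan_star`.
#' @export
arm_report <- function(result) {
  stopifnot(inherits(result, "annotation"))
  cnt <- result$mirna_counts$counts
  if (nrow(cnt) == 0) stopf("no miRNA counts to report")
  is_star <- grepl("\\*$", cnt$mirna)
  stars <- cnt[is_star, ]
  matures <- cnt[!is_star, ]
  sb <- mirna_base_id(stars$mirna)
  mb <- mirna_base_id(matures$mirna)
  bases <- unique(sb)
  rows <- lapply(bases, function(b) {
    s <- stars[sb == b, ][1, ]
    m_idx <- which(mb == b)
    observed_m <- length(m_idx) > 0 &&
      (matures$count_a[m_idx[1]] > 0 || matures$count_b[m_idx[1]] > 0)
    ma <- if (length(m_idx)) matures$count_a[m_idx[1]] else 0L
    mbc <- if (length(m_idx)) matures$count_b[m_idx[1]] else 0L
    data.frame(base_id = b, mature_a = ma, mature_b = mbc,
               star_a = s$count_a, star_b = s$count_b,
               star_dominant = s$count_a > ma && s$count_b > mbc,
               orphan_star = !observed_m &&
                 (s$count_a > 0 || s$count_b > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("arm_report", "data.frame")
  out
}

#' Read a reference bundle from a directory of FASTA files
#'
#' Expects `mature.fa` (mature and star arms; identifiers ending in `*` or
#' carrying `-3p` relative to a `-5p` sibling are star-flagged), `hairpin.fa`,
#' `ncrna.fa` (headers `classname|id`), and `genome.fa`. Arm coordinates are
#' located by exact search of each arm within its hairpin (matched by base
#' identifier, falling back to a scan over all hairpins).
#'
#' @param dir Directory containing the four FASTA files.
#' @return A `reference_bundle`.
#' @export
read_reference_bundle <- function(dir) {
  mature <- read_fasta(file.path(dir, "mature.fa"))
  hairpin <- read_fasta(file.path(dir, "hairpin.fa"))
  ncr <- read_fasta(file.path(dir, "ncrna.fa"), class_tag_rule = "pipe")
  genome <- read_fasta(file.path(dir, "genome.fa"))

  ids <- names(mature)
  is_star <- grepl("\\*$", ids) | grepl("-3p$", ids)
  base_id <- mirna_base_id(ids)
  hp_ids <- names(hairpin)
  hp_base <- tolower(base_id)
  rows <- lapply(seq_along(ids), function(i) {
    cand <- which(tolower(hp_ids) == hp_base[i])
    if (length(cand) == 0) cand <- seq_along(hairpin)
    for (j in cand) {
      p <- stringi::stri_locate_first_fixed(hairpin[[j]], mature[[i]])[1, "start"]
      if (!is.na(p)) {
        return(data.frame(id = ids[i], seq = unname(mature[[i]]),
                          is_star = is_star[i], base_id = base_id[i],
                          hairpin_id = hp_ids[j], arm_start = p,
                          arm_end = p + nchar(mature[[i]]) - 1L,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(id = ids[i], seq = unname(mature[[i]]), is_star = is_star[i],
               base_id = base_id[i], hairpin_id = NA_character_,
               arm_start = NA_integer_, arm_end = NA_integer_,
               stringsAsFactors = FALSE)
  })
  mirna <- do.call(rbind, rows)
  # star entries whose base resolves to no mature entry are orphans, kept
  orphan <- mirna$is_star & !(mirna$base_id %in% mirna$base_id[!mirna$is_star])
  mirna$orphan <- orphan
  structure(list(mirna = mirna, hairpin = hairpin, genome = genome,
                 ncrna = data.frame(id = names(ncr),
                                    class = attr(ncr, "class_tag"),
                                    seq = as.character(ncr),
                                    stringsAsFactors = FALSE),
                 spacer_pool = character(0)),
            class = "reference_bundle")
}

#' Write a reference bundle to a directory of FASTA files
#' @param bundle A `reference_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "reference_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(bundle$mirna$seq, bundle$mirna$id),
              file.path(dir, "mature.fa"))
  write_fasta(bundle$hairpin, file.path(dir, "hairpin.fa"))
  write_fasta(stats::setNames(bundle$ncrna$seq, bundle$ncrna$id),
              file.path(dir, "ncrna.fa"), class_tags = bundle$ncrna$class)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  invisible(dir)
}
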