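#' Simulation configuration for a two-library small RNA study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the structure of a deep-sequencing study of two pooled ovary libraries:
#' a heavy-tailed (log-normal) miRNA abundance distribution spanning tens to
#' hundreds of thousands of reads, a 22-nt modal insert length with 23 nt and
#' 21 nt next (the Dicer signature), mature arms dominating star arms with
#' occasional inversions, ncRNA/unannotated contamination, and a designated
#' fraction of miRNAs with true |log2 fold-change| at or above the calling
#' threshold of 1.
#'
#' @param n_mirnas Number of miRNA duplexes (mature + star pairs) to simulate.
#' @param abundance_meanlog,abundance_sdlog Log-scale mean and SD of the
#'   log-normal base-abundance law.
#' @param de_fraction Fraction of miRNAs with true differential expression.
#' @param effect_min,effect_max Minimum and maximum |log2 fold-change| for
#'   truly differential miRNAs (`effect_min >= 1` by default so every planted
#'   effect is callable at the |log2 ratio| >= 1 threshold).
#' @param star_ratio_meanlog,star_ratio_sdlog Log-normal law of the
#'   star:mature abundance ratio (well below 1 on average).
#' @param arm_inversion_prob Probability that a duplex has its arms inverted
#'   (star more abundant than mature, the miR-140-like case).
#' @param contamination Named proportions of clean reads for the classes
#'   `rRNA`, `tRNA`, `snRNA`, `scRNA`, `snoRNA`, `unannotated`; together with
#'   the implied miRNA fraction they must sum to at most 1.
#' @param library_sizes Target clean-read totals, `c(a =, b =)`; library A is
#'   the control condition.
#' @param length_probs Named probability vector over insert lengths 18–30 nt;
#'   the default puts 22 nt first, then 23 nt, then 21 nt.
#' @param adapter 3' adapter sequence appended to every simulated insert.
#' @param dispersion Negative-binomial dispersion of the count model
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param read_length Raw read length in the emitted FASTQ.
#' @param seed Integer random seed; every generator output is a pure
#'   function of (config, seed).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_mirnas = 300,
                       abundance_meanlog = log(200),
                       abundance_sdlog = 2,
                       de_fraction = 0.1,
                       effect_min = 1,
                       effect_max = 4,
                       star_ratio_meanlog = log(0.05),
                       star_ratio_sdlog = 1,
                       arm_inversion_prob = 0.02,
                       contamination = c(rRNA = 0.08, tRNA = 0.05,
                                         snRNA = 0.02, scRNA = 0.01,
                                         snoRNA = 0.04, unannotated = 0.40),
                       library_sizes = c(a = 1e6, b = 1e6),
                       length_probs = NULL,
                       adapter = "TGGAATTCTCGG",
                       dispersion = 0.05,
                       read_length = 40,
                       seed = 1) {
  if (is.null(length_probs)) {
    length_probs <- c(`18` = 0.020, `19` = 0.030, `20` = 0.060, `21` = 0.100,
                      `22` = 0.340, `23` = 0.170, `24` = 0.090, `25` = 0.060,
                      `26` = 0.040, `27` = 0.030, `28` = 0.025, `29` = 0.020,
                      `30` = 0.015)
  }
  stopifnot(n_mirnas >= 1, de_fraction >= 0, de_fraction <= 1,
            effect_min > 0, effect_max >= effect_min,
            dispersion >= 0, read_length >= 30)
  need <- c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA", "unannotated")
  if (!all(need %in% names(contamination)))
    stopf("contamination must name %s", paste(need, collapse = ", "))
  contamination <- contamination[need]
  if (any(contamination < 0) || sum(contamination) >= 1)
    stopf("contamination proportions must be non-negative and leave room for miRNA reads")
  if (!identical(names(length_probs), as.character(18:30)))
    stopf("length_probs must be named '18'..'30'")
  if (abs(sum(length_probs) - 1) > 1e-8)
    stopf("length_probs must sum to 1")
  if (length(library_sizes) != 2L || any(library_sizes < 1e3))
    stopf("library_sizes must be two totals of at least 1000 reads")
  names(library_sizes) <- c("a", "b")
  adapter <- normalize_seq(adapter, "adapter")
  structure(list(
    n_mirnas = as.integer(n_mirnas),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    de_fraction = de_fraction, effect_min = effect_min,
    effect_max = effect_max,
    star_ratio_meanlog = star_ratio_meanlog,
    star_ratio_sdlog = star_ratio_sdlog,
    arm_inversion_prob = arm_inversion_prob,
    contamination = contamination,
    mirna_fraction = 1 - sum(contamination),
    library_sizes = library_sizes,
    length_probs = length_probs,
    adapter = adapter, dispersion = dispersion,
    read_length = as.integer(read_length), seed = as.integer(seed)
  ), class = "sim_config")
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[min(i, length(len))],
                 replace = TRUE), collapse = "")
  }, character(1))
}

#' Build a synthetic reference bundle
#'
#' Constructs, deterministically from the config seed, a complete reference:
#' mature miRNA sequences, star arms derived from the complementary strand of
#' each hairpin, hairpin precursors, class-tagged ncRNA sequences, and genome
#' records in which every hairpin (hence every mature arm) is embedded exactly
#' once between random spacers. Mature sequences are mutually distinct and
#' distinct from all ncRNA sequences.
#'
#' @param config A [sim_config()].
#' @return Object of class `reference_bundle`: list with `mirna` (data frame
#'   of mature and star arms with hairpin coordinates), `hairpin`, `genome`,
#'   `ncrna` (data frame id/class/seq), and `spacer_pool` (genome background
#'   fragments used for unannotated-read simulation).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_mirnas
  if (n > 4^10) stopf("n_mirnas too large for distinct sequence generation")
  with_seed(config$seed, {
    # mature lengths concentrated on the miRNA range with a 22-nt mode
    lp <- config$length_probs[as.character(20:24)]
    mat_len <- sample(20:24, n, replace = TRUE, prob = lp / sum(lp))
    mature <- random_seq(n, mat_len)
    for (tries in 1:20) {
      dup <- duplicated(mature)
      if (!any(dup)) break
      mature[dup] <- random_seq(sum(dup), mat_len[dup])
    }
    if (anyDuplicated(mature)) stopf("could not generate distinct mature sequences")

    loop <- random_seq(n, rep(8L, n))
    p5 <- random_seq(n, rep(8L, n))
    p3 <- random_seq(n, rep(8L, n))
    arm3 <- revcomp(mature)                       # complementary strand arm
    hairpin <- paste0(p5, mature, loop, arm3, p3)
    # star: the complement arm with the canonical 2-nt duplex offset,
    # same length as the mature arm (so it passes the 18-30 nt window)
    star <- substr(hairpin,
                   nchar(p5) + nchar(mature) + nchar(loop) + 3L,
                   nchar(p5) + nchar(mature) + nchar(loop) + 2L + nchar(mature))

    ids <- sprintf("sim-miR-%d", seq_len(n))
    hp_ids <- sprintf("sim-mir-%d", seq_len(n))
    names(hairpin) <- hp_ids

    mat_start <- nchar(p5) + 1L
    star_start <- nchar(p5) + nchar(mature) + nchar(loop) + 3L
    mirna <- data.frame(
      id = c(ids, paste0(ids, "*")),
      seq = c(mature, star),
      is_star = rep(c(FALSE, TRUE), each = n),
      base_id = c(ids, ids),
      hairpin_id = c(hp_ids, hp_ids),
      arm_start = c(mat_start, star_start),
      arm_end = c(mat_start + nchar(mature) - 1L,
                  star_start + nchar(star) - 1L),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(mirna$seq))
      stopf("arm sequence collision; rerun with another seed")

    # genome: hairpins separated by random spacers, ~40 hairpins per record
    per_chr <- 40L
    n_chr <- ceiling(n / per_chr)
    chr_of <- rep(seq_len(n_chr), each = per_chr)[seq_len(n)]
    spacers <- random_seq(n + n_chr, rep(60L, n + n_chr))
    genome <- vapply(seq_len(n_chr), function(ci) {
      idx <- which(chr_of == ci)
      paste0(paste0(spacers[idx], hairpin[idx], collapse = ""),
             spacers[n + ci])
    }, character(1))
    names(genome) <- sprintf("chr%d", seq_len(n_chr))

    classes <- c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA")
    nc_len <- sample(70:150, 8L * length(classes), replace = TRUE)
    ncrna <- data.frame(
      id = sprintf("%s-%d", rep(classes, each = 8L), rep(1:8, length(classes))),
      class = rep(classes, each = 8L),
      seq = random_seq(8L * length(classes), nc_len),
      stringsAsFactors = FALSE
    )

    bundle <- structure(list(mirna = mirna, hairpin = hairpin,
                             genome = genome, ncrna = ncrna,
                             spacer_pool = spacers),
                        class = "reference_bundle")
    # contract: each mature arm occurs in exactly one genome record
    hits <- vapply(mature, function(s)
      sum(stringi::stri_detect_fixed(genome, s)), integer(1))
    if (any(hits != 1L))
      stopf("a mature sequence is not embedded in exactly one genome record; rerun with another seed")
    bundle
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("Reference bundle: %d mature + %d star miRNAs, %d hairpins,\n",
              sum(!x$mirna$is_star), sum(x$mirna$is_star), length(x$hairpin)))
  cat(sprintf("  %d ncRNAs (%s), %d genome records\n",
              nrow(x$ncrna), paste(unique(x$ncrna$class), collapse = "/"),
              length(x$genome)))
  invisible(x)
}

#' Draw the simulation ground truth
#'
#' Assigns each miRNA a base abundance from the heavy-tailed law, marks a
#' `de_fraction` subset as truly differential with |log2 fold-change| drawn
#' uniformly in `[effect_min, effect_max]` (random sign), and draws the
#' star:mature ratio with occasional arm inversion. Non-differential miRNAs
#' have a true log2 fold-change of exactly 0. Fold-changes are defined as
#' log2(library B / library A), library A being the control.
#'
#' @param config A [sim_config()].
#' @param bundle Optional [build_reference()] bundle. When supplied, the
#'   drawn abundances are rescaled so the expected miRNA read mass per
#'   insert length follows the configured length law — the library-level
#'   length profile (22-nt mode) then holds by construction even though a
#'   handful of miRNAs dominates the read mass.
#' @return Data frame of class `truth_table` with one row per miRNA duplex:
#'   `mirna`, `base_abundance`, `lfc`, `star_ratio`.
#' @export
simulate_truth <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_mirnas
  with_seed(config$seed + 1L, {
    base <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    n_de <- round(config$de_fraction * n)
    de_idx <- sample.int(n, n_de)
    lfc <- numeric(n)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, config$effect_min, config$effect_max)
    ratio <- stats::rlnorm(n, config$star_ratio_meanlog,
                           config$star_ratio_sdlog)
    ratio <- pmin(ratio, 0.8)
    inv <- stats::runif(n) < config$arm_inversion_prob
    ratio[inv] <- 1 / ratio[inv]
    if (!is.null(bundle)) {
      ids <- sprintf("sim-miR-%d", seq_len(n))
      len <- nchar(bundle$mirna$seq[match(ids, bundle$mirna$id)])
      tgt <- config$length_probs[as.character(sort(unique(len)))]
      tgt <- tgt / sum(tgt)
      total <- sum(base)
      for (L in names(tgt)) {
        sel <- len == as.integer(L)
        base[sel] <- base[sel] * tgt[[L]] * total / sum(base[sel])
      }
    }
    structure(data.frame(mirna = sprintf("sim-miR-%d", seq_len(n)),
                         base_abundance = base, lfc = lfc,
                         star_ratio = ratio, stringsAsFactors = FALSE),
              class = c("truth_table", "data.frame"))
  })
}

#' Simulate a two-library miRNA count table
#'
#' Counts for each arm (mature and star) in each library are drawn from a
#' negative binomial with mean proportional to the arm's base abundance,
#' split symmetrically across libraries for differential miRNAs
#' (a true log2 fold-change f multiplies the control library A by 2^(-f/2)
#' and library B by 2^(+f/2), keeping overall composition comparable), and
#' scaled so the expected miRNA read mass matches `mirna_fraction` of each
#' target library size. At `dispersion = 0` the counts are Poisson.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] table consistent with `config`.
#' @return A [count_table()] with one row per arm (star rows suffixed `*`)
#'   and totals equal to the target library sizes.
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  if (nrow(truth) != config$n_mirnas)
    stopf("truth table does not match config (n_mirnas)")
  w_mat <- truth$base_abundance
  w_star <- truth$base_abundance * truth$star_ratio
  W <- sum(w_mat + w_star)
  split_a <- 2^(-truth$lfc / 2)
  split_b <- 2^(+truth$lfc / 2)
  mu_a <- config$library_sizes["a"] * config$mirna_fraction *
    c(w_mat, w_star) * c(split_a, split_a) / W
  mu_b <- config$library_sizes["b"] * config$mirna_fraction *
    c(w_mat, w_star) * c(split_b, split_b) / W
  ids <- c(truth$mirna, paste0(truth$mirna, "*"))
  with_seed(config$seed + 2L, {
    draw <- function(mu) {
      if (config$dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    ca <- draw(mu_a)
    cb <- draw(mu_b)
  })
  if (sum(ca) > config$library_sizes["a"] ||
      sum(cb) > config$library_sizes["b"])
    stopf("simulated miRNA reads exceed the library size; lower mirna abundance or raise library_sizes")
  count_table(data.frame(mirna = ids, count_a = ca, count_b = cb,
                         stringsAsFactors = FALSE),
              config$library_sizes)
}

sample_insert_lengths <- function(n, config) {
  as.integer(sample(names(config$length_probs), n, replace = TRUE,
                    prob = config$length_probs))
}

# draw n random substrings (of lengths len) from a pool of source sequences
substring_inserts <- function(pool, n, len) {
  src <- sample.int(length(pool), n, replace = TRUE)
  sl <- nchar(pool[src])
  len <- pmin(len, sl)
  start <- floor(stats::runif(n) * (sl - len + 1)) + 1
  substr(pool[src], start, start + len - 1)
}

#' Simulate FASTQ read libraries from a count table
#'
#' Emits one FASTQ file per library. Each miRNA arm contributes exactly its
#' simulated count of reads (conservation is exact); contaminant reads fill
#' the remainder of the target library size, allocated across the ncRNA
#' classes and the unannotated pool in proportion to the configured
#' contamination. Every read is insert + 3' adapter, truncated to
#' `read_length`, with constant Phred quality "I". Optional spike-in
#' arguments plant reads that the preprocessing stage must reject, for
#' conservation testing.
#'
#' @param config A [sim_config()].
#' @param bundle A [build_reference()] bundle.
#' @param counts A [simulate_counts()] table consistent with `bundle`.
#' @param dir Output directory (created if needed).
#' @param spike_singletons Number of unique single-copy inserts per library.
#' @param spike_short Number of reads with inserts shorter than 18 nt.
#' @param spike_lowq Number of reads with uniformly low (Phred 2) quality.
#' @return Named character vector of the two FASTQ paths (`a`, `b`),
#'   invisibly classed with attribute `emitted` holding per-library raw
#'   read counts.
#' @export
simulate_reads <- function(config, bundle, counts, dir,
                           spike_singletons = 0, spike_short = 0,
                           spike_lowq = 0) {
  stopifnot(inherits(config, "sim_config"),
            inherits(bundle, "reference_bundle"),
            inherits(counts, "count_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq_of <- stats::setNames(bundle$mirna$seq, bundle$mirna$id)
  if (!all(counts$counts$mirna %in% names(seq_of)))
    stopf("count table names a miRNA absent from the bundle")
  paths <- c(a = file.path(dir, "library_a.fastq"),
             b = file.path(dir, "library_b.fastq"))
  emitted <- c(a = 0, b = 0)
  with_seed(config$seed + 3L, {
    # Contaminants are drawn from finite pools of distinct fragments with
    # heavy-tailed weights (degradation products recur in real libraries),
    # so a realistic share of them survives the single-read filter. The
    # unannotated mass splits into genome background (spacer fragments)
    # and foreign sequence absent from every reference.
    frag_pool <- function(pool, n_frag) {
      len <- sample_insert_lengths(n_frag, config)
      unique(substring_inserts(pool, n_frag, len))
    }
    pools <- list()
    for (cl in c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA"))
      pools[[cl]] <- frag_pool(bundle$ncrna$seq[bundle$ncrna$class == cl], 40L)
    pools[["genome_bg"]] <- frag_pool(bundle$spacer_pool, 80L)
    pools[["foreign"]] <- unique(random_seq(120L, sample_insert_lengths(120L, config)))
    # heavy-tailed fragment weights, rescaled so each pool's expected read
    # mass per insert length follows the configured length law
    weights <- lapply(pools, function(p) {
      w <- stats::rlnorm(length(p), 0, 1.5)
      len <- nchar(p)
      tgt <- config$length_probs[as.character(sort(unique(len)))]
      tgt <- tgt / sum(tgt)
      tot <- sum(w)
      for (L in names(tgt)) {
        sel <- len == as.integer(L)
        w[sel] <- w[sel] * tgt[[L]] * tot / sum(w[sel])
      }
      w
    })
    for (lib in c("a", "b")) {
      cc <- counts$counts[[paste0("count_", lib)]]
      mirna_inserts <- rep(unname(seq_of[counts$counts$mirna]), cc)
      n_cont <- as.integer(counts$totals[lib] - sum(cc))
      probs <- config$contamination / sum(config$contamination)
      alloc <- as.vector(stats::rmultinom(1, n_cont, probs))
      names(alloc) <- names(probs)
      cont_inserts <- character(0)
      draw_pool <- function(key, n) {
        if (n <= 0) return(character(0))
        k <- stats::rmultinom(1, n, weights[[key]])[, 1]
        rep(pools[[key]], k)
      }
      for (cl in c("rRNA", "tRNA", "snRNA", "scRNA", "snoRNA"))
        cont_inserts <- c(cont_inserts, draw_pool(cl, alloc[cl]))
      n_gen <- round(0.3 * alloc["unannotated"])
      cont_inserts <- c(cont_inserts, draw_pool("genome_bg", n_gen),
                        draw_pool("foreign", alloc["unannotated"] - n_gen))
      inserts <- c(mirna_inserts, cont_inserts)
      qual <- rep(strrep("I", config$read_length), length(inserts))
      if (spike_singletons > 0) {
        inserts <- c(inserts, random_seq(spike_singletons,
                                         rep(22L, spike_singletons)))
        qual <- c(qual, rep(strrep("I", config$read_length), spike_singletons))
      }
      if (spike_short > 0) {
        inserts <- c(inserts, random_seq(spike_short, rep(10L, spike_short)))
        qual <- c(qual, rep(strrep("I", config$read_length), spike_short))
      }
      if (spike_lowq > 0) {
        inserts <- c(inserts, random_seq(spike_lowq, rep(22L, spike_lowq)))
        qual <- c(qual, rep(strrep("#", config$read_length), spike_lowq))
      }
      reads <- substr(paste0(inserts, config$adapter), 1, config$read_length)
      qual <- substr(qual, 1, nchar(reads))
      ord <- sample.int(length(reads))
      reads <- reads[ord]
      qual <- qual[ord]
      out <- file(paths[lib], "w")
      writeLines(paste0("@", lib, "_", seq_along(reads), "\n", reads,
                        "\n+\n", qual), out, sep = "\n")
      close(out)
      emitted[lib] <- length(reads)
    }
  })
  attr(paths, "emitted") <- emitted
  invisible(paths)
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' Generates replicate threshold-cycle values for a target assay and a
#' reference assay (a 5S-rRNA-like invariant gene) across groups. For each
#' replicate, target Ct = reference Ct + baseline - log2(true level) +
#' Gaussian noise, so the downstream 2^-ddCt estimate recovers the
#' configured levels (exactly, in the zero-noise limit).
#'
#' @param groups Character vector of group labels.
#' @param true_levels Positive per-group relative expression levels
#'   (recycled names from `groups`).
#' @param replicates Biological replicates per group (>= 2).
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param seed Integer random seed.
#' @param ref_ct Mean reference-assay Ct.
#' @param baseline Offset between reference and target Ct at level 1.
#' @return A `ct_table` data frame (see [as_ct_table()]).
#' @export
simulate_ct_table <- function(groups, true_levels, replicates = 3,
                              noise_sd = 0.2, seed = 1,
                              ref_ct = 15, baseline = 8) {
  stopifnot(length(groups) == length(true_levels), replicates >= 2)
  if (any(true_levels <= 0)) stopf("true expression levels must be positive")
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(groups), function(i) {
      ref <- ref_ct + stats::rnorm(replicates, 0, noise_sd)
      tgt <- ref + baseline - log2(true_levels[i]) +
        stats::rnorm(replicates, 0, noise_sd)
      data.frame(group = groups[i], replicate = rep(seq_len(replicates), 2),
                 assay = rep(c("reference", "target"), each = replicates),
                 ct = c(ref, tgt), stringsAsFactors = FALSE)
    }))
    as_ct_table(rows)
  })
}
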