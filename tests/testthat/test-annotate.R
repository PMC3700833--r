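# a small hand-built bundle with known contents
toy_bundle <- function() {
  mature <- "ACGTACGTACGTACGTACGTAC"            # 22 nt
  loop <- "TTTTAAAA"
  arm3 <- ovamir:::revcomp(mature)
  p5 <- "GGGGCCCC"; p3 <- "AATTGGCC"
  hairpin <- paste0(p5, mature, loop, arm3, p3)
  star <- substr(hairpin, nchar(p5) + nchar(mature) + nchar(loop) + 3,
                 nchar(p5) + nchar(mature) + nchar(loop) + 2 + nchar(mature))
  mirna <- data.frame(
    id = c("toy-miR-1", "toy-miR-1*"),
    seq = c(mature, star), is_star = c(FALSE, TRUE),
    base_id = "toy-miR-1", hairpin_id = "toy-mir-1",
    arm_start = c(nchar(p5) + 1,
                  nchar(p5) + nchar(mature) + nchar(loop) + 3),
    arm_end = c(nchar(p5) + nchar(mature),
                nchar(p5) + nchar(mature) + nchar(loop) + 2 + nchar(mature)),
    stringsAsFactors = FALSE
  )
  rrna <- "GGCGGCGGCGGCAATTCCGGAATTCCAGGTTACGAGT"
  genome <- paste0("TTTTTTTT", hairpin, "CCCCAAAA")
  structure(list(mirna = mirna, hairpin = c(`toy-mir-1` = hairpin),
                 genome = c(chr1 = genome),
                 ncrna = data.frame(id = "r1", class = "rRNA", seq = rrna,
                                    stringsAsFactors = FALSE),
                 spacer_pool = character(0)),
            class = "reference_bundle")
}

test_that("classification follows the fixed category priority", {
  b <- toy_bundle()
  mature <- b$mirna$seq[1]
  # mature sequence is also a genome substring: miRNA wins by priority
  asg <- classify_tags(mature, b)
  expect_equal(asg$category, "miRNA")
  expect_equal(asg$mirna, "toy-miR-1")
  expect_false(asg$is_star)

  # star arm
  asg <- classify_tags(b$mirna$seq[2], b)
  expect_equal(asg$category, "miRNA")
  expect_true(asg$is_star)

  # an rRNA fragment maps to rRNA, not to miRNA counts
  frag <- substr(b$ncrna$seq[1], 3, 24)
  expect_equal(classify_tags(frag, b)$category, "rRNA")

  # genome fragment outside any arm
  expect_equal(classify_tags(paste0("TTTTTTTT", substr(b$hairpin[[1]], 1, 10)),
                             b)$category, "genome_only")

  # matches nothing
  expect_equal(classify_tags(strrep("ACCGGT", 4), b)$category, "unmatched")

  # a sub-arm fragment inside the mature arm is still that miRNA
  expect_equal(classify_tags(substr(mature, 2, 21), b)$mirna, "toy-miR-1")
})

test_that("classify_tags agrees with the brute-force oracle on a generated bundle", {
  cfg <- sim_config(n_mirnas = 12, library_sizes = c(a = 1e3, b = 1e3),
                    seed = 91)
  b <- build_reference(cfg)
  set.seed(17)
  tags <- c(
    sample(b$mirna$seq, 8),
    vapply(sample(nrow(b$ncrna), 5), function(i)
      substr(b$ncrna$seq[i], 5, 26), character(1)),
    substr(b$genome[1], 10, 31),
    vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T"), 22,
                                         replace = TRUE), collapse = ""),
           character(1))
  )
  got <- classify_tags(tags, b)
  for (i in seq_along(tags)) {
    want <- classify_oracle(tags[i], b)
    expect_identical(got$category[i], want$category, info = tags[i])
    if (want$category == "miRNA")
      expect_identical(got$mirna[i], want$mirna, info = tags[i])
  }
})

test_that("duplicate arm sequences resolve to the smallest identifier with a warning", {
  b <- toy_bundle()
  dup <- b$mirna[1, ]
  dup$id <- "toy-miR-9"
  b$mirna <- rbind(b$mirna, dup)
  expect_warning(asg <- classify_tags(b$mirna$seq[1], b), "multiple")
  expect_equal(asg$mirna, "toy-miR-1")
})

test_that("quantify_mirnas is additive over tags and partitions clean reads", {
  b <- toy_bundle()
  mature <- b$mirna$seq[1]
  sub_arm <- substr(mature, 2, 21)       # second tag of the same miRNA
  star <- b$mirna$seq[2]
  rfrag <- substr(b$ncrna$seq[1], 3, 24)
  noise <- strrep("ACCGGT", 4)
  lib_a <- as_clean_library(setNames(c(30L, 12L, 4L, 7L, 5L),
                                     c(mature, sub_arm, star, rfrag, noise)))
  lib_b <- as_clean_library(setNames(c(18L, 3L), c(mature, rfrag)))
  ann <- quantify_mirnas(lib_a, lib_b, b)

  cnt <- ann$mirna_counts$counts
  expect_equal(cnt$count_a[cnt$mirna == "toy-miR-1"], 42)  # 30 + 12
  expect_equal(cnt$count_b[cnt$mirna == "toy-miR-1"], 18)
  expect_equal(cnt$count_a[cnt$mirna == "toy-miR-1*"], 4)

  # partition: category totals sum to the clean totals, exactly
  expect_equal(unname(colSums(ann$category_totals)),
               unname(ann$clean_totals))
  expect_equal(ann$category_totals["rRNA", "a"], 7)
  expect_equal(ann$category_totals["unmatched", "a"], 5)

  # star detected only in A: excluded from the co-expressed set
  co <- cnt$mirna[cnt$count_a > 0 & cnt$count_b > 0]
  expect_true("toy-miR-1" %in% co)
  expect_false("toy-miR-1*" %in% co)
})

test_that("simulated counts are recovered exactly for unambiguous tags", {
  cfg <- sim_config(n_mirnas = 25, library_sizes = c(a = 2e4, b = 2e4),
                    seed = 101)
  b <- build_reference(cfg)
  tr <- simulate_truth(cfg)
  ct <- simulate_counts(cfg, tr)
  dir <- withr::local_tempdir()
  fq <- simulate_reads(cfg, b, ct, dir)
  # keep singletons so low-count miRNAs are not dropped by the filter
  la <- clean_and_collapse(fq["a"], cfg$adapter, drop_singletons = FALSE)
  lb <- clean_and_collapse(fq["b"], cfg$adapter, drop_singletons = FALSE)
  ann <- quantify_mirnas(la, lb, b)
  cnt <- ann$mirna_counts$counts
  m <- merge(ct$counts, cnt, by = "mirna", all.x = TRUE,
             suffixes = c("_true", "_got"))
  m[is.na(m)] <- 0
  expect_equal(m$count_a_got, m$count_a_true)
  expect_equal(m$count_b_got, m$count_b_true)
})

test_that("category percentages reproduce the printed reporting arithmetic", {
  expect_equal(genome_mapped_pct(9619834, 14545100), 66.14)
  expect_equal(genome_mapped_pct(11019895, 14774864), 74.59)
  expect_equal(genome_mapped_pct(0, 1000), 0)
  expect_error(genome_mapped_pct(1, 0), "positive")
})

test_that("arm_report flags star dominance and orphan stars", {
  # miR-140-like inversion: star out-reads mature in both libraries
  b <- toy_bundle()
  lib_a <- as_clean_library(setNames(c(7370L, 105474L),
                                     c(b$mirna$seq[1], b$mirna$seq[2])))
  lib_b <- as_clean_library(setNames(c(7953L, 95992L),
                                     c(b$mirna$seq[1], b$mirna$seq[2])))
  ann <- quantify_mirnas(lib_a, lib_b, b)
  rep_ <- arm_report(ann)
  expect_true(rep_$star_dominant[rep_$base_id == "toy-miR-1"])
  expect_false(rep_$orphan_star[rep_$base_id == "toy-miR-1"])

  # equal counts: strict inequality means not dominant
  lib_eq <- as_clean_library(setNames(c(10L, 10L),
                                      c(b$mirna$seq[1], b$mirna$seq[2])))
  ann_eq <- quantify_mirnas(lib_eq, lib_eq, b)
  expect_false(arm_report(ann_eq)$star_dominant[1])

  # star observed, mature absent -> orphan star
  lib_s <- as_clean_library(setNames(5L, b$mirna$seq[2]))
  ann_s <- quantify_mirnas(lib_s, lib_s, b)
  rep_s <- arm_report(ann_s)
  expect_true(rep_s$orphan_star[rep_s$base_id == "toy-miR-1"])
})

test_that("reference bundles round trip through FASTA directories", {
  cfg <- sim_config(n_mirnas = 8, library_sizes = c(a = 1e3, b = 1e3),
                    seed = 111)
  b <- build_reference(cfg)
  dir <- withr::local_tempdir()
  write_reference_bundle(b, dir)
  back <- read_reference_bundle(dir)
  expect_identical(setNames(back$mirna$seq, back$mirna$id),
                   setNames(b$mirna$seq, b$mirna$id))
  expect_identical(back$hairpin, b$hairpin)
  expect_identical(back$genome, b$genome)
  expect_identical(back$ncrna, b$ncrna)
  # arm coordinates rediscovered by search match the construction
  m <- merge(b$mirna, back$mirna, by = "id")
  expect_equal(m$arm_start.y, m$arm_start.x)
  expect_equal(m$arm_end.y, m$arm_end.x)
  # star arms resolve to a mature sibling, so no orphans here
  expect_false(any(back$mirna$orphan))
})

test_that("miRNA identifier helpers parse families and arms", {
  expect_equal(ovamir:::mirna_family("gga-let-7a"), "let-7")
  expect_equal(ovamir:::mirna_family("gga-miR-30a-5p"), "miR-30")
  expect_equal(ovamir:::mirna_family("gga-miR-140*"), "miR-140")
  expect_equal(ovamir:::mirna_family("gga-miR-458b-5p"), "miR-458")
  expect_equal(ovamir:::mirna_base_id("gga-miR-140*"), "gga-miR-140")
  expect_equal(ovamir:::mirna_base_id("gga-miR-458b-5p"), "gga-miR-458b")
})
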