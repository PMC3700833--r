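# End-to-end orchestration: simulate -> preprocess -> annotate -> diffexpr,
# with a run manifest (config snapshot, seed, per-stage digests, timings)
# so that identical (config, seed) reruns are verifiably identical.

#' Read a flat key=value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Vector-valued
#' fields (`library_sizes`, `contamination`, `length_probs`) take
#' comma-separated `name:value` pairs. Unknown keys are an error. All
#' thresholds default to the study's conventions: length window 18–30 nt,
#' quality floor 20, alpha 0.05, minimum |log2 ratio| 1, library A as the
#' control.
#'
#' @param path Path to the config file.
#' @return List with a validated `sim_config` plus pipeline thresholds.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  parse_named <- function(s) {
    parts <- strsplit(strsplit(s, ",")[[1]], ":")
    stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                    trimws(vapply(parts, `[`, character(1), 1)))
  }
  sim_keys <- c("n_mirnas", "abundance_meanlog", "abundance_sdlog",
                "de_fraction", "effect_min", "effect_max",
                "star_ratio_meanlog", "star_ratio_sdlog",
                "arm_inversion_prob", "contamination", "library_sizes",
                "length_probs", "adapter", "dispersion", "read_length",
                "seed")
  pipe_keys <- c("min_len", "max_len", "quality_floor", "alpha", "lfc_min",
                 "fold_floor")
  unknown <- setdiff(names(vals), c(sim_keys, pipe_keys))
  if (length(unknown)) stopf("unknown config key: %s", unknown[1])
  args <- list()
  for (key in intersect(names(vals), sim_keys)) {
    args[[key]] <- switch(key,
      adapter = vals[[key]],
      contamination = parse_named(vals[[key]]),
      library_sizes = parse_named(vals[[key]]),
      length_probs = parse_named(vals[[key]]),
      as.numeric(vals[[key]]))
  }
  cfg <- do.call(sim_config, args)
  thresholds <- list(min_len = 18L, max_len = 30L, quality_floor = 20,
                     alpha = 0.05, lfc_min = 1, fold_floor = 4)
  for (key in intersect(names(vals), pipe_keys))
    thresholds[[key]] <- as.numeric(vals[[key]])
  c(list(sim = cfg), thresholds)
}

#' Write the default pipeline configuration
#'
#' Emits a commented key=value file holding every simulation field and
#' pipeline threshold at its default, as a starting point for edits.
#'
#' @param path Output path.
#' @param config A `sim_config` to snapshot (defaults to [sim_config()]).
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(path, config = sim_config()) {
  fmt_named <- function(v) paste(sprintf("%s:%g", names(v), v), collapse = ",")
  lines <- c(
    "# ovamir pipeline configuration",
    sprintf("n_mirnas = %d", config$n_mirnas),
    sprintf("abundance_meanlog = %g", config$abundance_meanlog),
    sprintf("abundance_sdlog = %g", config$abundance_sdlog),
    sprintf("de_fraction = %g", config$de_fraction),
    sprintf("effect_min = %g", config$effect_min),
    sprintf("effect_max = %g", config$effect_max),
    sprintf("star_ratio_meanlog = %g", config$star_ratio_meanlog),
    sprintf("star_ratio_sdlog = %g", config$star_ratio_sdlog),
    sprintf("arm_inversion_prob = %g", config$arm_inversion_prob),
    sprintf("contamination = %s", fmt_named(config$contamination)),
    sprintf("library_sizes = %s", fmt_named(config$library_sizes)),
    sprintf("length_probs = %s", fmt_named(config$length_probs)),
    sprintf("adapter = %s", config$adapter),
    sprintf("dispersion = %g", config$dispersion),
    sprintf("read_length = %d", config$read_length),
    sprintf("seed = %d", config$seed),
    "# pipeline thresholds",
    "min_len = 18", "max_len = 30", "quality_floor = 20",
    "alpha = 0.05", "lfc_min = 1", "fold_floor = 4"
  )
  writeLines(lines, path)
  invisible(path)
}

stage_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(paths))
}

#' Run the full simulated two-library pipeline
#'
#' Executes, in order: reference/truth/count simulation, FASTQ emission,
#' per-library preprocessing, annotation, and differential-expression
#' calling, writing every stage's outputs plus a JSON run manifest
#' (config snapshot, seed, per-stage output digests and timings) under
#' `out_dir`. Identical (config, seed) inputs produce identical output
#' digests. Read-conservation numbers are logged per stage.
#'
#' @param config Either a path to a key=value config file
#'   (see [read_pipeline_config()]) or the list it returns.
#' @param out_dir Output directory (created; must be empty or absent).
#' @param quiet Suppress stage logging.
#' @return List of class `pipeline_run`: `counts`, `truth`, `libs`,
#'   `annotation`, `de`, `report`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config$sim, "sim_config"))
    stopf("config must carry a sim_config under $sim")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(tool = "ovamir",
                   version = as.character(utils::packageVersion("ovamir")),
                   seed = config$sim$seed,
                   config = config[setdiff(names(config), "sim")],
                   sim_config = unclass(config$sim),
                   stages = list())
  tick <- function(name, paths, t0) {
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      outputs = as.list(stats::setNames(stage_digest(paths),
                                        basename(paths))))
  }

  t0 <- as.numeric(Sys.time())
  cfg <- config$sim
  bundle <- build_reference(cfg)
  truth <- simulate_truth(cfg, bundle)
  counts <- simulate_counts(cfg, truth)
  ref_dir <- file.path(out_dir, "reference")
  write_reference_bundle(bundle, ref_dir)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts_path <- file.path(out_dir, "true_counts.tsv")
  write_count_table(counts, counts_path)
  fq <- simulate_reads(cfg, bundle, counts, file.path(out_dir, "reads"))
  say("simulate: %d miRNA duplexes, libraries of %s/%s reads",
      cfg$n_mirnas, format(counts$totals["a"], big.mark = ","),
      format(counts$totals["b"], big.mark = ","))
  tick("simulate", c(file.path(ref_dir, c("mature.fa", "hairpin.fa",
                                          "ncrna.fa", "genome.fa")),
                     truth_path, counts_path, fq), t0)

  t0 <- as.numeric(Sys.time())
  libs <- lapply(stats::setNames(c("a", "b"), c("a", "b")), function(lib) {
    cl <- clean_and_collapse(fq[lib], cfg$adapter,
                             min_len = config$min_len,
                             max_len = config$max_len,
                             quality_floor = config$quality_floor)
    say("preprocess %s: %s raw = %s clean + %s rejected", lib,
        format(cl$raw_total, big.mark = ","),
        format(cl$clean_total, big.mark = ","),
        format(sum(cl$rejects), big.mark = ","))
    cl
  })
  tag_paths <- c(file.path(out_dir, "tags_a.tsv"),
                 file.path(out_dir, "tags_b.tsv"))
  write_tag_table(libs$a, tag_paths[1])
  write_tag_table(libs$b, tag_paths[2])
  tick("preprocess", tag_paths, t0)

  t0 <- as.numeric(Sys.time())
  ann <- quantify_mirnas(libs$a, libs$b, bundle)
  stopifnot(all(colSums(ann$category_totals) == ann$clean_totals))
  say("annotate: categories partition %s + %s clean reads",
      format(ann$clean_totals["a"], big.mark = ","),
      format(ann$clean_totals["b"], big.mark = ","))
  ann_paths <- c(file.path(out_dir, "category_summary.tsv"),
                 file.path(out_dir, "mirna_counts.tsv"),
                 file.path(out_dir, "arm_report.tsv"))
  utils::write.table(category_proportions(ann), ann_paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_count_table(ann$mirna_counts, ann_paths[2])
  utils::write.table(arm_report(ann), ann_paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("annotate", ann_paths, t0)

  t0 <- as.numeric(Sys.time())
  de <- call_de(ann$mirna_counts, alpha = config$alpha,
                lfc_min = config$lfc_min)
  rep_ <- de_report(de, fold_floor = config$fold_floor)
  de_path <- file.path(out_dir, "de_table.tsv")
  write_de_table(de, de_path)
  say("diffexpr: %d significant (%d up, %d down) of %d tested",
      rep_$n_up + rep_$n_down, rep_$n_up, rep_$n_down, nrow(de))
  tick("diffexpr", de_path, t0)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(list(counts = counts, truth = truth, libs = libs,
                 annotation = ann, de = de, report = rep_,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("ovamir pipeline run in %s\n", x$out_dir))
  print(x$report)
  invisible(x)
}

#' Compare DE calls against the simulation ground truth
#'
#' Joins a [call_de()] result with a [simulate_truth()] table (mature arms
#' only) and computes recovery statistics for the planted effects:
#' sensitivity (truly differential miRNAs called significant), direction
#' accuracy among true positives, and the empirical false-positive rate
#' among truly null miRNAs.
#'
#' @param de A `de_result`.
#' @param truth A `truth_table`.
#' @param min_ne Restrict to miRNAs whose true expected normalized
#'   expression is at least this (low-abundance truths are not recoverable
#'   by any two-library test at finite depth).
#' @param config The `sim_config` used (for expected-abundance scaling).
#' @return List: `sensitivity`, `direction_accuracy`, `fpr`, `n_true_de`,
#'   `n_null`, plus the joined data frame.
#' @export
recovery_stats <- function(de, truth, config, min_ne = 0) {
  stopifnot(inherits(truth, "truth_table"))
  w <- truth$base_abundance * (1 + truth$star_ratio)
  exp_ne <- 1e6 * config$mirna_fraction * truth$base_abundance / sum(w)
  joined <- merge(as.data.frame(de), truth, by = "mirna")
  joined$exp_ne <- exp_ne[match(joined$mirna, truth$mirna)]
  joined <- joined[joined$exp_ne >= min_ne, ]
  is_de <- joined$lfc != 0
  called <- joined$significant
  tp <- is_de & called
  sens <- if (any(is_de)) mean(called[is_de]) else NA_real_
  dir_ok <- sign(joined$log2_ratio[tp]) == sign(joined$lfc[tp])
  list(sensitivity = sens,
       direction_accuracy = if (any(tp)) mean(dir_ok) else NA_real_,
       fpr = if (any(!is_de)) mean(called[!is_de]) else NA_real_,
       n_true_de = sum(is_de), n_null = sum(!is_de), joined = joined)
}
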