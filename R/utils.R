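#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals (the reporting convention for
# percentages such as 66.14/74.59; base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# DNA reverse complement for plain character vectors.
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, ""), function(s) {
    paste(rev(unname(comp[s])), collapse = "")
  }, character(1))
}

# Normalize a nucleotide string: uppercase, RNA U -> DNA T; error on anything
# outside {A,C,G,T,U,N}.
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,U,N}: %s",
                 what, substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  gsub("U", "T", x, fixed = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# Extract the miRNA family from a miRBase-style identifier:
# strip the species prefix ("gga-"), the legacy star marker, the arm suffix
# ("-5p"/"-3p"), and trailing letter/number variants:
#   "gga-let-7a" -> "let-7"; "gga-miR-30a-5p" -> "miR-30"; "gga-miR-140*" -> "miR-140".
mirna_family <- function(id) {
  x <- sub("^[a-z]{3,4}-", "", id)
  x <- sub("\\*$", "", x)
  x <- sub("-[35]p$", "", x)
  # drop paralogue letters and duplicate-locus suffixes: miR-29b-2 -> miR-29
  sub("^((let|miR|mir)-[0-9]+)[a-z]*(-[0-9]+)?$", "\\1", x)
}

# Base identifier shared by the arms of one duplex: strips "*" and "-5p"/"-3p".
mirna_base_id <- function(id) {
  x <- sub("\\*$", "", id)
  sub("-[35]p$", "", x)
}
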