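# Shared low-level helpers: nucleotide alphabet, reverse complement,
# genotype-string handling and seeded substreams.

NUC <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of DNA strings
#'
#' @param x character vector over the ACGT alphabet.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Diploid calls are stored as sorted "A/G" strings; NA is the missing genotype.
geno_string <- function(a1, a2) {
  out <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out[is.na(a1) | is.na(a2)] <- NA_character_
  out
}

geno_allele1 <- function(calls) {
  out <- substr(calls, 1L, 1L)
  out[!nzchar(out)] <- NA_character_
  out
}

geno_allele2 <- function(calls) {
  out <- substr(calls, 3L, 3L)
  out[!nzchar(out)] <- NA_character_
  out
}

is_het_call <- function(calls) {
  !is.na(calls) & geno_allele1(calls) != geno_allele2(calls)
}

# Complement the allele letters of calls (used when flipping tag orientation),
# re-sorting so the sorted-call invariant is kept.
comp_calls <- function(calls) {
  flipped <- chartr("ACGT", "TGCA", calls)
  out <- geno_string(geno_allele1(flipped), geno_allele2(flipped))
  dim(out) <- dim(calls)
  dimnames(out) <- dimnames(calls)
  out
}

# --- seeded substreams -------------------------------------------------------
# One master seed; every stochastic stage draws from a named substream so that
# stage-level reproducibility survives refactors that reorder stages.

substream_seed <- function(seed, name) {
  ints <- utf8ToInt(name)
  h <- sum(ints * seq_along(ints) * 2654435.0) %% 2147483646
  as.integer((as.numeric(seed) %% 2147483646 + h) %% 2147483646) + 1L
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
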