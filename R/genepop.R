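# GENEPOP reader/writer. Canonical dialect: 4-digit genotypes, two 2-digit
# allele codes with A=01, C=02, G=03, T=04 and "0000" for missing; 6-digit
# (3-digit allele) files are accepted on read.

GENEPOP_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Write a genotype matrix as a GENEPOP file
#'
#' Deterministic output: loci in the matrix's column order, one locus name
#' per line, populations emitted as "Pop" blocks in population-map order,
#' samples as "name ,  0104 ..." lines.
#'
#' @param gm genotype_matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genepop <- function(gm, path) {
  a1 <- geno_allele1(gm$calls); a2 <- geno_allele2(gm$calls)
  codes <- matrix(sprintf("%02d%02d",
                          ifelse(is.na(a1), 0L, GENEPOP_CODE[a1]),
                          ifelse(is.na(a2), 0L, GENEPOP_CODE[a2])),
                  nrow(gm$calls), ncol(gm$calls))
  lines <- c(sprintf("Panel %s exported by radpanels", gm$pipeline),
             gm$snps$snp_id)
  for (p in unique(gm$popmap)) {
    lines <- c(lines, "Pop")
    rows <- which(gm$popmap == p)
    lines <- c(lines, vapply(rows, function(i) {
      paste0(rownames(gm$calls)[i], " ,  ",
             paste(codes[i, ], collapse = " "))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file
#'
#' Accepts one-locus-per-line or comma-separated locus names, 4- or 6-digit
#' genotypes, and case-insensitive "Pop" separators. Populations are labelled
#' pop1..popK in block order; allele codes 1..4 are mapped back to A/C/G/T
#' (other codes raise an error). Locus names of the form
#' \code{<locus>_p<position>} are decomposed into locus/position metadata.
#'
#' @param path GENEPOP file.
#' @return genotype_matrix.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty GENEPOP file")
  lines <- lines[c(TRUE, nzchar(trimws(lines[-1])))]
  is_pop <- toupper(trimws(lines)) == "POP"
  is_pop[1] <- FALSE
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no Pop block found")
  header <- lines[seq(2, length.out = max(0, first_pop - 2))]
  loci <- trimws(unlist(strsplit(header, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  nl <- length(loci)

  samples <- character(0); pops <- character(0)
  rows <- list()
  pop_i <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (is_pop[i]) { pop_i <- pop_i + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop(sprintf("malformed GENEPOP line %d: '%s'", i, ln))
    }
    name <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != nl) {
      stop(sprintf("line %d: %d genotypes for %d loci", i, length(gts), nl))
    }
    if (name %in% samples) stop("duplicate sample name: ", name)
    samples <- c(samples, name)
    pops <- c(pops, sprintf("pop%d", pop_i))
    rows[[name]] <- gts
  }
  decode <- function(gts) {
    w <- nchar(gts)
    if (!all(w %in% c(4L, 6L))) stop("genotype fields must be 4 or 6 digits")
    half <- w / 2
    c1 <- as.integer(substr(gts, 1, half))
    c2 <- as.integer(substr(gts, half + 1, w))
    bad <- (c1 > 4) | (c2 > 4)
    if (any(bad)) stop("allele codes above 4 are not nucleotide-coded")
    a1 <- ifelse(c1 == 0, NA, NUC[pmax(c1, 1)])
    a2 <- ifelse(c2 == 0, NA, NUC[pmax(c2, 1)])
    out <- geno_string(a1, a2)
    out[c1 == 0 | c2 == 0] <- NA_character_
    out
  }
  calls <- t(vapply(rows, decode, character(nl)))
  if (nl == 1L) calls <- matrix(calls, ncol = 1,
                                dimnames = list(samples, NULL))
  if (nl == 0L) calls <- matrix(NA_character_, length(samples), 0,
                                dimnames = list(samples, NULL))
  rownames(calls) <- samples
  pos <- suppressWarnings(as.integer(sub("^.*_p(\\d+)$", "\\1", loci)))
  locus <- ifelse(is.na(pos), loci, sub("_p\\d+$", "", loci))
  snps <- data.frame(snp_id = loci, locus_id = locus, position = pos,
                     allele1 = rep(NA_character_, nl),
                     allele2 = rep(NA_character_, nl),
                     stringsAsFactors = FALSE)
  update_observed_alleles(
    genotype_matrix(calls, stats::setNames(pops, samples), snps,
                    pipeline = "genepop"))
}
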