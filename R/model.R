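# Core domain containers shared by every stage: locus catalogues (fixed-length
# RAD tags + SNP sites), genotype matrices with a population map, and per-site
# allele-depth arrays.

#' Construct a locus catalogue
#'
#' A catalogue is one pipeline's set of RAD loci: fixed-length tags (all of the
#' same length \code{L}, alphabet ACGT) plus the SNP sites annotated on them.
#'
#' @param loci data.frame with columns \code{locus_id} (unique) and \code{tag}.
#' @param snps data.frame with columns \code{locus_id}, \code{position}
#'   (0-based offset within the tag) and \code{alleles} (comma-separated
#'   nucleotides, 2--4 of them).
#' @param pipeline label of the producing pipeline (e.g. \code{"STA"}).
#' @return an object of class \code{locus_catalog}.
#' @export
locus_catalog <- function(loci, snps, pipeline = "catalog") {
  stopifnot(is.data.frame(loci), all(c("locus_id", "tag") %in% names(loci)))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_ids in catalogue")
  assert_acgt(loci$tag, "catalogue tag")
  L <- unique(nchar(loci$tag))
  if (length(L) > 1) stop("all tags in a catalogue must have identical length")
  if (length(L) == 0) L <- NA_integer_
  if (is.null(snps)) {
    snps <- data.frame(locus_id = character(), position = integer(),
                       alleles = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("locus_id", "position", "alleles") %in% names(snps)))
  if (nrow(snps)) {
    if (!all(snps$locus_id %in% loci$locus_id)) {
      stop("SNP sites reference loci absent from the catalogue")
    }
    if (any(snps$position < 0 | snps$position >= L)) {
      stop("SNP position outside the tag")
    }
  }
  structure(list(loci = loci, snps = snps,
                 pipeline = pipeline, L = as.integer(L)),
            class = "locus_catalog")
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("<locus_catalog '%s'> %d loci (L = %d bp), %d SNP sites\n",
              x$pipeline, nrow(x$loci), x$L, nrow(x$snps)))
  invisible(x)
}

snp_id <- function(locus_id, position) {
  sprintf("%s_p%02d", locus_id, as.integer(position))
}

#' Canonical orientation of RAD tags
#'
#' Returns, for each tag, the lexicographic minimum of the tag and its reverse
#' complement. This is the package's deterministic convention for putting two
#' independently built catalogues into a common orientation before clustering;
#' the \code{flipped} attribute records which tags were reversed so SNP
#' coordinates can be remapped (position p -> L-1-p, alleles complemented).
#'
#' @param tags character vector of ACGT tags.
#' @return character vector of canonical tags with logical attribute
#'   \code{flipped}.
#' @export
canonical_orientation <- function(tags) {
  assert_acgt(tags, "tag")
  rc <- revcomp(tags)
  flipped <- rc < tags
  out <- ifelse(flipped, rc, tags)
  attr(out, "flipped") <- flipped
  out
}

# Remap a 0-based position / allele set into canonical orientation.
canonical_position <- function(position, flipped, L) {
  ifelse(flipped, L - 1L - as.integer(position), as.integer(position))
}

canonical_allele_pair <- function(a1, a2, flipped) {
  a1f <- ifelse(flipped, unname(COMP[a1]), a1)
  a2f <- ifelse(flipped, unname(COMP[a2]), a2)
  paste(pmin(a1f, a2f), pmax(a1f, a2f), sep = "/")
}

#' Construct a genotype matrix
#'
#' @param calls character matrix, samples in rows and SNPs in columns; entries
#'   are sorted diploid strings (\code{"A/G"}) or \code{NA} for missing.
#' @param popmap named character vector mapping every sample (rowname) to a
#'   population label.
#' @param snps data.frame describing the columns: \code{snp_id},
#'   \code{locus_id}, \code{position}, and (possibly \code{NA}) \code{allele1},
#'   \code{allele2}.
#' @param pipeline source catalogue label.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, popmap, snps, pipeline = "panel") {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls))) stop("calls must carry sample rownames")
  if (!all(rownames(calls) %in% names(popmap))) {
    stop("every sample must be assigned a population in popmap")
  }
  popmap <- popmap[rownames(calls)]
  stopifnot(is.data.frame(snps), nrow(snps) == ncol(calls))
  colnames(calls) <- snps$snp_id
  structure(list(calls = calls, popmap = popmap, snps = snps,
                 pipeline = pipeline),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix '%s'> %d samples x %d SNPs, %d populations, %.1f%% missing\n",
    x$pipeline, nrow(x$calls), ncol(x$calls),
    length(unique(x$popmap)), 100 * mean(is.na(x$calls))))
  invisible(x)
}

n_snps <- function(gm) ncol(gm$calls)
n_samples <- function(gm) nrow(gm$calls)

# Subset the SNP columns of a genotype matrix (keeps popmap and class).
subset_snps <- function(gm, keep) {
  gm$calls <- gm$calls[, keep, drop = FALSE]
  gm$snps <- gm$snps[keep, , drop = FALSE]
  rownames(gm$snps) <- NULL
  gm
}

#' Observed alleles per SNP
#'
#' Tallies the distinct alleles present in the non-missing calls of each SNP
#' column and refreshes the \code{allele1}/\code{allele2} metadata (major
#' first by count, ties broken A<C<G<T). Sites with more than two observed
#' alleles keep \code{NA} metadata.
#'
#' @param gm genotype_matrix.
#' @return gm with updated snps table and an \code{n_alleles} column.
#' @export
update_observed_alleles <- function(gm) {
  nsnp <- n_snps(gm)
  if (nsnp == 0L) {
    gm$snps$allele1 <- character(0)
    gm$snps$allele2 <- character(0)
    gm$snps$n_alleles <- integer(0)
    return(gm)
  }
  a1 <- geno_allele1(gm$calls)
  a2 <- geno_allele2(gm$calls)
  cnt <- matrix(0L, nsnp, 4, dimnames = list(NULL, NUC))
  for (k in seq_along(NUC)) {
    cnt[, k] <- colSums(a1 == NUC[k], na.rm = TRUE) +
      colSums(a2 == NUC[k], na.rm = TRUE)
  }
  nall <- rowSums(cnt > 0)
  ord <- apply(cnt, 1L, order, decreasing = TRUE)  # ties keep A<C<G<T order
  maj <- NUC[ord[1L, ]]
  min2 <- NUC[ord[2L, ]]
  top2 <- cnt[cbind(seq_len(nsnp), ord[2L, ])]
  gm$snps$allele1 <- ifelse(nall >= 1 & nall <= 2, maj, NA_character_)
  gm$snps$allele2 <- ifelse(nall == 2 & top2 > 0, min2, NA_character_)
  gm$snps$n_alleles <- as.integer(nall)
  gm
}

# Copies of `allele2` carried by each call (0/1/2, NA when missing); the
# numeric workhorse behind MAC, HWE and all popgen statistics.
dosage_matrix <- function(gm) {
  a1 <- geno_allele1(gm$calls)
  a2 <- geno_allele2(gm$calls)
  ref <- matrix(gm$snps$allele2, nrow = n_samples(gm), ncol = n_snps(gm),
                byrow = TRUE)
  d <- (a1 == ref) + (a2 == ref)
  d[is.na(ref) & !is.na(gm$calls)] <- 0L   # monomorphic: no alt copies
  d[is.na(gm$calls)] <- NA_integer_
  mode(d) <- "integer"
  dimnames(d) <- dimnames(gm$calls)
  d
}

#' Construct a depth matrix
#'
#' Per (sample, SNP site) read counts for the four nucleotides.
#'
#' @param counts integer array \code{samples x snps x 4} (dimnames: samples,
#'   snp_ids, A/C/G/T). \code{NA} marks sites absent from the pipeline's
#'   catalogue (locus dropout); zero total depth is a legal observed value.
#' @param pipeline label.
#' @return object of class \code{depth_matrix}.
#' @export
depth_matrix <- function(counts, pipeline = "pipeline") {
  stopifnot(length(dim(counts)) == 3, dim(counts)[3] == 4)
  dimnames(counts)[[3]] <- NUC
  if (any(counts < 0, na.rm = TRUE)) stop("negative read counts")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, pipeline = pipeline), class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("<depth_matrix '%s'> %d samples x %d sites, mean depth %.1f\n",
              x$pipeline, dim(x$counts)[1], dim(x$counts)[2],
              mean(total_depth(x), na.rm = TRUE)))
  invisible(x)
}

# samples x snps matrix of total depths (NA where the locus is absent).
total_depth <- function(dm) {
  counts <- dm$counts
  d <- counts[, , 1] + counts[, , 2] + counts[, , 3] + counts[, , 4]
  if (is.null(dim(d))) {
    d <- matrix(d, dim(counts)[1], dim(counts)[2],
                dimnames = dimnames(counts)[1:2])
  }
  d
}

subset_depth <- function(dm, keep) {
  dm$counts <- dm$counts[, keep, , drop = FALSE]
  dm
}

#' Validate a genotype matrix against its catalogue and depths
#'
#' Report-based validation: returns a data.frame of violations (empty when all
#' invariants hold) instead of stopping, so a whole dataset can be audited in
#' one pass. Checks: SNP columns must exist in the catalogue (no orphans),
#' called alleles must be within the site's allele set, every sample must be
#' in the population map, and depth columns must cover the genotype columns.
#'
#' @param gm genotype_matrix.
#' @param cat locus_catalog the matrix claims to derive from.
#' @param dm optional depth_matrix.
#' @return data.frame with columns \code{check}, \code{item}, \code{detail}.
#' @export
validate_matrix <- function(gm, cat, dm = NULL) {
  bad <- list()
  note <- function(check, item, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, item = item,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  cat_ids <- snp_id(cat$snps$locus_id, cat$snps$position)
  orphan <- setdiff(gm$snps$snp_id, cat_ids)
  for (o in orphan) note("orphan_snp", o, "SNP not present in source catalogue")

  idx <- match(gm$snps$snp_id, cat_ids)
  for (j in which(!is.na(idx))) {
    allowed <- strsplit(cat$snps$alleles[idx[j]], ",", fixed = TRUE)[[1]]
    seen <- unique(na.omit(c(geno_allele1(gm$calls[, j]),
                             geno_allele2(gm$calls[, j]))))
    extra <- setdiff(seen, allowed)
    if (length(extra)) {
      note("allele_outside_site", gm$snps$snp_id[j],
           paste0("called allele(s) ", paste(extra, collapse = ","),
                  " not in site set {", cat$snps$alleles[idx[j]], "}"))
    }
  }
  unmapped <- rownames(gm$calls)[is.na(gm$popmap) |
                                   !nzchar(as.character(gm$popmap))]
  for (s in unmapped) note("popmap_gap", s, "sample has no population label")

  if (!is.null(dm)) {
    missing_depth <- setdiff(gm$snps$snp_id, dimnames(dm$counts)[[2]])
    for (s in missing_depth) note("no_depth", s, "SNP lacks a depth column")
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(), item = character(), detail = character(),
               stringsAsFactors = FALSE)
}
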