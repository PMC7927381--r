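# The seven ordered SNP filtering steps, each returning the filtered panel
# plus an audit record so the whole cascade can be traced step by step
# (counts of SNPs and loci before/after, missingness after).

audit_record <- function(step, before, after) {
  data.frame(step = step,
             snps_before = n_snps(before),
             snps_after = n_snps(after),
             loci_before = length(unique(before$snps$locus_id)),
             loci_after = length(unique(after$snps$locus_id)),
             missing_fraction_after =
               if (n_snps(after)) mean(is.na(after$calls)) else NA_real_,
             stringsAsFactors = FALSE)
}

per_sample_missing <- function(gm) {
  if (n_snps(gm) == 0) return(stats::setNames(rep(NA_real_, n_samples(gm)),
                                              rownames(gm$calls)))
  rowMeans(is.na(gm$calls))
}

#' Step 1 -- biallelic filter (BIAL)
#'
#' Removes SNPs with more than two alleles observed across all calls.
#' Monomorphic and biallelic sites pass (monomorphic sites fall to MAC later).
#'
#' @param gm genotype_matrix.
#' @return list(gm, audit).
#' @export
filter_biallelic <- function(gm) {
  gm <- update_observed_alleles(gm)
  out <- subset_snps(gm, gm$snps$n_alleles <= 2L)
  list(gm = out, audit = audit_record("BIAL", gm, out))
}

#' Step 2 -- minimum coverage filter (8x)
#'
#' Sets to missing every call whose total site depth is below the threshold.
#' The SNP set is unchanged at this step; only missingness grows.
#'
#' @param gm genotype_matrix.
#' @param dm depth_matrix covering all of \code{gm}'s SNPs.
#' @param threshold minimum reads per genotype (default 8).
#' @return list(gm, audit).
#' @export
apply_min_coverage <- function(gm, dm, threshold = 8) {
  td <- total_depth(dm)
  idx <- match(gm$snps$snp_id, colnames(td))
  if (anyNA(idx)) stop("depth data missing for SNP(s): ",
                       paste(utils::head(gm$snps$snp_id[is.na(idx)], 3),
                             collapse = ", "))
  td <- td[rownames(gm$calls), idx, drop = FALSE]
  if (any(!is.na(gm$calls) & is.na(td))) {
    stop("non-missing call lacking depth data")
  }
  out <- gm
  out$calls[!is.na(td) & td < threshold] <- NA_character_
  list(gm = out, audit = audit_record("MinCov", gm, out))
}

#' Step 3 -- maximum SNPs per RAD locus
#'
#' Removes all SNPs sitting on loci that carry more than \code{max_snps}
#' SNPs. By default loci are sized on the current (post-previous-filters) SNP
#' set; \code{count_on = "raw"} uses a raw catalogue count instead.
#'
#' @param gm genotype_matrix.
#' @param max_snps maximum SNPs a locus may carry (default 3).
#' @param count_on "current" (default) or "raw"; with "raw" supply \code{cat}.
#' @param cat locus_catalog, only needed for \code{count_on = "raw"}.
#' @return list(gm, audit).
#' @export
filter_max_snps_per_locus <- function(gm, max_snps = 3, count_on = "current",
                                      cat = NULL) {
  counts <- if (identical(count_on, "raw")) {
    if (is.null(cat)) stop("count_on='raw' needs the catalogue")
    table(cat$snps$locus_id)
  } else {
    table(gm$snps$locus_id)
  }
  per_locus <- as.integer(counts[gm$snps$locus_id])
  out <- subset_snps(gm, per_locus <= max_snps)
  list(gm = out, audit = audit_record("MaxSNP", gm, out))
}

#' Step 4 -- minimum allele count (MAC)
#'
#' Keeps a SNP only when its minor allele is carried at least
#' \code{min_count} times over the genotyped calls of the whole sample
#' (heterozygote = 1 copy, minor homozygote = 2). Monomorphic sites have
#' count 0 and are removed.
#'
#' @param gm genotype_matrix.
#' @param min_count minimum minor-allele copies (default 3).
#' @return list(gm, audit).
#' @export
filter_mac <- function(gm, min_count = 3) {
  gm <- update_observed_alleles(gm)
  d <- dosage_matrix(gm)
  n2 <- colSums(d, na.rm = TRUE)                     # copies of allele2
  n_called <- colSums(!is.na(d))
  n1 <- 2 * n_called - n2
  mac <- pmin(n1, n2)
  mac[gm$snps$n_alleles < 2] <- 0
  out <- subset_snps(gm, mac >= min_count)
  list(gm = out, audit = audit_record("MAC", gm, out))
}

#' Step 5 -- per-population call-rate filter (POP)
#'
#' Retains a SNP only when its missing fraction is strictly below
#' \code{max_missing} in every population.
#'
#' @param gm genotype_matrix.
#' @param max_missing maximum tolerated missing fraction (default 0.40;
#'   equality drops the SNP).
#' @return list(gm, audit).
#' @export
filter_pop_callrate <- function(gm, max_missing = 0.40) {
  pops <- unique(gm$popmap)
  if (any(table(factor(gm$popmap, levels = pops)) == 0)) {
    stop("empty population in popmap")
  }
  ok <- rep(TRUE, n_snps(gm))
  for (p in pops) {
    rows <- gm$popmap == p
    miss <- colMeans(is.na(gm$calls[rows, , drop = FALSE]))
    ok <- ok & (miss < max_missing)
  }
  out <- subset_snps(gm, ok)
  list(gm = out, audit = audit_record("POP", gm, out))
}

#' Step 6 -- Hardy-Weinberg filter (HW)
#'
#' Runs the biallelic conditional exact test per population and removes a
#' SNP when the count of populations with P below \code{p_threshold} is
#' strictly greater than half the number of populations analysed.
#' Populations with fewer than two genotyped individuals at the SNP are
#' skipped (they count neither way; the denominator stays the total number
#' of populations).
#'
#' @param gm genotype_matrix.
#' @param p_threshold exact-test significance level (default 0.01).
#' @return list(gm, audit, pvalues) where pvalues is a SNP x population
#'   matrix of exact-test P-values (NA where untestable).
#' @export
filter_hwe <- function(gm, p_threshold = 0.01) {
  gm <- update_observed_alleles(gm)
  pv <- hwe_pvalue_matrix(gm)
  n_pops <- length(unique(gm$popmap))
  n_sig <- rowSums(pv < p_threshold, na.rm = TRUE)
  out <- subset_snps(gm, !(n_sig > n_pops / 2))
  list(gm = out, audit = audit_record("HWE", gm, out), pvalues = pv)
}

# SNP x population matrix of HWE exact-test P-values; results memoised on the
# (hom1, het, hom2) configuration, which collapses thousands of tests to a
# few dozen distinct enumerations.
hwe_pvalue_matrix <- function(gm) {
  d <- dosage_matrix(gm)
  pops <- unique(gm$popmap)
  pv <- matrix(NA_real_, n_snps(gm), length(pops),
               dimnames = list(gm$snps$snp_id, pops))
  cache <- new.env(parent = emptyenv())
  for (p in pops) {
    rows <- gm$popmap == p
    dp <- d[rows, , drop = FALSE]
    n0 <- colSums(dp == 0L, na.rm = TRUE)
    n1 <- colSums(dp == 1L, na.rm = TRUE)
    n2 <- colSums(dp == 2L, na.rm = TRUE)
    n <- n0 + n1 + n2
    testable <- n >= 2
    for (j in which(testable)) {
      key <- paste(n0[j], n1[j], n2[j], sep = "_")
      val <- cache[[key]]
      if (is.null(val)) {
        val <- hwe_exact_test(n0[j], n1[j], n2[j])
        cache[[key]] <- val
      }
      pv[j, p] <- val
    }
  }
  pv
}

#' Step 7 -- one SNP per RAD locus
#'
#' Keeps, for each locus, only the SNP at the smallest position in canonical
#' tag orientation (a deterministic, pipeline-agnostic reading of "the first
#' SNP per RAD-locus"). When no catalogue is supplied, stored positions are
#' taken as already canonical.
#'
#' @param gm genotype_matrix.
#' @param cat locus_catalog with the tags (used to resolve orientation).
#' @return list(gm, audit).
#' @export
select_first_snp_per_locus <- function(gm, cat = NULL) {
  pos <- gm$snps$position
  if (!is.null(cat)) {
    ctag <- canonical_orientation(cat$loci$tag)
    flipped <- stats::setNames(attr(ctag, "flipped"), cat$loci$locus_id)
    fl <- flipped[gm$snps$locus_id]
    fl[is.na(fl)] <- FALSE
    pos <- canonical_position(pos, fl, cat$L)
  }
  ord <- order(gm$snps$locus_id, pos)
  first <- ord[!duplicated(gm$snps$locus_id[ord])]
  keep <- sort(first)
  out <- subset_snps(gm, seq_len(n_snps(gm)) %in% keep)
  list(gm = out, audit = audit_record("FirstSNP", gm, out))
}

#' The full seven-step filtering cascade
#'
#' Applies, in fixed order: BIAL, minimum coverage, maximum SNPs per locus,
#' MAC, per-population call rate, Hardy-Weinberg, first SNP per locus. The
#' audit trail records per-step SNP/locus counts and missingness; per-sample
#' missing fractions after the coverage step are attached as an attribute.
#'
#' @param gm raw genotype_matrix from one pipeline.
#' @param dm its depth_matrix.
#' @param cat its locus_catalog.
#' @param params list of thresholds: \code{min_coverage} (8), \code{max_snps}
#'   (3), \code{mac} (3), \code{pop_max_missing} (0.40), \code{hwe_alpha}
#'   (0.01).
#' @param stop_after_step integer 1..7; common/merged panel construction
#'   needs the cascade stopped after step 6.
#' @return list(panel = genotype_matrix, audit = data.frame of class
#'   \code{filter_audit}).
#' @export
run_cascade <- function(gm, dm, cat, params = list(), stop_after_step = 7) {
  p <- utils::modifyList(list(min_coverage = 8, max_snps = 3, mac = 3,
                              pop_max_missing = 0.40, hwe_alpha = 0.01),
                         params)
  steps <- list(
    function(g) filter_biallelic(g),
    function(g) apply_min_coverage(g, dm, p$min_coverage),
    function(g) filter_max_snps_per_locus(g, p$max_snps),
    function(g) filter_mac(g, p$mac),
    function(g) filter_pop_callrate(g, p$pop_max_missing),
    function(g) filter_hwe(g, p$hwe_alpha),
    function(g) select_first_snp_per_locus(g, cat)
  )
  audit <- list()
  sample_missing <- NULL
  for (i in seq_len(min(stop_after_step, 7L))) {
    res <- steps[[i]](gm)
    gm <- res$gm
    audit[[i]] <- res$audit
    if (i == 2L) sample_missing <- per_sample_missing(gm)
  }
  audit <- do.call(rbind, audit)
  class(audit) <- c("filter_audit", class(audit))
  attr(audit, "per_sample_missing_after_mincov") <- sample_missing
  attr(audit, "params") <- p
  gm <- update_observed_alleles(gm)
  list(panel = gm, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter cascade audit:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
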