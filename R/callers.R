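# The two genotype callers emulated by the generator. Both consume per-site
# allele depths and share the same < 3x calling floor; they differ in how they
# separate heterozygotes from homozygotes, which is the engine behind the
# cross-pipeline discordances studied downstream.

# Rank the four base counts of each row; ties resolved in A<C<G<T order.
.major_minor <- function(cnt) {
  n <- nrow(cnt)
  maj_ix <- max.col(cnt, ties.method = "first")
  cnt2 <- cnt
  cnt2[cbind(seq_len(n), maj_ix)] <- -1L
  min_ix <- max.col(cnt2, ties.method = "first")
  list(major = NUC[maj_ix], minor = NUC[min_ix],
       n_major = cnt[cbind(seq_len(n), maj_ix)],
       n_minor = cnt[cbind(seq_len(n), min_ix)])
}

#' Frequency-threshold genotype caller
#'
#' Calls each (sample, site) cell from its allele depths using the
#' minor-frequency rule: with \code{f} the fraction of the second most
#' frequent base, \code{f < lo} is called homozygous for the major base,
#' \code{f > hi} heterozygous (major/minor), and \code{lo <= f <= hi} is left
#' uncalled (uncertain). Cells with total depth below \code{min_depth} are
#' missing. Ties between base counts are broken in fixed A<C<G<T order.
#'
#' @param dm depth_matrix.
#' @param min_depth calling floor in reads (default 3).
#' @param lo,hi closed uncertain band for the minor-allele read fraction
#'   (defaults 0.1 and 0.2).
#' @return genotype call matrix (samples x sites, \code{"A/G"}-style strings).
#' @export
call_genotypes_freq_threshold <- function(dm, min_depth = 3, lo = 0.1,
                                          hi = 0.2) {
  stopifnot(lo <= hi)
  counts <- dm$counts
  ns <- dim(counts)[1]; nl <- dim(counts)[2]
  flat <- matrix(counts, ns * nl, 4)
  flat_na <- is.na(flat[, 1])
  flat[flat_na, ] <- 0L
  mm <- .major_minor(flat)
  tot <- rowSums(flat)
  f <- ifelse(tot > 0, mm$n_minor / tot, 0)
  call <- rep(NA_character_, ns * nl)
  hom <- f < lo
  het <- f > hi
  call[hom] <- geno_string(mm$major[hom], mm$major[hom])
  call[het] <- geno_string(mm$major[het], mm$minor[het])
  call[tot < min_depth] <- NA_character_
  call[flat_na] <- NA_character_
  matrix(call, ns, nl, dimnames = dimnames(counts)[1:2])
}

#' Likelihood-ratio genotype caller
#'
#' A simplified two-hypothesis multinomial emulation of a chi-square SNP
#' model: for each cell the log-likelihoods of HOM(major) and HET(major,
#' minor) are computed under a read model with per-read error rate
#' \code{seq_error} (errors spread uniformly over the other three bases), and
#' the better model is called only when the likelihood-ratio statistic
#' \code{2|dlnL|} exceeds the chi-square(1 df) critical value at \code{alpha};
#' otherwise the cell stays missing. Depth below \code{min_depth} is missing.
#'
#' @param dm depth_matrix.
#' @param min_depth calling floor in reads (default 3).
#' @param alpha significance level of the likelihood-ratio test.
#' @param seq_error assumed per-read error rate (floored at 1e-4 so the
#'   homozygous model keeps finite likelihood in the presence of stray reads).
#' @return genotype call matrix.
#' @export
call_genotypes_lrt <- function(dm, min_depth = 3, alpha = 0.05,
                               seq_error = 0.005) {
  stopifnot(alpha > 0, alpha < 1)
  eps <- max(seq_error, 1e-4)
  counts <- dm$counts
  ns <- dim(counts)[1]; nl <- dim(counts)[2]
  flat <- matrix(counts, ns * nl, 4)
  flat_na <- is.na(flat[, 1])
  flat[flat_na, ] <- 0L
  mm <- .major_minor(flat)
  tot <- rowSums(flat)
  n_rest <- tot - mm$n_major - mm$n_minor
  ll_hom <- mm$n_major * log1p(-eps) +
    (mm$n_minor + n_rest) * log(eps / 3)
  ll_het <- (mm$n_major + mm$n_minor) * log(0.5 - eps / 3) +
    n_rest * log(eps / 3)
  stat <- 2 * abs(ll_hom - ll_het)
  crit <- stats::qchisq(1 - alpha, df = 1)
  call <- rep(NA_character_, ns * nl)
  hom <- ll_hom > ll_het & stat > crit
  het <- ll_het > ll_hom & stat > crit
  call[hom] <- geno_string(mm$major[hom], mm$major[hom])
  call[het] <- geno_string(mm$major[het], mm$minor[het])
  call[tot < min_depth] <- NA_character_
  call[flat_na] <- NA_character_
  matrix(call, ns, nl, dimnames = dimnames(counts)[1:2])
}
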