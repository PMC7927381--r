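# Population-genetic statistics from first principles: observed / unbiased
# expected heterozygosity, multi-locus FIS with bootstrap CIs, global
# Weir-Cockerham theta, El Mousadik-Petit rarefied allelic richness and the
# biallelic Hardy-Weinberg conditional exact test.

# Per-(locus, population) sufficient statistics from a genotype matrix:
# genotyped count, alternate-allele frequency and observed-het fraction.
.pop_locus_stats <- function(gm) {
  d <- dosage_matrix(gm)
  pops <- unique(gm$popmap)
  nl <- n_snps(gm)
  N <- P <- H <- matrix(NA_real_, nl, length(pops),
                        dimnames = list(gm$snps$snp_id, pops))
  for (p in pops) {
    dp <- d[gm$popmap == p, , drop = FALSE]
    n <- colSums(!is.na(dp))
    N[, p] <- n
    P[, p] <- ifelse(n > 0, colSums(dp, na.rm = TRUE) / (2 * n), NA)
    H[, p] <- ifelse(n > 0, colSums(dp == 1L, na.rm = TRUE) / n, NA)
  }
  list(N = N, P = P, H = H, pops = pops)
}

#' Observed and unbiased expected heterozygosity per locus
#'
#' Ho is the heterozygote fraction among genotyped individuals; He is the
#' unbiased expected heterozygosity \eqn{\frac{2n}{2n-1}(1 - \sum p^2)} with
#' n the genotyped individuals at the locus.
#'
#' @param gm genotype_matrix.
#' @param pop population label.
#' @return data.frame with columns snp_id, n, Ho, He (loci with no genotyped
#'   individual are NA).
#' @export
obs_exp_het <- function(gm, pop) {
  stopifnot(pop %in% gm$popmap)
  d <- dosage_matrix(gm)[gm$popmap == pop, , drop = FALSE]
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA)
  ho <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA)
  he <- ifelse(n > 0, (2 * n) / (2 * n - 1) * 2 * p * (1 - p), NA)
  data.frame(snp_id = gm$snps$snp_id, n = unname(n), Ho = unname(ho),
             He = unname(he), row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-locus inbreeding coefficient FIS
#'
#' Ratio-of-sums estimator \eqn{1 - \sum_l Ho_l / \sum_l He_l} over loci with
#' at least \code{min_n} genotyped individuals (unbiased He). Returns NA when
#' the He sum is zero (monomorphic data).
#'
#' @param gm genotype_matrix.
#' @param pop population label.
#' @param min_n minimum genotyped individuals for a locus to count (default 2).
#' @return scalar FIS.
#' @export
fis <- function(gm, pop, min_n = 2) {
  oe <- obs_exp_het(gm, pop)
  use <- !is.na(oe$He) & oe$n >= min_n
  s_he <- sum(oe$He[use])
  if (s_he == 0) return(NA_real_)
  1 - sum(oe$Ho[use]) / s_he
}

#' Bootstrap percentile confidence interval for FIS
#'
#' Loci are resampled with replacement \code{n_boot} times; the multi-locus
#' FIS is recomputed per replicate and the percentile interval returned.
#'
#' @param gm genotype_matrix.
#' @param pop population label.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (deterministic CI for a given seed).
#' @return named numeric c(lower, upper).
#' @export
bootstrap_fis_ci <- function(gm, pop, n_boot = 1000, level = 0.95, seed = 1L) {
  oe <- obs_exp_het(gm, pop)
  use <- !is.na(oe$He) & oe$n >= 2
  ho <- oe$Ho[use]; he <- oe$He[use]
  nl <- length(ho)
  if (nl < 2) stop("need >= 2 usable loci for a bootstrap CI")
  reps <- with_substream(seed, paste0("fis_boot/", pop), {
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(nl, nl, replace = TRUE)
      s <- sum(he[ix])
      if (s == 0) NA_real_ else 1 - sum(ho[ix]) / s
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Global multi-locus Weir-Cockerham theta
#'
#' Per-locus variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) are computed from sample
#' sizes, allele frequencies and observed heterozygosity per population, and
#' combined as the ratio of sums \eqn{\theta = \sum_l a_l / \sum_l
#' (a_l+b_l+c_l)}. Loci with fewer than two populations containing genotyped
#' individuals, or with zero total variance, are skipped. Negative estimates
#' are reported as computed.
#'
#' @param gm genotype_matrix with >= 2 populations.
#' @return list with \code{theta} (multi-locus) and \code{per_locus}
#'   data.frame of components.
#' @export
global_fst_wc <- function(gm) {
  if (length(unique(gm$popmap)) < 2) stop("need >= 2 populations")
  st <- .pop_locus_stats(gm)
  N <- st$N; P <- st$P; H <- st$H
  N0 <- N; N0[N == 0] <- NA                 # pops absent at a locus drop out
  r <- rowSums(!is.na(N0))
  sumn <- rowSums(N0, na.rm = TRUE)
  nbar <- sumn / r
  nc <- (sumn - rowSums(N0^2, na.rm = TRUE) / sumn) / (r - 1)
  pbar <- rowSums(N0 * P, na.rm = TRUE) / sumn
  s2 <- rowSums(N0 * (P - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(N0 * H, na.rm = TRUE) / sumn
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  ok <- r >= 2 & nbar > 1 & nc > 0 & is.finite(tot) & tot != 0
  theta <- sum(a[ok]) / sum(tot[ok])
  list(theta = theta,
       per_locus = data.frame(snp_id = gm$snps$snp_id, a = a, b = b, c = cc,
                              used = ok, row.names = NULL,
                              stringsAsFactors = FALSE))
}

#' Rarefied allelic richness (El Mousadik-Petit)
#'
#' Expected number of distinct alleles in a random subsample of \code{g} gene
#' copies: \eqn{AR = \sum_a (1 - C(2n - N_a, g) / C(2n, g))} with 2n genotyped
#' gene copies and \eqn{N_a} copies of allele a in the population.
#'
#' @param gm genotype_matrix.
#' @param pop population label.
#' @param g rarefaction size in gene copies (>= 2; must not exceed 2n at any
#'   counted locus).
#' @return numeric vector of AR per locus (NA where 2n = 0 or g > 2n).
#' @export
allelic_richness <- function(gm, pop, g) {
  stopifnot(g >= 2)
  d <- dosage_matrix(gm)[gm$popmap == pop, , drop = FALSE]
  n <- colSums(!is.na(d))
  two_n <- 2 * n
  if (all(two_n == 0)) stop("no genotyped individuals in population")
  if (g > max(two_n)) stop("g exceeds available gene copies at every locus")
  n2 <- colSums(d, na.rm = TRUE)
  n1 <- two_n - n2
  term <- function(na) {
    # 1 - C(2n - na, g)/C(2n, g); na = 0 contributes 0 alleles of that type
    out <- 1 - exp(lchoose(two_n - na, g) - lchoose(two_n, g))
    out[na == 0] <- 0
    out
  }
  ar <- term(n1) + term(n2)
  ar[two_n == 0 | g > two_n] <- NA_real_
  unname(ar)
}

#' Biallelic Hardy-Weinberg conditional exact test
#'
#' Conditional on the observed allele counts, the probability of every
#' compatible heterozygote count is computed and the P-value is the sum of
#' probabilities of outcomes no more probable than the observed one (the
#' standard two-sided exact test). P = 1 when only one heterozygote count is
#' consistent with the allele counts.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (major hom, het, minor hom).
#' @return P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("no genotyped individuals")
  n_a <- 2 * n_hom2 + n_het                # minor-allele copies (either one)
  n_b <- 2 * n - n_a
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  hets <- seq(n_a %% 2, n_a, by = 2)       # compatible heterozygote counts
  if (length(hets) == 1) return(1)
  # log P(h) up to a shared constant: 2^h / ( ((nA-h)/2)! h! ((nB-h)/2)! )
  lp <- hets * log(2) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Panel-level population-genomic summary
#'
#' Assembles the metric suite for one SNP panel: per-population mean Ho, mean
#' unbiased He, multi-locus FIS with bootstrap CI, mean rarefied allelic
#' richness, plus the global Weir-Cockerham theta; grand means are taken
#' across loci and populations.
#'
#' @param gm genotype_matrix.
#' @param g rarefaction size in gene copies; default is twice the smallest
#'   per-(locus, population) genotyped count over counted loci (floored at 2).
#' @param n_boot bootstrap iterations for the FIS CI (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class \code{pop_metrics}: \code{per_pop} data.frame,
#'   \code{global_fst}, and means \code{Ho}, \code{He}, \code{FIS}, \code{AR}.
#' @export
summarize_panel <- function(gm, g = NULL, n_boot = 1000, seed = 1L) {
  pops <- unique(gm$popmap)
  gm <- update_observed_alleles(gm)
  st <- .pop_locus_stats(gm)
  usable <- rowSums(st$N >= 1) == length(pops)   # loci genotyped in every pop
  if (is.null(g)) {
    g <- max(2, 2 * min(st$N[usable, , drop = FALSE]))
  }
  per_pop <- lapply(pops, function(p) {
    oe <- obs_exp_het(gm, p)
    ar <- allelic_richness(gm, p, g = g)
    keep <- usable & !is.na(oe$He) & !is.na(ar)
    ci <- if (sum(keep) >= 2 && n_boot > 0) {
      bootstrap_fis_ci(gm, p, n_boot = n_boot, seed = seed)
    } else c(lower = NA_real_, upper = NA_real_)
    data.frame(pop = p, n_loci = sum(keep),
               Ho = mean(oe$Ho[keep]), He = mean(oe$He[keep]),
               FIS = fis(gm, p), FIS_lo = ci[["lower"]], FIS_hi = ci[["upper"]],
               AR = mean(ar[keep]), stringsAsFactors = FALSE)
  })
  per_pop <- do.call(rbind, per_pop)
  fst <- if (length(pops) >= 2) global_fst_wc(gm)$theta else NA_real_
  structure(list(per_pop = per_pop, global_fst = fst, g = g,
                 Ho = mean(per_pop$Ho), He = mean(per_pop$He),
                 FIS = mean(per_pop$FIS, na.rm = TRUE),
                 AR = mean(per_pop$AR)),
            class = "pop_metrics")
}

#' @export
print.pop_metrics <- function(x, ...) {
  cat(sprintf("Ho = %.3f  He = %.3f  FIS = %.3f  AR = %.3f  global FST = %.3f (g = %d)\n",
              x$Ho, x$He, x$FIS, x$AR, x$global_fst, x$g))
  print.data.frame(x$per_pop, row.names = FALSE, digits = 4)
  invisible(x)
}
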