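# Fixtures and independent oracles shared across the suite. All fixtures are
# built in code; the oracles deliberately re-derive results from first
# principles (enumeration / direct transcription of the stated rules) and
# never call the implementation paths they check.

NUCS <- c("A", "C", "G", "T")

# --- small genotype-matrix builders -----------------------------------------

# Build per-population call vectors: counts of (hom1, het, hom2, missing).
pop_calls <- function(n_hom1, n_het, n_hom2, n_miss = 0, alleles = c("A", "G")) {
  a <- alleles[1]; b <- alleles[2]
  c(rep(paste0(a, "/", a), n_hom1),
    rep(paste0(min(a, b), "/", max(a, b)), n_het),
    rep(paste0(b, "/", b), n_hom2),
    rep(NA_character_, n_miss))
}

# Assemble a genotype_matrix from a list of per-SNP call vectors.
mk_gm <- function(snp_calls, pops, locus_ids = NULL, positions = NULL,
                  pipeline = "test") {
  calls <- do.call(cbind, snp_calls)
  ns <- nrow(calls)
  samples <- sprintf("s%02d", seq_len(ns))
  rownames(calls) <- samples
  stopifnot(length(pops) == ns)
  if (is.null(locus_ids)) locus_ids <- sprintf("LX%02d", seq_along(snp_calls))
  if (is.null(positions)) positions <- rep(0L, length(snp_calls))
  snps <- data.frame(snp_id = radpanels:::snp_id(locus_ids, positions),
                     locus_id = locus_ids, position = positions,
                     allele1 = NA_character_, allele2 = NA_character_,
                     stringsAsFactors = FALSE)
  update_observed_alleles(
    genotype_matrix(calls, stats::setNames(pops, samples), snps, pipeline))
}

# Uniform-depth depth_matrix covering a genotype matrix (all reads on base A;
# the filters only consume totals).
mk_dm <- function(gm, depth = 10L, overrides = list()) {
  ns <- nrow(gm$calls); nl <- ncol(gm$calls)
  counts <- array(0L, c(ns, nl, 4),
                  dimnames = list(rownames(gm$calls), colnames(gm$calls), NUCS))
  counts[, , 1] <- depth
  for (ov in overrides) {   # list(sample=, snp=, depth=)
    i <- match(ov$sample, rownames(gm$calls))
    j <- match(ov$snp, colnames(gm$calls))
    counts[i, j, ] <- 0L
    counts[i, j, 1] <- ov$depth
  }
  depth_matrix(counts, gm$pipeline)
}

# Random genotype matrix for GENEPOP round trips (may include all-missing
# columns and monomorphic columns).
random_gm <- function(seed, ns = 8, nl = 6, n_pops = 2) {
  withr::with_seed(seed, {
    pops <- sort(rep_len(sprintf("pop%d", seq_len(n_pops)), ns))
    snp_calls <- lapply(seq_len(nl), function(j) {
      ab <- sort(sample(NUCS, 2))
      states <- c(paste0(ab[1], "/", ab[1]), paste0(ab[1], "/", ab[2]),
                  paste0(ab[2], "/", ab[2]), NA)
      if (j == 1) rep(NA_character_, ns)       # all-missing column
      else sample(states, ns, replace = TRUE)
    })
    mk_gm(snp_calls, pops, locus_ids = sprintf("LR%02d", seq_len(nl)),
          positions = seq_len(nl) %% 30)
  })
}

# --- independent oracles ------------------------------------------------------

# HWE exact test by full enumeration of genotype configurations: probability
# of (nAA, nAa, naa) conditional on allele counts is proportional to the
# number of ways n individuals can carry those genotypes times 2^het.
oracle_hwe_enum <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  configs <- list(); probs <- c()
  for (h in 0:n) {
    rem <- nA - h
    if (rem < 0 || rem %% 2 != 0) next
    aa <- rem / 2
    bb <- n - h - aa
    if (bb < 0) next
    w <- factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
    configs[[length(configs) + 1]] <- c(aa, h, bb)
    probs <- c(probs, w)
  }
  probs <- probs / sum(probs)
  obs <- which(vapply(configs, function(cf) cf[2] == n_het, logical(1)))
  sum(probs[probs <= probs[obs] * (1 + 1e-9)])
}

# Frequency-threshold caller rule, scalar transcription. counts: named A/C/G/T.
oracle_freq_call <- function(counts, min_depth = 3, lo = 0.1, hi = 0.2) {
  tot <- sum(counts)
  if (tot < min_depth) return(NA_character_)
  ord <- order(-counts, match(names(counts), NUCS))
  major <- names(counts)[ord[1]]; minor <- names(counts)[ord[2]]
  f <- counts[[ord[2]]] / tot
  if (f < lo) return(paste0(major, "/", major))
  if (f > hi) return(paste(sort(c(major, minor)), collapse = "/"))
  NA_character_
}

# Likelihood-ratio caller rule, scalar transcription.
oracle_lrt_call <- function(counts, min_depth = 3, alpha = 0.05, eps = 0.005) {
  tot <- sum(counts)
  if (tot < min_depth) return(NA_character_)
  eps <- max(eps, 1e-4)
  ord <- order(-counts, match(names(counts), NUCS))
  major <- names(counts)[ord[1]]; minor <- names(counts)[ord[2]]
  nmaj <- counts[[ord[1]]]; nmin <- counts[[ord[2]]]
  nrest <- tot - nmaj - nmin
  ll_hom <- nmaj * log(1 - eps) + (nmin + nrest) * log(eps / 3)
  ll_het <- (nmaj + nmin) * log(0.5 - eps / 3) + nrest * log(eps / 3)
  if (2 * abs(ll_hom - ll_het) <= qchisq(1 - alpha, 1)) return(NA_character_)
  if (ll_hom > ll_het) return(paste0(major, "/", major))
  paste(sort(c(major, minor)), collapse = "/")
}

# Scalar Weir-Cockerham theta for one biallelic locus, coded straight from
# the published component formulas (independent of the vectorised version).
oracle_wc_locus <- function(geno_by_pop) {
  # geno_by_pop: list of integer vectors of alt-allele dosages (no NA)
  n_i <- vapply(geno_by_pop, length, numeric(1))
  p_i <- vapply(geno_by_pop, function(g) mean(g) / 2, numeric(1))
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1), numeric(1))
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Build a depth_matrix holding one site per row of a two-allele count table.
depths_from_counts <- function(tab) {
  # tab: data.frame with columns base1, base2, n1, n2 (one synthetic site each)
  nl <- nrow(tab)
  counts <- array(0L, c(1, nl, 4),
                  dimnames = list("s1", sprintf("D%04d_p00", seq_len(nl)), NUCS))
  for (j in seq_len(nl)) {
    counts[1, j, match(tab$base1[j], NUCS)] <- tab$n1[j]
    counts[1, j, match(tab$base2[j], NUCS)] <-
      counts[1, j, match(tab$base2[j], NUCS)] + tab$n2[j]
  }
  depth_matrix(counts, "oracle")
}

# --- the designed seven-step cascade fixture (criterion 1) -------------------
# 12 SNPs on 8 loci, 3 populations of 10. Each step removes a known subset:
#   BIAL: s3 (triallelic)              12 -> 11
#   MinCov: none removed (missingness) 11 -> 11
#   MaxSNP: s4..s7 (locus LC has 4)    11 -> 7
#   MAC: s8 (minor count 2)             7 -> 6
#   POP: s9 (designed missing) and s12 (depth-7 cells pushed missing) 6 -> 4
#   HWE: s10 (het deficit in pops 1,2)  4 -> 3
#   FirstSNP: s2 (LA keeps position 5)  3 -> 2  (survivors s1, s11)
cascade_fixture <- function() {
  pops <- rep(c("pop1", "pop2", "pop3"), each = 10)
  bal <- function(alleles = c("A", "G")) {        # HWE-friendly 3/5/2 per pop
    unlist(lapply(1:3, function(i) pop_calls(3, 5, 2, alleles = alleles)))
  }
  s1 <- bal(); s2 <- bal(c("C", "T")); s11 <- bal()
  s3 <- c(rep("A/A", 15), rep("A/C", 10), rep("T/T", 5))       # 3 alleles
  s4 <- bal(); s5 <- bal(); s6 <- bal(); s7 <- bal()
  s8 <- c(rep("A/A", 28), rep("A/G", 2))                       # MAC = 2
  s9 <- c(pop_calls(3, 5, 2), pop_calls(2, 3, 1, 4), pop_calls(3, 5, 2))
  s10 <- c(pop_calls(5, 0, 5), pop_calls(5, 0, 5), pop_calls(3, 5, 2))
  s12 <- bal()
  snp_calls <- list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5, s6 = s6,
                    s7 = s7, s8 = s8, s9 = s9, s10 = s10, s11 = s11,
                    s12 = s12)
  locus_ids <- c("LA", "LA", "LB", "LC", "LC", "LC", "LC", "LD", "LE", "LF",
                 "LG", "LH")
  positions <- c(5L, 20L, 3L, 1L, 2L, 3L, 4L, 7L, 0L, 9L, 11L, 2L)
  gm <- mk_gm(snp_calls, pops, locus_ids, positions)
  # depth-7 cells on s12 for the first four pop2 samples (MinCov -> missing)
  ov <- lapply(sprintf("s%02d", 11:14),
               function(s) list(sample = s, snp = "LH_p02", depth = 7L))
  dm <- mk_dm(gm, depth = 10L, overrides = ov)
  # catalogue with canonical tags (orientation-neutral step 7)
  tags <- withr::with_seed(99, vapply(1:8, function(i)
    paste(sample(NUCS, 36, replace = TRUE), collapse = ""), character(1)))
  tags <- as.character(canonical_orientation(tags))
  loci <- data.frame(locus_id = c("LA", "LB", "LC", "LD", "LE", "LF", "LG",
                                  "LH"), tag = tags, stringsAsFactors = FALSE)
  snp_sidecar <- data.frame(locus_id = locus_ids, position = positions,
                            alleles = "A,C,G,T", stringsAsFactors = FALSE)
  cat <- locus_catalog(loci, snp_sidecar, "fixture")
  list(gm = gm, dm = dm, cat = cat,
       expected = data.frame(
         step = c("BIAL", "MinCov", "MaxSNP", "MAC", "POP", "HWE",
                  "FirstSNP"),
         snps_before = c(12L, 11L, 11L, 7L, 6L, 4L, 3L),
         snps_after = c(11L, 11L, 7L, 6L, 4L, 3L, 2L),
         stringsAsFactors = FALSE),
       survivors = c("LA_p05", "LG_p11"))
}

# One-population single-SNP genotype matrix from a call vector.
one_pop_gm_accept <- function(calls_vec) {
  calls <- matrix(calls_vec, ncol = 1)
  rownames(calls) <- sprintf("s%02d", seq_along(calls_vec))
  snps <- data.frame(snp_id = "L1_p00", locus_id = "L1", position = 0L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  update_observed_alleles(
    genotype_matrix(calls, stats::setNames(rep("pop1", length(calls_vec)),
                                           rownames(calls)), snps))
}

# Small deterministic end-to-end configs.
tiny_cfg <- function(seed = 1L, ...) {
  load_run_config(NULL, overrides = utils::modifyList(
    list(n_loci = 120, pop_sizes = c(10L, 10L), n_pops = 2, n_boot = 50,
         seed = seed), list(...)))
}

zero_perturb_pipelines <- function() {
  list(STA = list(read_loss = 0, locus_dropout = 0, oversplit = 0, flip = 0),
       ALT = list(read_loss = 0, locus_dropout = 0, oversplit = 0, flip = 0))
}
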