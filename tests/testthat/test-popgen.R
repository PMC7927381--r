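one_pop_gm <- function(calls_by_snp, alleles = c("A", "G")) {
  calls <- do.call(cbind, calls_by_snp)
  rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  snps <- data.frame(snp_id = sprintf("L%d_p00", seq_along(calls_by_snp)),
                     locus_id = sprintf("L%d", seq_along(calls_by_snp)),
                     position = 0L, allele1 = alleles[1], allele2 = alleles[2],
                     stringsAsFactors = FALSE)
  update_observed_alleles(
    genotype_matrix(calls, stats::setNames(rep("pop1", nrow(calls)),
                                           rownames(calls)), snps))
}

test_that("Ho and unbiased He match their closed forms", {
  gm <- one_pop_gm(list(rep("A/G", 10)))
  oe <- obs_exp_het(gm, "pop1")
  expect_equal(oe$Ho, 1)
  expect_equal(oe$He, 20 / 19 * 0.5)
  gm0 <- one_pop_gm(list(rep("A/A", 10)))
  oe0 <- obs_exp_het(gm0, "pop1")
  expect_equal(oe0$Ho, 0)
  expect_equal(oe0$He, 0)
})

test_that("sampled HWE loci have Ho ~ He ~ 0.5 at p = 0.5", {
  f <- matrix(0.5, 1, 1, dimnames = list(NULL, "pop1"))
  tg <- simulate_true_genotypes(f, 10000, seed = 77)
  snps <- data.frame(snp_id = "L1_p00", locus_id = "L1", position = 0L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(radpanels:::dosage_to_calls(tg$dosage, snps),
                        tg$popmap, snps)
  oe <- obs_exp_het(gm, "pop1")
  expect_lt(abs(oe$Ho - 0.5), 0.02)
  expect_lt(abs(oe$He - 0.5), 0.02)
})

test_that("unbiased He estimates 2p(1-p) without bias", {
  p <- 0.3
  he <- withr::with_seed(31, vapply(1:2000, function(i) {
    dos <- rbinom(12, 2, p)
    n <- 12
    phat <- mean(dos) / 2
    (2 * n) / (2 * n - 1) * 2 * phat * (1 - phat)
  }, numeric(1)))
  expect_lt(abs(mean(he) - 2 * p * (1 - p)), 0.005)
  # and the package computes the same statistic on equivalent data
  gm <- one_pop_gm(list(c(rep("A/A", 5), rep("A/G", 5), rep("G/G", 2))))
  oe <- obs_exp_het(gm, "pop1")
  phat <- (5 + 4) / 24
  expect_equal(oe$He, 24 / 23 * 2 * phat * (1 - phat))
})

test_that("FIS is a ratio of sums with the documented edge cases", {
  # all individuals HET at every locus -> strong heterozygote excess
  gm <- one_pop_gm(list(rep("A/G", 10), rep("A/G", 10)))
  expect_lt(fis(gm, "pop1"), -0.8)
  # two-locus hand example
  gm2 <- one_pop_gm(list(c(rep("A/A", 4), rep("A/G", 4), rep("G/G", 2)),
                         c(rep("A/A", 6), rep("A/G", 2), rep("G/G", 2))))
  oe <- obs_exp_het(gm2, "pop1")
  expect_equal(fis(gm2, "pop1"), 1 - sum(oe$Ho) / sum(oe$He))
  ho1 <- 0.4; p1 <- 0.6
  he1 <- 20 / 19 * 2 * p1 * (1 - p1)
  ho2 <- 0.2; p2 <- 0.7
  he2 <- 20 / 19 * 2 * p2 * (1 - p2)
  expect_equal(fis(gm2, "pop1"), 1 - (ho1 + ho2) / (he1 + he2))
  # monomorphic data -> undefined
  gm3 <- one_pop_gm(list(rep("A/A", 10)))
  expect_true(is.na(fis(gm3, "pop1")))
})

test_that("bootstrap FIS CI is percentile-based and deterministic", {
  profile <- c(rep("A/A", 3), rep("A/G", 5), rep("G/G", 2))
  gm <- one_pop_gm(rep(list(profile), 6))
  ci <- bootstrap_fis_ci(gm, "pop1", n_boot = 200, seed = 5)
  # identical locus profiles -> degenerate CI at the point estimate
  expect_equal(unname(ci["lower"]), unname(ci["upper"]))
  expect_equal(unname(ci["lower"]), fis(gm, "pop1"))
  gm2 <- one_pop_gm(list(profile, rev(profile), c(rep("A/G", 6), rep("A/A", 4)),
                         c(rep("G/G", 2), rep("A/G", 3), rep("A/A", 5))))
  ci_a <- bootstrap_fis_ci(gm2, "pop1", n_boot = 300, seed = 9)
  ci_b <- bootstrap_fis_ci(gm2, "pop1", n_boot = 300, seed = 9)
  expect_identical(ci_a, ci_b)
  expect_lt(ci_a["lower"], ci_a["upper"])
})

test_that("bootstrap CI covers a true FIS of zero at roughly the right rate", {
  hits <- withr::with_seed(41, vapply(1:40, function(i) {
    dos <- matrix(rbinom(30 * 20, 2, 0.5), 30, 20)
    snps <- data.frame(snp_id = sprintf("L%02d_p00", 1:20),
                       locus_id = sprintf("L%02d", 1:20), position = 0L,
                       allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
    calls <- radpanels:::dosage_to_calls(dos, snps)
    rownames(calls) <- sprintf("s%02d", 1:30)
    gm <- genotype_matrix(calls, stats::setNames(rep("pop1", 30),
                                                 rownames(calls)), snps)
    ci <- bootstrap_fis_ci(gm, "pop1", n_boot = 200, seed = i)
    ci["lower"] <= 0 && 0 <= ci["upper"]
  }, logical(1)))
  expect_gte(mean(hits), 0.8)   # 95% nominal, generous band at 40 reps
})

test_that("Weir-Cockerham theta matches a hand-coded component oracle", {
  pops <- rep(c("pop1", "pop2"), each = 8)
  s1 <- c(pop_calls(3, 4, 1), pop_calls(1, 3, 4))
  s2 <- c(pop_calls(5, 2, 1), pop_calls(4, 3, 1))
  calls <- cbind(s1, s2)
  rownames(calls) <- sprintf("s%02d", 1:16)
  snps <- data.frame(snp_id = c("L1_p00", "L2_p00"),
                     locus_id = c("L1", "L2"), position = 0L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, stats::setNames(pops, rownames(calls)), snps)
  res <- global_fst_wc(gm)
  d <- radpanels:::dosage_matrix(gm)
  comp <- lapply(1:2, function(j) {
    oracle_wc_locus(list(d[pops == "pop1", j], d[pops == "pop2", j]))
  })
  expect_equal(res$per_locus$a, vapply(comp, `[[`, numeric(1), "a"))
  expect_equal(res$per_locus$b, vapply(comp, `[[`, numeric(1), "b"))
  expect_equal(res$per_locus$c, vapply(comp, `[[`, numeric(1), "c"))
  num <- sum(vapply(comp, `[[`, numeric(1), "a"))
  den <- sum(vapply(comp, function(x) sum(x), numeric(1)))
  expect_equal(res$theta, num / den)
})

test_that("theta degenerate cases: identical pops near zero, fixed diff = 1", {
  pops <- rep(c("pop1", "pop2"), each = 10)
  prof <- pop_calls(3, 5, 2)
  gm <- one_pop_gm(list(c(prof, prof)))
  gm$popmap[] <- pops
  expect_lte(global_fst_wc(gm)$theta, 0.001)
  gm2 <- one_pop_gm(list(c(rep("A/A", 10), rep("G/G", 10))))
  gm2$popmap[] <- pops
  expect_equal(global_fst_wc(gm2)$theta, 1)
  expect_error(global_fst_wc(one_pop_gm(list(prof))), "2 populations")
})

test_that("allelic richness has its closed form and bounds", {
  gm <- one_pop_gm(list(c(rep("A/A", 5), rep("G/G", 5)),   # p = 0.5, 2n = 20
                        rep("A/A", 10)))                   # monomorphic
  ar2 <- allelic_richness(gm, "pop1", g = 2)
  expect_equal(ar2[1], 2 - 2 * choose(10, 2) / choose(20, 2))
  expect_equal(ar2[2], 1)
  ar10 <- allelic_richness(gm, "pop1", g = 10)
  expect_true(all(ar10 >= 1 & ar10 <= 2))
  expect_error(allelic_richness(gm, "pop1", g = 30), "exceeds")
})

test_that("HWE exact test: degenerate and enumerated cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 2, 0), oracle_hwe_enum(0, 2, 0))
  expect_error(hwe_exact_test(0, 0, 0), "no genotyped")
  # symmetric in allele labelling
  expect_equal(hwe_exact_test(6, 3, 1), hwe_exact_test(1, 3, 6))
})

test_that("panel summary assembles the metric suite consistently", {
  pops <- rep(c("pop1", "pop2"), each = 10)
  s1 <- c(pop_calls(3, 5, 2), pop_calls(2, 5, 3))
  s2 <- c(pop_calls(4, 4, 2, alleles = c("C", "T")),
          pop_calls(2, 6, 2, alleles = c("C", "T")))
  calls <- cbind(s1, s2)
  rownames(calls) <- sprintf("s%02d", 1:20)
  snps <- data.frame(snp_id = c("L1_p00", "L2_p05"),
                     locus_id = c("L1", "L2"), position = c(0L, 5L),
                     allele1 = NA, allele2 = NA, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, stats::setNames(pops, rownames(calls)), snps)
  m <- summarize_panel(gm, n_boot = 50, seed = 3)
  oe1 <- obs_exp_het(update_observed_alleles(gm), "pop1")
  expect_equal(m$per_pop$Ho[1], mean(oe1$Ho))
  expect_equal(m$per_pop$He[1], mean(oe1$He))
  expect_equal(m$global_fst, global_fst_wc(update_observed_alleles(gm))$theta)
  expect_equal(m$Ho, mean(m$per_pop$Ho))
  expect_true(all(m$per_pop$AR >= 1 & m$per_pop$AR <= 2))
})
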