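test_that("BIAL removes >2-allele sites and keeps the rest", {
  pops <- rep(c("pop1", "pop2"), each = 5)
  tri <- c(rep("A/A", 4), rep("C/C", 3), rep("T/T", 3))
  bi <- c(pop_calls(2, 2, 1), pop_calls(2, 2, 1))
  gm <- mk_gm(c(rep(list(bi), 8), list(tri), list(tri)), pops,
              locus_ids = sprintf("L%02d", 1:10), positions = rep(0L, 10))
  res <- filter_biallelic(gm)
  expect_equal(res$audit$snps_before, 10L)
  expect_equal(res$audit$snps_after, 8L)
  # all-biallelic panel unchanged
  gm2 <- mk_gm(rep(list(bi), 4), pops)
  expect_equal(n_snps <- ncol(filter_biallelic(gm2)$gm$calls), 4L)
})

test_that("minimum-coverage filter blanks sub-threshold calls only", {
  pops <- rep("pop1", 4)
  gm <- mk_gm(list(a = c("A/A", "A/G", "G/G", "A/A"),
                   b = c("C/C", "C/T", "T/T", "C/C")),
              pops, locus_ids = c("L1", "L2"), positions = c(0L, 1L))
  dm <- mk_dm(gm, depth = 10L,
              overrides = list(list(sample = "s01", snp = "L1_p00", depth = 7L),
                               list(sample = "s02", snp = "L1_p00", depth = 8L)))
  res <- apply_min_coverage(gm, dm, threshold = 8)
  expect_true(is.na(res$gm$calls["s01", "L1_p00"]))   # depth 7 -> missing
  expect_equal(res$gm$calls["s02", "L1_p00"], "A/G")  # depth 8 retained
  expect_equal(res$audit$snps_after, 2L)              # SNP set unchanged
  # all depths >= 8 -> unchanged
  res2 <- apply_min_coverage(gm, mk_dm(gm, depth = 8L))
  expect_identical(res2$gm$calls, gm$calls)
  # known depth histogram -> missing fraction matches hand count (1 cell of 8)
  expect_equal(res$audit$missing_fraction_after, 1 / 8)
  # non-missing call without depth data errors
  dm_bad <- mk_dm(gm)
  dimnames(dm_bad$counts)[[2]][1] <- "other"
  expect_error(apply_min_coverage(gm, dm_bad), "depth")
})

test_that("max-SNPs-per-locus drops whole loci above the cap", {
  pops <- rep("pop1", 4)
  cv <- c("A/A", "A/G", "G/G", "A/A")
  k <- c(1, 2, 3, 4, 5)
  locus_ids <- unlist(mapply(function(l, n) rep(sprintf("L%d", l), n),
                             seq_along(k), k))
  positions <- unlist(lapply(k, seq_len)) - 1L
  gm <- mk_gm(rep(list(cv), sum(k)), pops, locus_ids, positions)
  res <- filter_max_snps_per_locus(gm, max_snps = 3)
  expect_equal(res$audit$snps_after, 6L)      # 1 + 2 + 3
  expect_setequal(unique(res$gm$snps$locus_id), c("L1", "L2", "L3"))
})

test_that("MAC counts minor copies over genotyped calls only", {
  pops <- rep("pop1", 10)
  mk <- function(n_het, n_minhom) {
    c(rep("A/G", n_het), rep("G/G", n_minhom),
      rep("A/A", 10 - n_het - n_minhom))
  }
  # counts 0,1,2,3,4 -> two retained (3 and 4)
  gm <- mk_gm(list(mk(0, 0), mk(1, 0), mk(2, 0), mk(1, 1), mk(0, 2)), pops)
  res <- filter_mac(gm, min_count = 3)
  expect_equal(res$audit$snps_after, 2L)
  # 1 het + 1 minor hom = 3 kept; 2 het = 2 removed
  gm2 <- mk_gm(list(keep = mk(1, 1), drop = mk(2, 0)), pops)
  expect_equal(filter_mac(gm2)$gm$snps$snp_id, gm2$snps$snp_id[1])
  # missing calls carry no copies
  with_na <- c(rep("A/G", 3), rep(NA, 7))
  gm3 <- mk_gm(list(with_na), pops)
  expect_equal(filter_mac(gm3)$audit$snps_after, 1L)
})

test_that("POP filter applies a strict per-population missing bound", {
  pops <- rep(c("pop1", "pop2"), each = 10)
  s_boundary <- c(pop_calls(4, 2, 1, 3), pop_calls(3, 2, 1, 4))  # 0.3 / 0.4
  s_clean <- c(pop_calls(4, 4, 2), pop_calls(4, 4, 2))
  gm <- mk_gm(list(b = s_boundary, c = s_clean), pops)
  res <- filter_pop_callrate(gm, max_missing = 0.40)
  expect_equal(res$gm$snps$snp_id, gm$snps$snp_id[2])   # 0.4 not < 0.4
  # mixed patterns across 3 pops match hand enumeration
  pops3 <- rep(c("pop1", "pop2", "pop3"), each = 5)
  s1 <- c(pop_calls(3, 1, 0, 1), pop_calls(4, 1, 0), pop_calls(5, 0, 0))
  s2 <- c(pop_calls(3, 0, 0, 2), pop_calls(5, 0, 0), pop_calls(5, 0, 0))
  s3 <- c(pop_calls(4, 1, 0), pop_calls(3, 1, 0, 1), pop_calls(4, 0, 0, 1))
  gm3 <- mk_gm(list(s1 = s1, s2 = s2, s3 = s3), pops3)
  res3 <- filter_pop_callrate(gm3, max_missing = 0.40)
  expect_setequal(res3$gm$snps$snp_id, gm3$snps$snp_id[c(1, 3)])  # s2: 2/5
})

test_that("HWE filter uses the strict more-than-half rule", {
  pops <- rep(c("pop1", "pop2", "pop3"), each = 10)
  dev <- pop_calls(5, 0, 5)            # exact P ~ 0.0014 (het deficit)
  ok <- pop_calls(3, 5, 2)
  gm <- mk_gm(list(two_dev = c(dev, dev, ok), one_dev = c(dev, ok, ok)), pops)
  res <- filter_hwe(gm, p_threshold = 0.01)
  expect_equal(res$gm$snps$snp_id, gm$snps$snp_id[2])   # 2 > 1.5 removed
  # with 2 pops, one significant is not > 1 -> kept
  pops2 <- rep(c("pop1", "pop2"), each = 10)
  gm2 <- mk_gm(list(one = c(dev, ok)), pops2)
  expect_equal(filter_hwe(gm2)$audit$snps_after, 1L)
  # populations with < 2 genotyped individuals are skipped
  tiny <- c(pop_calls(0, 1, 0, 9), dev, dev)
  gm3 <- mk_gm(list(tiny), pops)
  expect_equal(filter_hwe(gm3)$audit$snps_after, 0L)    # 2 sig of 3 counted
})

test_that("first-SNP selection keeps the smallest canonical position", {
  pops <- rep("pop1", 4)
  cv <- c("A/A", "A/G", "G/G", "A/A")
  gm <- mk_gm(rep(list(cv), 3), pops, locus_ids = c("L1", "L1", "L2"),
              positions = c(17L, 5L, 30L))
  res <- select_first_snp_per_locus(gm)
  expect_setequal(res$gm$snps$snp_id, c("L1_p05", "L2_p30"))
  # with a flipped-orientation tag, "first" follows the canonical coordinates
  tagF <- strrep("T", 36)            # canonical form is its revcomp
  cat <- locus_catalog(data.frame(locus_id = "L1", tag = tagF),
                       data.frame(locus_id = "L1", position = c(5L, 17L),
                                  alleles = c("A,G", "A,G")))
  gmF <- mk_gm(rep(list(cv), 2), pops, locus_ids = c("L1", "L1"),
               positions = c(5L, 17L))
  resF <- select_first_snp_per_locus(gmF, cat)
  expect_equal(resF$gm$snps$snp_id, "L1_p17")  # 36-1-17 < 36-1-5
})

test_that("the designed cascade fixture reproduces its audit exactly", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$gm, fx$dm, fx$cat)
  expect_equal(res$audit$step, fx$expected$step)
  expect_equal(res$audit$snps_before, fx$expected$snps_before)
  expect_equal(res$audit$snps_after, fx$expected$snps_after)
  expect_setequal(res$panel$snps$snp_id, fx$survivors)
  # stop_after_step = 6 leaves both LA SNPs in place
  res6 <- run_cascade(fx$gm, fx$dm, fx$cat, stop_after_step = 6)
  expect_setequal(res6$panel$snps$snp_id, c("LA_p05", "LA_p20", "LG_p11"))
})

test_that("filter order matters on the designed fixture", {
  fx <- cascade_fixture()
  # MAC before MinCov vs the canonical order: s12's depth-7 cells only go
  # missing after MinCov, so running POP before MinCov keeps s12
  canonical <- run_cascade(fx$gm, fx$dm, fx$cat)$panel$snps$snp_id
  g <- filter_biallelic(fx$gm)$gm
  g <- filter_pop_callrate(g)$gm                 # POP first: s12 survives it
  g <- apply_min_coverage(g, fx$dm)$gm
  g <- filter_max_snps_per_locus(g)$gm
  g <- filter_mac(g)$gm
  g <- filter_hwe(g)$gm
  g <- select_first_snp_per_locus(g, fx$cat)$gm
  expect_false(setequal(g$snps$snp_id, canonical))
  expect_true("LH_p02" %in% g$snps$snp_id)
})

test_that("audit SNP counts are non-increasing on simulated data", {
  r <- build_pipeline_outputs(tiny_cfg(seed = 51, n_loci = 100)$sim)
  for (pn in c("STA", "ALT")) {
    pl <- r$pipelines[[pn]]
    aud <- run_cascade(pl$genotypes, pl$depths, pl$catalog)$audit
    expect_true(all(aud$snps_after <= aud$snps_before))
    expect_true(all(diff(aud$snps_before) <= 0))
  }
})

test_that("the cascade is idempotent on its own (stable) output", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$gm, fx$dm, fx$cat)
  res2 <- run_cascade(res$panel, fx$dm, fx$cat)
  expect_identical(res2$panel$calls, res$panel$calls)
  expect_equal(res2$audit$snps_after[7], ncol(res$panel$calls))
})

test_that("raising the coverage threshold never weakens the POP filter", {
  removed_by_pop <- function(gm, dm, threshold) {
    g <- apply_min_coverage(gm, dm, threshold)$gm
    res <- filter_pop_callrate(g)
    res$audit$snps_before - res$audit$snps_after
  }
  for (s in 61:64) {
    r <- build_pipeline_outputs(tiny_cfg(seed = s, n_loci = 80)$sim)
    pl <- r$pipelines$ALT
    expect_lte(removed_by_pop(pl$genotypes, pl$depths, 5),
               removed_by_pop(pl$genotypes, pl$depths, 12))
  }
})
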