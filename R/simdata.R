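# Synthetic two-pipeline RAD dataset generator. The generator states a world:
# island-model populations (Balding-Nichols allele frequencies), biallelic SNPs
# on fixed-length tags, a shared negative-binomial read pool per (sample,
# locus), sequencing error, and pipeline-specific perturbations (locus-level
# read loss, catalogue dropout, oversplitting, orientation scrambling) that
# reproduce the mismatch structure seen when two de novo building-loci
# pipelines genotype the same individuals.

#' Simulation configuration
#'
#' Defaults describe a moderate 2b-RAD-like study: three populations of 20,
#' 500 loci of 36 bp carrying mostly one SNP each, mean locus coverage 15x
#' with strong overdispersion (negative-binomial size 2, a variance-to-mean
#' ratio of ~8 at the mean, consistent with the high missing-data fractions
#' real 2b-RAD panels show), 0.5% per-read error, and mild pipeline
#' perturbations. Pipeline A ("STA") genotypes with the likelihood-ratio
#' caller, pipeline B ("ALT") with the frequency-threshold caller; B's
#' catalogue is stored with random tag orientations to exercise the
#' canonical-orientation machinery.
#'
#' @param n_pops number of populations.
#' @param pop_sizes integer vector (length n_pops) of diploid sample sizes.
#' @param n_loci number of true RAD loci.
#' @param snps_per_locus_dist probabilities for 1..5 SNPs per locus.
#' @param L tag length (36, or 32 for CspCI-style tags).
#' @param fst_sim Balding-Nichols divergence parameter in [0, 1).
#' @param cov_mean mean of the negative-binomial read depth per (sample,
#'   locus).
#' @param cov_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param seq_error per-read per-base error rate.
#' @param triallelic_rate fraction of SNP sites receiving a systematic
#'   third-allele read contamination (exercises the BIAL filter).
#' @param pipelines named list of two per-pipeline perturbation lists with
#'   elements \code{read_loss} (probability that a (sample, locus) loses all
#'   its reads in this pipeline: locus-level recruitment/alignment failure),
#'   \code{locus_dropout} (probability a locus is absent from this pipeline's
#'   catalogue), \code{oversplit} (probability a polymorphic locus is split,
#'   stranding its minor-allele reads on a new private locus) and \code{flip}
#'   (probability a locus is stored reverse-complemented).
#' @param seed master seed; all stages draw from named substreams of it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_pops = 3,
                       pop_sizes = rep(20L, n_pops),
                       n_loci = 500,
                       snps_per_locus_dist = c(0.55, 0.25, 0.12, 0.05, 0.03),
                       L = 36,
                       fst_sim = 0.05,
                       cov_mean = 15,
                       cov_dispersion = 2,
                       seq_error = 0.005,
                       triallelic_rate = 0.01,
                       pipelines = list(
                         STA = list(read_loss = 0, locus_dropout = 0.05,
                                    oversplit = 0.02, flip = 0),
                         ALT = list(read_loss = 0.05, locus_dropout = 0.05,
                                    oversplit = 0.02, flip = 0.5)),
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), pop_sizes = as.integer(pop_sizes),
              n_loci = as.integer(n_loci),
              snps_per_locus_dist = snps_per_locus_dist / sum(snps_per_locus_dist),
              L = as.integer(L), fst_sim = fst_sim, cov_mean = cov_mean,
              cov_dispersion = cov_dispersion, seq_error = seq_error,
              triallelic_rate = triallelic_rate, pipelines = pipelines,
              seed = as.integer(seed))
  stopifnot(length(cfg$pop_sizes) == cfg$n_pops, all(cfg$pop_sizes >= 1),
            cfg$cov_mean > 0, cfg$fst_sim >= 0,
            cfg$seq_error >= 0, cfg$seq_error <= 1)
  if (cfg$fst_sim >= 1) stop("fst_sim must be < 1")
  for (p in cfg$pipelines) {
    stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Balding-Nichols per-population allele frequencies
#'
#' Ancestral frequencies are drawn Uniform(0.05, 0.95); each population's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral p, so the
#' expected Weir-Cockerham theta of the resulting populations is F. F = 0
#' degenerates to all populations sharing the ancestral frequency exactly.
#'
#' @param fst_sim divergence parameter F in [0, 1).
#' @param n_snps number of SNPs.
#' @param n_pops number of populations.
#' @param seed integer seed.
#' @return matrix n_snps x n_pops of frequencies of the alternate allele,
#'   with the ancestral frequency as attribute \code{ancestral}.
#' @export
simulate_allele_freqs <- function(fst_sim, n_snps, n_pops, seed = 1L) {
  if (fst_sim >= 1) stop("fst_sim must be < 1")
  if (fst_sim < 0) stop("fst_sim must be >= 0")
  with_substream(seed, "allele_freqs", {
    p <- stats::runif(n_snps, 0.05, 0.95)
    if (fst_sim == 0) {
      freqs <- matrix(p, n_snps, n_pops)
    } else {
      shape_scale <- (1 - fst_sim) / fst_sim
      freqs <- matrix(stats::rbeta(n_snps * n_pops,
                                   rep(p, n_pops) * shape_scale,
                                   rep(1 - p, n_pops) * shape_scale),
                      n_snps, n_pops)
    }
    colnames(freqs) <- sprintf("pop%d", seq_len(n_pops))
    attr(freqs, "ancestral") <- p
    freqs
  })
}

#' True diploid genotypes under within-population Hardy-Weinberg proportions
#'
#' @param freqs matrix n_snps x n_pops of alternate-allele frequencies.
#' @param pop_sizes diploid individuals per population.
#' @param seed integer seed.
#' @return list with \code{dosage} (samples x snps integer matrix of
#'   alternate-allele copies), \code{popmap}, and the input \code{freqs}.
#' @export
simulate_true_genotypes <- function(freqs, pop_sizes, seed = 1L) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  n_snps <- nrow(freqs); n_pops <- ncol(freqs)
  stopifnot(length(pop_sizes) == n_pops)
  with_substream(seed, "true_genotypes", {
    blocks <- lapply(seq_len(n_pops), function(k) {
      matrix(stats::rbinom(pop_sizes[k] * n_snps, 2L,
                           rep(freqs[, k], each = pop_sizes[k])),
             pop_sizes[k], n_snps)
    })
    dosage <- do.call(rbind, blocks)
    samples <- sprintf("ind%03d", seq_len(sum(pop_sizes)))
    rownames(dosage) <- samples
    popmap <- stats::setNames(rep(colnames(freqs), pop_sizes), samples)
    list(dosage = dosage, popmap = popmap, freqs = freqs)
  })
}

#' Random, well-separated truth tag catalogue
#'
#' Draws random ACGT tags and rejects any tag whose Hamming distance to an
#' accepted tag is not strictly greater than \code{min_pairwise_mismatch}, so
#' that downstream cross-catalogue clustering has unambiguous ground truth.
#'
#' @param n_loci number of tags.
#' @param L tag length.
#' @param min_pairwise_mismatch required separation (all pairwise distances
#'   must exceed it; use > 2m+1 for clustering at m mismatches).
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget.
#' @return character vector of tags named by locus_id.
#' @export
simulate_tag_catalog <- function(n_loci, L = 36, min_pairwise_mismatch = 7,
                                 seed = 1L, max_tries = 50 * n_loci) {
  with_substream(seed, "tag_catalog", {
    onehot <- function(tag) {
      ch <- strsplit(tag, "", fixed = TRUE)[[1]]
      as.numeric(outer(NUC, ch, "=="))          # 4L-vector, column per position
    }
    tags <- character(n_loci)
    hot <- matrix(0, n_loci, 4 * L)
    accepted <- 0L
    tries <- 0L
    while (accepted < n_loci) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not satisfy pairwise tag separation within retry budget")
      }
      cand <- paste(sample(NUC, L, replace = TRUE), collapse = "")
      h <- onehot(cand)
      if (accepted > 0L) {
        matches <- hot[seq_len(accepted), , drop = FALSE] %*% h
        if (max(matches) >= L - min_pairwise_mismatch) next  # distance <= min
      }
      accepted <- accepted + 1L
      tags[accepted] <- cand
      hot[accepted, ] <- h
    }
    names(tags) <- sprintf("L%04d", seq_len(n_loci))
    tags
  })
}

# Assemble the truth locus_catalog: tags plus SNP sites with allele pairs.
simulate_truth_catalog <- function(cfg) {
  tags <- simulate_tag_catalog(cfg$n_loci, cfg$L,
                               min_pairwise_mismatch = 7, seed = cfg$seed)
  with_substream(cfg$seed, "snp_sites", {
    k <- sample(seq_along(cfg$snps_per_locus_dist), cfg$n_loci,
                replace = TRUE, prob = cfg$snps_per_locus_dist)
    locus_id <- rep(names(tags), k)
    pos <- unlist(lapply(k, function(n) sort(sample.int(cfg$L, n) - 1L)))
    # uniform unordered nucleotide pair per SNP; alleles must include the tag
    # base, so allele1 is pinned to the reference base at that position
    a1 <- substr(rep(tags, k), pos + 1L, pos + 1L)
    a2 <- vapply(a1, function(a) sample(setdiff(NUC, a), 1L), character(1))
    snps <- data.frame(locus_id = locus_id, position = pos,
                       alleles = paste(pmin(a1, a2), pmax(a1, a2), sep = ","),
                       allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
    cat <- locus_catalog(data.frame(locus_id = names(tags), tag = unname(tags),
                                    stringsAsFactors = FALSE),
                         snps[c("locus_id", "position", "alleles")], "truth")
    cat$snps$allele1 <- snps$allele1
    cat$snps$allele2 <- snps$allele2
    cat
  })
}

#' Simulate per-pipeline allele depths from true genotypes
#'
#' One shared read pool per (sample, locus): total depth is negative binomial
#' (\code{cov_mean}, size \code{cov_dispersion}); every site on a locus sees
#' the same total. Reads at a site are drawn from the individual's two
#' haplotypes, and each read is mis-read with probability \code{seq_error}
#' (uniformly to the other three bases). On top of the shared pool each
#' pipeline applies its perturbations: \code{read_loss} zeroes all reads of a
#' (sample, locus) with the given probability, and \code{oversplit} strands
#' the minor-allele reads of a designated site on a new private locus. Locus
#' dropout and orientation flips act on the catalogue and are handled by
#' \code{\link{build_pipeline_outputs}}.
#'
#' @param truth result of \code{\link{simulate_true_genotypes}}.
#' @param cat truth locus_catalog.
#' @param cov_mean,cov_dispersion negative-binomial depth parameters.
#' @param seq_error per-read error rate.
#' @param pipeline_params named list of per-pipeline perturbation lists (see
#'   \code{\link{sim_config}}).
#' @param seed integer seed.
#' @param triallelic_rate systematic third-allele contamination rate.
#' @return named list of \code{depth_matrix} objects, one per pipeline, plus
#'   attribute \code{oversplit} recording the split loci per pipeline.
#' @export
simulate_depths <- function(truth, cat, cov_mean, cov_dispersion, seq_error,
                            pipeline_params, seed = 1L,
                            triallelic_rate = 0) {
  ns <- nrow(truth$dosage)
  snps <- cat$snps
  nl <- nrow(snps)
  samples <- rownames(truth$dosage)
  sid <- snp_id(snps$locus_id, snps$position)
  locus_of_snp <- match(snps$locus_id, cat$loci$locus_id)

  base <- with_substream(seed, "read_pool", {
    d_locus <- matrix(stats::rnbinom(ns * nrow(cat$loci), mu = cov_mean,
                                     size = cov_dispersion),
                      ns, nrow(cat$loci))
    depth <- d_locus[, locus_of_snp, drop = FALSE]   # sites share locus reads
    dos <- truth$dosage                              # copies of allele2
    frac2 <- matrix(c(0, 0.5, 1)[dos + 1L], ns, nl)
    n2 <- matrix(stats::rbinom(ns * nl, as.vector(depth), as.vector(frac2)),
                 ns, nl)
    n1 <- depth - n2
    counts <- array(0L, dim = c(ns, nl, 4),
                    dimnames = list(samples, sid, NUC))
    a1_ix <- matrix(match(snps$allele1, NUC), ns, nl, byrow = TRUE)
    a2_ix <- matrix(match(snps$allele2, NUC), ns, nl, byrow = TRUE)
    scatter <- function(counts, n_src, src_ix) {
      # sequencing error: each read flips to one of the other 3 bases
      err <- matrix(stats::rbinom(ns * nl, as.vector(n_src), seq_error), ns, nl)
      keep <- n_src - err
      e1 <- matrix(stats::rbinom(ns * nl, as.vector(err), 1 / 3), ns, nl)
      e2 <- matrix(stats::rbinom(ns * nl, as.vector(err - e1), 1 / 2), ns, nl)
      e3 <- err - e1 - e2
      others <- matrix(NA_integer_, 3L, ns * nl)
      for (cell_base in 1:4) {
        sel <- which(src_ix == cell_base)
        others[, sel] <- setdiff(1:4, cell_base)
      }
      add <- function(b_ix, val) {
        flat_ix <- cbind(rep(seq_len(ns), nl), rep(seq_len(nl), each = ns),
                         as.vector(b_ix))
        counts[flat_ix] <- counts[flat_ix] + as.vector(val)
        counts
      }
      counts <- add(matrix(others[1, ], ns, nl), e1)
      counts <- add(matrix(others[2, ], ns, nl), e2)
      counts <- add(matrix(others[3, ], ns, nl), e3)
      counts <- add(src_ix, keep)
      counts
    }
    counts <- scatter(counts, n1, a1_ix)
    counts <- scatter(counts, n2, a2_ix)
    if (triallelic_rate > 0) {
      tri <- which(stats::runif(nl) < triallelic_rate)
      for (j in tri) {
        third <- setdiff(NUC, c(snps$allele1[j], snps$allele2[j]))[1]
        extra <- stats::rbinom(ns, depth[, j], 0.25)
        counts[, j, third] <- counts[, j, third] + extra
      }
    }
    counts
  })

  out <- list()
  split_info <- list()
  for (pname in names(pipeline_params)) {
    pp <- pipeline_params[[pname]]
    counts <- base
    with_substream(seed, paste0("perturb_depth/", pname), {
      if (pp$read_loss > 0) {
        lost <- matrix(stats::runif(ns * nrow(cat$loci)) < pp$read_loss,
                       ns, nrow(cat$loci))
        lost_site <- lost[, locus_of_snp, drop = FALSE]
        for (b in 1:4) {
          slab <- counts[, , b]
          slab[lost_site] <- 0L
          counts[, , b] <- slab
        }
      }
      splits <- character(0)
      if (pp$oversplit > 0) {
        poly_loci <- unique(snps$locus_id)
        splits <- poly_loci[stats::runif(length(poly_loci)) < pp$oversplit]
        for (loc in splits) {
          j <- which(snps$locus_id == loc)[1]          # designated site
          tot2 <- sum(counts[, j, match(snps$allele2[j], NUC)])
          tot1 <- sum(counts[, j, match(snps$allele1[j], NUC)])
          minor <- if (tot2 <= tot1) snps$allele2[j] else snps$allele1[j]
          counts[, j, match(minor, NUC)] <- 0L
        }
      }
      split_info[[pname]] <- splits
    })
    out[[pname]] <- depth_matrix(counts, pname)
  }
  attr(out, "oversplit") <- split_info
  out
}

# Mutate a parent tag at 8 spread positions (complementing the base) to build
# the synthetic tag of an oversplit-derived private locus: far enough (Hamming
# 8) from its parent not to co-cluster at m <= 3.
.oversplit_tag <- function(tag, L) {
  pos <- round(seq(2, L - 1, length.out = 8))
  ch <- strsplit(tag, "", fixed = TRUE)[[1]]
  ch[pos] <- unname(COMP[ch[pos]])
  paste(ch, collapse = "")
}

#' Run the full two-pipeline generator
#'
#' Produces, from one configuration: the truth (catalogue + genotypes), and
#' per pipeline a perturbed catalogue, a depth matrix and a raw genotype
#' matrix. Pipeline "STA" is genotyped with \code{\link{call_genotypes_lrt}},
#' pipeline "ALT" with \code{\link{call_genotypes_freq_threshold}}; both use
#' the shared < 3x floor. Catalogue perturbations: dropout removes loci
#' (their sites disappear from that pipeline's panel and depths), oversplit
#' adds a private locus carrying the stranded reads' tag, and flip stores a
#' locus reverse-complemented (positions, alleles, depths and calls remapped
#' into that pipeline's local orientation).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{truth} (catalog, dosage, popmap, freqs, and the
#'   truth genotype_matrix) and \code{pipelines}, a named list with
#'   \code{catalog}, \code{depths}, \code{genotypes} per pipeline.
#' @export
build_pipeline_outputs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth_cat <- simulate_truth_catalog(cfg)
  freqs <- simulate_allele_freqs(cfg$fst_sim, nrow(truth_cat$snps),
                                 cfg$n_pops, seed = cfg$seed)
  truth <- simulate_true_genotypes(freqs, cfg$pop_sizes, seed = cfg$seed)
  depths <- simulate_depths(truth, truth_cat, cfg$cov_mean,
                            cfg$cov_dispersion, cfg$seq_error,
                            cfg$pipelines, seed = cfg$seed,
                            triallelic_rate = cfg$triallelic_rate)
  splits <- attr(depths, "oversplit")

  truth_calls <- dosage_to_calls(truth$dosage, truth_cat$snps)
  truth_gm <- genotype_matrix(truth_calls, truth$popmap,
                              data.frame(snp_id = snp_id(truth_cat$snps$locus_id,
                                                         truth_cat$snps$position),
                                         locus_id = truth_cat$snps$locus_id,
                                         position = truth_cat$snps$position,
                                         allele1 = truth_cat$snps$allele1,
                                         allele2 = truth_cat$snps$allele2,
                                         stringsAsFactors = FALSE),
                              "truth")

  pipes <- list()
  for (pname in names(cfg$pipelines)) {
    pp <- cfg$pipelines[[pname]]
    loci <- truth_cat$loci
    snps <- truth_cat$snps
    dm <- depths[[pname]]

    with_substream(cfg$seed, paste0("catalog/", pname), {
      keep <- stats::runif(nrow(loci)) >= pp$locus_dropout
      flip <- stats::runif(nrow(loci)) < pp$flip
      keep_loci <- loci$locus_id[keep]
      flip_map <- stats::setNames(flip, loci$locus_id)

      loci2 <- loci[keep, , drop = FALSE]
      snps2 <- snps[snps$locus_id %in% keep_loci, , drop = FALSE]
      dm2 <- subset_depth(dm, snps$locus_id %in% keep_loci)

      # orientation flips: tag revcomped, positions mirrored, alleles and
      # depth base columns complemented
      fl <- flip_map[loci2$locus_id]
      loci2$tag[fl] <- revcomp(loci2$tag[fl])
      sfl <- flip_map[snps2$locus_id]
      snps2$position[sfl] <- cfg$L - 1L - snps2$position[sfl]
      comp_or_keep <- function(x, f) ifelse(f, unname(COMP[x]), x)
      a1 <- comp_or_keep(snps2$allele1, sfl)
      a2 <- comp_or_keep(snps2$allele2, sfl)
      snps2$allele1 <- a1
      snps2$allele2 <- a2
      snps2$alleles <- paste(pmin(a1, a2), pmax(a1, a2), sep = ",")
      dm2$counts[, sfl, ] <- dm2$counts[, sfl, c(4, 3, 2, 1)]

      # oversplit-derived private loci join the catalogue (no SNP sites: the
      # stranded reads stack into an apparently monomorphic private tag)
      sp <- intersect(splits[[pname]], keep_loci)
      if (length(sp)) {
        parent <- loci2$tag[match(sp, loci2$locus_id)]
        loci2 <- rbind(loci2,
                       data.frame(locus_id = paste0(sp, "s"),
                                  tag = vapply(parent, .oversplit_tag,
                                               character(1), L = cfg$L),
                                  stringsAsFactors = FALSE))
      }
      ord <- order(loci2$locus_id)
      loci2 <- loci2[ord, , drop = FALSE]

      # re-key depth columns and snp ids in pipeline-local coordinates
      sid2 <- snp_id(snps2$locus_id, snps2$position)
      dimnames(dm2$counts)[[2]] <- sid2
      dm2$pipeline <- pname

      cat2 <- locus_catalog(loci2,
                            data.frame(locus_id = snps2$locus_id,
                                       position = snps2$position,
                                       alleles = snps2$alleles,
                                       stringsAsFactors = FALSE),
                            pname)
      calls <- if (pname == "STA") {
        call_genotypes_lrt(dm2, seq_error = cfg$seq_error)
      } else {
        call_genotypes_freq_threshold(dm2)
      }
      gm <- genotype_matrix(calls, truth$popmap,
                            data.frame(snp_id = sid2,
                                       locus_id = snps2$locus_id,
                                       position = snps2$position,
                                       allele1 = snps2$allele1,
                                       allele2 = snps2$allele2,
                                       stringsAsFactors = FALSE),
                            pname)
      pipes[[pname]] <- list(catalog = cat2, depths = dm2, genotypes = gm)
    })
  }
  list(truth = c(truth, list(catalog = truth_cat, genotypes = truth_gm)),
       pipelines = pipes)
}

# Expand a dosage matrix into sorted diploid call strings.
dosage_to_calls <- function(dosage, snps) {
  ns <- nrow(dosage); nl <- ncol(dosage)
  a1 <- matrix(snps$allele1, ns, nl, byrow = TRUE)
  a2 <- matrix(snps$allele2, ns, nl, byrow = TRUE)
  first <- ifelse(dosage == 2L, a2, a1)
  second <- ifelse(dosage >= 1L, a2, a1)
  calls <- geno_string(first, second)
  dim(calls) <- c(ns, nl)
  rownames(calls) <- rownames(dosage)
  colnames(calls) <- snp_id(snps$locus_id, snps$position)
  calls
}
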