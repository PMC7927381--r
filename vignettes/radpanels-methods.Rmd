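---
title: "radpanels: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radpanels: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpanels)
```

## The question the package addresses

De novo RAD-seq studies must pick a building-loci pipeline, and different
pipelines produce different locus catalogues, different genotype callers and
therefore different SNP panels from the same reads. `radpanels` provides the
machinery to ask, quantitatively, whether that choice matters for the
population-genomic conclusions: it builds the two pipelines' panels (STA and
ALT), their intersection (COM) and union (MER), classifies every genotype
disagreement between them, traces each missing-data disagreement to its
mechanism, and computes the standard metric suite on all four panels.

Because real comparisons require external binaries and large read archives,
the package ships a generator that states a synthetic world in which every
stage is testable end to end.

## The synthetic world

**Population model.** Allele frequencies follow the Balding-Nichols island
model: an ancestral frequency $p \sim U(0.05, 0.95)$ per SNP, and each
population draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, so the
expected Weir-Cockerham $\theta$ across populations is the divergence
parameter `fst_sim` (at $F=0$ all populations share $p$ exactly). Diploid
genotypes are drawn under Hardy-Weinberg proportions within populations.
There is no linkage between loci and no coalescent genealogy: the generator
targets the marginal site-frequency behaviour that the downstream statistics
consume, not haplotype structure.

**Loci and reads.** True RAD tags are uniform-length (36 bp by default, 32
supported) random sequences kept pairwise well separated (Hamming distance
&gt; 7 by rejection sampling) so that cross-catalogue clustering has
unambiguous ground truth. Read depth per (sample, locus) is negative
binomial with mean `cov_mean` (default 15, matching typical 2b-RAD median
coverages of 10-20x) and size `cov_dispersion` (default 2, a variance-to-mean
ratio near 8 at the default mean). The strong overdispersion is deliberate:
it is what produces the realistic 20-40% missing-genotype fractions after a
coverage filter that real short-tag RAD panels show. All SNP sites on a
locus share the locus's reads; at each site a read samples one of the two
haplotypes uniformly, then mis-reads to one of the other three bases with
probability `seq_error` (default 0.005).

**One read pool, two pipelines.** Both pipelines observe the *same* base
read pool per (sample, locus); each then applies its own perturbations:

* `read_loss` (rho): with this probability a (sample, locus) loses **all**
  its reads in that pipeline. This models locus-level recruitment or
  alignment failure -- the all-or-nothing character is essential, because a
  uniform per-read thinning of a shared pool can essentially never produce
  the signature cross-pipeline cell "confidently genotyped by one pipeline,
  below the 3x calling floor in the other", which is the dominant
  missing-data mechanism the comparison is designed to expose.
* `locus_dropout` (delta): the locus is absent from that pipeline's
  catalogue entirely.
* `oversplit` (sigma): the locus is split; the minor-allele reads of its
  first SNP site are stranded on a new private tag in that pipeline's
  catalogue, biasing the original site toward homozygous calls -- the
  classic oversplitting artefact and a mechanical source of
  heterozygote-deficit HWE failures.
* `flip`: the locus is stored reverse-complemented (the ALT default is 0.5),
  exercising the orientation machinery that real independently built
  catalogues require.

A consequence worth knowing: with a shared read pool and symmetric coverage,
the missing-data source "genotyped but removed by the 8x filter in one
pipeline only" can arise only through asymmetric depth perturbations such as
oversplitting, so in the default world it is rare. Real datasets in which
that source dominates (it happens) correspond to pipelines with
systematically different effective coverage, which this generator does not
emulate.

**Two callers.** Pipeline STA genotypes with a two-hypothesis multinomial
likelihood-ratio caller: log-likelihoods of HOM(major) and HET(major, minor)
under the error model, calling the better model only when
$2|\Delta \ln L| > \chi^2_{1,1-\alpha}$ (default $\alpha = 0.05$),
otherwise missing. This is an explicit *emulation* of chi-square-style SNP
models in stack-based pipelines, not a reimplementation of any particular
one. Pipeline ALT uses the nucleotide-frequency rule: with $f$ the minor
base's read fraction, $f < 0.1$ is homozygous, $f > 0.2$ heterozygous, and
$0.1 \le f \le 0.2$ -- a deliberately closed interval, the literal reading
of "lower than"/"higher than" -- is left uncalled. Both callers share the
&lt; 3x depth floor (depth exactly 3 is callable). Ties between equal base
counts are broken in fixed A&lt;C&lt;G&lt;T order everywhere, so calls are
deterministic.

The callers disagree by construction in the closed uncertain band: a true
heterozygote whose minor-read fraction lands in $[0.1, 0.2]$ is HET under
the likelihood caller and missing (or, below 0.1 at depth $\ge$ 11,
homozygous) under the frequency caller *on identical reads*. At depth 30 the
band is hit with probability $\sim 10^{-3}$ per heterozygous cell, more
under overdispersion. This means a zero-perturbation, zero-error run does
**not** produce literally identical panels at any non-trivial scale --
discordances of order 0.1-0.3% of genotypes remain, all of them
heterozygote/missing or heterozygote/homozygote cells. The acceptance suite
states the idealised expectation and records this measured residual rather
than papering over it.

## The filtering cascade

Seven steps, fixed order, each auditable:

1. **BIAL** -- sites with more than two observed alleles are removed.
   Monomorphic sites pass (they fall to MAC); only the >2-allele condition
   excludes.
2. **Min coverage (8x)** -- calls with site depth below 8 become missing.
   The SNP set is unchanged; only missingness grows.
3. **<= 3 SNPs per locus** -- loci carrying more than three SNPs are dropped
   whole. SNPs are counted on the *current* (post-BIAL) set by default;
   sites already removed as triallelic should not disqualify a locus. A
   raw-count mode is provided for users who prefer catalogue counts.
4. **MAC (3)** -- the minor allele must be observed at least three times
   across the whole sample; copies are counted only over genotyped calls
   (heterozygote = 1, minor homozygote = 2).
5. **POP (< 40%)** -- the missing fraction must be *strictly* below 0.40 in
   every population; equality drops the SNP (literal reading of "less
   than").
6. **HW (P < 0.01 in more than half the populations)** -- biallelic exact
   test per population; a SNP is removed when the count of populations with
   $P < 0.01$ strictly exceeds $n_\mathrm{pops}/2$. Populations with fewer
   than two genotyped individuals are skipped -- the test is undefined
   there, and counting them as conforming would bias retention. The
   denominator stays the total number of populations.
7. **First SNP per locus** -- "first" is defined as the smallest position in
   *canonical tag orientation* (see below), a deterministic,
   pipeline-agnostic convention; catalogue order would be pipeline-dependent.

Step order matters (the coverage filter feeds the MAC and POP filters
through missingness), which is why the audit trail records before/after SNP
and locus counts and missingness at every step, and why panel reconciliation
consumes the *step-6* checkpoint: the surviving first SNP of a shared locus
can differ between pipelines after step 7.

## Catalogue reconciliation

Tags are put into canonical orientation -- the lexicographic minimum of the
tag and its reverse complement, with SNP positions remapped $p \mapsto
L-1-p$ and alleles complemented when flipped. Any deterministic convention
would do; this one is order-independent and cheap. Pooled tags are then
clustered greedily in a deterministic order (canonical tag, pipeline,
locus id): a tag joins the best-matching existing representative (minimum
mismatches, ties to the earliest) when within `m` mismatches (2 for
fish-like, 3 for bivalve-like panels), else founds a cluster. For
equal-length ungapped tags this reproduces cd-hit-est configured with
identity $(L-m)/L$, best-match assignment and band width 1 (no indels),
without the binary dependency. Greedy order sensitivity only arises for
loci closer than $2m+1$; the generator's separation guarantee makes the
clustering provably order-independent on simulated data, and the suite
asserts it under input shuffling.

Within a shared cluster, two SNPs match iff their canonical positions and
unordered (canonically complemented) allele pairs are equal -- position
alone would conflate different mutations at homoplastic sites. COM is the
matched set with one SNP per cluster retained; it is carried twice, once
under each pipeline's calls, because the concordance analysis needs both.
MER adds the private-locus SNPs of each pipeline (native calls, one SNP per
locus). Where a single genotype set is needed for COM/MER metrics, the
first-named pipeline's calls are used; the choice is logged in every output
and irrelevant to label-free statistics when panels agree.

## Concordance and missing-data attribution

Every (sample, matched SNP) cell is classified into concordant-hom,
concordant-het, both-missing, or one of seven mismatch categories (Hom/Hom
with different alleles, Hom/MD, MD/Hom, Het/MD, MD/Het, Hom/Het, Het/Hom).
"X -> Y" means X in the first-named panel. Frequencies are relative to
total genotypes (samples x SNPs). The concordant and both-missing cells are
tabulated too, so counts provably sum to the total.

Cells where exactly one panel is missing are attributed by that panel's
depth: (i) below the 3x calling floor or locus absent -- never genotyped;
(ii) depth in [3, 8) -- genotyped but removed by the coverage filter;
(iii) depth >= 8 -- called-but-uncertain (ambiguous minor-allele
frequency). Under the default world with asymmetric `read_loss`, source (i)
dominates, with (iii) a minority and (ii) rare (see above).

## Population-genomic statistics

All computed from first principles on dosage matrices:

* $H_o$ = heterozygote fraction among genotyped individuals;
  $H_e = \frac{2n}{2n-1}\,2p(1-p)$ (unbiased, small-sample corrected).
* $F_{IS} = 1 - \sum_l H_{o,l} / \sum_l H_{e,l}$, a ratio of sums over loci
  -- stable for small panels, where a mean of per-locus ratios explodes at
  nearly monomorphic loci. 95% CIs by percentile bootstrap over loci
  (default 1000 iterations, seeded).
* Global $F_{ST}$: Weir-Cockerham variance components $a, b, c$ per locus,
  combined as $\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)$. Negative
  estimates are reported as computed, loci without at least two populations
  of genotyped individuals (or with zero total variance) are skipped.
* Allelic richness by El Mousadik-Petit rarefaction,
  $AR = \sum_a \left(1 - \binom{2n-N_a}{g}/\binom{2n}{g}\right)$; the
  default rarefaction size is twice the smallest per-(locus, population)
  genotyped count, floored at 2 gene copies.
* HWE: the biallelic conditional exact test; the P-value sums the
  probabilities of all heterozygote counts no more probable than the
  observed one, conditional on allele counts.

## Determinism and numerics

All randomness flows from one master seed through named substreams per
stage, so changing one stage's draw count cannot silently shift another's,
and a full run is byte-reproducible (asserted in the suite). The exact-test
uses log-gamma arithmetic with a $10^{-12}$ tie tolerance; the LRT caller
floors its error rate at $10^{-4}$ so the homozygous hypothesis keeps a
finite likelihood in the presence of stray reads. GENEPOP output uses the
4-digit dialect (A=01..T=04, "0000" missing); 6-digit files are accepted on
read. Population labels are not part of the GENEPOP format; the reader
assigns `pop1..popK` in block order, which round-trips the package's own
output exactly.

## What a green test does and does not establish

The generator reproduces: island-model divergence recoverable by
$\hat\theta$, overdispersed coverage and its missing-data consequences, the
dominance of genotyped-vs-missing mismatches between pipelines with
negligible opposite-homozygote cells, and catalogue artefacts (dropout,
oversplitting, orientation scrambling). It does not simulate read
sequences, linkage, paralogy beyond the oversplit caricature, null alleles,
or pipeline-specific coverage biases -- so green tests certify the
statistical machinery and the stated mechanisms, not the behaviour of any
particular real pipeline on any particular genome.

## A short tour

```{r example, eval = FALSE}
cfg <- load_run_config(NULL, overrides = list(n_loci = 300, seed = 42))
res <- run_full(cfg, out_dir = "radpanels_out")
res$audits$STA          # per-step filter audit
res$concordance         # Table of genotype (dis)agreements on COM
res$missing_sources     # mechanism behind each missing-data mismatch
res$metrics$COM         # Ho, He, FIS (CI), AR, global FST
```
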