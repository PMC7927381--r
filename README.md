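# radpanels

Does the choice of de novo RAD-seq building-loci pipeline change the
population-genomic story? `radpanels` is an R package for answering that
question quantitatively. Two pipelines applied to the same individuals
produce different locus catalogues and different genotype callers, hence
different SNP panels. The package builds and compares four panels — the two
pipelines' own (**STA**, **ALT**), their shared SNPs (**COM**) and the
shared-plus-private union (**MER**) — and reports whether genetic diversity
and differentiation survive the pipeline swap.

It is aimed at population geneticists working on non-model organisms
without reference genomes (2b-RAD and similar short uniform tags, 32–36 bp),
and at anyone who wants the comparison machinery itself: the filtering
cascade, catalogue reconciliation, concordance typology and metric suite are
all usable on their own data (GENEPOP + FASTA + depth TSVs).

## What is inside

* **Synthetic-data generator** — Balding–Nichols structured populations
  (`fst_sim` = expected Weir–Cockerham θ), negative-binomial read depths
  shared between pipelines, sequencing error, and pipeline perturbations:
  locus-level read loss, catalogue dropout, oversplitting, orientation
  scrambling. Two emulated callers: a χ²-style multinomial likelihood-ratio
  caller (STA) and a minor-frequency-threshold caller (ALT; f < 0.1 hom,
  f > 0.2 het, closed band [0.1, 0.2] uncertain, < 3× never called).
* **Seven-step filtering cascade** with a full audit trail, in fixed order:
  biallelic → min coverage 8× → ≤ 3 SNPs/locus → MAC ≥ 3 → < 40 % missing
  per population → HWE exact test (P < 0.01 in more than half the
  populations) → first SNP per locus.
* **Catalogue reconciliation** — canonical tag orientation (lexicographic
  min of tag and reverse complement) and greedy best-match Hamming
  clustering at m ∈ {2, 3} mismatches (cd-hit-est `-c (L−m)/L -g 1 -b 1`
  semantics re-implemented for equal-length ungapped tags); COM/MER
  construction from step-6 checkpoints.
* **Concordance** — the full genotype-difference typology (Hom→Hom with
  different alleles, Hom→MD, MD→Hom, Het→MD, MD→Het, Hom→Het, Het→Hom, plus
  concordant and both-missing cells so counts conserve), and attribution of
  every missing-data mismatch to (i) below the 3× calling floor,
  (ii) removed by the 8× filter, or (iii) called-but-uncertain.
* **Population genomics from first principles** — Ho, unbiased He, FIS as a
  ratio of sums with percentile-bootstrap 95 % CIs (1000 iterations),
  global Weir–Cockerham θ (ratio of component sums across loci),
  El Mousadik–Petit rarefied allelic richness, and the biallelic
  Hardy–Weinberg conditional exact test:

  θ = Σₗ aₗ / Σₗ (aₗ + bₗ + cₗ),  He = 2n/(2n−1) · 2p(1−p),
  AR = Σₐ (1 − C(2n−Nₐ, g)/C(2n, g)).

## Worked example

```r
library(radpanels)
cfg <- load_run_config(NULL, overrides = list(n_loci = 300, seed = 42,
                                              n_boot = 500))
res <- run_full(cfg, out_dir = "radpanels_out", quiet = TRUE)
res$audits$STA
#> Filter cascade audit:
#>      step snps_before snps_after loci_before loci_after missing_fraction_after
#>      BIAL         485        437         277        266             0.08531655
#>    MinCov         437        437         266        266             0.30369947
#>    MaxSNP         437        376         266        251             0.30469858
#>       MAC         376        363         251        244             0.30266299
#>       POP         363        147         244        108             0.25578231
#>       HWE         147        147         108        108             0.25578231
#>  FirstSNP         147        108         108        108             0.25864198
```

Of 485 raw STA SNPs, 108 survive; the big cut is the per-population
call-rate filter, driven by the ~30 % missingness that the 8× coverage
filter creates under overdispersed depth — the characteristic shape of
short-tag RAD filtering.

```r
res$concordance
#> Concordance COM/STA vs COM/ALT: 4200 genotypes (60 samples x 70 SNPs)
#>  category count frequency
#>   ConcHom  2051  0.488333
#>   ConcHet   987  0.235000
#>    BothMD  1025  0.244048
#>    HomHom     0  0.000000
#>     HomMD    90  0.021429
#>     MDHom    10  0.002381
#>     HetMD    37  0.008810
#>     ...
res$missing_sources
#> Missing-genotype mismatch sources (floor 3x, filter 8x):
#>      direction          source count
#>  MD_in_COM/ALT     below_floor   120
#>  MD_in_COM/ALT  uncertain_call     7
#>  MD_in_COM/STA  uncertain_call    10   (zero rows omitted)
```

On the 70 shared (COM) SNPs, every disagreement is genotyped-vs-missing or
caller-borderline; opposite homozygotes are absent. The dominant mechanism
(120/167) is "called by STA, below the 3× floor in ALT" — read loss in one
pipeline, not miscalling.

```r
res$metrics$STA
#> Ho = 0.335  He = 0.327  FIS = -0.027  AR = 1.937  global FST = 0.060 (g = 26)
res$metrics$COM
#> Ho = 0.324  He = 0.319  FIS = -0.015  AR = 1.923  global FST = 0.076 (g = 26)
```

Diversity and differentiation barely move between panels — the
panel-robustness conclusion the comparison is designed to probe.

## Command line

```sh
Rscript inst/cli/radpanels.R full-run --config my.yaml --seed 42 --out out/
# also: simulate | filter | reconcile | compare | popgen
```

Configs are YAML (`n_loci`, `fst_sim`, `cov_mean`, `pipelines`, filter
thresholds, `cluster_mismatch`, …); every threshold and seed used at run
time is recorded in `out/manifest.json`. Exit codes: 0 ok, 1 validation
failure, 2 runtime error.

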