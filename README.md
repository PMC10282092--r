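# paleoimpute

Simulation-driven evaluation of genotype imputation for low-coverage
(ancient) genomes.

Ancient DNA is fragmented, damaged by postmortem C-to-T deamination, and
usually sequenced far too shallowly for confident diploid genotype
calling. Imputation against a phased reference panel can recover diploid
genotypes from coverages as low as a fraction of 1x — but before imputed
ancient genomes are used for population-genetic inference, the error
structure of that imputation has to be quantified: how accuracy depends
on depth of coverage, on minor allele frequency, on the ancestry's
representation in the panel, on post-imputation filtering, and whether
imputation biases downstream analyses. `paleoimpute` packages that whole
evaluation as tested, reproducible R code for methodologists and aDNA
analysts who want to study imputation behaviour under controlled
conditions.

## What it does

* **Synthetic study data** — phased multi-population haplotype panels
  with a Balding–Nichols-diverged, underrepresented population;
  held-out diploid targets and Mendel-consistent trios; Poisson-depth
  site read counts with elevated transition-site error mimicking
  deamination; binomial downsampling to a 0.1–2.0x coverage grid.
* **Genotype likelihoods and validation calls** — binomial
  genotype-likelihood model; high-coverage validation genotypes filtered
  by the depth window `[max(DoC/3, 8), 2·DoC]` and `QUAL ≥ 30`.
* **Imputation** — an exact diploid Li–Stephens haplotype-copying HMM
  (Rcpp): hidden state = ordered pair of panel haplotypes, per-interval
  switch mass `λ = 1 − exp(−4·Ne·d/K)` for map distance `d` (Morgans),
  miscopy probability `μ`; forward–backward genotype probabilities `GP`,
  dosage `DS = GP₁ + 2·GP₂`, and Viterbi-phased haplotypes.
* **Accuracy statistics** — MAF-binned dosage `r²`; per-class genotype
  discordance; non-reference discordance
  `NRD = (e_RR+e_RA+e_AA)/(m_RA+m_AA+e_RR+e_RA+e_AA)`; GP filtering
  (0.70–0.99) with heterozygote-retention accounting; the ≥8-read /
  posterior ≥0.9999 validation mask; capture-style site-subset reports.
* **Trio QC** — Mendel error rate (excluding sites where all three truth
  genotypes are homozygous reference) and switch error rate against
  trio-derived haplotypes.
* **Downstream comparisons** — pairwise allelic distances; PCA with
  least-squares projection of targets and t-tests of
  imputed-vs-validation coordinate shifts; ROH detection with PLINK
  `--homozyg` window semantics and the 1.6 Mb long/short split; Spearman
  permutation tests.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` figures; `run_pipeline()` chains every stage
deterministically from one master seed.

## A worked example

```r
library(paleoimpute)
res <- run_pipeline(pipeline_config(seed = 1))
res$concordance
#> # A tibble: 6 × 7
#>   depth n_eval    nrd r2_pooled  err_rr err_ra   err_aa
#>   <dbl>  <int>  <dbl>     <dbl>   <dbl>  <dbl>    <dbl>
#> 1  0.1    3526 0.0574     0.969 0       0.708  0.00178
#> 2  0.25   3526 0.0422     0.977 0.00344 0.551  0.000843
#> 3  0.5    3526 0.0413     0.973 0.00683 0.125  0.0103
#> 4  0.75   3526 0.0341     0.977 0.00372 0.0977 0.00863
#> 5  1      3526 0.0348     0.976 0.00664 0.0851 0.00999
#> 6  2      3526 0.0195     0.986 0.00290 0.0503 0.00487
res$trio
#> # A tibble: 6 × 5
#>   depth mendel_rate mendel_n switch_rate switch_pairs
#>   <dbl>       <dbl>    <int>       <dbl>        <int>
#> 1  0.1       0.0411     2725      0.113           354
#> 2  0.25      0.0661     2725      0.0230          478
#> 3  0.5       0.0415     2725      0.0188          531
#> 4  0.75      0.0356     2725      0.0193          571
#> 5  1         0.0220     2725      0.0221          543
#> 6  2         0.0220     2725      0.0342          584
```

Reading the output: over the default study conditions (a 200-haplotype
panel, 5,000 candidate sites on 10 Mb, one held-out target and one trio),
non-reference discordance of the GP-filtered target falls from 5.7% at
0.1x to 2.0% at 2x while pooled dosage `r²` rises to 0.986; heterozygous
sites are by far the hardest class (70.8% error at 0.1x, 5.0% at 2x).
The trio, imputed independently at every depth, shows Mendel error
dropping from 4.1% to 2.2% and phasing switch error from 11.3% at 0.1x
to ~2% at 0.5–1x. `glance(res)` condenses the run to one row;
`autoplot(res)` and `plot_gp_tradeoff(res)` draw the coverage curves and
the GP-filter trade-off (stricter thresholds cut discordance but cost
heterozygotes, far more severely at 0.1x than at 1x).

Individual stages are ordinary functions on tibbles, e.g.:

```r
panel  <- simulate_panel(seed = 1)
target <- sample_diploid(panel, "main", seed = 2)          # held out
reads  <- simulate_reads(target$genome, panel, mean_depth = 30, seed = 3)
gl1x   <- genotype_likelihoods(downsample_reads(reads, 1, seed = 4))
imp    <- impute_genotypes(gl1x, target$panel, phase = TRUE)
val    <- call_validation(genotype_likelihoods(reads), mean_doc = 30)
glance(concordance_report(gp_filter(imp, 0.8), val, panel$maf))
```

A thin command-line wrapper for whole runs lives at
`inst/scripts/paleoimpute-pipeline.R` (`--config config.yaml --seed N
--out run_dir`).

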