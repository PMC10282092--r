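---
title: "Evaluating low-coverage ancient-genome imputation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating low-coverage ancient-genome imputation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoimpute)
```

## The problem

Most ancient genomes are sequenced to well below the depth needed for
confident diploid genotype calling, and postmortem deamination (C-to-T
damage at fragment ends) adds systematic errors at transition sites.
Genotype imputation against a phased reference panel can recover diploid
calls from such data, but its error structure — across coverages,
ancestries, allele frequencies, and downstream analyses — has to be
measured before the imputed genotypes can be trusted.

`paleoimpute` provides that measurement apparatus as a self-contained,
simulation-driven pipeline: it generates phased panels and target genomes
with aDNA-like read data, imputes them with a diploid haplotype-copying
hidden Markov model, and computes the standard accuracy statistics
(MAF-stratified dosage $r^2$, per-class discordance, non-reference
discordance, trio-based Mendel and switch-error rates) together with
downstream comparisons (PCA projection shifts, runs of homozygosity,
pairwise allelic distances).

## The copying model

Imputation uses the Li–Stephens haplotype-copying model in its diploid
form. The hidden state at site $l$ is an ordered pair $(j, k)$ of panel
haplotypes. Between adjacent sites separated by $d$ Morgans, each copied
haplotype switches with mass
$$\lambda = 1 - \exp(-\rho\, d / K),$$
spread uniformly over the $K$ panel haplotypes (so the stay probability is
$1-\lambda+\lambda/K$); the diploid transition factorises as the product
of the two haploid transitions, which keeps the forward–backward update
$O(K^2)$ per site via row/column sums. Emission at $(j,k)$ mixes the
copied alleles through a miscopy probability $\mu$:
$$P(\text{data}\mid j,k)=\sum_{a,b\in\{0,1\}}
  P(a\mid H_{j})\,P(b\mid H_{k})\,e^{L_{a+b}},$$
where $L_g$ are the max-normalised genotype log-likelihoods and
$P(a\mid h)=1-\mu$ if $a=h$, else $\mu$.

Posterior genotype probabilities (GP) come from exact forward–backward
over all $K^2$ states, marginalised over copied-allele pairs; dosage is
$DS = GP_1 + 2\,GP_2$; the hard call is the GP argmax with ties resolved
to the lowest genotype index. Phasing uses Viterbi decoding over the same
state space, with per-site copied-allele maximisation given the decoded
state. Everything runs in scaled (not log) space with per-site
renormalisation, implemented in C++; instances up to $10^4$ sites and 200
haplotypes run without underflow, and the exactness of both recursions is
tested against full path enumeration on small instances.

Defaults: $\rho = 4N_e$ with $N_e = 20{,}000$ (the conventional
population-scaled recombination rate) and $\mu = 10^{-3}$ (a small
miscopy rate, standard in Li–Stephens implementations). Both are exposed
through `copying_params()`. This is deliberately an *exact* small-panel
implementation: production imputation tools add state selection, sampling
iterations and chunking to scale to thousands of haplotypes; none of that
is replicated here, and no equivalence with any specific tool is claimed
beyond the copying-model contract above.

## The synthetic data generator

`simulate_panel()` builds each population from a small set of founder
haplotypes. Base allele frequencies follow a symmetric Beta(0.2, 0.2)
spectrum (U-shaped, rare-variant heavy); a diverged population perturbs
them with a Balding–Nichols draw
$p' \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$
with a single divergence parameter $F$ per population. Panel haplotypes
are recombinant mosaics of their founders (Poisson crossovers on the
genetic map, scaled by a "generations" knob, default 50) plus a small
mutation rate ($5\times10^{-3}$ per site). The founder construction is
the essential choice: it makes panel members share haplotype segments, so
a *held-out* target (its source haplotypes removed from the panel via
`exclude_from_panel`) remains imputable from relatives — with independent
haplotypes, leave-out imputation would be impossible and every accuracy
statistic would be meaningless.

The default study conditions are a 200-haplotype panel (160 in the main
population, 40 in a diverged one with $F = 0.1$, emulating an
underrepresented ancestry), 5,000 candidate sites over 10 Mb at a uniform
1 cM/Mb, two-thirds of sites transitions. Read data are Poisson-depth
site counts: each read reports the true allele flipped with the base
error ($10^{-3}$), and transition sites receive an additional independent
flip with the deamination rate (default 0.05), so the effective
transition-site error is $b + d - 2bd$. Coverage series are produced by
per-site binomial thinning (`downsample_reads()`), matching the way real
high-coverage genomes are subsampled to 0.1–2.0x. Trios transmit one
recombinant haplotype per parent (Poisson crossovers with mean equal to
the map length in Morgans), which makes them Mendel-consistent and
switch-free by construction — the zero baseline the trio statistics are
validated against.

What the generator does *not* emulate: sequence-level reads (no
alignment, mapping error or fragment-end position — damage is collapsed
to a per-read site-level flip), indels and multi-allelic sites,
population growth or realistic LD decay, and reference-panel phasing
error. Passing tests therefore demonstrate the correctness and the
qualitative behaviour of the evaluation machinery under controlled
conditions, not quantitative error rates for any real dataset.

## Likelihoods, validation calls, and filters

`genotype_likelihoods()` uses the binomial read model with per-read
alternative-allele probabilities $\{\varepsilon, 1/2, 1-\varepsilon\}$
for genotypes 0/1/2 (assumed error $\varepsilon = 0.01$ by default,
deliberately looser than the simulated base error, as real callers assume
a generic error rate). Sites without reads carry the uninformative triple.

Validation ("truth") genotypes mimic high-coverage calling: hard calls
under a flat genotype prior with `QUAL` defined as
$-10\log_{10}(1-\text{posterior of the best genotype})$ — a documented
stand-in for a production caller's QUAL, which depends on internals not
reproduced here. The validation filter keeps sites with depth in
$[\max(\mathrm{DoC}/3, 8),\, 2\,\mathrm{DoC}]$ and $QUAL \ge 30$.
Separately, concordance evaluation masks to sites with at least 8 reads
and genotype posterior $\ge 0.9999$ — two distinct filters applied at two
different stages, on purpose.

## Evaluation statistics

* **$r^2$ by MAF bin** — squared Pearson correlation between imputed
  dosage and the validation genotype, in bins with edges
  0.001/0.01/0.02/0.05/0.1/0.2/0.5; bins with zero variance on either
  side are flagged undefined rather than reported as 0. Pooling is across
  sites (per-genome pooled $r^2$ is also reported); whether to pool
  across samples or average per-sample $r^2$ is genuinely open, so both
  are exposed.
* **Per-class discordance and NRD** — matches/errors classed by the
  validation genotype;
  $NRD = (e_{RR}+e_{RA}+e_{AA})/(m_{RA}+m_{AA}+e_{RR}+e_{RA}+e_{AA})$,
  which removes the overwhelming correct homozygous-reference class from
  the denominator.
* **GP filtering** — sites with $\max GP$ below a threshold (working
  range 0.70–0.99, default 0.80 for downstream use) become missing;
  retained sets are nested across thresholds, and heterozygote retention
  is the fraction of correctly-imputed heterozygotes surviving the
  filter.
* **Trio QC** — a Mendel error is a site where no assignment of one
  allele per parent yields the child's genotype, with sites where all
  three *truth* genotypes are homozygous-reference excluded from the
  denominator (they are trivially easy and would dilute the rate); switch
  errors are counted between consecutive trio-resolvable heterozygous
  sites as flips of the phase orientation, a definition invariant to
  swapping the two haplotypes wholesale. Sites where both parents are
  heterozygous are unresolvable and skipped — the standard convention
  when the source of each allele cannot be deduced.
* **Downstream** — pairwise allelic distance is the mean of
  $|g_1-g_2|$ over pairwise-complete sites (one reading of "allelic
  pairwise differences", labelled as such); PCA standardises panel sites
  by $\sqrt{2p(1-p)}$ and projects targets by least squares on their
  non-missing sites only (never refitting the panel), with
  imputed-vs-validation coordinate shifts normalised by the panel score
  standard deviation — a normalisation chosen for invariance to
  eigenvector scaling — and tested per component with an unadjusted
  two-sided one-sample t-test; ROH detection follows the PLINK
  `--homozyg` window semantics (50-SNP windows, ≤1 heterozygote, ≤5
  missing, 5% hit-rate eligibility, segments ≥50 SNPs, ≥500 kb, ≤50
  kb/SNP, split at >100 kb gaps; the per-segment heterozygote cap is left
  unlimited since only window-level limits are specified), with totals
  split at 1.6 Mb into long and short ROH; the Spearman permutation test
  uses 10,000 permutations and the add-one-corrected two-sided p-value
  $(b+1)/(n_{perm}+1)$.

### The evaluation site universe

Concordance statistics are computed at sites that still segregate in the
imputation panel actually used (after removing the target's source
haplotypes). A site monomorphic in the reference panel cannot be imputed
as variant by any copying model — in real pipelines such sites are simply
not in the panel's site list — and with small simulated panels a held-out
target's private variants would otherwise be counted as confident,
unavoidable errors, distorting the GP-filter calibration at the strictest
thresholds.

## Numerical and degenerate-input choices

* GP triples are renormalised per site; `DS = GP1 + 2*GP2` holds exactly
  by construction.
* Hard-call and validation-call ties break to the lowest genotype index.
* `QUAL` is capped where $1-\text{posterior}$ underflows.
* Undefined quantities (empty MAF bins, zero NRD denominators, no
  correct heterozygotes pre-filter, fewer than two resolvable
  heterozygote pairs, zero-variance shift components) are flagged `NA`,
  never reported as 0; a degenerate t-test (zero variance, nonzero mean)
  is flagged instead of given a p-value.
* ROH callers reject unsorted positions; the Viterbi phaser limits the
  panel to 256 haplotypes (byte backpointers) — ample for the exact
  $K^2$-state regime this implementation targets.
* All randomness flows from explicit seeds; pipeline sub-stages draw
  named sub-seeds from the master seed, so every run is reproducible and
  byte-identical given the configuration (tables are stamped with a
  configuration hash).

## Problem sizes used in the tests

The test suite exercises the study conditions at sizes chosen to keep an
exhaustive-oracle comparison feasible: HMM equivalence on all instances
with $K\le4$, $M\le5$ (100 instances against full path enumeration);
coverage monotonicity, ancestry mismatch and GP-filter behaviour on 20
replicates of the default 200-haplotype / 5,000-site panel across the
0.1–2.0x grid; ROH equality against a brute-force window scan on
instances up to 500 SNPs; statistical calibration on 1,000 null
replicates; and the full default pipeline (6 depths, one trio) run twice
for byte-identical determinism. These sizes are the package's chosen
testing conditions, stated here so results can be reproduced exactly.

## A worked run

```{r, eval = FALSE}
library(paleoimpute)
res <- run_pipeline(pipeline_config(seed = 1))
res$concordance   # NRD and pooled r2 per depth of coverage
res$trio          # Mendel and switch-error rates per depth
autoplot(res)     # coverage curves
plot_gp_tradeoff(res)
```

## Known limitations

* The copying model is exact but desk-scale; panels beyond a few hundred
  haplotypes need the state-selection machinery of production tools.
* Damage is site-level and symmetric (ref↔alt); strand- and
  position-specific deamination, contamination, and reference bias are
  out of scope, so damage-aware callers cannot be benchmarked here.
* The default simulation yields outbred genomes, so the pipeline's ROH
  comparison is typically empty (both datasets agree on "no ROH"); ROH
  caller correctness is established on constructed fixtures instead.
* Validation genotypes inherit the flat-prior QUAL stand-in; absolute
  QUAL scales are not comparable with any particular production caller.
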