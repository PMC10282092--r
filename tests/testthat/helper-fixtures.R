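# Small fixtures built in code.

# A panel assembled by hand from an explicit allele matrix.
manual_panel <- function(alleles, positions = NULL, pop = NULL,
                         site_class = NULL, cm = NULL, chrom = "1") {
  m <- ncol(alleles)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(pop)) pop <- rep("A", nrow(alleles))
  if (is.null(site_class)) site_class <- rep("tv", m)
  if (is.null(cm)) cm <- positions / 1e6
  af <- colMeans(alleles)
  structure(list(positions = as.integer(positions),
                 alleles = alleles, pop = pop, site_class = site_class,
                 maf = pmin(af, 1 - af),
                 map = tibble::tibble(pos = as.integer(positions), cm = cm),
                 chrom = chrom),
            class = "haplotype_panel")
}

# Uninformative / dominant genotype-likelihood tables.
flat_gl <- function(panel) {
  tibble::tibble(chrom = panel$chrom, pos = panel$positions,
                 depth = 0L, ll_rr = 0, ll_ra = 0, ll_aa = 0)
}

dominant_gl <- function(panel, genotype, strength = 60) {
  m <- length(genotype)
  ll <- matrix(-strength, m, 3)
  ll[cbind(seq_len(m), genotype + 1L)] <- 0
  tibble::tibble(chrom = panel$chrom, pos = panel$positions,
                 depth = 30L, ll_rr = ll[, 1], ll_ra = ll[, 2],
                 ll_aa = ll[, 3])
}

# Random tiny HMM instance for oracle comparisons.
random_hmm_instance <- function(K, M, seed) {
  withr::with_seed(seed, {
    H <- matrix(rbinom(K * M, 1, 0.5), K, M)
    loggl <- matrix(log(runif(M * 3, 0.05, 1)), M, 3)
    loggl <- loggl - apply(loggl, 1, max)
    cm <- cumsum(runif(M, 0.01, 2))
    list(H = H, loggl = loggl, cm = cm,
         rho = runif(1, 20, 400), mu = runif(1, 1e-4, 0.05))
  })
}
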