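test_that("panel simulation is deterministic and polymorphic", {
  p1 <- simulate_panel(n_haps = c(A = 20, B = 10), n_sites = 500,
                       region_length = 2e6, divergence = c(A = 0, B = 0.1),
                       seed = 5)
  p2 <- simulate_panel(n_haps = c(A = 20, B = 10), n_sites = 500,
                       region_length = 2e6, divergence = c(A = 0, B = 0.1),
                       seed = 5)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$positions, p2$positions)
  expect_true(all(p1$alleles %in% 0:1))
  expect_false(is.unsorted(p1$positions, strictly = TRUE))
  expect_true(all(p1$maf > 0 & p1$maf <= 0.5))
  ac <- colSums(p1$alleles)
  expect_true(all(ac > 0 & ac < nrow(p1$alleles)))
  # maf recomputable from alleles
  expect_equal(p1$maf, pmin(colMeans(p1$alleles), 1 - colMeans(p1$alleles)))
  p3 <- simulate_panel(n_haps = c(A = 20, B = 10), n_sites = 500,
                       region_length = 2e6, divergence = c(A = 0, B = 0.1),
                       seed = 6)
  expect_false(identical(p1$alleles, p3$alleles))
})

test_that("zero divergence gives equal population frequencies in expectation", {
  p <- simulate_panel(n_haps = c(A = 60, B = 60), n_sites = 4000,
                      region_length = 1e7, divergence = c(A = 0, B = 0),
                      seed = 11)
  d <- panel_maf(p, "A", minor = FALSE) - panel_maf(p, "B", minor = FALSE)
  # same founder-frequency law for both: mean difference ~ 0
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("population divergence matches a Monte-Carlo oracle for the drift law", {
  f <- 0.1
  n_f <- 16
  na <- 40; nb <- 40
  gens <- 50
  mse_reps <- vapply(1:12, function(r) {
    p <- simulate_panel(n_haps = c(A = na, B = nb), n_sites = 10000,
                        region_length = 2e7, divergence = c(A = 0, B = f),
                        n_founders = n_f, founder_generations = gens,
                        mutation_rate = 0, seed = 20 + r)
    mean((panel_maf(p, "A", minor = FALSE) -
            panel_maf(p, "B", minor = FALSE))^2)
  }, numeric(1))
  mse_obs <- mean(mse_reps)

  # Independent direct simulation of the generative law: Beta(0.2, 0.2)
  # base frequency, Balding-Nichols drift for population B, founder
  # resampling, then per-haplotype Bernoulli draws from the founder
  # frequency (the mosaic redistributes founder segments but leaves each
  # haplotype marginally Bernoulli(founder frequency)); conditioned on
  # panel-wide polymorphism like the generator.
  nrep <- 1e5
  sims <- withr::with_seed(99, {
    pb <- rbeta(nrep, 0.2, 0.2)
    pb <- pmin(pmax(pb, 1e-4), 1 - 1e-4)
    pa2 <- pb
    pb2 <- rbeta(nrep, pb * (1 - f) / f, (1 - pb) * (1 - f) / f)
    fa <- rbinom(nrep, n_f, pa2) / n_f
    fb <- rbinom(nrep, n_f, pb2) / n_f
    qa <- rbinom(nrep, na, fa) / na
    qb <- rbinom(nrep, nb, fb) / nb
    poly <- (qa * na + qb * nb) > 0 & (qa * na + qb * nb) < na + nb
    (qa[poly] - qb[poly])^2
  })
  # SE of the observed mean from the replicate panels, plus the (small)
  # Monte-Carlo error of the oracle itself
  se <- sqrt(var(mse_reps) / length(mse_reps) +
               var(sims) / length(sims))
  expect_lt(abs(mse_obs - mean(sims)), 3 * se)
})

test_that("copy-mode diploid sampling sums two panel haplotypes and can exclude them", {
  p <- simulate_panel(n_haps = c(A = 20), n_sites = 300,
                      region_length = 1e6, divergence = c(A = 0), seed = 3)
  s <- sample_diploid(p, "A", seed = 8, mode = "copy",
                      exclude_from_panel = TRUE)
  expect_length(s$source_haps, 2)
  expect_equal(s$genome$genotype,
               unname(p$alleles[s$source_haps[1], ] +
                        p$alleles[s$source_haps[2], ]))
  expect_equal(nrow(s$panel$alleles), nrow(p$alleles) - 2)
  expect_equal(s$genome$genotype, s$genome$hap1 + s$genome$hap2)

  s2 <- sample_diploid(p, "A", seed = 8, mode = "mosaic",
                       exclude_from_panel = TRUE)
  expect_equal(nrow(s2$panel$alleles),
               nrow(p$alleles) - length(s2$source_haps))
  expect_error(sample_diploid(p, "Z", seed = 1), "population")
})

test_that("mosaic crossover count matches the Poisson-thinning oracle", {
  p <- simulate_panel(n_haps = c(A = 16), n_sites = 150,
                      region_length = 1e7, divergence = c(A = 0), seed = 4)
  nx <- unlist(lapply(1:1000, function(i)
    sample_diploid(p, "A", seed = i, mode = "mosaic",
                   expected_crossovers = 3,
                   exclude_from_panel = FALSE)$n_crossovers))
  # oracle: crossovers ~ Poisson(3); a crossover is an effective source
  # change with probability (n - 1)/n when the new source is uniform
  expected <- 3 * (16 - 1) / 16
  expect_lt(abs(mean(nx) - expected), 3 * sd(nx) / sqrt(length(nx)))
})

test_that("read simulation respects error model, depth, and determinism", {
  p <- simulate_panel(n_haps = c(A = 10), n_sites = 2000,
                      region_length = 1e7, divergence = c(A = 0), seed = 2)
  g <- sample_diploid(p, "A", seed = 1, mode = "copy",
                      exclude_from_panel = FALSE)$genome
  r0 <- simulate_reads(g, p, mean_depth = 2, base_error = 0,
                       deam_error = 0, seed = 7)
  expect_identical(r0, simulate_reads(g, p, mean_depth = 2, base_error = 0,
                                      deam_error = 0, seed = 7))
  hom_ref <- g$genotype == 0
  expect_true(all(r0$n_alt[hom_ref] == 0))
  hom_alt <- g$genotype == 2
  expect_true(all(r0$n_ref[hom_alt] == 0))
  expect_error(simulate_reads(g, p, mean_depth = 0), "mean_depth")
})

test_that("deamination inflates flips at transitions only", {
  m <- 1e5
  sites <- tibble::tibble(pos = seq_len(m) * 10L,
                          site_class = rep(c("ts", "tv"), length.out = m))
  genome <- structure(list(id = "g", pop = "A",
                           hap1 = rep(0L, m), hap2 = rep(0L, m),
                           genotype = rep(0L, m)), class = "true_genome")
  b <- 0.01; d <- 0.1
  r <- simulate_reads(genome, sites, mean_depth = 1, base_error = b,
                      deam_error = d, seed = 13)
  ts <- r$site_class == "ts"
  flips_tv <- sum(r$n_alt[!ts]); reads_tv <- sum(r$n_ref[!ts] + r$n_alt[!ts])
  flips_ts <- sum(r$n_alt[ts]);  reads_ts <- sum(r$n_ref[ts] + r$n_alt[ts])
  # transversions: flip rate = base_error alone (binomial 3-sigma band)
  expect_lt(abs(flips_tv / reads_tv - b), 3 * sqrt(b * (1 - b) / reads_tv))
  # transitions: composed flip probability, strictly above transversions
  comp <- b + d - 2 * b * d
  expect_lt(abs(flips_ts / reads_ts - comp),
            3 * sqrt(comp * (1 - comp) / reads_ts))
  expect_gt(flips_ts / reads_ts, flips_tv / reads_tv)
  # Poisson depth: empirical mean within 3 SE of nominal
  depth <- r$n_ref + r$n_alt
  expect_lt(abs(mean(depth) - 1), 3 * sd(depth) / sqrt(m))
})

test_that("downsampling is binomial thinning to the target depth", {
  m <- 1e5
  sites <- tibble::tibble(pos = seq_len(m) * 10L, site_class = rep("tv", m))
  genome <- structure(list(id = "g", pop = "A",
                           hap1 = rep(0L, m), hap2 = rep(1L, m),
                           genotype = rep(1L, m)), class = "true_genome")
  r20 <- simulate_reads(genome, sites, mean_depth = 20, base_error = 0.001,
                        deam_error = 0, seed = 17)
  expect_identical(downsample_reads(r20, mean_depth_of(r20), seed = 1)[
    c("n_ref", "n_alt")], r20[c("n_ref", "n_alt")])
  r1 <- downsample_reads(r20, 1, seed = 19)
  depth <- r1$n_ref + r1$n_alt
  expect_lt(abs(mean(depth) - 1), 3 * sd(depth) / sqrt(m))
  expect_equal(mean_depth_of(r1), 1)
  expect_error(downsample_reads(r20, 0), "target_doc")
  expect_error(downsample_reads(r1, 2), "no upsampling")
})

test_that("trio construction is Mendel-consistent and switch-free", {
  p <- simulate_panel(n_haps = c(A = 30), n_sites = 1500,
                      region_length = 1e7, divergence = c(A = 0), seed = 23)
  tr <- simulate_trio(p, "A", seed = 31)
  expect_equal(nrow(tr$panel$alleles), nrow(p$alleles) - 4)
  mer <- mendel_error_rate(tr$child$genotype, tr$mother$genotype,
                           tr$father$genotype, tr$child$genotype,
                           tr$mother$genotype, tr$father$genotype)
  expect_identical(mer$n_errors, 0L)
  ph <- trio_phase(tr$child$genotype, tr$mother$genotype,
                   tr$father$genotype)
  ser <- switch_error_rate(tr$child$hap1, tr$child$hap2, ph)
  expect_identical(ser$n_switches, 0L)
  expect_gt(ser$n_pairs, 0)

  # zero genetic map length: transmissions are unrecombined parental haplotypes
  p0 <- simulate_panel(n_haps = c(A = 12), n_sites = 400,
                       region_length = 2e6, divergence = c(A = 0),
                       cm_per_mb = 0, seed = 37)
  tr0 <- simulate_trio(p0, "A", seed = 41)
  expect_true(identical(tr0$child$hap1, tr0$father$hap1) ||
                identical(tr0$child$hap1, tr0$father$hap2))
  expect_true(identical(tr0$child$hap2, tr0$mother$hap1) ||
                identical(tr0$child$hap2, tr0$mother$hap2))
})
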