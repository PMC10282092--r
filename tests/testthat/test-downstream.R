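test_that("pairwise allelic differences match the formula and the loop oracle", {
  g <- rbind(ind1 = c(0L, 2L, 1L), ind2 = c(2L, 0L, 1L))
  d <- pairwise_allelic_diff(c(0L, 2L, 1L), g)
  expect_equal(d$distance, c(0, 4 / 3))
  # symmetry of the per-site contribution
  d2 <- pairwise_allelic_diff(c(2L, 0L, 1L), g)
  expect_equal(d2$distance[1], d$distance[2])
  set.seed(80)
  tgt <- sample(c(0:2, NA), 200, replace = TRUE)
  gm <- matrix(sample(c(0:2, NA), 2000, replace = TRUE), nrow = 10)
  got <- pairwise_allelic_diff(tgt, gm)
  expect_equal(got$distance, oracle_pairwise(tgt, gm))
  # per-site contributions satisfy the triangle inequality
  a <- sample(0:2, 50, TRUE); b <- sample(0:2, 50, TRUE)
  c_ <- sample(0:2, 50, TRUE)
  expect_true(all(abs(a - c_) <= abs(a - b) + abs(b - c_)))
  expect_true(is.na(pairwise_allelic_diff(
    c(NA_integer_, NA_integer_),
    matrix(c(0L, 1L), nrow = 1))$distance))
})

test_that("targets from their own population are closer than diverged panel members", {
  wins <- vapply(1:20, function(r) {
    p <- simulate_panel(n_haps = c(A = 30, B = 30), n_sites = 800,
                        region_length = 4e6, divergence = c(A = 0, B = 0.15),
                        seed = 900 + r)
    tgt <- sample_diploid(p, "A", seed = 950 + r,
                          exclude_from_panel = TRUE)
    d <- pairwise_allelic_diff(tgt$genome$genotype, tgt$panel)
    mean(d$distance[d$pop == "A"]) < mean(d$distance[d$pop == "B"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("projection reproduces panel individuals and rejects empty targets", {
  p <- simulate_panel(n_haps = c(A = 40, B = 40), n_sites = 600,
                      region_length = 3e6, divergence = c(A = 0, B = 0.2),
                      seed = 81)
  g <- panel_genotypes(p)
  proj <- pca_project(p, targets = list(copy = g[5, ]), n_components = 6)
  expect_equal(unlist(proj$target_scores[1, paste0("PC", 1:6)]),
               unlist(proj$panel_scores[5, paste0("PC", 1:6)]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(pca_project(p, targets = list(bad = rep(NA_integer_,
                                                       ncol(g)))),
               "non-missing")
})

test_that("the first component separates diverged populations", {
  sil <- vapply(1:10, function(r) {
    p <- simulate_panel(n_haps = c(A = 30, B = 30), n_sites = 600,
                        region_length = 3e6, divergence = c(A = 0, B = 0.2),
                        seed = 820 + r)
    proj <- pca_project(p, n_components = 2)
    pc1 <- proj$panel_scores$PC1
    pop <- proj$panel_scores$pop
    # sign-invariant separation: silhouette-style gap on PC1
    m_a <- mean(pc1[pop == "A"]); m_b <- mean(pc1[pop == "B"])
    s_a <- sd(pc1[pop == "A"]); s_b <- sd(pc1[pop == "B"])
    abs(m_a - m_b) - (s_a + s_b) > 0
  }, logical(1))
  expect_true(all(sil))
})

test_that("projection uses only the target's non-missing sites", {
  p <- simulate_panel(n_haps = c(A = 30), n_sites = 500,
                      region_length = 3e6, divergence = c(A = 0), seed = 83)
  g <- panel_genotypes(p)
  tgt <- g[3, ]
  tgt[sample(length(tgt), 150)] <- NA
  proj <- pca_project(p, targets = list(t = tgt), n_components = 4)
  # oracle: explicit least squares on the complete sites
  ok <- !is.na(tgt[proj$keep])
  v <- proj$loadings[ok, ]
  xt <- (tgt[proj$keep][ok] - proj$center[ok]) / proj$scale[ok]
  want <- drop(solve(crossprod(v), crossprod(v, xt)))
  expect_equal(unlist(proj$target_scores[1, paste0("PC", 1:4)]), want,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("coordinate shift test handles exact agreement and degeneracy", {
  set.seed(83)
  coords <- matrix(rnorm(20), 5, 4)
  r <- coordinate_shift_test(coords, coords, score_sd = rep(1, 4))
  expect_true(all(r$p_value == 1))
  expect_true(all(r$mean_diff == 0))
  shifted <- coords + 0.5
  r2 <- coordinate_shift_test(shifted, coords, score_sd = rep(1, 4))
  expect_true(all(is.na(r2$p_value)))
  expect_match(r2$note[1], "degenerate")
  set.seed(84)
  imp <- coords + matrix(rnorm(20, sd = 0.1), 5, 4)
  r3 <- coordinate_shift_test(imp, coords, score_sd = rep(2, 4))
  # agrees with a direct t-test on the normalised differences
  want <- t.test((imp[, 2] - coords[, 2]) / 2)$p.value
  expect_equal(r3$p_value[2], want)
  expect_error(coordinate_shift_test(coords[1, , drop = FALSE],
                                     coords[1, , drop = FALSE],
                                     rep(1, 4)), "2 paired samples")
})

test_that("Spearman permutation test hits its extreme cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  r <- spearman_perm_test(x, x, n_perm = 500, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 1 / 501)
  rev <- spearman_perm_test(x, -x, n_perm = 500, seed = 1)
  expect_equal(rev$rho, -1)
  expect_true(is.na(spearman_perm_test(x, rep(1, 10))$rho))
  expect_error(spearman_perm_test(1:2, 1:2), "length")
  # determinism
  a <- spearman_perm_test(x, sample(x), n_perm = 200, seed = 9)
  b <- spearman_perm_test(x, x[c(2:10, 1)], n_perm = 200, seed = 9)
  expect_equal(spearman_perm_test(x, x[c(2:10, 1)], n_perm = 200, seed = 9),
               b)
})
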