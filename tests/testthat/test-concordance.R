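make_imputed <- function(gp, missing = rep(FALSE, nrow(gp)),
                         pos = seq_len(nrow(gp)) * 100L) {
  out <- tibble::tibble(chrom = "1", pos = pos,
                        gp0 = gp[, 1], gp1 = gp[, 2], gp2 = gp[, 3],
                        ds = gp[, 2] + 2 * gp[, 3],
                        gt = max.col(gp, ties.method = "first") - 1L,
                        missing = missing)
  class(out) <- c("imputed_genotype", class(out))
  out
}

test_that("validation mask requires depth and posterior thresholds", {
  val <- tibble::tibble(depth = c(7L, 8L, 8L, 20L),
                        gt = c(0L, 1L, 2L, NA),
                        posterior = c(1, 0.99999, 0.999, 1))
  expect_equal(validation_mask(val), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("MAF-binned r2 matches hand computation and flags degenerate bins", {
  # perfect imputation: r2 = 1 in every non-degenerate bin
  d <- tibble::tibble(ds = c(0, 1, 2, 0, 1, 2),
                      gt = c(0L, 1L, 2L, 0L, 1L, 2L),
                      maf = c(0.005, 0.005, 0.005, 0.3, 0.3, 0.3))
  r <- maf_bin_r2(d)
  def <- r[r$defined, ]
  expect_true(all(abs(def$r2 - 1) < 1e-12))
  # anti-correlated dosage: correlation squared loses the sign
  d2 <- dplyr::mutate(d, ds = 2 - gt)
  expect_true(all(abs(maf_bin_r2(d2)$r2[r$defined] - 1) < 1e-12))
  # hand-computed Pearson on a 6-site bin
  ds <- c(0.1, 0.9, 1.8, 0.2, 1.1, 2.0)
  gt <- c(0L, 1L, 2L, 0L, 1L, 2L)
  d3 <- tibble::tibble(ds = ds, gt = gt, maf = 0.15)
  r3 <- maf_bin_r2(d3)
  hand <- (sum((ds - mean(ds)) * (gt - mean(gt))) /
             sqrt(sum((ds - mean(ds))^2) * sum((gt - mean(gt))^2)))^2
  expect_equal(r3$r2[r3$defined], hand)
  # zero-variance genotype bin: undefined, not 0
  d4 <- tibble::tibble(ds = c(0.2, 0.4), gt = c(0L, 0L), maf = 0.3)
  r4 <- maf_bin_r2(d4)
  expect_false(any(r4$defined))
  expect_true(all(is.na(r4$r2)))
})

test_that("discordance tallies match the counting oracle", {
  expect_identical(discordance(c(0L, 1L, 2L), c(0L, 1L, 2L))$counts,
                   c(m_rr = 1L, m_ra = 1L, m_aa = 1L,
                     e_rr = 0L, e_ra = 0L, e_aa = 0L))
  d <- discordance(c(0L, 2L, 2L), c(0L, 1L, 2L))
  expect_equal(unname(d$counts[c("e_ra", "m_rr", "m_aa")]), c(1L, 1L, 1L))
  expect_equal(d$rates$error_rate[d$rates$class == "RA"], 1)

  set.seed(60)
  for (i in 1:5) {
    imp <- sample(c(0:2, NA), 1000, replace = TRUE)
    val <- sample(c(0:2, NA), 1000, replace = TRUE,
                  prob = c(0.6, 0.2, 0.15, 0.05))
    got <- discordance(imp, val)
    want <- oracle_discordance(imp, val)
    expect_equal(unname(got$counts), unname(want$counts))
    expect_equal(got$n_missing, want$missing)
    # count conservation over the site universe
    expect_equal(sum(got$counts) + got$n_missing, 1000)
    expect_equal(nrd(got), oracle_nrd(want$counts))
  }
})

test_that("NRD follows the published formula", {
  expect_equal(nrd(c(m_rr = 50, m_ra = 10, m_aa = 6,
                     e_rr = 1, e_ra = 2, e_aa = 1)), 0.2)
  expect_equal(nrd(c(m_rr = 9, m_ra = 5, m_aa = 5,
                     e_rr = 0, e_ra = 0, e_aa = 0)), 0)
  # m_rr is excluded from the denominator: errors only -> rate 1
  expect_equal(nrd(c(m_rr = 100, m_ra = 0, m_aa = 0,
                     e_rr = 5, e_ra = 0, e_aa = 0)), 1)
  expect_true(is.na(nrd(c(m_rr = 10, m_ra = 0, m_aa = 0,
                          e_rr = 0, e_ra = 0, e_aa = 0))))
})

test_that("GP filtering is monotone and nested across thresholds", {
  set.seed(61)
  raw <- matrix(runif(300), ncol = 3)
  gp <- raw / rowSums(raw)
  imp <- make_imputed(gp)
  expect_identical(gp_filter(imp, 0)$missing, imp$missing)   # identity
  f <- gp_filter(make_imputed(matrix(c(0.5, 0.3, 0.2), 1)), 0.8)
  expect_true(f$missing[1])
  f80 <- gp_filter(imp, 0.80)
  f99 <- gp_filter(imp, 0.99)
  expect_true(all(!f99$missing | f80$missing | f99$missing))
  # retained at 0.99 is a subset of retained at 0.80
  expect_true(all(which(!f99$missing) %in% which(!f80$missing)))
})

test_that("heterozygote retention counts correct hets surviving the filter", {
  gp <- rbind(matrix(rep(c(0.05, 0.9, 0.05), 10), ncol = 3, byrow = TRUE),
              matrix(rep(c(0.2, 0.6, 0.2), 10), ncol = 3, byrow = TRUE))
  pre <- make_imputed(gp)
  val <- rep(1L, 20)
  expect_equal(het_retention(pre, gp_filter(pre, 0), val), 1)
  post <- gp_filter(pre, 0.8)  # keeps the 10 confident hets only
  expect_equal(het_retention(pre, post, val), 0.5)
  expect_equal(het_retention(pre, post, val),
               oracle_het_retention(pre$missing, post$missing, pre$gt, val))
  # non-increasing in threshold
  r <- vapply(c(0, 0.5, 0.7, 0.9, 0.99), function(t)
    het_retention(pre, gp_filter(pre, t), val), numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_true(is.na(het_retention(pre, post, rep(0L, 20))))
})

test_that("subset evaluation partitions the site universe", {
  set.seed(62)
  m <- 400
  gp <- matrix(runif(3 * m), ncol = 3)
  gp <- gp / rowSums(gp)
  imp <- make_imputed(gp)
  val <- tibble::tibble(chrom = "1", pos = imp$pos, depth = 30L,
                        gt = sample(0:2, m, replace = TRUE),
                        posterior = 1, qual = 99, pass_filter = TRUE)
  maf <- runif(m, 0.01, 0.5)
  mask <- seq_len(m) <= 250
  both <- subset_eval(imp, val, maf, mask)
  full <- concordance_report(imp, val, maf)
  expect_equal(both$inside$n_eval + both$outside$n_eval, full$n_eval)
  all_in <- subset_eval(imp, val, maf, rep(TRUE, m))
  expect_equal(glance(all_in$inside), glance(full))
  expect_equal(all_in$outside$n_eval, 0)

  # errors confined to the mask: inside NRD > 0, outside NRD = 0
  imp2 <- make_imputed(gp)
  imp2$gt <- val$gt
  imp2$gt[1:20] <- (val$gt[1:20] + 1L) %% 3L
  both2 <- subset_eval(imp2, val, maf, mask)
  expect_gt(both2$inside$nrd, 0)
  expect_equal(both2$outside$nrd, 0)
})
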