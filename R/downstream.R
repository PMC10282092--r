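#' Diploid genotype matrix of the panel's individuals
#'
#' Pairs consecutive haplotypes (1-2, 3-4, ...) into individuals and sums
#' them into 0/1/2 genotypes.
#'
#' @param panel A `haplotype_panel`; a trailing unpaired haplotype (as can
#'   remain after excluding target sources) is ignored.
#' @return Integer matrix, individuals x sites, with `pop` attribute.
#' @export
panel_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  k <- nrow(panel$alleles)
  if (k < 2) stop("panel must have at least 2 haplotypes")
  k <- 2L * (k %/% 2L)
  odd <- seq(1, k - 1, by = 2)
  g <- panel$alleles[odd, , drop = FALSE] +
    panel$alleles[odd + 1, , drop = FALSE]
  rownames(g) <- paste0("ind", seq_len(k / 2))
  attr(g, "pop") <- panel$pop[odd]
  g
}

#' Pairwise allelic differences to each panel individual
#'
#' The distance to an individual is the mean over pairwise-complete sites
#' of `|g_target - g_other|`, the minimal allele mismatch count between two
#' unphased diploid genotypes.
#'
#' @param target Integer genotypes (0/1/2/`NA`) of the target genome.
#' @param panel A `haplotype_panel` or an individuals x sites genotype
#'   matrix (optionally with a `pop` attribute).
#' @return Tibble with `individual`, `pop`, `n_sites`, `distance`.
#' @export
pairwise_allelic_diff <- function(target, panel) {
  g <- if (inherits(panel, "haplotype_panel")) panel_genotypes(panel) else panel
  stopifnot(length(target) == ncol(g))
  pop <- attr(g, "pop")
  if (is.null(pop)) pop <- rep(NA_character_, nrow(g))
  res <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    ok <- !is.na(target) & !is.na(g[i, ])
    tibble::tibble(
      individual = rownames(g)[i] %||% paste0("ind", i),
      pop = pop[i],
      n_sites = sum(ok),
      distance = if (sum(ok) == 0) NA_real_
                 else mean(abs(target[ok] - g[i, ok])))
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA of panel genotypes with least-squares projection of targets
#'
#' Principal components are computed from the panel individuals' genotypes,
#' each site centred at its mean and scaled by `sqrt(2 p (1 - p))` (the
#' binomial variance convention of smartpca); sites fixed in the panel are
#' dropped. Targets are never included in the decomposition: each target is
#' standardised with the panel's centre/scale and projected by least
#' squares onto the site loadings using its non-missing sites only
#' (the `lsqproject` convention, which keeps projections unbiased under
#' missingness).
#'
#' @param panel A `haplotype_panel` or genotype matrix (individuals x
#'   sites).
#' @param targets Named list of target genotype vectors (0/1/2/`NA`), or a
#'   samples x sites matrix, or `NULL`.
#' @param n_components Number of leading components (default 10).
#' @return A `pca_projection`: list with `panel_scores` and `target_scores`
#'   tibbles (`id`, `pop`, `PC1..PCn`), `score_sd` (per-component panel
#'   score standard deviations), `loadings`, `keep` (site filter),
#'   `center`, `scale`.
#' @export
pca_project <- function(panel, targets = NULL, n_components = 10) {
  g <- if (inherits(panel, "haplotype_panel")) panel_genotypes(panel) else panel
  pop <- attr(g, "pop") %||% rep(NA_character_, nrow(g))
  p <- colMeans(g) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("panel has no polymorphic sites")
  p <- p[keep]
  scale <- sqrt(2 * p * (1 - p))
  x <- sweep(sweep(g[, keep, drop = FALSE], 2, 2 * p), 2, scale, "/")
  n_components <- min(n_components, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = n_components, nv = n_components)
  loadings <- sv$v
  scores <- x %*% loadings
  colnames(scores) <- paste0("PC", seq_len(n_components))

  project_one <- function(gt) {
    gt <- gt[keep]
    ok <- !is.na(gt)
    if (!any(ok)) stop("target genome has no non-missing sites to project")
    xt <- (gt[ok] - 2 * p[ok]) / scale[ok]
    v <- loadings[ok, , drop = FALSE]
    drop(solve(crossprod(v), crossprod(v, xt)))
  }

  target_scores <- NULL
  if (!is.null(targets)) {
    if (is.matrix(targets))
      targets <- setNames(lapply(seq_len(nrow(targets)),
                                 function(i) targets[i, ]),
                          rownames(targets) %||%
                            paste0("target", seq_len(nrow(targets))))
    if (is.null(names(targets)))
      names(targets) <- paste0("target", seq_along(targets))
    tg <- t(vapply(targets, project_one, numeric(n_components)))
    colnames(tg) <- paste0("PC", seq_len(n_components))
    target_scores <- dplyr::bind_cols(tibble::tibble(id = names(targets)),
                                      tibble::as_tibble(tg))
  }
  structure(
    list(panel_scores = dplyr::bind_cols(
           tibble::tibble(id = rownames(g) %||%
                            paste0("ind", seq_len(nrow(g))), pop = pop),
           tibble::as_tibble(scores)),
         target_scores = target_scores,
         score_sd = apply(scores, 2, sd),
         loadings = loadings, keep = keep, center = 2 * p, scale = scale,
         n_components = n_components),
    class = "pca_projection")
}

#' @method print pca_projection
#' @export
print.pca_projection <- function(x, ...) {
  cat("<pca_projection> ", nrow(x$panel_scores), " panel individuals, ",
      x$n_components, " components",
      if (!is.null(x$target_scores))
        paste0(", ", nrow(x$target_scores), " projected targets"),
      "\n", sep = "")
  invisible(x)
}

#' Test coordinate shifts between imputed and validation projections
#'
#' Per principal component, the paired differences
#' `(imputed - validation) / panel score SD` are tested against zero mean
#' with a two-sided one-sample t-test; no multiple-testing adjustment is
#' applied. A component whose differences are identically zero reports
#' `p = 1`; a degenerate component (zero variance around a nonzero mean)
#' is flagged rather than given a numeric p-value.
#'
#' @param imputed,validation Matrices (samples x components) of paired
#'   projection coordinates, or `pca_projection` target-score tibbles.
#' @param score_sd Per-component panel score standard deviations used for
#'   normalisation.
#' @return Tibble with `component`, `mean_diff`, `statistic`, `p_value`,
#'   `note`.
#' @export
coordinate_shift_test <- function(imputed, validation, score_sd) {
  imputed <- as_coord_matrix(imputed)
  validation <- as_coord_matrix(validation)
  stopifnot(all(dim(imputed) == dim(validation)),
            ncol(imputed) == length(score_sd))
  if (nrow(imputed) < 2) stop("need at least 2 paired samples")
  diffs <- sweep(imputed - validation, 2, score_sd, "/")
  purrr::map_dfr(seq_len(ncol(diffs)), function(j) {
    d <- diffs[, j]
    # guard the t-test against numerically constant differences
    if (sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
      if (all(d == 0))
        tibble::tibble(component = j, mean_diff = 0, statistic = NA_real_,
                       p_value = 1, note = "all differences zero")
      else
        tibble::tibble(component = j, mean_diff = mean(d),
                       statistic = NA_real_, p_value = NA_real_,
                       note = "degenerate: zero variance, nonzero mean")
    } else {
      tt <- t.test(d)
      tibble::tibble(component = j, mean_diff = mean(d),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value, note = NA_character_)
    }
  })
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  pc <- grep("^PC[0-9]+$", names(x), value = TRUE)
  as.matrix(x[, pc])
}

#' Spearman correlation with a two-sided permutation test
#'
#' Spearman's rank correlation with a permutation p-value: `y` is permuted
#' `n_perm` times and `p = (b + 1) / (n_perm + 1)` where `b` counts
#' permutations with `|rho| >= |rho_observed|` (add-one correction).
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed for the permutations.
#' @return List with `rho`, `p_value`, `n_perm`.
#' @export
spearman_perm_test <- function(x, y, n_perm = 10000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_perm = n_perm))
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  with_seed_if(seed, {
    b <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(rx, sample(ry))) >= abs(rho) - 1e-12
    }, logical(1)))
    list(rho = rho, p_value = (b + 1) / (n_perm + 1), n_perm = n_perm)
  })
}
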