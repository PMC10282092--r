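#' Biallelic genotype likelihoods from read counts
#'
#' For genotype `g` in {0, 1, 2} alternative alleles, each read carries the
#' alternative allele with probability `e`, `1/2`, `1 - e` respectively,
#' where `e` is the assumed per-read error. The per-site log-likelihood is
#' the binomial form `n_alt * log(p) + n_ref * log(1 - p)` (the binomial
#' coefficient is constant across genotypes and dropped), max-normalised so
#' the largest of the triple is 0. Sites with no reads carry the
#' uninformative triple (0, 0, 0).
#'
#' @param reads A site read-count tibble (columns `n_ref`, `n_alt`).
#' @param base_error Assumed per-read error rate, in (0, 0.5).
#' @return A tibble with columns `chrom`, `pos`, `depth`, `ll_rr`, `ll_ra`,
#'   `ll_aa` (natural-log, max-normalised).
#' @export
genotype_likelihoods <- function(reads, base_error = 0.01) {
  stopifnot(base_error > 0, base_error < 0.5)
  n_ref <- reads$n_ref
  n_alt <- reads$n_alt
  p <- c(base_error, 0.5, 1 - base_error)
  ll <- vapply(p, function(pi) n_alt * log(pi) + n_ref * log1p(-pi),
               numeric(length(n_ref)))
  ll <- matrix(ll, ncol = 3)
  ll <- ll - apply(ll, 1, max)
  tibble::tibble(
    chrom = if ("chrom" %in% names(reads)) reads$chrom else "1",
    pos = if ("pos" %in% names(reads)) reads$pos else seq_along(n_ref),
    depth = n_ref + n_alt,
    ll_rr = ll[, 1], ll_ra = ll[, 2], ll_aa = ll[, 3])
}

#' Validation depth filter bounds
#'
#' The depth window used for validation genotypes: a site passes when its
#' depth lies between `max(DoC / 3, 8)` and `2 * DoC`, where `DoC` is the
#' genome's mean depth of coverage.
#'
#' @param mean_doc Mean depth of coverage, > 0.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' depth_filter_bounds(30)  # c(lower = 10, upper = 60)
#' depth_filter_bounds(18)  # the 8-read floor binds: c(8, 36)
depth_filter_bounds <- function(mean_doc) {
  stopifnot(mean_doc > 0)
  c(lower = max(mean_doc / 3, 8), upper = 2 * mean_doc)
}

#' Call and filter validation genotypes from likelihoods
#'
#' The hard call is the maximum-likelihood genotype (flat prior over the
#' three genotypes; ties resolved to the lowest genotype index). `QUAL` is
#' the Phred-scaled probability that the call is wrong,
#' `-10 log10(1 - posterior)`. A site passes the filter when its depth lies
#' within [depth_filter_bounds()] for the supplied mean depth, `QUAL >=
#' qual_min`, and it is not excluded by a site mask. Sites with no reads are
#' missing (genotype `NA`) and never pass.
#'
#' @param gl Genotype-likelihood tibble from [genotype_likelihoods()].
#' @param mean_doc Mean depth of coverage of the genome the calls come from.
#' @param qual_min Minimum QUAL (default 30).
#' @param site_mask Optional logical vector, `TRUE` at sites to keep.
#' @return A tibble with columns `chrom`, `pos`, `depth`, `gt` (0/1/2 or
#'   `NA`), `posterior`, `qual`, `pass_filter`.
#' @export
call_validation <- function(gl, mean_doc, qual_min = 30, site_mask = NULL) {
  stopifnot(qual_min >= 0)
  m <- as.matrix(gl[, c("ll_rr", "ll_ra", "ll_aa")])
  lik <- exp(m)
  post <- lik / rowSums(lik)
  gt <- argmax_genotype(post)
  pmax_post <- post[cbind(seq_len(nrow(post)), gt + 1L)]
  qual <- -10 * log10(pmax(1 - pmax_post, 1e-300))
  bounds <- depth_filter_bounds(mean_doc)
  pass <- gl$depth >= bounds[["lower"]] & gl$depth <= bounds[["upper"]] &
    qual >= qual_min
  if (!is.null(site_mask)) {
    stopifnot(length(site_mask) == nrow(gl))
    pass <- pass & site_mask
  }
  gt[gl$depth == 0] <- NA_integer_
  pass[gl$depth == 0] <- FALSE
  tibble::tibble(chrom = gl$chrom, pos = gl$pos, depth = gl$depth,
                 gt = gt, posterior = pmax_post, qual = qual,
                 pass_filter = pass)
}
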