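#' Copying-model parameters for the Li-Stephens HMM
#'
#' The per-interval switch mass is `1 - exp(-rho_scale * d / K)` for genetic
#' distance `d` in Morgans and `K` panel haplotypes, spread uniformly over
#' the haplotypes; `rho_scale` defaults to `4 * ne` with an effective
#' population size of 20,000. `mu` is the miscopying probability of the
#' emission model.
#'
#' @param ne Effective population size (sets `rho_scale = 4 * ne`).
#' @param mu Miscopy probability, in (0, 0.5).
#' @param rho_scale Override for the recombination scaling; > 0.
#' @return A `copying_params` list.
#' @export
copying_params <- function(ne = 20000, mu = 1e-3, rho_scale = 4 * ne) {
  stopifnot(rho_scale > 0, mu > 0, mu < 0.5)
  structure(list(rho_scale = rho_scale, mu = mu), class = "copying_params")
}

#' Impute genotypes with a diploid Li-Stephens HMM
#'
#' Runs exact forward-backward over ordered pairs of panel haplotypes
#' (`K^2` states with factorised transitions) on the target's genotype
#' likelihoods, yielding per-site genotype probabilities `GP`, dosages
#' `DS = GP1 + 2 GP2`, and hard calls (argmax GP, ties to the lowest
#' genotype). With `phase = TRUE` a Viterbi pass over the same state space
#' emits a phased haplotype pair.
#'
#' @param gl Genotype-likelihood tibble from [genotype_likelihoods()]; its
#'   sites must match the panel's exactly.
#' @param panel A `haplotype_panel` (>= 2 haplotypes).
#' @param params A [copying_params()] list.
#' @param phase Also compute a Viterbi-phased haplotype pair.
#' @return An `imputed_genotype` tibble: `chrom`, `pos`, `gp0`, `gp1`,
#'   `gp2`, `ds`, `gt`, `missing` (all `FALSE` here; set by [gp_filter()]),
#'   and with `phase = TRUE` also `hap1`, `hap2`, `phase_consistent`
#'   (`hap1 + hap2 == gt`).
#' @export
impute_genotypes <- function(gl, panel, params = copying_params(),
                             phase = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(params, "copying_params"))
  if (nrow(gl) != length(panel$positions) ||
      !all(gl$pos == panel$positions))
    stop("genotype likelihood sites and panel sites are misaligned")
  if (nrow(panel$alleles) < 2)
    stop("reference panel must contain at least 2 haplotypes")

  loggl <- as.matrix(gl[, c("ll_rr", "ll_ra", "ll_aa")])
  fb <- ls_forward_backward_cpp(panel$alleles, loggl, panel$map$cm,
                                params$rho_scale, params$mu)
  gp <- fb$gp
  out <- tibble::tibble(
    chrom = gl$chrom, pos = gl$pos,
    gp0 = gp[, 1], gp1 = gp[, 2], gp2 = gp[, 3],
    ds = gp[, 2] + 2 * gp[, 3],
    gt = argmax_genotype(gp),
    missing = FALSE)
  if (phase) {
    vit <- ls_viterbi_cpp(panel$alleles, loggl, panel$map$cm,
                          params$rho_scale, params$mu)
    out$hap1 <- vit$haps[, 1]
    out$hap2 <- vit$haps[, 2]
    out$phase_consistent <- (out$hap1 + out$hap2) == out$gt
  }
  attr(out, "loglik") <- fb$loglik
  class(out) <- c("imputed_genotype", class(out))
  out
}

#' Genotype dosage from a genotype-probability triple
#'
#' `DS = GP1 + 2 * GP2`, the expected alternative-allele count in [0, 2].
#'
#' @param gp Numeric length-3 vector or 3-column matrix of genotype
#'   probabilities; each triple must sum to 1 within 1e-6.
#' @return Numeric dosage(s).
#' @export
#' @examples
#' dosage(c(0.1, 0.2, 0.7))  # 1.6
dosage <- function(gp) {
  if (is.null(dim(gp))) gp <- matrix(gp, ncol = 3, byrow = TRUE)
  stopifnot(ncol(gp) == 3)
  if (any(abs(rowSums(gp) - 1) > 1e-6))
    stop("genotype probability triples must sum to 1")
  drop(gp[, 2] + 2 * gp[, 3])
}

#' Hard calls of an imputed genome, honouring the missing flag
#'
#' @param imputed An `imputed_genotype` tibble.
#' @return Integer vector of 0/1/2 with `NA` at filtered (missing) sites.
#' @export
hard_calls <- function(imputed) {
  gt <- imputed$gt
  gt[imputed$missing] <- NA_integer_
  gt
}
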