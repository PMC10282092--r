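#' Simulate site-level read counts with deamination-like error
#'
#' Per-site read totals are Poisson with the requested mean depth. Each read
#' reports the true allele flipped with probability `base_error`; at
#' transition-class sites an additional independent ref/alt flip with
#' probability `deam_error` emulates, at the site-count level, terminal
#' C-to-T deamination damage. The two flips compose to an effective
#' per-read error of `b + d - 2 b d` at transitions and `b` at transversions.
#'
#' @param genome A `true_genome`.
#' @param panel The `haplotype_panel` the genome was drawn from (supplies
#'   positions and transition/transversion site classes), or a tibble with
#'   columns `pos` and `site_class`.
#' @param mean_depth Mean depth of coverage (DoC), > 0.
#' @param base_error Per-read sequencing error, in [0, 0.5).
#' @param deam_error Additional per-read flip probability at transition
#'   sites, in [0, 0.5).
#' @param seed Integer seed.
#' @return A tibble with columns `chrom`, `pos`, `site_class`, `n_ref`,
#'   `n_alt`, carrying the nominal mean depth in attribute `mean_doc`.
#' @export
simulate_reads <- function(genome, panel, mean_depth = 1,
                           base_error = 0.001, deam_error = 0.05,
                           seed = NULL) {
  stopifnot(inherits(genome, "true_genome"), mean_depth > 0,
            base_error >= 0, base_error < 0.5,
            deam_error >= 0, deam_error < 0.5)
  if (inherits(panel, "haplotype_panel")) {
    pos <- panel$positions
    site_class <- panel$site_class
    chrom <- panel$chrom
  } else {
    pos <- panel$pos
    site_class <- panel$site_class
    chrom <- if ("chrom" %in% names(panel)) panel$chrom[1] else "1"
  }
  m <- length(genome$genotype)
  stopifnot(length(pos) == m)

  flip <- ifelse(site_class == "ts",
                 base_error + deam_error - 2 * base_error * deam_error,
                 base_error)
  p_alt_true <- genome$genotype / 2
  p_alt <- p_alt_true * (1 - flip) + (1 - p_alt_true) * flip

  with_seed_if(seed, {
    n <- rpois(m, mean_depth)
    n_alt <- rbinom(m, n, p_alt)
    out <- tibble::tibble(chrom = chrom, pos = pos, site_class = site_class,
                          n_ref = n - n_alt, n_alt = n_alt)
    attr(out, "mean_doc") <- mean_depth
    out
  })
}

#' Mean depth of coverage of a read-count table
#'
#' Returns the nominal mean depth stored by the simulator or downsampler
#' when present, otherwise the empirical mean of `n_ref + n_alt`.
#' @param reads A site read-count tibble.
#' @return A single number.
#' @export
mean_depth_of <- function(reads) {
  doc <- attr(reads, "mean_doc")
  if (!is.null(doc)) doc else mean(reads$n_ref + reads$n_alt)
}

#' Binomially downsample read counts to a target depth
#'
#' Every read is retained independently with probability
#' `target_doc / mean_doc` (binomial thinning per site). Upsampling is
#' refused.
#'
#' @param reads A site read-count tibble (from [simulate_reads()]).
#' @param target_doc Target mean depth, in (0, current mean depth].
#' @param seed Integer seed.
#' @return A read-count tibble with attribute `mean_doc = target_doc`.
#' @export
downsample_reads <- function(reads, target_doc, seed = NULL) {
  doc <- mean_depth_of(reads)
  if (target_doc <= 0) stop("target_doc must be > 0")
  if (target_doc > doc)
    stop("target_doc (", target_doc, ") exceeds current mean depth (",
         doc, "): no upsampling")
  p <- target_doc / doc
  with_seed_if(seed, {
    out <- reads
    if (p < 1) {
      out$n_ref <- rbinom(nrow(reads), reads$n_ref, p)
      out$n_alt <- rbinom(nrow(reads), reads$n_alt, p)
    }
    attr(out, "mean_doc") <- target_doc
    out
  })
}
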