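#' Mendel error rate of an imputed trio
#'
#' A site is a Mendel error when no assignment of one allele from each
#' parent can produce the child's genotype. Errors are counted on the
#' imputed genotypes; the denominator excludes sites at which all three
#' *truth* (non-imputed) genotypes are homozygous reference, and sites
#' where any imputed genotype is missing.
#'
#' @param child,mother,father Imputed genotypes (0/1/2/`NA`) of the trio.
#' @param truth_child,truth_mother,truth_father Truth genotypes used for
#'   the all-reference exclusion.
#' @param chrom Optional chromosome label per site for per-chromosome
#'   rates.
#' @return List with `rate`, `n_errors`, `n_sites`, and (when `chrom` is
#'   given) `by_chrom` tibble.
#' @export
mendel_error_rate <- function(child, mother, father,
                              truth_child, truth_mother, truth_father,
                              chrom = NULL) {
  n <- length(child)
  stopifnot(length(mother) == n, length(father) == n,
            length(truth_child) == n, length(truth_mother) == n,
            length(truth_father) == n)
  all_ref <- truth_child == 0L & truth_mother == 0L & truth_father == 0L
  use <- !is.na(child) & !is.na(mother) & !is.na(father) &
    !is.na(all_ref) & !all_ref
  err <- use & mendel_violation(child, mother, father)
  rate_of <- function(e, u) if (sum(u) == 0) NA_real_ else sum(e) / sum(u)
  out <- list(rate = rate_of(err, use), n_errors = sum(err),
              n_sites = sum(use))
  if (!is.null(chrom)) {
    out$by_chrom <- tibble::tibble(chrom = chrom, err = err, use = use) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(n_errors = sum(.data$err), n_sites = sum(.data$use),
                       rate = rate_of(.data$err, .data$use),
                       .groups = "drop")
  }
  out
}

# TRUE where (mother, father) cannot transmit child's genotype
mendel_violation <- function(child, mother, father) {
  can_give <- function(g) cbind(g != 2L, g != 0L)  # can transmit 0 / 1
  cm <- can_give(mother)
  cf <- can_give(father)
  ok <- (child == 0L & cm[, 1] & cf[, 1]) |
    (child == 1L & ((cm[, 1] & cf[, 2]) | (cm[, 2] & cf[, 1]))) |
    (child == 2L & cm[, 2] & cf[, 2])
  !ok
}

#' Trio-derived phase of the child genome
#'
#' At child-heterozygous, Mendel-consistent sites the parental origin of
#' each allele is deduced when exactly one assignment of one allele per
#' parent is compatible with the parental genotypes; sites with both
#' parents heterozygous are unresolvable. Homozygous child sites and
#' Mendel-inconsistent sites are flagged unresolvable too (the latter also
#' flagged inconsistent).
#'
#' @param child,mother,father Truth genotypes (0/1/2) of the trio.
#' @return A `trio_phase` tibble with `resolvable`, `pat`, `mat` (the
#'   paternal/maternal allele at resolvable sites, `NA` elsewhere) and
#'   `inconsistent`.
#' @export
trio_phase <- function(child, mother, father) {
  n <- length(child)
  stopifnot(length(mother) == n, length(father) == n)
  bad <- mendel_violation(child, mother, father)
  het <- !is.na(child) & child == 1L
  both_het <- mother == 1L & father == 1L
  resolvable <- het & !bad & !both_het &
    !is.na(mother) & !is.na(father) & !both_het
  # at a resolvable child het, the parent that cannot transmit the alt
  # allele fixes the assignment (and vice versa)
  pat <- rep(NA_integer_, n)
  mat <- rep(NA_integer_, n)
  idx <- which(resolvable)
  for (i in idx) {
    f <- father[i]
    m <- mother[i]
    if (f == 0L || m == 2L) {          # father gives 0, mother gives 1
      pat[i] <- 0L; mat[i] <- 1L
    } else if (f == 2L || m == 0L) {   # father gives 1, mother gives 0
      pat[i] <- 1L; mat[i] <- 0L
    } else {                           # one parent het, ambiguous? no:
      # remaining case is exactly one parent het and the other hom,
      # which the two branches above already cover; both het excluded
      resolvable[i] <- FALSE
    }
  }
  structure(tibble::tibble(resolvable = resolvable, pat = pat, mat = mat,
                           inconsistent = bad),
            class = c("trio_phase", "tbl_df", "tbl", "data.frame"))
}

#' Switch error rate against a trio-derived phase
#'
#' Over consecutive pairs of trio-resolvable, imputed-heterozygous sites,
#' counts pairs where the imputed phase orientation relative to the
#' trio-derived orientation flips. The rate is invariant to swapping the
#' two imputed haplotypes wholesale.
#'
#' @param hap1,hap2 Imputed phased haplotypes of the child (0/1 per site).
#' @param phase_ref A `trio_phase` tibble from [trio_phase()].
#' @return List with `rate` (`NA` when fewer than two usable sites),
#'   `n_switches`, `n_pairs`.
#' @export
switch_error_rate <- function(hap1, hap2, phase_ref) {
  n <- length(hap1)
  stopifnot(length(hap2) == n, nrow(phase_ref) == n)
  use <- phase_ref$resolvable & !is.na(hap1) & !is.na(hap2) &
    (hap1 + hap2) == 1L
  if (sum(use) < 2)
    return(list(rate = NA_real_, n_switches = 0L, n_pairs = 0L))
  # orientation: does hap1 carry the paternal allele?
  ori <- hap1[use] == phase_ref$pat[use]
  flips <- ori[-1] != ori[-length(ori)]
  list(rate = mean(flips), n_switches = sum(flips),
       n_pairs = length(flips))
}
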