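#' Default minor-allele-frequency bin edges
#'
#' Strata used for accuracy-by-MAF reporting; the edges cover the
#' conventional "rare" (0.1-1%) through "common" (>= 10-20%) ranges.
#' @return Numeric vector of bin edges.
#' @export
maf_bin_edges <- function() c(0.001, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5)

#' High-confidence validation site mask
#'
#' Marks sites usable for concordance evaluation: covered by at least
#' `min_reads` reads and with a genotype posterior of at least
#' `min_posterior`. This evaluation-time mask is independent of the
#' validation call filter (`pass_filter`).
#'
#' @param validation A validation-call tibble from [call_validation()].
#' @param min_reads Minimum read depth (default 8).
#' @param min_posterior Minimum genotype posterior (default 0.9999).
#' @return Logical vector, `TRUE` at usable sites.
#' @export
validation_mask <- function(validation, min_reads = 8, min_posterior = 0.9999) {
  validation$depth >= min_reads &
    !is.na(validation$gt) &
    validation$posterior >= min_posterior
}

#' MAF-binned squared dosage correlation
#'
#' Per MAF bin, the squared Pearson correlation between imputed dosage and
#' validation genotype (0/1/2). Bins where either vector has zero variance
#' (or no sites) are flagged undefined rather than reported as 0.
#'
#' @param data Tibble with columns `ds` (imputed dosage), `gt` (validation
#'   genotype) and `maf`, already restricted to evaluation sites.
#' @param bin_edges Bin edges; sites with `maf <= min(bin_edges)` or
#'   `maf > max(bin_edges)` are not binned.
#' @return Tibble with `bin`, `n`, `r2`, `defined`.
#' @export
maf_bin_r2 <- function(data, bin_edges = maf_bin_edges()) {
  stopifnot(all(c("ds", "gt", "maf") %in% names(data)))
  bins <- cut(data$maf, breaks = bin_edges, include.lowest = FALSE)
  lv <- levels(bins)
  out <- purrr::map_dfr(lv, function(b) {
    d <- data[!is.na(bins) & bins == b & !is.na(data$ds) & !is.na(data$gt), ]
    if (nrow(d) < 2 || sd(d$ds) == 0 || sd(d$gt) == 0) {
      tibble::tibble(bin = b, n = nrow(d), r2 = NA_real_, defined = FALSE)
    } else {
      tibble::tibble(bin = b, n = nrow(d),
                     r2 = cor(d$ds, d$gt)^2, defined = TRUE)
    }
  })
  out
}

#' Genotype discordance by validation class
#'
#' Tallies matches and errors between imputed hard calls and validation
#' genotypes, classed by the validation genotype (RR = homozygous
#' reference, RA = heterozygous, AA = homozygous alternative). Missing
#' entries on either side are excluded from all denominators and reported
#' separately.
#'
#' @param imputed Integer vector of imputed hard calls (0/1/2, `NA`
#'   missing).
#' @param validation Integer vector of validation genotypes (0/1/2, `NA`
#'   missing).
#' @return A `discordance_counts` list: `counts` (named `m_rr`, `m_ra`,
#'   `m_aa`, `e_rr`, `e_ra`, `e_aa`), `rates` tibble (per-class error rate
#'   `e_X / (e_X + m_X)`), `n_missing`, `n_used`.
#' @export
discordance <- function(imputed, validation) {
  stopifnot(length(imputed) == length(validation))
  use <- !is.na(imputed) & !is.na(validation)
  imp <- imputed[use]
  val <- validation[use]
  match <- imp == val
  cls <- c("rr", "ra", "aa")
  counts <- c(
    m_rr = sum(match & val == 0L), m_ra = sum(match & val == 1L),
    m_aa = sum(match & val == 2L),
    e_rr = sum(!match & val == 0L), e_ra = sum(!match & val == 1L),
    e_aa = sum(!match & val == 2L))
  rates <- tibble::tibble(
    class = toupper(cls),
    n = unname(counts[paste0("m_", cls)] + counts[paste0("e_", cls)]),
    error_rate = ifelse(.data$n > 0,
                        unname(counts[paste0("e_", cls)]) / .data$n,
                        NA_real_))
  structure(list(counts = counts, rates = rates,
                 n_missing = sum(!use), n_used = sum(use)),
            class = "discordance_counts")
}

#' @method print discordance_counts
#' @export
print.discordance_counts <- function(x, ...) {
  cat("<discordance_counts> n =", x$n_used, "(missing", x$n_missing, ")\n")
  print(x$rates)
  cat("NRD:", format(nrd(x), digits = 4), "\n")
  invisible(x)
}

#' Non-reference discordance
#'
#' `NRD = (e_RR + e_RA + e_AA) / (m_RA + m_AA + e_RR + e_RA + e_AA)`:
#' the error rate excluding correctly imputed homozygous-reference sites
#' from the denominator, which up-weights errors at alternative-allele
#' sites.
#'
#' @param x A `discordance_counts` object or a named count vector with
#'   elements `m_ra`, `m_aa`, `e_rr`, `e_ra`, `e_aa`.
#' @return NRD in [0, 1], or `NA` when the denominator is zero.
#' @export
#' @examples
#' nrd(c(m_rr = 100, m_ra = 10, m_aa = 6, e_rr = 1, e_ra = 2, e_aa = 1)) # 0.2
nrd <- function(x) {
  counts <- if (inherits(x, "discordance_counts")) x$counts else x
  err <- counts[["e_rr"]] + counts[["e_ra"]] + counts[["e_aa"]]
  den <- counts[["m_ra"]] + counts[["m_aa"]] + err
  if (den == 0) NA_real_ else err / den
}

#' Filter imputed genotypes on maximum genotype probability
#'
#' Sites whose best genotype probability falls below `threshold` are set to
#' missing; retained-site sets are nested across increasing thresholds.
#'
#' @param imputed An `imputed_genotype` tibble.
#' @param threshold GP threshold in [0, 1] (the conventional working range
#'   is 0.70-0.99; 0.80 is the usual default for downstream analyses).
#' @return The tibble with its `missing` flag updated.
#' @export
gp_filter <- function(imputed, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  gpmax <- pmax(imputed$gp0, imputed$gp1, imputed$gp2)
  imputed$missing <- imputed$missing | gpmax < threshold
  imputed
}

#' Heterozygote retention of a GP filter
#'
#' The proportion of sites correctly imputed as heterozygous before
#' filtering that survive the filter.
#'
#' @param pre,post The imputed tibble before and after filtering (same
#'   sites).
#' @param validation Integer validation genotypes (0/1/2/`NA`).
#' @return Proportion in [0, 1], or `NA` when no correct heterozygotes
#'   exist pre-filter.
#' @export
het_retention <- function(pre, post, validation) {
  stopifnot(nrow(pre) == nrow(post), nrow(pre) == length(validation))
  correct_het <- !pre$missing & pre$gt == 1L &
    !is.na(validation) & validation == 1L
  if (!any(correct_het)) return(NA_real_)
  sum(correct_het & !post$missing) / sum(correct_het)
}

#' Full concordance report for one imputed genome
#'
#' Combines the high-confidence validation mask, MAF-binned dosage
#' r-squared, per-class discordance and NRD into one report.
#'
#' @param imputed An `imputed_genotype` tibble.
#' @param validation A validation-call tibble from [call_validation()]
#'   covering the same sites.
#' @param maf Per-site minor allele frequency (typically [panel_maf()]).
#' @param bin_edges MAF bin edges.
#' @param mask Optional additional logical site mask (e.g. a capture
#'   subset); combined with [validation_mask()].
#' @param min_reads,min_posterior Passed to [validation_mask()].
#' @return A `concordance_report`: list with `by_bin`, `discordance`,
#'   `nrd`, `r2_pooled`, `n_sites`, `n_eval`.
#' @export
concordance_report <- function(imputed, validation, maf,
                               bin_edges = maf_bin_edges(), mask = NULL,
                               min_reads = 8, min_posterior = 0.9999) {
  stopifnot(nrow(imputed) == nrow(validation),
            nrow(imputed) == length(maf))
  keep <- validation_mask(validation, min_reads, min_posterior)
  if (!is.null(mask)) keep <- keep & mask
  data <- tibble::tibble(
    ds = ifelse(imputed$missing, NA_real_, imputed$ds),
    gt = validation$gt, maf = maf)[keep, ]
  by_bin <- maf_bin_r2(data, bin_edges)
  ok <- !is.na(data$ds) & !is.na(data$gt)
  r2_pooled <- if (sum(ok) >= 2 && sd(data$ds[ok]) > 0 && sd(data$gt[ok]) > 0)
    cor(data$ds[ok], data$gt[ok])^2 else NA_real_
  disc <- discordance(hard_calls(imputed)[keep], validation$gt[keep])
  structure(list(by_bin = by_bin, discordance = disc, nrd = nrd(disc),
                 r2_pooled = r2_pooled,
                 n_sites = nrow(imputed), n_eval = sum(keep)),
            class = "concordance_report")
}

#' @method print concordance_report
#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_eval, "/", x$n_sites,
      " evaluation sites\n", sep = "")
  cat("pooled r2:", format(x$r2_pooled, digits = 4),
      " NRD:", format(x$nrd, digits = 4), "\n")
  print(x$by_bin)
  invisible(x)
}

#' Concordance inside and outside a site mask
#'
#' Computes the full concordance stack separately for sites inside a mask
#' (for example, capture-target sites) and its complement.
#'
#' @inheritParams concordance_report
#' @param mask Logical vector over the site universe, `TRUE` inside.
#' @return List with elements `inside` and `outside`, each a
#'   `concordance_report`.
#' @export
subset_eval <- function(imputed, validation, maf, mask,
                        bin_edges = maf_bin_edges(), ...) {
  stopifnot(length(mask) == nrow(imputed))
  list(inside = concordance_report(imputed, validation, maf,
                                   bin_edges = bin_edges, mask = mask, ...),
       outside = concordance_report(imputed, validation, maf,
                                    bin_edges = bin_edges, mask = !mask, ...))
}
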