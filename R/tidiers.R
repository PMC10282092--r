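#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance report
#'
#' One row per MAF bin with the bin's site count and squared dosage
#' correlation.
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.concordance_report <- function(x, ...) x$by_bin

#' One-row summary of a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A tibble with `n_eval`, `r2_pooled`, `nrd` and the per-class
#'   error rates.
#' @export
glance.concordance_report <- function(x, ...) {
  r <- x$discordance$rates
  tibble::tibble(n_eval = x$n_eval, r2_pooled = x$r2_pooled, nrd = x$nrd,
                 err_rr = r$error_rate[1], err_ra = r$error_rate[2],
                 err_aa = r$error_rate[3],
                 n_missing = x$discordance$n_missing)
}

#' Tidy per-class discordance counts
#'
#' @param x A `discordance_counts` object.
#' @param ... Unused.
#' @return Tibble with one row per validation genotype class.
#' @export
tidy.discordance_counts <- function(x, ...) x$rates

#' One-row summary of discordance counts
#'
#' @param x A `discordance_counts` object.
#' @param ... Unused.
#' @return Tibble with totals and NRD.
#' @export
glance.discordance_counts <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_missing = x$n_missing,
                 n_errors = sum(x$counts[c("e_rr", "e_ra", "e_aa")]),
                 nrd = nrd(x))
}

#' Tidy a pipeline result
#'
#' The per-depth concordance and trio-rate tables joined on depth.
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble, one row per depth.
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::left_join(x$concordance, x$trio, by = "depth")
}

#' One-row summary of a pipeline run
#'
#' Headline numbers at the depth closest to 1x.
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.pipeline_result <- function(x, ...) {
  i <- which.min(abs(x$concordance$depth - 1))
  tibble::tibble(depth = x$concordance$depth[i],
                 nrd = x$concordance$nrd[i],
                 r2_pooled = x$concordance$r2_pooled[i],
                 mendel_rate = x$trio$mendel_rate[i],
                 switch_rate = x$trio$switch_rate[i],
                 depth_nrd_rho = x$depth_nrd_test$rho,
                 config_hash = x$config_hash)
}
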