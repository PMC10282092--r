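#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow the PLINK `--homozyg` window semantics: 50-SNP sliding
#' windows tolerating at most 1 heterozygote and 5 missing genotypes; a SNP
#' is run-eligible when at least 5% of the windows overlapping it are
#' homozygous; candidate runs are split at inter-SNP gaps above 100 kb and
#' kept when they contain at least 50 SNPs, span at least 500 kb, and have
#' at most 50 kb per SNP.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het Maximum heterozygotes for a homozygous window.
#' @param window_missing Maximum missing genotypes per window.
#' @param window_threshold Minimum homozygous-window hit rate per SNP.
#' @param min_snp Minimum SNPs per segment.
#' @param min_kb Minimum segment span (kb).
#' @param max_gap_kb Split runs at inter-SNP gaps larger than this (kb).
#' @param max_density_kb_per_snp Maximum kb per SNP within a segment.
#' @return A `roh_params` list.
#' @export
roh_params <- function(window_snp = 50, window_het = 1, window_missing = 5,
                       window_threshold = 0.05, min_snp = 50, min_kb = 500,
                       max_gap_kb = 100, max_density_kb_per_snp = 50) {
  structure(list(window_snp = window_snp, window_het = window_het,
                 window_missing = window_missing,
                 window_threshold = window_threshold, min_snp = min_snp,
                 min_kb = min_kb, max_gap_kb = max_gap_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH caller over hard genotypes. Windows of
#' `window_snp` consecutive SNPs are homozygous when they contain at most
#' `window_het` heterozygotes and `window_missing` missing calls; each SNP's
#' hit rate is the fraction of overlapping windows that are homozygous, and
#' SNPs with a hit rate of at least `window_threshold` are run-eligible.
#' Maximal runs of eligible SNPs are split at gaps above `max_gap_kb` and
#' then filtered on SNP count, span and density.
#'
#' @param data Tibble with columns `chrom`, `pos` (ascending within
#'   chromosome), `gt` (0/1/2 or `NA`).
#' @param params A [roh_params()] list.
#' @return A `roh_segments` tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `length_kb`.
#' @export
call_roh <- function(data, params = roh_params()) {
  stopifnot(all(c("chrom", "pos", "gt") %in% names(data)),
            inherits(params, "roh_params"))
  out <- data |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(~ roh_one_chrom(.x$pos, .x$gt, .y$chrom, params)) |>
    dplyr::bind_rows()
  if (nrow(out) == 0)
    out <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_snps = integer(0),
                          length_kb = numeric(0))
  class(out) <- c("roh_segments", class(out))
  out
}

roh_one_chrom <- function(pos, gt, chrom, p) {
  n <- length(pos)
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be strictly increasing within a chromosome")
  w <- p$window_snp
  if (n < 1) return(NULL)
  eligible <- logical(n)
  if (n >= w) {
    het <- as.integer(!is.na(gt) & gt == 1L)
    mis <- as.integer(is.na(gt))
    ch <- c(0L, cumsum(het))
    cm <- c(0L, cumsum(mis))
    starts <- seq_len(n - w + 1L)
    hom_win <- (ch[starts + w] - ch[starts]) <= p$window_het &
      (cm[starts + w] - cm[starts]) <= p$window_missing
    # hit rate per SNP: homozygous windows overlapping / windows overlapping
    cw <- c(0, cumsum(as.numeric(hom_win)))
    lo <- pmax(1L, seq_len(n) - w + 1L)
    hi <- pmin(seq_len(n), n - w + 1L)
    n_win <- hi - lo + 1L
    n_hom <- cw[hi + 1L] - cw[lo]
    eligible <- n_win > 0 & (n_hom / pmax(n_win, 1L)) >= p$window_threshold
  }
  if (!any(eligible)) return(NULL)
  # maximal runs of eligible SNPs, split at large gaps
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    gap_break <- which(diff(pos[idx]) > p$max_gap_kb * 1000)
    piece_start <- c(1L, gap_break + 1L)
    piece_end <- c(gap_break, length(idx))
    for (j in seq_along(piece_start)) {
      ii <- idx[piece_start[j]:piece_end[j]]
      n_snps <- length(ii)
      length_kb <- (pos[ii[n_snps]] - pos[ii[1]]) / 1000
      if (n_snps >= p$min_snp && length_kb >= p$min_kb &&
          length_kb / n_snps <= p$max_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <-
          tibble::tibble(chrom = chrom, start = pos[ii[1]],
                         end = pos[ii[n_snps]], n_snps = n_snps,
                         length_kb = length_kb)
      }
    }
  }
  if (length(segs) == 0) NULL else dplyr::bind_rows(segs)
}

#' Summarise ROH segments by length class
#'
#' Totals segment lengths per user-defined class and for the long/short
#' dichotomy at `long_short_split_mb` (conventionally 1.6 Mb).
#'
#' @param segments A `roh_segments` tibble.
#' @param class_edges_mb Interior class edges in Mb.
#' @param long_short_split_mb Split point for the long/short totals.
#' @return List with `by_class` tibble (`class`, `n`, `total_mb`),
#'   `short_mb` (< split), `long_mb` (>= split), `total_mb`.
#' @export
roh_summary <- function(segments, class_edges_mb = c(0.5, 1, 1.5, 2, 4, 8),
                        long_short_split_mb = 1.6) {
  mb <- segments$length_kb / 1000
  edges <- sort(unique(c(0, class_edges_mb, Inf)))
  cls <- cut(mb, breaks = edges, include.lowest = TRUE, right = FALSE)
  by_class <- tibble::tibble(class = levels(cls)) |>
    dplyr::left_join(
      tibble::tibble(class = as.character(cls), mb = mb) |>
        dplyr::group_by(.data$class) |>
        dplyr::summarise(n = dplyr::n(), total_mb = sum(.data$mb),
                         .groups = "drop"),
      by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  total_mb = dplyr::coalesce(.data$total_mb, 0))
  list(by_class = by_class,
       short_mb = sum(mb[mb < long_short_split_mb]),
       long_mb = sum(mb[mb >= long_short_split_mb]),
       total_mb = sum(mb))
}
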