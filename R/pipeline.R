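#' Configuration for the end-to-end evaluation pipeline
#'
#' Collects the study conditions: panel composition, depth grid, error
#' rates, copying-model parameters, and the evaluation filters. All
#' randomness descends from `seed` through named per-stage sub-streams.
#'
#' @param seed Master seed.
#' @param n_haps,divergence,n_sites,region_length,n_founders Passed to
#'   [simulate_panel()]; the default panel has 160 haplotypes in the main
#'   population and 40 in a diverged one (Balding-Nichols F = 0.1).
#' @param depth_grid Coverages to downsample to (default 0.1, 0.25, 0.5,
#'   0.75, 1.0, 2.0x).
#' @param high_depth Depth of the high-coverage "truth" sequencing run
#'   that yields validation calls.
#' @param base_error,deam_error Read-simulation error rates.
#' @param gl_error Per-read error assumed by the likelihood model.
#' @param qual_min Validation QUAL threshold.
#' @param gp_threshold Post-imputation GP filter.
#' @param maf_min MAF filter for downstream analyses.
#' @param bin_edges MAF bin edges for accuracy reporting.
#' @param ne,mu Copying-model parameters ([copying_params()]).
#' @param roh ROH parameters ([roh_params()]).
#' @param n_components Principal components for the projection analysis.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_haps = c(main = 160, diverged = 40),
                            divergence = c(main = 0, diverged = 0.1),
                            n_sites = 5000,
                            region_length = 1e7,
                            n_founders = 16,
                            depth_grid = c(0.1, 0.25, 0.5, 0.75, 1, 2),
                            high_depth = 30,
                            base_error = 0.001,
                            deam_error = 0.05,
                            gl_error = 0.01,
                            qual_min = 30,
                            gp_threshold = 0.8,
                            maf_min = 0.05,
                            bin_edges = maf_bin_edges(),
                            ne = 20000,
                            mu = 1e-3,
                            roh = roh_params(),
                            n_components = 10) {
  stopifnot(all(depth_grid > 0), !is.unsorted(depth_grid),
            gp_threshold >= 0, gp_threshold <= 1,
            maf_min >= 0, maf_min <= 0.5,
            all(depth_grid <= high_depth))
  cfg <- list(seed = seed, n_haps = n_haps, divergence = divergence,
              n_sites = n_sites, region_length = region_length,
              n_founders = n_founders, depth_grid = depth_grid,
              high_depth = high_depth, base_error = base_error,
              deam_error = deam_error, gl_error = gl_error,
              qual_min = qual_min, gp_threshold = gp_threshold,
              maf_min = maf_min, bin_edges = bin_edges, ne = ne, mu = mu,
              roh = roh, n_components = n_components)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be overridden from a YAML
#' document; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in c("n_haps", "divergence"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  if (!is.null(vals$roh)) vals$roh <- do.call(roh_params, vals$roh)
  do.call(pipeline_config, vals)
}

#' Run the full simulation-imputation-evaluation pipeline
#'
#' Simulates a panel, one held-out target genome and one trio; sequences
#' them at high coverage for validation calls; downsamples across the
#' depth grid; imputes every genome at every depth with the Li-Stephens
#' HMM; and evaluates concordance (per depth), trio Mendel/switch rates,
#' the GP-filter trade-off, PCA projection shifts and ROH agreement at
#' 1x. Deterministic: the same configuration yields byte-identical summary
#' tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every summary table is
#'   written there as tab-separated text stamped with the configuration
#'   hash.
#' @return A `pipeline_result` list of summary tibbles (`concordance`,
#'   `r2_by_bin`, `trio`, `gp_tradeoff`, `pca_shift`, `roh`,
#'   `depth_nrd_test`), plus `config` and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 10,
                        c("panel", "target", "trio", "reads_target",
                          "reads_mother", "reads_father", "reads_child",
                          "downsample", "spearman", "unused"))

  panel0 <- simulate_panel(n_haps = config$n_haps, n_sites = config$n_sites,
                           region_length = config$region_length,
                           divergence = config$divergence,
                           n_founders = config$n_founders,
                           seed = seeds[["panel"]])
  main_pop <- names(config$n_haps)[1]
  target <- sample_diploid(panel0, main_pop, seed = seeds[["target"]],
                           exclude_from_panel = TRUE)
  trio <- simulate_trio(target$panel, main_pop, seed = seeds[["trio"]],
                        exclude_from_panel = TRUE)
  ref_panel <- trio$panel
  params <- copying_params(ne = config$ne, mu = config$mu)
  maf <- panel0$maf
  # evaluation universe: sites still segregating in the imputation panel
  seg <- panel_maf(ref_panel) > 0

  genomes <- list(target = target$genome, mother = trio$mother,
                  father = trio$father, child = trio$child)
  reads_hc <- purrr::imap(genomes, function(g, nm)
    simulate_reads(g, panel0, mean_depth = config$high_depth,
                   base_error = config$base_error,
                   deam_error = config$deam_error,
                   seed = seeds[[paste0("reads_", nm)]]))
  validation <- purrr::map(reads_hc, function(r)
    call_validation(genotype_likelihoods(r, config$gl_error),
                    mean_doc = config$high_depth,
                    qual_min = config$qual_min))

  ds_seeds <- derive_seeds(seeds[["downsample"]],
                           length(config$depth_grid) * length(genomes))
  dim(ds_seeds) <- c(length(config$depth_grid), length(genomes))

  conc_rows <- list()
  bin_rows <- list()
  trio_rows <- list()
  gp_rows <- list()
  imputed_1x <- list()
  thresholds <- c(0.7, 0.8, 0.9, 0.95, 0.99)

  for (di in seq_along(config$depth_grid)) {
    depth <- config$depth_grid[di]
    imp <- list()
    for (gi in seq_along(genomes)) {
      nm <- names(genomes)[gi]
      reads <- downsample_reads(reads_hc[[nm]], depth,
                                seed = ds_seeds[di, gi])
      gl <- genotype_likelihoods(reads, config$gl_error)
      imp[[nm]] <- impute_genotypes(gl, ref_panel, params,
                                    phase = (nm == "child"))
    }
    if (depth == 1) imputed_1x <- imp

    filt <- gp_filter(imp$target, config$gp_threshold)
    rep_t <- concordance_report(filt, validation$target, maf,
                                bin_edges = config$bin_edges, mask = seg)
    conc_rows[[di]] <- tibble::tibble(
      depth = depth, n_eval = rep_t$n_eval, nrd = rep_t$nrd,
      r2_pooled = rep_t$r2_pooled,
      err_rr = rep_t$discordance$rates$error_rate[1],
      err_ra = rep_t$discordance$rates$error_rate[2],
      err_aa = rep_t$discordance$rates$error_rate[3])
    bin_rows[[di]] <- dplyr::mutate(rep_t$by_bin, depth = depth,
                                    .before = 1)

    # GP-filter trade-off on the unfiltered target imputation
    gp_rows[[di]] <- purrr::map_dfr(thresholds, function(th) {
      f <- gp_filter(imp$target, th)
      d <- discordance(hard_calls(f)[seg], validation$target$gt[seg])
      tibble::tibble(depth = depth, threshold = th,
                     discordance = 1 - sum(d$counts[1:3]) / d$n_used,
                     nrd = nrd(d),
                     het_retention = het_retention(imp$target[seg, ],
                                                   f[seg, ],
                                                   validation$target$gt[seg]))
    })

    tphase <- trio_phase(trio$child$genotype, trio$mother$genotype,
                         trio$father$genotype)
    mer <- mendel_error_rate(imp$child$gt, imp$mother$gt, imp$father$gt,
                             trio$child$genotype, trio$mother$genotype,
                             trio$father$genotype)
    ser <- switch_error_rate(imp$child$hap1, imp$child$hap2, tphase)
    trio_rows[[di]] <- tibble::tibble(
      depth = depth, mendel_rate = mer$rate, mendel_n = mer$n_sites,
      switch_rate = ser$rate, switch_pairs = ser$n_pairs)
  }

  # downstream comparisons at 1x (or the closest depth in the grid)
  d1 <- which.min(abs(config$depth_grid - 1))
  keep_maf <- maf >= config$maf_min & seg
  pca_shift <- roh_tbl <- NULL
  if (length(imputed_1x) == 0) {
    depth <- config$depth_grid[d1]
    for (gi in seq_along(genomes)) {
      nm <- names(genomes)[gi]
      reads <- downsample_reads(reads_hc[[nm]], depth,
                                seed = ds_seeds[d1, gi])
      gl <- genotype_likelihoods(reads, config$gl_error)
      imputed_1x[[nm]] <- impute_genotypes(gl, ref_panel, params,
                                           phase = (nm == "child"))
    }
  }
  imp_gts <- purrr::map(imputed_1x, function(x)
    hard_calls(gp_filter(x, config$gp_threshold)))
  val_gts <- purrr::map(validation, function(v)
    ifelse(v$pass_filter, v$gt, NA_integer_))
  proj <- pca_project(ref_panel,
                      targets = c(setNames(purrr::map(imp_gts, ~
                        ifelse(keep_maf, .x, NA_integer_)),
                        paste0("imp_", names(imp_gts))),
                        setNames(purrr::map(val_gts, ~
                        ifelse(keep_maf, .x, NA_integer_)),
                        paste0("val_", names(val_gts)))),
                      n_components = config$n_components)
  ts <- proj$target_scores
  imp_coord <- as_coord_matrix(ts[grepl("^imp_", ts$id), ])
  val_coord <- as_coord_matrix(ts[grepl("^val_", ts$id), ])
  pca_shift <- coordinate_shift_test(imp_coord, val_coord, proj$score_sd)

  roh_in <- function(gt) tibble::tibble(chrom = panel0$chrom,
                                        pos = panel0$positions, gt = gt)
  roh_imp <- call_roh(roh_in(imp_gts$target), config$roh)
  roh_val <- call_roh(roh_in(val_gts$target), config$roh)
  roh_tbl <- tibble::tibble(
    dataset = c("imputed_1x", "validation"),
    n_segments = c(nrow(roh_imp), nrow(roh_val)),
    total_mb = c(roh_summary(roh_imp)$total_mb,
                 roh_summary(roh_val)$total_mb),
    long_mb = c(roh_summary(roh_imp)$long_mb,
                roh_summary(roh_val)$long_mb),
    short_mb = c(roh_summary(roh_imp)$short_mb,
                 roh_summary(roh_val)$short_mb))

  concordance <- dplyr::bind_rows(conc_rows)
  sp <- if (length(config$depth_grid) >= 3) {
    spearman_perm_test(concordance$depth, concordance$nrd,
                       n_perm = 10000, seed = seeds[["spearman"]])
  } else {
    list(rho = NA_real_, p_value = NA_real_, n_perm = 0L)
  }

  result <- structure(
    list(concordance = concordance,
         r2_by_bin = dplyr::bind_rows(bin_rows),
         trio = dplyr::bind_rows(trio_rows),
         gp_tradeoff = dplyr::bind_rows(gp_rows),
         pca_shift = pca_shift,
         roh = roh_tbl,
         depth_nrd_test = tibble::tibble(rho = sp$rho,
                                         p_value = sp$p_value,
                                         n_perm = sp$n_perm),
         config = config,
         config_hash = rlang::hash(unclass(config))),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> config", x$config_hash, "\n")
  cat("concordance by depth:\n")
  print(x$concordance)
  cat("trio rates by depth:\n")
  print(x$trio)
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("concordance", "r2_by_bin", "trio", "gp_tradeoff",
              "pca_shift", "roh", "depth_nrd_test")
  for (nm in tables) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", result$config_hash), con)
    write.table(as.data.frame(result[[nm]]), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(out_dir)
}
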