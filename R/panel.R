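#' Simulate a phased multi-population reference panel
#'
#' Generates a phased haplotype panel over ordered biallelic sites, together
#' with a (uniform-rate) recombination map. Each population descends from a
#' small set of founder haplotypes: founder allele frequencies follow a
#' heavy-tailed (Beta) frequency spectrum, optionally perturbed by a
#' Balding-Nichols drift draw so that one or more populations are *diverged*
#' from the base frequencies, emulating ancestries that are underrepresented
#' in real reference panels. Panel haplotypes are recombinant mosaics of
#' their population's founders with a small per-site mutation rate, so panel
#' members share haplotype segments and held-out targets remain imputable.
#'
#' Only sites that are polymorphic across the whole panel are retained, so
#' the returned panel can have fewer sites than requested.
#'
#' @param n_haps Named integer vector: haplotypes per population (each >= 4).
#' @param n_sites Number of candidate biallelic sites (>= 2).
#' @param region_length Region length in base pairs.
#' @param divergence Named numeric vector, one Balding-Nichols F per
#'   population (0 = no drift from the base frequencies).
#' @param n_founders Founder haplotypes per population.
#' @param founder_generations Expected crossovers per panel haplotype equal
#'   `founder_generations` times the genetic map length in Morgans.
#' @param mutation_rate Per-site allele flip probability on panel haplotypes.
#' @param ts_prob Probability that a site is a transition (A/G here); the
#'   default 2/3 mimics the genome-wide transition excess.
#' @param maf_shape Shape parameter of the symmetric Beta frequency spectrum.
#' @param cm_per_mb Uniform recombination rate (centimorgans per megabase).
#' @param chrom Chromosome name used in coordinates and VCF output.
#' @param seed Integer seed; the panel is a pure function of the arguments
#'   and the seed.
#'
#' @return A `haplotype_panel`: list with `positions` (1-based bp, strictly
#'   increasing), `alleles` (haplotype x site 0/1 matrix), `pop` (population
#'   label per haplotype), `site_class` (`"ts"`/`"tv"` per site), `maf`
#'   (panel-wide minor allele frequency), `map` (tibble with `pos`, `cm`),
#'   and `chrom`.
#' @export
#' @examples
#' p <- simulate_panel(n_haps = c(A = 8, B = 6), n_sites = 50,
#'                     region_length = 1e6, divergence = c(A = 0, B = 0.1),
#'                     seed = 1)
#' p$maf[1:5]
simulate_panel <- function(n_haps = c(main = 160, diverged = 40),
                           n_sites = 5000,
                           region_length = 1e7,
                           divergence = c(main = 0, diverged = 0.1),
                           n_founders = 16,
                           founder_generations = 50,
                           mutation_rate = 0.005,
                           ts_prob = 2 / 3,
                           maf_shape = 0.2,
                           cm_per_mb = 1,
                           chrom = "1",
                           seed = NULL) {
  stopifnot(length(n_haps) >= 1, all(n_haps >= 4), n_sites >= 2,
            region_length > n_sites)
  if (is.null(names(n_haps))) names(n_haps) <- paste0("pop", seq_along(n_haps))
  divergence <- setNames(as.numeric(divergence[names(n_haps)]), names(n_haps))
  divergence[is.na(divergence)] <- 0
  if (any(divergence < 0)) stop("divergence parameters must be >= 0")

  with_seed_if(seed, {
    positions <- sort(sample.int(region_length, n_sites))
    cm <- positions / 1e6 * cm_per_mb
    p_base <- rbeta(n_sites, maf_shape, maf_shape)
    p_base <- pmin(pmax(p_base, 1e-4), 1 - 1e-4)
    site_class <- sample(c("ts", "tv"), n_sites, replace = TRUE,
                         prob = c(ts_prob, 1 - ts_prob))

    alleles <- NULL
    pop <- character(0)
    for (pn in names(n_haps)) {
      f <- divergence[[pn]]
      p_pop <- if (f > 0) {
        rbeta(n_sites, p_base * (1 - f) / f, (1 - p_base) * (1 - f) / f)
      } else {
        p_base
      }
      founders <- matrix(rbinom(n_founders * n_sites, 1L, rep(p_pop, each = n_founders)),
                         nrow = n_founders)
      exp_x <- founder_generations * (max(cm) - min(cm)) / 100
      haps <- matrix(0L, nrow = n_haps[[pn]], ncol = n_sites)
      for (i in seq_len(n_haps[[pn]])) {
        h <- mosaic_over(founders, cm, exp_x)$hap
        flip <- rbinom(n_sites, 1L, mutation_rate) == 1L
        h[flip] <- 1L - h[flip]
        haps[i, ] <- h
      }
      alleles <- rbind(alleles, haps)
      pop <- c(pop, rep(pn, n_haps[[pn]]))
    }

    ac <- colSums(alleles)
    keep <- ac > 0 & ac < nrow(alleles)
    if (!any(keep)) stop("no polymorphic sites remain after simulation")
    alleles <- alleles[, keep, drop = FALSE]
    positions <- positions[keep]
    cm <- cm[keep]
    site_class <- site_class[keep]
    af <- colMeans(alleles)

    rownames(alleles) <- paste0(pop, "_h", seq_along(pop))
    structure(
      list(positions = positions,
           alleles = alleles,
           pop = pop,
           site_class = site_class,
           maf = pmin(af, 1 - af),
           map = tibble::tibble(pos = positions, cm = cm),
           chrom = chrom),
      class = "haplotype_panel")
  })
}

# One mosaic haplotype over the rows of `source` (hap x site matrix):
# Poisson(expected_crossovers) breakpoints uniform on the genetic map, a
# uniformly chosen source row per interval.
mosaic_over <- function(source, cm, expected_crossovers) {
  n <- nrow(source)
  m <- length(cm)
  nx <- rpois(1, expected_crossovers)
  if (nx == 0 || m == 1) {
    idx <- sample.int(n, 1)
    return(list(hap = source[idx, ], sources = idx, n_crossovers = 0L))
  }
  breaks <- sort(runif(nx, min(cm), max(cm)))
  seg <- findInterval(cm, breaks) + 1L           # interval index per site
  src <- sample.int(n, nx + 1L, replace = TRUE)  # source per interval
  hap <- source[cbind(src[seg], seq_len(m))]
  # crossovers are counted where the copied source actually changes
  eff <- sum(src[-1] != src[-length(src)])
  list(hap = hap, sources = unique(src), n_crossovers = eff)
}

#' @method print haplotype_panel
#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      length(x$positions), " sites on chr", x$chrom, "\n", sep = "")
  tab <- table(x$pop)
  cat("  populations: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  span: ", min(x$positions), "-", max(x$positions), " bp, ",
      round(max(x$map$cm) - min(x$map$cm), 2), " cM\n", sep = "")
  invisible(x)
}

#' Per-site allele frequencies of a panel
#'
#' @param panel A `haplotype_panel`.
#' @param population Optional population label; default uses all haplotypes.
#' @param minor If `TRUE` (default) fold to the minor allele frequency.
#' @return Numeric vector, one value per site.
#' @export
panel_maf <- function(panel, population = NULL, minor = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  if (!is.null(population)) {
    if (!population %in% panel$pop) stop("unknown population: ", population)
    a <- a[panel$pop == population, , drop = FALSE]
  }
  af <- colMeans(a)
  if (minor) pmin(af, 1 - af) else af
}

# drop haplotype rows (by index) from a panel
drop_haplotypes <- function(panel, idx) {
  if (length(idx) == 0) return(panel)
  panel$alleles <- panel$alleles[-idx, , drop = FALSE]
  panel$pop <- panel$pop[-idx]
  panel
}

new_true_genome <- function(hap1, hap2, pop, id) {
  structure(list(id = id, pop = pop,
                 hap1 = as.integer(hap1), hap2 = as.integer(hap2),
                 genotype = as.integer(hap1 + hap2)),
            class = "true_genome")
}

#' @method print true_genome
#' @export
print.true_genome <- function(x, ...) {
  cat("<true_genome> ", x$id, " (", x$pop, "), ", length(x$genotype),
      " sites, heterozygosity ", round(mean(x$genotype == 1L), 3), "\n",
      sep = "")
  invisible(x)
}

#' Sample a diploid target genome from a panel population
#'
#' Draws two haplotypes as copies of, or recombinant mosaics of, the
#' population's panel haplotypes. With `exclude_from_panel = TRUE` the source
#' haplotypes are removed from the returned panel, so downstream imputation
#' cannot copy the target from itself.
#'
#' @param panel A `haplotype_panel`.
#' @param population Population label to draw from (>= 2 haplotypes).
#' @param seed Integer seed.
#' @param mode `"mosaic"` (recombinant copies, the default) or `"copy"`
#'   (two unmodified panel haplotypes).
#' @param expected_crossovers Mean crossover count per haplotype in mosaic
#'   mode; default is 30 times the genetic map length in Morgans
#'   (separation of roughly 30 generations from the panel).
#' @param exclude_from_panel Remove the source haplotypes from the returned
#'   panel (default `TRUE`).
#' @param id Sample identifier.
#' @return List with `genome` (a `true_genome`), `panel` (possibly reduced),
#'   `source_haps` (row indices used, in the input panel), and
#'   `n_crossovers` (length-2 integer, crossovers per haplotype).
#' @export
sample_diploid <- function(panel, population, seed = NULL,
                           mode = c("mosaic", "copy"),
                           expected_crossovers = NULL,
                           exclude_from_panel = TRUE,
                           id = "target") {
  stopifnot(inherits(panel, "haplotype_panel"))
  mode <- match.arg(mode)
  in_pop <- which(panel$pop == population)
  if (length(in_pop) < 2)
    stop("population ", population, " needs at least 2 haplotypes")
  cm <- panel$map$cm
  if (is.null(expected_crossovers))
    expected_crossovers <- 30 * (max(cm) - min(cm)) / 100

  with_seed_if(seed, {
    if (mode == "copy") {
      pick <- sample(in_pop, 2)
      hap1 <- panel$alleles[pick[1], ]
      hap2 <- panel$alleles[pick[2], ]
      sources <- pick
      nx <- c(0L, 0L)
    } else {
      sub <- panel$alleles[in_pop, , drop = FALSE]
      m1 <- mosaic_over(sub, cm, expected_crossovers)
      m2 <- mosaic_over(sub, cm, expected_crossovers)
      hap1 <- m1$hap
      hap2 <- m2$hap
      sources <- in_pop[sort(unique(c(m1$sources, m2$sources)))]
      nx <- c(m1$n_crossovers, m2$n_crossovers)
    }
    out_panel <- if (exclude_from_panel) drop_haplotypes(panel, sources) else panel
    list(genome = new_true_genome(hap1, hap2, population, id),
         panel = out_panel,
         source_haps = sources,
         n_crossovers = as.integer(nx))
  })
}

#' Simulate a trio with recombinant Mendelian transmission
#'
#' The mother and father each copy two distinct panel haplotypes from the
#' chosen population; the child receives one recombinant transmission from
#' each parent (crossover count Poisson with mean equal to the genetic map
#' length in Morgans, breakpoints uniform on the map). The child's first
#' haplotype is paternal, the second maternal; the construction is
#' Mendel-consistent at every site and switch-free by definition.
#'
#' @param panel A `haplotype_panel`.
#' @param population Population to draw the parents from (>= 4 haplotypes).
#' @param seed Integer seed.
#' @param exclude_from_panel Remove the four parental source haplotypes from
#'   the returned panel.
#' @return A `trio`: list with `mother`, `father`, `child` (`true_genome`s),
#'   `transmitted` (per-parent crossover breakpoints in cM and starting
#'   haplotype), `panel`, and `source_haps`.
#' @export
simulate_trio <- function(panel, population, seed = NULL,
                          exclude_from_panel = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  in_pop <- which(panel$pop == population)
  if (length(in_pop) < 4)
    stop("population ", population, " needs at least 4 haplotypes for a trio")
  cm <- panel$map$cm
  map_morgans <- (max(cm) - min(cm)) / 100

  with_seed_if(seed, {
    pick <- sample(in_pop, 4)
    mother <- new_true_genome(panel$alleles[pick[1], ], panel$alleles[pick[2], ],
                              population, "mother")
    father <- new_true_genome(panel$alleles[pick[3], ], panel$alleles[pick[4], ],
                              population, "father")
    transmit <- function(parent) {
      nx <- rpois(1, map_morgans)
      breaks <- if (nx > 0) sort(runif(nx, min(cm), max(cm))) else numeric(0)
      start <- sample(1:2, 1)
      seg <- findInterval(cm, breaks)            # 0..nx
      which_hap <- ifelse(seg %% 2 == 0, start, 3L - start)
      hap <- ifelse(which_hap == 1L, parent$hap1, parent$hap2)
      list(hap = as.integer(hap), breaks_cm = breaks, start_hap = start)
    }
    tp <- transmit(father)
    tm <- transmit(mother)
    child <- new_true_genome(tp$hap, tm$hap, population, "child")
    out_panel <- if (exclude_from_panel) drop_haplotypes(panel, pick) else panel
    structure(list(mother = mother, father = father, child = child,
                   transmitted = list(father = tp[-1], mother = tm[-1]),
                   panel = out_panel, source_haps = pick),
              class = "trio")
  })
}

#' @method print trio
#' @export
print.trio <- function(x, ...) {
  cat("<trio> ", length(x$child$genotype), " sites; crossovers: father ",
      length(x$transmitted$father$breaks_cm), ", mother ",
      length(x$transmitted$mother$breaks_cm), "\n", sep = "")
  invisible(x)
}
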