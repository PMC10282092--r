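# VCF, recombination-map, read-table and BED interchange.
#
# Reading goes through vcfR; writing composes the records as text (the
# package controls its own FORMAT subsets: GT, PL, DP, GP, DS). Site
# classes are encoded in the REF/ALT pair: transitions as A/G,
# transversions as A/T, so a written panel round-trips losslessly.

vcf_header <- function(chrom, format_lines, sample_ids) {
  c("##fileformat=VCFv4.2",
    "##source=paleoimpute",
    paste0("##contig=<ID=", chrom, ">"),
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

site_alleles <- function(site_class) {
  list(ref = rep("A", length(site_class)),
       alt = ifelse(site_class == "ts", "G", "T"))
}

#' Write a phased haplotype panel as VCF
#'
#' Consecutive haplotypes are paired into diploid samples with phased
#' (`|`) GT fields. Transition sites are written as A/G, transversions as
#' A/T, so the site class survives a round trip.
#'
#' @param panel A `haplotype_panel` with an even number of haplotypes.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"),
            nrow(panel$alleles) %% 2 == 0)
  k <- nrow(panel$alleles)
  odd <- seq(1, k, by = 2)
  ids <- paste0(panel$pop[odd], "_ind", seq_along(odd))
  al <- site_alleles(panel$site_class)
  gt <- matrix(paste0(t(panel$alleles[odd, , drop = FALSE]), "|",
                      t(panel$alleles[odd + 1, , drop = FALSE])),
               nrow = length(panel$positions))
  body <- paste(panel$chrom, panel$positions, ".", al$ref, al$alt, ".", ".",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(panel$chrom,
                          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                          ids),
               body), path)
  invisible(path)
}

check_biallelic <- function(vcf) {
  alt <- vcfR::getALT(vcf)
  bad <- grepl(",", alt)
  if (any(bad))
    stop("multi-allelic record(s) at VCF data line(s) ",
         paste(head(which(bad), 5), collapse = ", "),
         ": only biallelic SNPs are supported")
  pos <- vcfR::getPOS(vcf)
  if (anyNA(pos)) stop("malformed POS field in VCF")
  invisible(vcf)
}

#' Read a phased haplotype panel from VCF
#'
#' Inverse of [write_panel_vcf()]. Population labels are recovered from the
#' sample-name prefix before `_ind`; the site class from the REF/ALT pair
#' (A/G transition, otherwise transversion). The recombination map is not
#' part of VCF and must be supplied or attached afterwards.
#'
#' @param path VCF path.
#' @param map Optional recombination-map tibble (`pos`, `cm`); default is a
#'   uniform 1 cM/Mb map over the positions.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(path, map = NULL) {
  vcf <- check_biallelic(vcfR::read.vcfR(path, verbose = FALSE))
  gt <- vcfR::extract.gt(vcf)
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop("panel VCF must contain phased biallelic GT fields")
  pos <- vcfR::getPOS(vcf)
  chrom <- vcfR::getCHROM(vcf)[1]
  h1 <- substr(gt, 1, 1) == "1"
  h2 <- substr(gt, 3, 3) == "1"
  m <- nrow(gt)
  ids <- colnames(gt)
  alleles <- matrix(0L, nrow = 2 * length(ids), ncol = m)
  for (i in seq_along(ids)) {
    alleles[2 * i - 1, ] <- as.integer(h1[, i])
    alleles[2 * i, ] <- as.integer(h2[, i])
  }
  pop <- rep(sub("_ind[0-9]+$", "", ids), each = 2)
  rownames(alleles) <- paste0(pop, "_h", seq_len(nrow(alleles)))
  site_class <- ifelse(vcfR::getALT(vcf) == "G", "ts", "tv")
  af <- colMeans(alleles)
  if (is.null(map))
    map <- tibble::tibble(pos = pos, cm = pos / 1e6)
  structure(list(positions = pos, alleles = alleles, pop = pop,
                 site_class = site_class, maf = pmin(af, 1 - af),
                 map = map, chrom = chrom),
            class = "haplotype_panel")
}

#' Write genotype likelihoods as a single-sample VCF (PL/DP)
#'
#' @param gl Genotype-likelihood tibble from [genotype_likelihoods()].
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param site_class Optional per-site class (`"ts"`/`"tv"`) for the
#'   REF/ALT encoding; defaults to transversions.
#' @return `path`, invisibly.
#' @export
write_gl_vcf <- function(gl, path, sample_id = "sample",
                         site_class = NULL) {
  if (is.null(site_class)) site_class <- rep("tv", nrow(gl))
  al <- site_alleles(site_class)
  pl <- round(-10 / log(10) *
                cbind(gl$ll_rr, gl$ll_ra, gl$ll_aa))
  pl <- pl - apply(pl, 1, min)
  body <- paste(gl$chrom, gl$pos, ".", al$ref, al$alt, ".", ".", ".",
                "PL:DP",
                paste0(pl[, 1], ",", pl[, 2], ",", pl[, 3], ":", gl$depth),
                sep = "\t")
  writeLines(c(vcf_header(gl$chrom[1],
                          c('##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
                            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
                          sample_id),
               body), path)
  invisible(path)
}

#' Read single-sample genotype likelihoods from a VCF with PL
#'
#' @param path VCF path.
#' @return A genotype-likelihood tibble (`chrom`, `pos`, `depth`, `ll_rr`,
#'   `ll_ra`, `ll_aa`), PL converted back to max-normalised natural logs.
#' @export
read_gl_vcf <- function(path) {
  vcf <- check_biallelic(vcfR::read.vcfR(path, verbose = FALSE))
  pl <- vcfR::extract.gt(vcf, element = "PL")[, 1]
  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])
  parts <- do.call(rbind, strsplit(pl, ",", fixed = TRUE))
  if (ncol(parts) != 3) stop("PL fields must carry 3 genotype likelihoods")
  ll <- -log(10) / 10 * matrix(as.numeric(parts), ncol = 3)
  ll <- ll - apply(ll, 1, max)
  tibble::tibble(chrom = vcfR::getCHROM(vcf), pos = vcfR::getPOS(vcf),
                 depth = dp, ll_rr = ll[, 1], ll_ra = ll[, 2],
                 ll_aa = ll[, 3])
}

#' Write an imputed genome as a single-sample VCF (GT/GP/DS)
#'
#' Phased haplotypes are written as `a|b` when present; filtered (missing)
#' sites as `./.`. GP and DS carry 4 decimals.
#'
#' @param imputed An `imputed_genotype` tibble.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(imputed, path, sample_id = "imputed") {
  has_phase <- all(c("hap1", "hap2") %in% names(imputed))
  gt <- if (has_phase) paste0(imputed$hap1, "|", imputed$hap2)
        else c("0/0", "0/1", "1/1")[imputed$gt + 1L]
  gt[imputed$missing] <- if (has_phase) ".|." else "./."
  num <- function(x) formatC(x, format = "f", digits = 4)
  body <- paste(imputed$chrom, imputed$pos, ".", "A", "T", ".", ".", ".",
                "GT:GP:DS",
                paste0(gt, ":", num(imputed$gp0), ",", num(imputed$gp1),
                       ",", num(imputed$gp2), ":", num(imputed$ds)),
                sep = "\t")
  writeLines(c(vcf_header(imputed$chrom[1],
                          c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                            '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
                            '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">'),
                          sample_id),
               body), path)
  invisible(path)
}

#' Read an imputed genome from a GT/GP/DS VCF
#'
#' @param path VCF path.
#' @return An `imputed_genotype` tibble.
#' @export
read_imputed_vcf <- function(path) {
  vcf <- check_biallelic(vcfR::read.vcfR(path, verbose = FALSE))
  gp <- vcfR::extract.gt(vcf, element = "GP")[, 1]
  ds <- as.numeric(vcfR::extract.gt(vcf, element = "DS")[, 1])
  gtf <- unname(vcfR::extract.gt(vcf)[, 1])
  parts <- do.call(rbind, strsplit(gp, ",", fixed = TRUE))
  gpm <- matrix(as.numeric(parts), ncol = 3)
  missing <- is.na(gtf) | grepl("\\.", gtf)
  phased <- grepl("\\|", gtf) & !missing
  h1 <- ifelse(phased, as.integer(substr(gtf, 1, 1)), NA_integer_)
  h2 <- ifelse(phased, as.integer(substr(gtf, 3, 3)), NA_integer_)
  out <- tibble::tibble(
    chrom = vcfR::getCHROM(vcf), pos = vcfR::getPOS(vcf),
    gp0 = gpm[, 1], gp1 = gpm[, 2], gp2 = gpm[, 3], ds = ds,
    gt = argmax_genotype(gpm), missing = missing,
    hap1 = h1, hap2 = h2)
  class(out) <- c("imputed_genotype", class(out))
  out
}

#' Write / read a recombination map (chrom, pos, cM)
#'
#' Three-column tab-separated interchange.
#' @param map Tibble with `pos`, `cm`.
#' @param path File path.
#' @param chrom Chromosome label.
#' @return `path` / the map tibble.
#' @export
write_recomb_map <- function(map, path, chrom = "1") {
  write.table(data.frame(chrom = chrom, pos = map$pos, cm = map$cm),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "integer", "numeric"))
  if (is.unsorted(d$cm)) stop("genetic positions must be non-decreasing")
  tibble::tibble(pos = d$pos, cm = d$cm)
}

#' Write / read a site read-count table
#'
#' Tab-separated columns `chrom`, `pos`, `site_class`, `n_ref`, `n_alt`;
#' the nominal mean depth is stored in a `# mean_doc` header comment.
#' @param reads Read-count tibble.
#' @param path File path.
#' @return `path` / the read tibble.
#' @export
write_reads_table <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mean_doc=", mean_depth_of(reads)), con)
  write.table(as.data.frame(reads), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_table
#' @export
read_reads_table <- function(path) {
  first <- readLines(path, n = 1)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  colClasses = c("character", "integer", "character",
                                 "integer", "integer"))
  out <- tibble::as_tibble(d)
  if (grepl("^# mean_doc=", first))
    attr(out, "mean_doc") <- as.numeric(sub("^# mean_doc=", "", first))
  out
}

#' Read a BED mask and test site membership
#'
#' BED intervals are 0-based half-open; a 1-based site position `pos` falls
#' in `[start, end)` when `start < pos <= end`.
#'
#' @param path BED path (3+ tab-separated columns, no header).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t")
  if (ncol(d) < 3) stop("BED file needs at least 3 columns")
  tibble::tibble(chrom = as.character(d[[1]]), start = d[[2]], end = d[[3]])
}

#' @rdname read_bed
#' @param positions 1-based site positions.
#' @param bed A BED tibble from [read_bed()].
#' @param chrom Chromosome of the positions.
#' @return Logical vector, `TRUE` where a position is covered.
#' @export
positions_in_bed <- function(positions, bed, chrom = "1") {
  bed <- bed[bed$chrom == chrom, , drop = FALSE]
  out <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(bed)))
    out <- out | (positions > bed$start[i] & positions <= bed$end[i])
  out
}

#' Write a truth genome as a single-sample phased VCF
#'
#' @param genome A `true_genome`.
#' @param panel The `haplotype_panel` supplying positions and site classes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_vcf <- function(genome, panel, path) {
  stopifnot(inherits(genome, "true_genome"),
            inherits(panel, "haplotype_panel"),
            length(genome$hap1) == length(panel$positions))
  al <- site_alleles(panel$site_class)
  body <- paste(panel$chrom, panel$positions, ".", al$ref, al$alt, ".", ".",
                ".", "GT", paste0(genome$hap1, "|", genome$hap2),
                sep = "\t")
  writeLines(c(vcf_header(panel$chrom,
                          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                          genome$id),
               body), path)
  invisible(path)
}

#' Write validation calls as a single-sample VCF (GT/DP with QUAL)
#'
#' The QUAL column carries the Phred-scaled call confidence; FILTER is
#' `PASS` for sites passing the validation filter and `FAIL` otherwise.
#'
#' @param validation A validation-call tibble from [call_validation()].
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_validation_vcf <- function(validation, path, sample_id = "validation") {
  gt_str <- c("0/0", "0/1", "1/1")[validation$gt + 1L]
  gt_str[is.na(validation$gt)] <- "./."
  body <- paste(validation$chrom, validation$pos, ".", "A", "T",
                formatC(validation$qual, format = "f", digits = 2),
                ifelse(validation$pass_filter, "PASS", "FAIL"), ".",
                "GT:DP", paste0(gt_str, ":", validation$depth), sep = "\t")
  writeLines(c(vcf_header(validation$chrom[1],
                          c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
                            '##FILTER=<ID=FAIL,Description="Failed validation filters">'),
                          sample_id),
               body), path)
  invisible(path)
}

#' Read validation calls from a VCF written by [write_validation_vcf()]
#'
#' @param path VCF path.
#' @return A validation-call tibble (without the genotype posterior, which
#'   is not part of the VCF representation).
#' @export
read_validation_vcf <- function(path) {
  vcf <- check_biallelic(vcfR::read.vcfR(path, verbose = FALSE))
  gtf <- unname(vcfR::extract.gt(vcf)[, 1])
  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])
  gt <- rep(NA_integer_, length(gtf))
  gt[gtf == "0/0"] <- 0L
  gt[gtf == "0/1"] <- 1L
  gt[gtf == "1/1"] <- 2L
  tibble::tibble(chrom = vcfR::getCHROM(vcf), pos = vcfR::getPOS(vcf),
                 depth = dp, gt = gt,
                 qual = as.numeric(vcfR::getQUAL(vcf)),
                 pass_filter = vcfR::getFILTER(vcf) == "PASS")
}
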