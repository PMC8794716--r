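# The snp_dataset container: a biallelic SNP genotype matrix (alt-allele
# dosage 0/1/2, NA = missing) with per-locus and per-individual metadata.
# Every stage of the pipeline -- filtering, panel subsampling, spatial
# thinning, degradation, measurement -- consumes and returns this object.

#' Construct a SNP dataset
#'
#' Bundles a genotype matrix with locus and individual metadata and validates
#' the result. Genotypes are stored as alt-allele dosage: 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate), `NA` (missing
#' call). Rows are individuals, columns are loci.
#'
#' @param genotypes Numeric or integer matrix of values in `{0, 1, 2, NA}`;
#'   rows = individuals, columns = loci.
#' @param loci `data.frame` with columns `locus_id`, `contig_id`,
#'   `position_in_contig` (non-negative integer, orders loci within a contig)
#'   and optionally `reproducibility` (fraction in `[0, 1]`, `NA` if the
#'   genotyping platform reported no technical-replicate score).
#' @param individuals `data.frame` with columns `individual_id`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), and planar capture coordinates
#'   `x`, `y` in metres.
#'
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(genotypes, loci, individuals) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!"reproducibility" %in% names(loci)) loci$reproducibility <- NA_real_
  if (!"sex" %in% names(individuals)) individuals$sex <- "unknown"
  loci$locus_id <- as.character(loci$locus_id)
  loci$contig_id <- as.character(loci$contig_id)
  individuals$individual_id <- as.character(individuals$individual_id)
  if (nrow(genotypes) != nrow(individuals))
    stop("genotype rows (", nrow(genotypes), ") != individuals (",
         nrow(individuals), ")", call. = FALSE)
  if (ncol(genotypes) != nrow(loci))
    stop("genotype columns (", ncol(genotypes), ") != loci (", nrow(loci),
         ")", call. = FALSE)
  rownames(loci) <- NULL
  rownames(individuals) <- NULL
  rownames(genotypes) <- individuals$individual_id
  colnames(genotypes) <- loci$locus_id
  ds <- structure(list(genotypes = genotypes, loci = loci,
                       individuals = individuals),
                  class = "snp_dataset")
  validate_snp_dataset(ds)
}

#' @rdname snp_dataset
#' @param ds An `snp_dataset`.
#' @export
validate_snp_dataset <- function(ds) {
  g <- ds$genotypes
  if (nrow(g) != nrow(ds$individuals))
    stop("genotype rows (", nrow(g), ") != individuals (",
         nrow(ds$individuals), ")", call. = FALSE)
  if (ncol(g) != nrow(ds$loci))
    stop("genotype columns (", ncol(g), ") != loci (", nrow(ds$loci), ")",
         call. = FALSE)
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad)) {
    idx <- which(bad)[1]
    rc <- arrayInd(idx, dim(g))
    stop("invalid genotype value ", g[idx], " at individual ", rc[1],
         ", locus ", rc[2], " (allowed: 0, 1, 2, NA)", call. = FALSE)
  }
  if (anyDuplicated(ds$loci$locus_id))
    stop("duplicate locus IDs: ",
         paste(unique(ds$loci$locus_id[duplicated(ds$loci$locus_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(ds$individuals$individual_id))
    stop("duplicate individual IDs: ",
         paste(unique(ds$individuals$individual_id[
           duplicated(ds$individuals$individual_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(ds$individuals$sex %in% c("male", "female", "unknown")))
    stop("sex must be one of 'male', 'female', 'unknown'", call. = FALSE)
  if (nrow(ds$individuals) > 0 &&
      (!all(is.finite(ds$individuals$x)) || !all(is.finite(ds$individuals$y))))
    stop("individual coordinates must be finite", call. = FALSE)
  if (nrow(ds$loci) > 0) {
    pos <- ds$loci$position_in_contig
    if (any(!is.finite(pos)) || any(pos < 0))
      stop("position_in_contig must be non-negative and finite",
           call. = FALSE)
    rep_ok <- is.na(ds$loci$reproducibility) |
      (ds$loci$reproducibility >= 0 & ds$loci$reproducibility <= 1)
    if (!all(rep_ok))
      stop("reproducibility scores must lie in [0, 1] or be NA",
           call. = FALSE)
  }
  ds
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("snp_dataset:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  cat("  contigs:", length(unique(x$loci$contig_id)), "\n")
  invisible(x)
}

#' Number of individuals / loci in a dataset
#' @param ds An `snp_dataset`.
#' @export
n_individuals <- function(ds) nrow(ds$genotypes)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) ncol(ds$genotypes)

#' Subset a dataset by locus or individual
#'
#' Both accept a logical, integer, or character (ID) index and keep the
#' genotype matrix and metadata aligned.
#'
#' @param ds An `snp_dataset`.
#' @param keep Index into loci (`subset_loci`) or individuals
#'   (`subset_individuals`).
#' @export
subset_loci <- function(ds, keep) {
  if (is.character(keep)) keep <- match(keep, ds$loci$locus_id)
  g <- ds$genotypes[, keep, drop = FALSE]
  reindex(structure(list(genotypes = g, loci = ds$loci[keep, , drop = FALSE],
                         individuals = ds$individuals),
                    class = "snp_dataset"))
}

#' @rdname subset_loci
#' @export
subset_individuals <- function(ds, keep) {
  if (is.character(keep)) keep <- match(keep, ds$individuals$individual_id)
  g <- ds$genotypes[keep, , drop = FALSE]
  reindex(structure(list(genotypes = g, loci = ds$loci,
                         individuals = ds$individuals[keep, , drop = FALSE]),
                    class = "snp_dataset"))
}

reindex <- function(ds) {
  rownames(ds$loci) <- NULL
  rownames(ds$individuals) <- NULL
  ds
}

#' Per-locus call rates
#'
#' The call rate of a locus is the proportion of individuals with a
#' non-missing genotype at that locus.
#'
#' @param ds An `snp_dataset` with at least one individual.
#' @return Named numeric vector in `[0, 1]`, one element per locus.
#' @export
call_rates <- function(ds) {
  if (n_individuals(ds) == 0) stop("call rates need >= 1 individual",
                                   call. = FALSE)
  r <- colMeans(!is.na(ds$genotypes))
  names(r) <- ds$loci$locus_id
  r
}

#' Per-locus alternate-allele frequencies
#'
#' Computed on observed (non-missing) genotypes only:
#' `sum(dosage) / (2 * n_observed)`. Loci with no observed genotypes get
#' `NA` (frequency undefined).
#'
#' @param ds An `snp_dataset`.
#' @return Named numeric vector in `[0, 1]` (or `NA`), one element per locus.
#' @export
allele_frequencies <- function(ds) {
  g <- ds$genotypes
  n_obs <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  names(p) <- ds$loci$locus_id
  p
}
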