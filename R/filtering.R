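# Locus quality filters in the dartR style, applied identically to the
# complete dataset and to every simulated one: reproducibility >= threshold
# (inclusive), call rate > threshold (strict), minor allele frequency >
# threshold (strict, on observed genotypes), and removal of secondary SNPs
# (all but the first SNP on each contig). Filters only ever remove loci --
# never individuals, never genotype values.

#' Filtering configuration
#'
#' Defaults reproduce the standard koala-genomics filter set: call rate
#' > 0.70, MAF > 0.01, reproducibility >= 0.95, secondary SNPs removed.
#'
#' @param min_call_rate Keep loci with call rate strictly greater than this.
#' @param min_maf Keep loci with minor allele frequency strictly greater
#'   than this (computed on observed genotypes).
#' @param min_reproducibility Keep loci with technical-replicate
#'   reproducibility greater than or equal to this.
#' @param drop_secondary Remove all but the first SNP on each contig.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_call_rate = 0.70, min_maf = 0.01,
                          min_reproducibility = 0.95, drop_secondary = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            min_reproducibility >= 0, min_reproducibility <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_reproducibility = min_reproducibility,
                 drop_secondary = isTRUE(drop_secondary)),
            class = "filter_config")
}

#' Individual locus filters
#'
#' Each returns the dataset restricted to passing loci. `filter_call_rate()`
#' and `filter_maf()` use strict inequalities; `filter_reproducibility()` is
#' inclusive. Loci without a reproducibility score pass that filter with a
#' warning. `remove_secondary_snps()` keeps, within each contig, only the
#' locus with the smallest `position_in_contig` (ties broken by locus ID).
#'
#' @param ds An `snp_dataset`.
#' @param threshold Fraction in `[0, 1]`.
#' @export
filter_call_rate <- function(ds, threshold = 0.70) {
  subset_loci(ds, call_rates(ds) > threshold)
}

#' @rdname filter_call_rate
#' @export
filter_maf <- function(ds, threshold = 0.01) {
  p <- allele_frequencies(ds)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > threshold
  subset_loci(ds, keep)
}

#' @rdname filter_call_rate
#' @export
filter_reproducibility <- function(ds, threshold = 0.95) {
  rep <- ds$loci$reproducibility
  if (anyNA(rep))
    warning(sum(is.na(rep)), " locus/loci without reproducibility scores ",
            "retained", call. = FALSE)
  subset_loci(ds, is.na(rep) | rep >= threshold)
}

#' @rdname filter_call_rate
#' @export
remove_secondary_snps <- function(ds) {
  l <- ds$loci
  ord <- order(l$contig_id, l$position_in_contig, l$locus_id)
  first <- !duplicated(l$contig_id[ord])
  keep_ids <- l$locus_id[ord][first]
  subset_loci(ds, ds$loci$locus_id %in% keep_ids)
}

#' Apply the full filter pipeline
#'
#' Runs reproducibility, call-rate, MAF, and secondary-SNP filters in that
#' order (MAF is therefore recomputed on whatever missingness the dataset
#' carries when it reaches that step) and reports per-step removals.
#'
#' @param ds An `snp_dataset`.
#' @param cfg A [filter_config()].
#' @return List with `dataset` (the filtered `snp_dataset`) and `report`, a
#'   `data.frame` of per-step locus removals whose removed counts plus the
#'   survivor count sum to the input locus count.
#' @export
apply_filters <- function(ds, cfg = filter_config()) {
  n0 <- n_loci(ds)
  steps <- character(0); removed <- integer(0)
  ds1 <- suppressWarnings(filter_reproducibility(ds, cfg$min_reproducibility))
  steps <- c(steps, "reproducibility"); removed <- c(removed, n0 - n_loci(ds1))
  ds2 <- filter_call_rate(ds1, cfg$min_call_rate)
  steps <- c(steps, "call_rate"); removed <- c(removed, n_loci(ds1) - n_loci(ds2))
  ds3 <- filter_maf(ds2, cfg$min_maf)
  steps <- c(steps, "maf"); removed <- c(removed, n_loci(ds2) - n_loci(ds3))
  if (cfg$drop_secondary) {
    ds4 <- remove_secondary_snps(ds3)
  } else {
    ds4 <- ds3
  }
  steps <- c(steps, "secondary"); removed <- c(removed, n_loci(ds3) - n_loci(ds4))
  report <- data.frame(step = steps, removed = removed,
                       stringsAsFactors = FALSE)
  report$survivors_after <- n0 - cumsum(removed)
  list(dataset = ds4, report = report)
}
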