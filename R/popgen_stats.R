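# Scalar genetic measures on a biallelic dosage matrix: expected and observed
# heterozygosity, Shannon's information index, the inbreeding coefficient
# FIS = (He - Ho) / He on multilocus means, and per-individual internal
# relatedness IR = (2H - sum(f_i)) / (2N - sum(f_i)).
#
# All estimators work on observed (non-missing) genotypes; loci with no data
# are excluded from locus averages. He uses the plain 2p(1-p) convention
# (no n/(n-1) small-sample correction) unless `unbiased = TRUE`.

locus_he <- function(ds, unbiased = FALSE) {
  p <- allele_frequencies(ds)
  he <- 2 * p * (1 - p)
  if (unbiased) {
    n <- colSums(!is.na(ds$genotypes))
    corr <- ifelse(n > 1, (2 * n) / (2 * n - 1), NA_real_)
    he <- he * corr
  }
  he
}

#' Expected heterozygosity
#'
#' Per-locus `2 p (1 - p)` on observed allele frequencies, averaged over loci
#' with data. The `spread` is the standard error across loci
#' (`sd / sqrt(n_loci)`), matching the "0.284 +/- 0.002" reporting style.
#'
#' @param ds An `snp_dataset`.
#' @param unbiased Apply the `2n/(2n-1)` small-sample correction per locus
#'   (a dialect switch; default off).
#' @return List with `mean` and `se`.
#' @export
expected_heterozygosity <- function(ds, unbiased = FALSE) {
  he <- locus_he(ds, unbiased)
  he <- he[!is.na(he)]
  if (length(he) == 0) stop("no locus with observed genotypes", call. = FALSE)
  list(mean = mean(he), se = stats::sd(he) / sqrt(length(he)))
}

#' Observed heterozygosity
#'
#' Per-locus fraction of observed genotypes that are heterozygous, averaged
#' over loci with data.
#'
#' @param ds An `snp_dataset`.
#' @return Scalar in `[0, 1]`.
#' @export
observed_heterozygosity <- function(ds) {
  g <- ds$genotypes
  n_obs <- colSums(!is.na(g))
  ho <- colSums(g == 1L, na.rm = TRUE) / n_obs
  ho <- ho[n_obs > 0]
  if (length(ho) == 0) stop("no locus with observed genotypes", call. = FALSE)
  mean(ho)
}

#' Shannon's information index
#'
#' Per-locus allele-frequency entropy `-(p ln p + q ln q)` (natural log),
#' averaged over loci with data; monomorphic loci contribute 0.
#'
#' @inheritParams expected_heterozygosity
#' @return List with `mean` and `se` (standard error across loci).
#' @export
shannon_index <- function(ds) {
  p <- allele_frequencies(ds)
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no locus with observed genotypes", call. = FALSE)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  i <- -(xlx(p) + xlx(1 - p))
  list(mean = mean(i), se = stats::sd(i) / sqrt(length(i)))
}

#' Inbreeding coefficient FIS
#'
#' `FIS = (He - Ho) / He`, computed from the multilocus mean expected and
#' observed heterozygosities (not as a mean of per-locus ratios). Positive
#' values indicate a population-wide heterozygote deficit.
#'
#' @inheritParams expected_heterozygosity
#' @return Scalar `<= 1`.
#' @export
inbreeding_coefficient <- function(ds, unbiased = FALSE) {
  he <- expected_heterozygosity(ds, unbiased)$mean
  if (he == 0) stop("FIS undefined: mean expected heterozygosity is 0",
                    call. = FALSE)
  (he - observed_heterozygosity(ds)) / he
}

#' All diversity measures at once
#'
#' Convenience wrapper returning He (mean, spread), Ho, Shannon's I (mean,
#' spread) and FIS in one pass.
#'
#' @inheritParams expected_heterozygosity
#' @return List with `he_mean`, `he_se`, `ho_mean`, `shannon_mean`,
#'   `shannon_se`, `fis`.
#' @export
diversity_estimates <- function(ds, unbiased = FALSE) {
  he <- expected_heterozygosity(ds, unbiased)
  sh <- shannon_index(ds)
  ho <- observed_heterozygosity(ds)
  list(he_mean = he$mean, he_se = he$se, ho_mean = ho,
       shannon_mean = sh$mean, shannon_se = sh$se,
       fis = (he$mean - ho) / he$mean)
}

#' Internal relatedness
#'
#' Per-individual IR = `(2H - sum(f_i)) / (2N - sum(f_i))` where, over the
#' individual's non-missing loci, `H` is the number of homozygous loci, `N`
#' the number of loci, and `sum(f_i)` the summed population frequencies of
#' the `2N` allele copies the individual carries. Frequencies are computed
#' from the same dataset (a cohort-relative measure) and by default include
#' the focal individual's own alleles.
#'
#' A fully homozygous individual scores 1; high IR indicates the individual
#' carries common alleles in homozygous state more often than expected.
#'
#' @param ds An `snp_dataset`.
#' @param exclude_self Recompute allele frequencies without the focal
#'   individual's own two allele copies (default `FALSE`, matching the
#'   standard implementation).
#' @return Named numeric vector, one value per individual; `NA` (with a
#'   warning) for individuals with no observed genotypes.
#' @export
internal_relatedness <- function(ds, exclude_self = FALSE) {
  g <- ds$genotypes
  n_ind <- nrow(g)
  p <- allele_frequencies(ds)
  n_obs <- colSums(!is.na(g))
  ir <- rep(NA_real_, n_ind)
  for (i in seq_len(n_ind)) {
    gi <- g[i, ]
    use <- !is.na(gi) & !is.na(p)
    if (!any(use)) next
    gi <- gi[use]
    if (exclude_self) {
      n_o <- n_obs[use]
      pj <- ifelse(n_o > 1, (p[use] * 2 * n_o - gi) / (2 * (n_o - 1)),
                   NA_real_)
      ok <- !is.na(pj)
      gi <- gi[ok]; pj <- pj[ok]
      if (length(gi) == 0) next
    } else {
      pj <- p[use]
    }
    # summed frequency of the two carried copies: dosage-weighted alt freq
    # plus (2 - dosage)-weighted ref freq
    sum_f <- sum(gi * pj + (2 - gi) * (1 - pj))
    h <- sum(gi != 1L)
    n <- length(gi)
    ir[i] <- (2 * h - sum_f) / (2 * n - sum_f)
  }
  if (anyNA(ir))
    warning(sum(is.na(ir)), " individual(s) with no observed genotypes: ",
            "IR undefined", call. = FALSE)
  names(ir) <- ds$individuals$individual_id
  ir
}

#' Pearson correlation on pairwise-complete pairs
#'
#' Product-moment correlation over entries where both vectors are
#' non-missing; used to compare per-individual IR from a simulated dataset
#' with the full-data IR of the same individuals.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need >= 3 paired non-missing values", call. = FALSE)
  stats::cor(x[ok], y[ok])
}
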