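# Multilocus spatial autocorrelation in the Smouse-Peakall framework:
# pairwise squared genetic distances are double-centered into a covariance
# form c = -1/2 (d^2 centered), and for each geographic distance class h
#
#   r_h = sum over ordered pairs (x, y) in h of c_xy
#         / sum over ordered pairs (x, y) in h of c_xx
#
# Significance comes from (a) 95% bootstrap confidence intervals around r_h
# (resampling pairs within the class) and (b) a permutation null obtained by
# shuffling individual locations.

#' Distance-class specification
#'
#' Half-open classes `[k w, (k+1) w)` tiling `[0, max_distance)`. Defaults:
#' 250-m classes to 3500 m. Zero-distance pairs fall in the first class.
#'
#' @param class_width Class width, metres.
#' @param max_distance Upper end of the tiling, metres.
#' @return A `distance_class_spec` list with a `breaks` vector.
#' @export
distance_class_spec <- function(class_width = 250, max_distance = 3500) {
  stopifnot(class_width > 0, max_distance > class_width)
  breaks <- seq(0, max_distance, by = class_width)
  if (breaks[length(breaks)] < max_distance)
    breaks <- c(breaks, max_distance)
  structure(list(class_width = class_width, max_distance = max_distance,
                 breaks = breaks), class = "distance_class_spec")
}

#' Pairwise geographic distances
#'
#' Euclidean distances on the planar capture coordinates, in metres.
#'
#' @param individuals Individual metadata `data.frame` (or an
#'   `snp_dataset`).
#' @return Symmetric matrix with zero diagonal.
#' @export
geo_distance_matrix <- function(individuals) {
  if (inherits(individuals, "snp_dataset"))
    individuals <- individuals$individuals
  as.matrix(stats::dist(cbind(individuals$x, individuals$y)))
}

#' Pairwise squared genetic distances
#'
#' The standard codominant squared-distance metric for biallelic loci:
#' per locus, 0 for identical genotypes, 1 between a homozygote and a
#' heterozygote, 4 between opposite homozygotes (i.e. the squared dosage
#' difference), summed over loci observed in *both* individuals. To keep
#' distances comparable under uneven missingness, each pair's sum is scaled
#' by `n_loci / n_shared` (the reciprocal of the fraction of the panel the
#' pair shares). Pairs sharing no locus get `NA` with a warning.
#'
#' @param ds An `snp_dataset`.
#' @return Symmetric matrix of scaled squared distances.
#' @export
genetic_distance_matrix <- function(ds) {
  g <- ds$genotypes
  l <- ncol(g)
  m <- (!is.na(g)) * 1
  g0 <- g; g0[is.na(g0)] <- 0L
  storage.mode(g0) <- "double"
  shared <- m %*% t(m)
  cross <- g0 %*% t(g0)
  sq <- (g0^2) %*% t(m) # sum of g_x^2 over loci observed in both x and y
  d2 <- sq + t(sq) - 2 * cross
  scale <- ifelse(shared > 0, l / shared, NA_real_)
  out <- d2 * scale
  if (any(shared == 0 & upper.tri(shared)))
    warning(sum(shared == 0 & upper.tri(shared)),
            " pair(s) share no observed locus: distance undefined",
            call. = FALSE)
  diag(out) <- 0
  rownames(out) <- colnames(out) <- ds$individuals$individual_id
  out
}

# c = -1/2 * double-centered squared-distance matrix (the covariance form
# of the autocorrelation framework)
center_distance_matrix <- function(d2) {
  n <- nrow(d2)
  rm <- rowMeans(d2)
  gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm)
}

# Unordered pair indices per distance class
class_pairs <- function(geo, spec) {
  n <- nrow(geo)
  ut <- which(upper.tri(geo), arr.ind = TRUE)
  d <- geo[upper.tri(geo)]
  cls <- findInterval(d, spec$breaks, rightmost.closed = FALSE)
  k <- length(spec$breaks) - 1
  lapply(seq_len(k), function(h) ut[cls == h, , drop = FALSE])
}

r_from_pairs <- function(cmat, pairs) {
  if (nrow(pairs) == 0) return(NA_real_)
  num <- sum(cmat[pairs])
  den <- sum(diag(cmat)[pairs[, 1]] + diag(cmat)[pairs[, 2]]) / 2
  if (den <= 0) return(NA_real_)
  num / den
}

#' Per-class spatial autocorrelation r
#'
#' @param gd Squared genetic distance matrix
#'   ([genetic_distance_matrix()]).
#' @param geo Geographic distance matrix ([geo_distance_matrix()]).
#' @param spec A [distance_class_spec()].
#' @return `data.frame` with `class_lo`, `class_hi`, `n_pairs`, `r`
#'   (`NA` for empty classes).
#' @export
autocorrelation_r <- function(gd, geo, spec = distance_class_spec()) {
  stopifnot(all(dim(gd) == dim(geo)))
  cmat <- center_distance_matrix(gd)
  pairs <- class_pairs(geo, spec)
  k <- length(pairs)
  data.frame(
    class_lo = spec$breaks[seq_len(k)],
    class_hi = spec$breaks[seq_len(k) + 1],
    n_pairs = vapply(pairs, nrow, integer(1)),
    r = vapply(pairs, function(p) r_from_pairs(cmat, p), numeric(1)))
}

#' Bootstrap confidence intervals for per-class r
#'
#' Resamples pairs within each distance class with replacement `n_boot`
#' times, recomputes `r`, and takes the `alpha/2` and `1 - alpha/2`
#' percentiles.
#'
#' @inheritParams autocorrelation_r
#' @param n_boot Number of bootstrap iterations (999 by convention).
#' @param alpha Two-sided error level for the interval.
#' @param seed Integer seed.
#' @return `data.frame` with `boot_lo`, `boot_hi` per class.
#' @export
bootstrap_r_ci <- function(gd, geo, spec = distance_class_spec(),
                           n_boot = 999, alpha = 0.05, seed = NULL) {
  cmat <- center_distance_matrix(gd)
  pairs <- class_pairs(geo, spec)
  with_seed(seed, {
    ci <- t(vapply(pairs, function(p) {
      np <- nrow(p)
      if (np == 0) return(c(NA_real_, NA_real_))
      reps <- vapply(seq_len(n_boot), function(b) {
        r_from_pairs(cmat, p[sample.int(np, np, replace = TRUE), ,
                             drop = FALSE])
      }, numeric(1))
      stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                      names = FALSE)
    }, numeric(2)))
    data.frame(boot_lo = ci[, 1], boot_hi = ci[, 2])
  })
}

#' Permutation null bounds for per-class r
#'
#' Permutes individual locations among individuals (equivalently, applies a
#' common random permutation to the rows and columns of the geographic
#' distance matrix), recomputes per-class `r`, and returns percentile
#' bounds of the null distribution -- the expectation of `r` under a random
#' geographic arrangement of the genotypes.
#'
#' @inheritParams bootstrap_r_ci
#' @param n_perm Number of permutations (999 by convention).
#' @return `data.frame` with `null_lo`, `null_hi` per class.
#' @export
permutation_null_ci <- function(gd, geo, spec = distance_class_spec(),
                                n_perm = 999, alpha = 0.05, seed = NULL) {
  cmat <- center_distance_matrix(gd)
  n <- nrow(geo)
  k <- length(spec$breaks) - 1
  with_seed(seed, {
    null_r <- matrix(NA_real_, n_perm, k)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      pairs <- class_pairs(geo[perm, perm], spec)
      null_r[b, ] <- vapply(pairs, function(p) r_from_pairs(cmat, p),
                            numeric(1))
    }
    ci <- apply(null_r, 2, stats::quantile, probs = c(alpha / 2,
                                                      1 - alpha / 2),
                na.rm = TRUE, names = FALSE)
    data.frame(null_lo = ci[1, ], null_hi = ci[2, ])
  })
}

#' Full correlogram for a dataset
#'
#' Computes genetic and geographic distances, per-class `r`, bootstrap CIs
#' and the permutation null, optionally separately by sex. Classes with no
#' pairs carry `NA` and a `significant_positive` flag of `FALSE`; sex
#' groups with fewer than 3 individuals are skipped with a warning.
#'
#' @param ds An `snp_dataset`.
#' @param spec A [distance_class_spec()].
#' @param grouping `"all"` (one correlogram) or `"by_sex"` (one per sex).
#' @param n_boot,n_perm Bootstrap and permutation iteration counts.
#' @param alpha Two-sided error level.
#' @param seed Integer seed.
#' @return For `grouping = "all"`, a `correlogram` `data.frame` (class
#'   bounds, `n_pairs`, `r`, `boot_lo/hi`, `null_lo/hi`,
#'   `significant_positive`); for `"by_sex"`, a named list of them.
#' @export
correlogram <- function(ds, spec = distance_class_spec(),
                        grouping = c("all", "by_sex"), n_boot = 999,
                        n_perm = 999, alpha = 0.05, seed = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "by_sex") {
    sexes <- unique(ds$individuals$sex)
    out <- list()
    for (s in sexes) {
      idx <- which(ds$individuals$sex == s)
      if (length(idx) < 3) {
        warning("sex group '", s, "' has fewer than 3 individuals: skipped",
                call. = FALSE)
        next
      }
      out[[s]] <- correlogram(subset_individuals(ds, idx), spec, "all",
                              n_boot, n_perm, alpha, seed)
    }
    return(out)
  }
  gd <- genetic_distance_matrix(ds)
  geo <- geo_distance_matrix(ds)
  res <- autocorrelation_r(gd, geo, spec)
  res <- cbind(res,
               bootstrap_r_ci(gd, geo, spec, n_boot, alpha,
                              seed = derive_seed(seed %||% 0, 1)),
               permutation_null_ci(gd, geo, spec, n_perm, alpha,
                                   seed = derive_seed(seed %||% 0, 2)))
  res$significant_positive <- !is.na(res$r) & res$r > 0 &
    !is.na(res$boot_lo) & res$boot_lo > 0
  class(res) <- c("correlogram", class(res))
  res
}

#' Positive-structure call for one distance class
#'
#' A class shows significant positive genetic structure when its `r` is
#' positive and the lower bound of its 95% bootstrap CI is above zero --
#' the rule used to flag sample sizes where >95% of replicates detect
#' structure.
#'
#' @param corr A `correlogram` (from [correlogram()]).
#' @param class_of_interest Lower bound (metres) of the class to test,
#'   e.g. `0` for the first (0-250 m) class; alternatively a row index if
#'   `by = "index"`.
#' @param by Interpret `class_of_interest` as a class lower bound
#'   (`"lo"`, default) or a row index (`"index"`).
#' @return Logical.
#' @export
detect_positive_structure <- function(corr, class_of_interest = 0,
                                      by = c("lo", "index")) {
  by <- match.arg(by)
  row <- if (by == "lo") which(corr$class_lo == class_of_interest)
         else class_of_interest
  if (length(row) != 1 || row > nrow(corr))
    stop("no unique distance class matching ", class_of_interest,
         call. = FALSE)
  isTRUE(corr$significant_positive[row])
}
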