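# Simulated genetic non-invasive sampling (gNIS): a fixed SNP panel
# subsample, spatially explicit thinning of individuals, and per-locus
# call-rate degradation calibrated so the panel's global call-rate
# statistics match a measured profile (e.g. 2-week experimentally aged
# scat: min 0.43, max 1, mean 0.62, sd 0.13).

#' Call-rate degradation profile
#'
#' The four global call-rate statistics a degraded panel must match. The
#' default is the 2-week aged-scat profile.
#'
#' @param min_rate,max_rate,mean_rate,sd_rate Global per-locus call-rate
#'   minimum, maximum, mean and standard deviation.
#' @return A `call_rate_profile` list.
#' @export
call_rate_profile <- function(min_rate = 0.43, max_rate = 1,
                              mean_rate = 0.62, sd_rate = 0.13) {
  stopifnot(min_rate >= 0, max_rate <= 1, sd_rate >= 0)
  if (min_rate > mean_rate || mean_rate > max_rate)
    stop("infeasible profile: need min_rate <= mean_rate <= max_rate",
         call. = FALSE)
  structure(list(min_rate = min_rate, max_rate = max_rate,
                 mean_rate = mean_rate, sd_rate = sd_rate),
            class = "call_rate_profile")
}

#' Experimental design for a gNIS simulation
#'
#' Defaults reproduce the full design: a fixed 1300-SNP panel, population
#' subsamples of 40 to 420 individuals in steps of 20, 100 replicates per
#' size, and the aged-scat degradation profile.
#'
#' @param panel_size Number of SNPs in the fixed panel.
#' @param sample_sizes Ordered vector of individual subsample sizes.
#' @param replicates Replicates per sample size.
#' @param profile A [call_rate_profile()].
#' @param master_seed Integer seed from which all per-replicate seeds are
#'   derived.
#' @return A `gnis_design` list.
#' @export
gnis_design <- function(panel_size = 1300,
                        sample_sizes = seq(40, 420, by = 20),
                        replicates = 100,
                        profile = call_rate_profile(),
                        master_seed = 1) {
  stopifnot(panel_size >= 1, replicates >= 1, all(sample_sizes >= 1),
            inherits(profile, "call_rate_profile"))
  structure(list(panel_size = panel_size,
                 sample_sizes = as.integer(sort(sample_sizes)),
                 replicates = as.integer(replicates), profile = profile,
                 master_seed = master_seed),
            class = "gnis_design")
}

#' Subsample a fixed SNP panel
#'
#' Draws `panel_size` loci uniformly without replacement. The panel is meant
#' to be drawn once per experiment and reused for every replicate, so that
#' replicate-to-replicate variation reflects sampling and degradation, not
#' panel composition.
#'
#' @param ds An `snp_dataset`.
#' @param panel_size Number of loci to keep.
#' @param seed Integer seed.
#' @return The dataset restricted to the panel loci.
#' @export
subsample_panel <- function(ds, panel_size, seed = NULL) {
  if (panel_size > n_loci(ds))
    stop("panel_size (", panel_size, ") exceeds available loci (",
         n_loci(ds), ")", call. = FALSE)
  with_seed(seed, {
    keep <- sort(sample.int(n_loci(ds), panel_size))
    subset_loci(ds, keep)
  })
}

#' Spatially explicit thinning of individuals
#'
#' Mirrors field protocols that survey locations rather than individuals:
#' draws `n_keep` uniform random points within the convex hull of the
#' capture coordinates and, for each point in turn, retains the nearest
#' not-yet-selected individual. Compared with uniform random subsampling
#' this preserves the spatial spread of the population, down-weighting
#' dense aggregations.
#'
#' @param ds An `snp_dataset` with capture coordinates.
#' @param n_keep Number of individuals to retain.
#' @param seed Integer seed.
#' @param type `"random"` (uniform points in the hull, default) or
#'   `"regular"` (a jittered square grid clipped to the hull).
#' @return The dataset restricted to the selected individuals.
#' @export
spatial_thin <- function(ds, n_keep, seed = NULL, type = c("random",
                                                           "regular")) {
  type <- match.arg(type)
  n <- n_individuals(ds)
  if (n_keep > n)
    stop("n_keep (", n_keep, ") exceeds population size (", n, ")",
         call. = FALSE)
  if (n_keep == n) return(ds)
  xy <- cbind(ds$individuals$x, ds$individuals$y)
  hull_idx <- grDevices::chull(xy)
  degenerate <- length(hull_idx) < 3 ||
    abs(polygon_area(xy[hull_idx, , drop = FALSE])) < 1e-9
  with_seed(seed, {
    if (degenerate) {
      warning("fewer than 3 non-collinear coordinates: falling back to ",
              "uniform random subsampling", call. = FALSE)
      keep <- sort(sample.int(n, n_keep))
      return(subset_individuals(ds, keep))
    }
    pts <- sample_in_hull(xy, hull_idx, n_keep, type)
    selected <- integer(0)
    avail <- rep(TRUE, n)
    for (i in seq_len(nrow(pts))) {
      d2 <- (xy[, 1] - pts[i, 1])^2 + (xy[, 2] - pts[i, 2])^2
      d2[!avail] <- Inf
      j <- which.min(d2)
      selected <- c(selected, j)
      avail[j] <- FALSE
    }
    subset_individuals(ds, sort(selected))
  })
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

# Uniform (or jittered-regular) points inside the convex hull, by rejection
# from the bounding box using mgcv's point-in-polygon test.
sample_in_hull <- function(xy, hull_idx, n_pts, type) {
  bnd <- xy[c(hull_idx, hull_idx[1]), , drop = FALSE]
  rx <- range(bnd[, 1]); ry <- range(bnd[, 2])
  if (type == "regular") {
    # jittered grid over the bounding box, clipped to the hull, then topped
    # up with random points if the clip leaves too few
    k <- ceiling(sqrt(n_pts * diff(rx) * diff(ry) /
                        max(abs(polygon_area(xy[hull_idx, , drop = FALSE])),
                            1e-9)))
    gx <- seq(rx[1], rx[2], length.out = k + 1)
    gy <- seq(ry[1], ry[2], length.out = k + 1)
    grid <- as.matrix(expand.grid(gx, gy))
    grid <- grid + cbind(stats::runif(nrow(grid), 0, diff(rx) / (2 * k)),
                         stats::runif(nrow(grid), 0, diff(ry) / (2 * k)))
    inside <- mgcv::in.out(bnd, grid)
    pts <- grid[inside, , drop = FALSE]
    if (nrow(pts) >= n_pts)
      return(pts[sample.int(nrow(pts), n_pts), , drop = FALSE])
    need <- n_pts - nrow(pts)
  } else {
    pts <- matrix(numeric(0), 0, 2)
    need <- n_pts
  }
  guard <- 0
  while (need > 0 && guard < 1000) {
    cand <- cbind(stats::runif(4 * need, rx[1], rx[2]),
                  stats::runif(4 * need, ry[1], ry[2]))
    inside <- mgcv::in.out(bnd, cand)
    acc <- cand[inside, , drop = FALSE]
    if (nrow(acc) > 0) {
      take <- utils::head(acc, need)
      pts <- rbind(pts, take)
      need <- need - nrow(take)
    }
    guard <- guard + 1
  }
  if (need > 0) stop("failed to sample points inside the hull",
                     call. = FALSE)
  pts
}

#' Calibrate per-locus expected call rates to a profile
#'
#' Draws expected call rates from a normal distribution truncated to
#' `[min_rate, max_rate]`, pins one locus to the minimum and one to the
#' maximum (so the printed extremes are realized exactly), then iteratively
#' rescales (affine adjustment + re-truncation, at most 100 iterations)
#' until the realized mean is within 0.005 and the realized standard
#' deviation within 0.01 of the profile.
#'
#' @param n_loci Number of loci to calibrate.
#' @param profile A [call_rate_profile()].
#' @param seed Integer seed.
#' @return Numeric vector of expected call rates in
#'   `[min_rate, max_rate]`.
#' @export
calibrate_locus_call_rates <- function(n_loci, profile, seed = NULL) {
  stopifnot(inherits(profile, "call_rate_profile"), n_loci >= 1)
  lo <- profile$min_rate; hi <- profile$max_rate
  m <- profile$mean_rate; s <- profile$sd_rate
  # degenerate cases: no spread requested, or too few loci to pin both
  # extremes while holding the moments
  if (s == 0 || n_loci <= 2) return(rep(m, n_loci))
  with_seed(seed, {
    # inverse-CDF truncated-normal draw
    plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
    x <- stats::qnorm(stats::runif(n_loci, plo, phi), m, s)
    pin_min <- which.min(x); x[pin_min] <- lo
    pin_max <- which.max(x); x[pin_max] <- hi
    free <- setdiff(seq_len(n_loci), c(pin_min, pin_max))
    for (it in seq_len(100)) {
      cur_m <- mean(x); cur_s <- stats::sd(x)
      if (abs(cur_m - m) < 1e-3 && abs(cur_s - s) < 2e-3) break
      k <- length(free)
      mf <- (n_loci * m - lo - hi) / k
      ss_target <- (n_loci - 1) * s^2 - (lo - m)^2 - (hi - m)^2
      ssc_target <- ss_target - k * (mf - m)^2
      xc <- x[free] - mean(x[free])
      ssc <- sum(xc^2)
      alpha <- if (ssc > 0 && ssc_target > 0) sqrt(ssc_target / ssc) else 1
      x[free] <- pmin(pmax(mf + alpha * xc, lo), hi)
    }
    x
  })
}

#' Degrade genotypes to expected call rates
#'
#' For locus `j`, each individual's genotype is independently set missing
#' with probability `1 - expected_rates[j]`, on top of any existing
#' missingness (a missing call never becomes observed, and an observed
#' genotype's value is never altered). Fresh randomness per replicate means
#' a locus is not degraded the same way, or to the same extent, across
#' simulated datasets.
#'
#' @param ds An `snp_dataset`.
#' @param expected_rates Vector of per-locus expected call rates, length
#'   `n_loci(ds)`.
#' @param seed Integer seed.
#' @return The degraded dataset.
#' @export
degrade <- function(ds, expected_rates, seed = NULL) {
  stopifnot(length(expected_rates) == n_loci(ds),
            all(expected_rates >= 0), all(expected_rates <= 1))
  with_seed(seed, {
    g <- ds$genotypes
    u <- matrix(stats::runif(length(g)), nrow(g), ncol(g))
    miss <- sweep(u, 2, expected_rates, `>`)
    g[miss] <- NA_integer_
    ds$genotypes <- g
    ds
  })
}

#' Simulate one gNIS replicate
#'
#' Runs the per-replicate portion of the simulation workflow: spatial
#' thinning to `n_keep` individuals, restriction to the fixed SNP panel,
#' call-rate calibration, degradation, and the standard filter pipeline.
#' All randomness derives from `replicate_seed`.
#'
#' @param full_ds The complete (already quality-filtered) dataset.
#' @param panel Character vector of panel locus IDs (from
#'   [subsample_panel()]).
#' @param n_keep Number of individuals to retain.
#' @param profile A [call_rate_profile()].
#' @param replicate_seed Integer seed for this replicate.
#' @param filter_cfg A [filter_config()] applied after degradation.
#' @return List with `dataset` (filtered, degraded `snp_dataset`) and
#'   `filter_report`.
#' @export
simulate_replicate <- function(full_ds, panel, n_keep,
                               profile = call_rate_profile(),
                               replicate_seed = 1,
                               filter_cfg = filter_config()) {
  thinned <- suppressWarnings(
    spatial_thin(full_ds, n_keep, seed = derive_seed(replicate_seed, 1)))
  panel_ds <- subset_loci(thinned, panel)
  rates <- calibrate_locus_call_rates(n_loci(panel_ds), profile,
                                      seed = derive_seed(replicate_seed, 2))
  degraded <- degrade(panel_ds, rates, seed = derive_seed(replicate_seed, 3))
  res <- suppressWarnings(apply_filters(degraded, filter_cfg))
  list(dataset = res$dataset, filter_report = res$report)
}
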