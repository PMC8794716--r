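test_that("geographic distances are planar Euclidean", {
  ind <- toy_individuals(3, x = c(0, 300, 300), y = c(0, 0, 400))
  geo <- geo_distance_matrix(ind)
  expect_equal(geo[1, 2], 300)
  expect_equal(geo[2, 3], 400)
  expect_equal(geo[1, 3], 500)
  expect_equal(diag(geo), rep(0, 3), ignore_attr = TRUE)
  same <- toy_individuals(2, x = c(5, 5), y = c(2, 2))
  expect_equal(geo_distance_matrix(same)[1, 2], 0)
})

test_that("genetic distances follow the codominant squared metric", {
  ds <- toy_ds(matrix(c(0, 2), 2, 1))
  expect_equal(genetic_distance_matrix(ds)[1, 2], 4)
  ds <- toy_ds(matrix(c(0, 1), 2, 1))
  expect_equal(genetic_distance_matrix(ds)[1, 2], 1)
  ds <- toy_ds(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(genetic_distance_matrix(ds)[1, 2], 0)
  # shared-locus scaling: 2 loci, only one comparable, d2 = 1 -> 1 * 2/1
  ds <- toy_ds(rbind(c(0, 1), c(1, NA)))
  expect_equal(genetic_distance_matrix(ds)[1, 2], 2)
  # pair with no shared locus flagged
  ds <- toy_ds(rbind(c(0, NA), c(NA, 1)))
  expect_warning(gd <- genetic_distance_matrix(ds), "share no observed")
  expect_true(is.na(gd[1, 2]))
})

test_that("autocorrelation r matches the brute-force oracle", {
  breaks <- seq(0, 1000, by = 250)
  for (seed in 1:6) {
    set.seed(seed)
    g <- matrix(sample(0:2, 12 * 30, replace = TRUE), 12, 30)
    g[matrix(runif(12 * 30) < 0.1, 12, 30)] <- NA
    xy <- cbind(runif(12, 0, 900), runif(12, 0, 900))
    ds <- snp_dataset(g, toy_loci(30),
                      toy_individuals(12, x = xy[, 1], y = xy[, 2]))
    spec <- distance_class_spec(250, 1000)
    res <- autocorrelation_r(genetic_distance_matrix(ds),
                             geo_distance_matrix(ds), spec)
    expect_equal(res$r, brute_r(g, xy, breaks), tolerance = 1e-10)
  }
})

test_that("clustered genotype pools give signed r by distance class", {
  # two spatial clusters with distinct fixed genotype pools: positive r
  # within clusters, negative r between them
  g <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L),
             c(2L, 2L, 2L), c(2L, 2L, 1L), c(2L, 1L, 2L))
  ind <- toy_individuals(6, x = c(0, 10, 20, 1000, 1010, 1020),
                         y = rep(0, 6))
  ds <- snp_dataset(g, toy_loci(3), ind)
  spec <- distance_class_spec(500, 1500)
  res <- autocorrelation_r(genetic_distance_matrix(ds),
                           geo_distance_matrix(ds), spec)
  expect_gt(res$r[1], 0)   # within-cluster class (0-500 m)
  expect_lt(res$r[2], 0)   # between-cluster class (500-1000 ... 1000+)
})

test_that("self-similar duplicates maximise first-class r", {
  set.seed(8)
  g <- matrix(sample(0:2, 8 * 40, replace = TRUE), 8, 40)
  xy <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
  g2 <- rbind(g, g)
  ind <- toy_individuals(16, x = rep(xy[, 1], 2), y = rep(xy[, 2], 2))
  ds <- snp_dataset(g2, toy_loci(40), ind)
  res <- autocorrelation_r(genetic_distance_matrix(ds),
                           geo_distance_matrix(ds),
                           distance_class_spec(500, 3000))
  expect_equal(which.max(res$r), 1)
})

test_that("bootstrap CIs bracket r and are seed-stable", {
  set.seed(91)
  sp <- population_spec(n_individuals = 40, n_loci = 80, n_contigs = 60,
                        seed = 91)
  ds <- generate_population(sp)
  gd <- genetic_distance_matrix(ds)
  geo <- geo_distance_matrix(ds)
  spec <- distance_class_spec(500, 3000)
  ci <- bootstrap_r_ci(gd, geo, spec, n_boot = 199, seed = 14)
  ci2 <- bootstrap_r_ci(gd, geo, spec, n_boot = 199, seed = 14)
  expect_equal(ci, ci2)
  r <- autocorrelation_r(gd, geo, spec)$r
  ok <- !is.na(r)
  expect_true(all(ci$boot_lo[ok] <= r[ok] + 1e-9))
  expect_true(all(ci$boot_hi[ok] >= r[ok] - 1e-9))
})

test_that("a single-pair class has a zero-width bootstrap CI", {
  ind <- toy_individuals(4, x = c(0, 10, 2000, 4000), y = rep(0, 4))
  set.seed(2)
  g <- matrix(sample(0:2, 4 * 20, replace = TRUE), 4, 20)
  ds <- snp_dataset(g, toy_loci(20), ind)
  spec <- distance_class_spec(100, 5000)
  ci <- bootstrap_r_ci(genetic_distance_matrix(ds),
                       geo_distance_matrix(ds), spec, n_boot = 99,
                       seed = 3)
  r <- autocorrelation_r(genetic_distance_matrix(ds),
                         geo_distance_matrix(ds), spec)
  expect_equal(ci$boot_lo[1], ci$boot_hi[1])
  expect_equal(ci$boot_lo[1], r$r[1])
})

test_that("permutation null is seed-stable and brackets null data", {
  sp <- population_spec(n_individuals = 50, n_loci = 100, n_contigs = 80,
                        ibd_range = 0, ibd_sd = 0, seed = 95)
  ds <- generate_population(sp)
  gd <- genetic_distance_matrix(ds)
  geo <- geo_distance_matrix(ds)
  spec <- distance_class_spec(500, 3000)
  n1 <- permutation_null_ci(gd, geo, spec, n_perm = 99, seed = 5)
  expect_equal(n1, permutation_null_ci(gd, geo, spec, n_perm = 99,
                                       seed = 5))
  r <- autocorrelation_r(gd, geo, spec)$r
  # location-independent genotypes: observed r inside the null bounds for
  # most classes
  inside <- r >= n1$null_lo & r <= n1$null_hi
  expect_gte(mean(inside, na.rm = TRUE), 0.8)
})

test_that("positive-structure detection applies the CI rule", {
  corr <- data.frame(class_lo = c(0, 250), class_hi = c(250, 500),
                     n_pairs = c(10, 10), r = c(0.05, 0.05),
                     boot_lo = c(0.01, -0.01), boot_hi = c(0.09, 0.11))
  corr$significant_positive <- corr$r > 0 & corr$boot_lo > 0
  class(corr) <- c("correlogram", class(corr))
  expect_true(detect_positive_structure(corr, 0))
  expect_false(detect_positive_structure(corr, 250))
  corr$r[1] <- -0.02; corr$boot_lo[1] <- -0.04; corr$boot_hi[1] <- -0.01
  corr$significant_positive <- corr$r > 0 & corr$boot_lo > 0
  expect_false(detect_positive_structure(corr, 0))
  expect_error(detect_positive_structure(corr, 999), "no unique")
})

test_that("correlogram grouping by sex matches per-sex computation", {
  sp <- population_spec(n_individuals = 30, n_loci = 60, n_contigs = 50,
                        seed = 97)
  ds <- generate_population(sp)
  spec <- distance_class_spec(1000, 4000)
  both <- correlogram(ds, spec, "by_sex", n_boot = 49, n_perm = 49,
                      seed = 6)
  expect_setequal(names(both), c("male", "female"))
  males <- subset_individuals(ds, ds$individuals$sex == "male")
  direct <- correlogram(males, spec, "all", n_boot = 49, n_perm = 49,
                        seed = 6)
  expect_equal(both$male, direct)
  # all-female dataset yields a single correlogram
  f <- ds
  f$individuals$sex <- "female"
  one <- correlogram(f, spec, "by_sex", n_boot = 9, n_perm = 9, seed = 1)
  expect_equal(names(one), "female")
  # a tiny group is skipped with a warning
  g <- ds
  g$individuals$sex <- c("male", "male", rep("female", 28))
  expect_warning(res <- correlogram(g, spec, "by_sex", n_boot = 9,
                                    n_perm = 9, seed = 1), "fewer than 3")
  expect_equal(names(res), "female")
})
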