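small_pop <- function(seed = 101) {
  generate_population(population_spec(n_individuals = 70, n_loci = 250,
                                      n_contigs = 200,
                                      spatial_extent = 2000, seed = seed))
}

small_dc <- distance_class_spec(class_width = 500, max_distance = 3000)

test_that("ground truth filters once and measures everything", {
  ds <- small_pop()
  tr <- ground_truth(ds, dc_spec = small_dc, classes_of_interest = c(0, 500),
                     n_boot = 49, seed = 1)
  expect_lte(tr$n_loci_post_filter, n_loci(ds))
  expect_equal(tr$n_loci_post_filter, n_loci(tr$dataset))
  expect_length(tr$ir, 70)
  # deterministic for fixed input
  tr2 <- ground_truth(ds, dc_spec = small_dc,
                      classes_of_interest = c(0, 500), n_boot = 49, seed = 1)
  expect_equal(tr, tr2)
  # truth FIS recovers the generator target
  expect_lt(abs(tr$diversity$fis - 0.125), 0.03)
})

test_that("the replicate loop yields one row per design cell", {
  ds <- small_pop(seed = 103)
  design <- gnis_design(panel_size = 80, sample_sizes = c(40, 60),
                        replicates = 3, master_seed = 11)
  out <- run_experiment(ds, design, dc_spec = small_dc,
                        classes_of_interest = c(0, 500), n_boot = 29)
  expect_equal(nrow(out$results), 6)
  expect_equal(sort(unique(out$results$sample_size)), c(40, 60))
  expect_equal(length(out$panel), 80)
  # reproducible end to end
  out2 <- run_experiment(ds, design, dc_spec = small_dc,
                         classes_of_interest = c(0, 500), n_boot = 29)
  expect_equal(out$results, out2$results)
})

test_that("a degradation-free full-coverage design has zero bias", {
  ds <- small_pop(seed = 105)
  tr <- ground_truth(ds, dc_spec = small_dc, classes_of_interest = c(0, 500),
                     n_boot = 29, seed = 2)
  design <- gnis_design(panel_size = n_loci(tr$dataset),
                        sample_sizes = n_individuals(tr$dataset),
                        replicates = 2,
                        profile = call_rate_profile(1, 1, 1, 0),
                        master_seed = 21)
  out <- run_experiment(ds, design, dc_spec = small_dc,
                        classes_of_interest = c(0, 500), n_boot = 29)
  s <- out$summary$per_size
  expect_equal(s$bias_he, 0, tolerance = 1e-12)
  expect_equal(s$bias_i, 0, tolerance = 1e-12)
  expect_equal(s$bias_fis, 0, tolerance = 1e-12)
  expect_equal(out$results$ir_corr, c(1, 1), tolerance = 1e-12)
})

test_that("summaries match hand arithmetic on a built table", {
  results <- data.frame(
    sample_size = rep(c(40, 80), each = 4),
    replicate = rep(1:4, 2), seed = 1:8,
    n_loci_post_filter = 50, failed = FALSE,
    he = c(0.30, 0.32, 0.29, 0.31, 0.28, 0.30, 0.30, 0.32),
    he_se = 0, ho = 0.25, shannon = c(0.45, 0.47, 0.44, 0.46,
                                      0.43, 0.45, 0.45, 0.47),
    shannon_se = 0, fis = c(0.10, 0.12, 0.09, 0.11, 0.08, 0.10,
                            0.10, 0.12),
    ir_corr = c(0.6, 0.7, 0.65, 0.75, 0.8, 0.85, 0.8, 0.95),
    sig_0 = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  truth <- list(diversity = list(he_mean = 0.30, shannon_mean = 0.45,
                                 fis = 0.10))
  s <- summarize_experiment(results, truth, detection_threshold = 0.95)
  expect_equal(s$per_size$bias_he, c(mean(results$he[1:4]) - 0.30,
                                     mean(results$he[5:8]) - 0.30))
  expect_equal(s$per_size$sd_fis,
               c(sd(results$fis[1:4]), sd(results$fis[5:8])))
  expect_equal(s$per_size$mean_ir_corr, c(0.675, 0.85))
  expect_equal(s$per_size$detection_rate_0, c(0.75, 1))
  # only size 80 strictly exceeds the 0.95 detection threshold
  expect_equal(unname(s$threshold_sizes["class_0"]), 80)
  # nothing qualifies at a higher threshold
  s2 <- summarize_experiment(results, truth, detection_threshold = 1)
  expect_true(is.na(s2$threshold_sizes["class_0"]))
  # all replicates significant: threshold is the smallest size
  results$sig_0 <- TRUE
  s3 <- summarize_experiment(results, truth)
  expect_equal(unname(s3$threshold_sizes["class_0"]), 40)
})

test_that("failed replicates are excluded from summaries but counted", {
  results <- data.frame(
    sample_size = 40, replicate = 1:3, seed = 1:3,
    n_loci_post_filter = c(50, 0, 50), failed = c(FALSE, TRUE, FALSE),
    he = c(0.3, NA, 0.32), he_se = 0, ho = 0.25,
    shannon = c(0.45, NA, 0.46), shannon_se = 0,
    fis = c(0.1, NA, 0.12), ir_corr = c(0.6, NA, 0.7),
    sig_0 = c(TRUE, NA, TRUE))
  truth <- list(diversity = list(he_mean = 0.3, shannon_mean = 0.45,
                                 fis = 0.1))
  s <- summarize_experiment(results, truth)
  expect_equal(s$per_size$n_replicates, 2)
  expect_equal(s$per_size$n_failed, 1)
  expect_equal(s$per_size$bias_he, mean(c(0.3, 0.32)) - 0.3)
  expect_equal(s$per_size$detection_rate_0, 1)
})

test_that("an interrupted run resumes from the results file", {
  ds <- small_pop(seed = 107)
  design <- gnis_design(panel_size = 60, sample_sizes = 40, replicates = 2,
                        master_seed = 31)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "run.csv")
  full <- run_experiment(ds, design, dc_spec = small_dc,
                         classes_of_interest = 0, n_boot = 19,
                         out_file = f1)
  # re-running against the completed file reuses every row
  resumed <- run_experiment(ds, design, dc_spec = small_dc,
                            classes_of_interest = 0, n_boot = 19,
                            out_file = f1)
  expect_equal(resumed$results$he, full$results$he)
  expect_equal(resumed$results$sig_0, full$results$sig_0)
})
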