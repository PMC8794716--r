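# Orchestration of the full simulation experiment: ground truth from the
# complete dataset, the replicate loop over sample sizes, and the
# accuracy / precision / detection summary.

#' Ground truth from the complete dataset
#'
#' Filters the complete dataset once and computes every measure on it:
#' diversity estimates, the per-individual IR vector (kept for
#' per-replicate correlations), and the correlogram of the classes of
#' interest.
#'
#' @param full_ds The complete `snp_dataset`.
#' @param filter_cfg A [filter_config()].
#' @param dc_spec A [distance_class_spec()].
#' @param classes_of_interest Lower bounds (metres) of the distance classes
#'   tracked per replicate; default the 250-m and 500-m classes.
#' @param n_boot Bootstrap iterations for the truth correlogram.
#' @param seed Integer seed (bootstrap only; the truth measures themselves
#'   are deterministic).
#' @return List with `dataset` (filtered), `n_loci_post_filter`,
#'   `diversity`, `ir` (named vector), and `structure` (per tracked class:
#'   `r`, bootstrap CI, significance flag).
#' @export
ground_truth <- function(full_ds, filter_cfg = filter_config(),
                         dc_spec = distance_class_spec(),
                         classes_of_interest = c(0, 250), n_boot = 999,
                         seed = 1) {
  filt <- suppressWarnings(apply_filters(full_ds, filter_cfg))
  ds <- filt$dataset
  if (n_loci(ds) == 0) stop("no loci survive filtering", call. = FALSE)
  div <- diversity_estimates(ds)
  ir <- suppressWarnings(internal_relatedness(ds))
  structure_rows <- replicate_structure(ds, dc_spec, classes_of_interest,
                                        n_boot, seed)
  list(dataset = ds, n_loci_post_filter = n_loci(ds), diversity = div,
       ir = ir, structure = structure_rows, filter_report = filt$report)
}

# r + bootstrap CI restricted to the requested classes (cheaper than a full
# correlogram when only one or two classes are tracked per replicate)
replicate_structure <- function(ds, dc_spec, class_lo, n_boot, seed) {
  gd <- suppressWarnings(genetic_distance_matrix(ds))
  geo <- geo_distance_matrix(ds)
  cmat <- center_distance_matrix(gd)
  pairs <- class_pairs(geo, dc_spec)
  k <- length(dc_spec$breaks) - 1
  rows <- match(class_lo, dc_spec$breaks[seq_len(k)])
  if (anyNA(rows)) stop("classes_of_interest must be class lower bounds",
                        call. = FALSE)
  out <- data.frame(class_lo = class_lo, r = NA_real_, boot_lo = NA_real_,
                    boot_hi = NA_real_, n_pairs = NA_integer_,
                    significant = FALSE)
  with_seed(seed, {
    for (i in seq_along(rows)) {
      p <- pairs[[rows[i]]]
      out$n_pairs[i] <- nrow(p)
      if (nrow(p) == 0) next
      out$r[i] <- r_from_pairs(cmat, p)
      reps <- vapply(seq_len(n_boot), function(b) {
        r_from_pairs(cmat, p[sample.int(nrow(p), nrow(p),
                                        replace = TRUE), , drop = FALSE])
      }, numeric(1))
      ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE)
      out$boot_lo[i] <- ci[1]; out$boot_hi[i] <- ci[2]
      out$significant[i] <- !is.na(out$r[i]) && out$r[i] > 0 && ci[1] > 0
    }
  })
  out
}

#' Run the full gNIS simulation experiment
#'
#' Draws the fixed SNP panel once from the filtered complete dataset, then
#' for every (sample size, replicate) cell: spatially thins individuals,
#' degrades the panel, re-filters, and measures diversity, the IR
#' correlation with truth (over the individuals present in the replicate),
#' and spatial structure in the tracked distance classes. Every cell's seed
#' derives from `design$master_seed` and the cell index, so any replicate
#' is reproducible in isolation and results are independent of execution
#' order.
#'
#' @param full_ds The complete `snp_dataset` (unfiltered).
#' @param design A [gnis_design()].
#' @param filter_cfg A [filter_config()], applied to the complete dataset
#'   and re-applied to every degraded replicate.
#' @param dc_spec A [distance_class_spec()].
#' @param classes_of_interest Distance-class lower bounds tracked per
#'   replicate.
#' @param n_boot Bootstrap iterations per replicate.
#' @param out_file Optional CSV path; replicate rows are appended as they
#'   complete, and cells already present in the file are skipped, making a
#'   long run resumable.
#' @param progress Print a line per completed sample size.
#' @return List with `results` (one `data.frame` row per replicate),
#'   `summary` (an [summarize_experiment()] table), `truth`, and `panel`
#'   (the fixed panel's locus IDs).
#' @export
run_experiment <- function(full_ds, design = gnis_design(),
                           filter_cfg = filter_config(),
                           dc_spec = distance_class_spec(),
                           classes_of_interest = c(0, 250), n_boot = 999,
                           out_file = NULL, progress = FALSE) {
  truth <- ground_truth(full_ds, filter_cfg, dc_spec, classes_of_interest,
                        n_boot, seed = derive_seed(design$master_seed, 0))
  if (design$panel_size > n_loci(truth$dataset))
    stop("panel_size exceeds post-filter locus count", call. = FALSE)
  if (max(design$sample_sizes) > n_individuals(truth$dataset))
    stop("largest sample size exceeds population size", call. = FALSE)
  panel_ds <- subsample_panel(truth$dataset, design$panel_size,
                              seed = derive_seed(design$master_seed, 1))
  panel <- panel_ds$loci$locus_id

  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file, stringsAsFactors = FALSE)
  }
  rows <- list()
  counter <- 1L
  for (si in seq_along(design$sample_sizes)) {
    size <- design$sample_sizes[si]
    for (rep_i in seq_len(design$replicates)) {
      cell_seed <- derive_seed(design$master_seed,
                               1000L + si * 10000L + rep_i)
      if (!is.null(done) &&
          any(done$sample_size == size & done$replicate == rep_i)) {
        rows[[counter]] <- done[done$sample_size == size &
                                  done$replicate == rep_i, , drop = FALSE]
        counter <- counter + 1L
        next
      }
      row <- run_one_replicate(truth, panel, size, rep_i, cell_seed,
                               design$profile, filter_cfg, dc_spec,
                               classes_of_interest, n_boot)
      rows[[counter]] <- row
      counter <- counter + 1L
      if (!is.null(out_file)) {
        utils::write.table(row, out_file, sep = ",", append =
                             file.exists(out_file),
                           col.names = !file.exists(out_file),
                           row.names = FALSE)
      }
    }
    if (progress)
      message("sample size ", size, ": ", design$replicates,
              " replicates done")
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       summary = summarize_experiment(results, truth),
       truth = truth, panel = panel)
}

run_one_replicate <- function(truth, panel, size, rep_i, cell_seed,
                              profile, filter_cfg, dc_spec,
                              classes_of_interest, n_boot) {
  sim <- simulate_replicate(truth$dataset, panel, size, profile,
                            replicate_seed = cell_seed,
                            filter_cfg = filter_cfg)
  ds <- sim$dataset
  base <- data.frame(sample_size = size, replicate = rep_i,
                     seed = cell_seed, n_loci_post_filter = n_loci(ds),
                     failed = FALSE, he = NA_real_, he_se = NA_real_,
                     ho = NA_real_, shannon = NA_real_,
                     shannon_se = NA_real_, fis = NA_real_,
                     ir_corr = NA_real_)
  for (lo in classes_of_interest) {
    base[[paste0("r_", lo)]] <- NA_real_
    base[[paste0("r_", lo, "_lo")]] <- NA_real_
    base[[paste0("r_", lo, "_hi")]] <- NA_real_
    base[[paste0("sig_", lo)]] <- NA
  }
  if (n_loci(ds) == 0 || n_individuals(ds) < 3) {
    base$failed <- TRUE
    return(base)
  }
  div <- diversity_estimates(ds)
  base$he <- div$he_mean; base$he_se <- div$he_se; base$ho <- div$ho_mean
  base$shannon <- div$shannon_mean; base$shannon_se <- div$shannon_se
  base$fis <- div$fis
  ir_rep <- suppressWarnings(internal_relatedness(ds))
  ir_true <- truth$ir[match(ds$individuals$individual_id,
                            names(truth$ir))]
  ok <- !is.na(ir_rep) & !is.na(ir_true)
  base$ir_corr <- if (sum(ok) >= 3) pearson_r(ir_rep[ok], ir_true[ok])
                  else NA_real_
  st <- replicate_structure(ds, dc_spec, classes_of_interest, n_boot,
                            seed = derive_seed(cell_seed, 99))
  for (i in seq_along(classes_of_interest)) {
    lo <- classes_of_interest[i]
    base[[paste0("r_", lo)]] <- st$r[i]
    base[[paste0("r_", lo, "_lo")]] <- st$boot_lo[i]
    base[[paste0("r_", lo, "_hi")]] <- st$boot_hi[i]
    base[[paste0("sig_", lo)]] <- st$significant[i]
  }
  base
}

#' Summarise an experiment
#'
#' Per sample size, over successful replicates: accuracy (mean estimate
#' minus full-data truth) and precision (standard deviation across
#' replicates) for He, Shannon's I and FIS; the mean IR correlation with
#' truth; and, per tracked distance class, the fraction of replicates
#' flagged significantly positive. The detection-threshold size for a class
#' is the smallest sample size whose detection rate strictly exceeds
#' `detection_threshold`.
#'
#' @param results Replicate table from [run_experiment()].
#' @param truth Ground-truth record from [ground_truth()].
#' @param detection_threshold Detection-rate threshold (default 0.95).
#' @return List with `per_size` (a `data.frame`) and `threshold_sizes`
#'   (named vector, `NA` where no size qualifies).
#' @export
summarize_experiment <- function(results, truth,
                                 detection_threshold = 0.95) {
  sizes <- sort(unique(results$sample_size))
  sig_cols <- grep("^sig_", names(results), value = TRUE)
  per_size <- do.call(rbind, lapply(sizes, function(s) {
    sub <- results[results$sample_size == s & !results$failed, ,
                   drop = FALSE]
    n_fail <- sum(results$sample_size == s & results$failed)
    row <- data.frame(
      sample_size = s, n_replicates = nrow(sub), n_failed = n_fail,
      bias_he = mean(sub$he) - truth$diversity$he_mean,
      bias_i = mean(sub$shannon) - truth$diversity$shannon_mean,
      bias_fis = mean(sub$fis) - truth$diversity$fis,
      sd_he = stats::sd(sub$he), sd_i = stats::sd(sub$shannon),
      sd_fis = stats::sd(sub$fis),
      mean_ir_corr = mean(sub$ir_corr, na.rm = TRUE))
    for (col in sig_cols) {
      row[[paste0("detection_rate_", sub("^sig_", "", col))]] <-
        mean(sub[[col]], na.rm = TRUE)
    }
    row
  }))
  thresholds <- vapply(sig_cols, function(col) {
    rate_col <- paste0("detection_rate_", sub("^sig_", "", col))
    qual <- per_size$sample_size[!is.na(per_size[[rate_col]]) &
                                   per_size[[rate_col]] >
                                     detection_threshold]
    if (length(qual) == 0) NA_real_ else min(qual)
  }, numeric(1))
  names(thresholds) <- paste0("class_", sub("^sig_", "", sig_cols))
  list(per_size = per_size, threshold_sizes = thresholds)
}
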