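# Fixture builders: small datasets constructed in code.

toy_loci <- function(n, contig = NULL, pos = NULL, repro = NULL) {
  data.frame(
    locus_id = sprintf("L%03d", seq_len(n)),
    contig_id = contig %||% sprintf("c%03d", seq_len(n)),
    position_in_contig = pos %||% rep(1L, n),
    reproducibility = repro %||% rep(0.99, n),
    stringsAsFactors = FALSE)
}

toy_individuals <- function(n, x = NULL, y = NULL, sex = NULL) {
  data.frame(
    individual_id = sprintf("I%03d", seq_len(n)),
    sex = sex %||% rep("unknown", n),
    x = x %||% (seq_len(n) * 10), y = y %||% rep(0, n),
    stringsAsFactors = FALSE)
}

# genotypes given as an individuals x loci matrix (possibly with NA)
toy_ds <- function(g, ...) {
  g <- as.matrix(g)
  snp_dataset(g, toy_loci(ncol(g), ...), toy_individuals(nrow(g)))
}

# random valid dataset with missingness, deterministic given seed
random_ds <- function(n_ind, n_loc, miss = 0.1, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_ind * n_loc, replace = TRUE), n_ind, n_loc)
  g[matrix(runif(n_ind * n_loc) < miss, n_ind, n_loc)] <- NA
  snp_dataset(g,
              toy_loci(n_loc,
                       contig = sprintf("c%03d", sample.int(max(1, n_loc %/% 2),
                                                            n_loc,
                                                            replace = TRUE)),
                       pos = sample.int(10000, n_loc),
                       repro = runif(n_loc, 0.9, 1)),
              toy_individuals(n_ind, x = runif(n_ind, 0, 1000),
                              y = runif(n_ind, 0, 1000)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
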