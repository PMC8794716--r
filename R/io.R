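# Readers and writers for the genotype CSV dialect and VCF 4.2.
#
# CSV dialect: UTF-8, comma-separated. The genotype file has a header row of
# locus IDs with first column "individual_id"; one row per individual; cells
# are alt-allele dosages 0/1/2 or the missing sentinel (default "NA").
# Companion files <stem>.loci.csv (locus_id, contig_id, position_in_contig,
# reproducibility) and <stem>.individuals.csv (individual_id, sex, x, y) carry
# the metadata.

companion_paths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(loci = paste0(stem, ".loci.csv"),
       individuals = paste0(stem, ".individuals.csv"))
}

#' Read / write the genotype CSV trio
#'
#' `write_genotype_csv()` writes a dataset as three CSV files (genotypes,
#' locus metadata, individual metadata); `read_genotype_csv()` reads them
#' back. The round trip is the identity.
#'
#' @param path Path of the genotype CSV; companion metadata files are located
#'   at `<stem>.loci.csv` and `<stem>.individuals.csv`.
#' @param missing Sentinel token written/parsed for missing genotypes.
#' @return `read_genotype_csv()` returns an `snp_dataset`;
#'   `write_genotype_csv()` returns `path` invisibly.
#' @export
read_genotype_csv <- function(path, missing = "NA") {
  cp <- companion_paths(path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1 || names(raw)[1] != "individual_id")
    stop("genotype CSV must have 'individual_id' as its first column",
         call. = FALSE)
  ids <- raw[[1]]
  locus_ids <- names(raw)[-1]
  g <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(locus_ids))
  for (j in seq_along(locus_ids)) {
    tok <- raw[[j + 1]]
    is_miss <- tok == missing | is.na(tok)
    ok <- tok %in% c("0", "1", "2") | is_miss
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("malformed genotype token '", tok[i], "' at row ", i,
           " (individual ", ids[i], "), column ", locus_ids[j], call. = FALSE)
    }
    g[!is_miss, j] <- as.integer(tok[!is_miss])
  }
  loci <- utils::read.csv(cp$loci, stringsAsFactors = FALSE)
  individuals <- utils::read.csv(cp$individuals, stringsAsFactors = FALSE)
  if (!identical(as.character(loci$locus_id), locus_ids))
    stop("locus IDs in ", cp$loci, " do not match the genotype header",
         call. = FALSE)
  if (!identical(as.character(individuals$individual_id), ids))
    stop("individual IDs in ", cp$individuals,
         " do not match the genotype rows", call. = FALSE)
  snp_dataset(g, loci, individuals)
}

#' @rdname read_genotype_csv
#' @param ds An `snp_dataset`.
#' @export
write_genotype_csv <- function(ds, path, missing = "NA") {
  cp <- companion_paths(path)
  g <- ds$genotypes
  tok <- matrix(as.character(g), nrow = nrow(g), ncol = ncol(g))
  tok[is.na(g)] <- missing
  df <- data.frame(individual_id = ds$individuals$individual_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  gdf <- as.data.frame(tok, stringsAsFactors = FALSE)
  names(gdf) <- ds$loci$locus_id
  utils::write.csv(cbind(df, gdf), path, row.names = FALSE, quote = FALSE,
                   na = missing)
  utils::write.csv(ds$loci, cp$loci, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$individuals, cp$individuals, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write biallelic VCF
#'
#' `read_vcf()` imports GT fields of biallelic sites from a VCF 4.2 file
#' (parsed with \pkg{vcfR}): `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`;
#' phased separators are accepted. `contig_id` is taken from CHROM and
#' `position_in_contig` copies POS verbatim (1-based, per the VCF standard).
#' Multiallelic sites are skipped with a warning. VCF carries no coordinates
#' or sex, so individuals get `unknown` sex and `(0, 0)` coordinates unless a
#' template is supplied.
#'
#' `write_vcf()` writes the dataset as a minimal uncompressed VCF 4.2 with
#' GT-only genotype columns.
#'
#' @param path VCF file path (plain or gzipped for reading).
#' @param individuals Optional individual metadata `data.frame` to attach
#'   (matched by `individual_id` to VCF sample names).
#' @return `read_vcf()` returns an `snp_dataset`; `write_vcf()` returns
#'   `path` invisibly.
#' @export
read_vcf <- function(path, individuals = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  g <- t(matrix(code(gt), nrow = nrow(gt), ncol = ncol(gt))) # ind x loci
  ids <- colnames(gt)
  loci <- data.frame(
    locus_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                      paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    contig_id = fix[, "CHROM"],
    position_in_contig = as.integer(fix[, "POS"]),
    reproducibility = NA_real_,
    stringsAsFactors = FALSE)
  if (is.null(individuals)) {
    individuals <- data.frame(individual_id = ids, sex = "unknown",
                              x = 0, y = 0, stringsAsFactors = FALSE)
  } else {
    individuals <- individuals[match(ids, individuals$individual_id), ,
                               drop = FALSE]
  }
  snp_dataset(g, loci, individuals)
}

#' @rdname read_vcf
#' @param ds An `snp_dataset`.
#' @export
write_vcf <- function(ds, path) {
  g <- ds$genotypes
  gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
  codes <- c("0/0", "0/1", "1/1")
  obs <- !is.na(g)
  gt[t(obs)] <- codes[t(g)[t(obs)] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gnisim",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$individuals$individual_id), collapse = "\t"))
  body <- paste(ds$loci$contig_id, ds$loci$position_in_contig,
                ds$loci$locus_id, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (ncol(g) == 0) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
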