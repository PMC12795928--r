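#' Genotype dosage matrix
#'
#' Container for an individuals-by-SNPs matrix of allele dosages (0, 1 or 2),
#' the substrate for GRM construction, GWAS and polygenic-index scoring.
#'
#' @param dosages integer matrix with entries in \{0, 1, 2\}; rows are
#'   individuals, columns SNPs.
#' @param sample_ids character vector of unique individual identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param allele_freq optional numeric vector of per-SNP coded-allele
#'   frequencies in (0, 1). Ancestral truth for simulated data; estimated
#'   from the sample when omitted.
#' @param subpop_labels optional integer vector of subpopulation labels
#'   (present when simulating population structure).
#' @param coded_allele optional character vector naming the allele counted by
#'   the dosage for each SNP (used for effect-allele matching when scoring).
#'
#' @return An object of class `genotype_matrix` with fields `sample_ids`,
#'   `snp_ids`, `dosages`, `allele_freq`, `subpop_labels`, `coded_allele`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_ids = colnames(dosages), allele_freq = NULL,
                            subpop_labels = NULL, coded_allele = NULL) {
  if (!is.matrix(dosages)) input_error("dosages must be a matrix")
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(sample_ids)) input_error("duplicate sample ids")
  if (anyDuplicated(snp_ids)) input_error("duplicate SNP ids")
  if (length(sample_ids) != nrow(dosages) || length(snp_ids) != ncol(dosages))
    input_error("id lengths do not match dosage dimensions")
  if (any(!(dosages %in% c(0L, 1L, 2L))))
    input_error("dosages must be 0, 1 or 2")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, snp_ids)
  if (is.null(allele_freq)) allele_freq <- colMeans(dosages) / 2
  if (length(allele_freq) != ncol(dosages))
    input_error("allele_freq length does not match the number of SNPs")
  if (!is.null(subpop_labels) && length(subpop_labels) != nrow(dosages))
    input_error("subpop_labels length does not match the number of individuals")
  structure(list(
    sample_ids = sample_ids, snp_ids = snp_ids, dosages = dosages,
    allele_freq = as.numeric(allele_freq),
    subpop_labels = subpop_labels,
    coded_allele = coded_allele
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              length(x$sample_ids), length(x$snp_ids)))
  if (!is.null(x$subpop_labels))
    cat(sprintf("  subpopulations: %s\n",
                paste(names(table(x$subpop_labels)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by individual ids
#'
#' @param G a [genotype_matrix()].
#' @param ids character vector of sample ids to keep (order respected).
#' @return a `genotype_matrix` restricted to `ids`.
#' @export
subset_genotypes <- function(G, ids) {
  idx <- match(ids, G$sample_ids)
  if (anyNA(idx)) input_error("unknown sample ids in subset")
  genotype_matrix(G$dosages[idx, , drop = FALSE], sample_ids = ids,
                  snp_ids = G$snp_ids, allele_freq = G$allele_freq,
                  subpop_labels = G$subpop_labels[idx],
                  coded_allele = G$coded_allele)
}

# Column-standardized dosages on the GCTA scale: (x - 2p)/sqrt(2p(1-p)) with
# p the sample allele frequency. Monomorphic columns are dropped.
standardized_dosages <- function(G) {
  p <- colMeans(G$dosages) / 2
  # zero-variance columns (including the all-heterozygote case) carry no
  # relatedness information and break standardization downstream
  v <- colMeans(G$dosages^2) - (2 * p)^2
  poly <- p > 0 & p < 1 & v > 0
  if (!any(poly)) degenerate_error("all SNPs are monomorphic")
  Z <- sweep(G$dosages[, poly, drop = FALSE], 2L, 2 * p[poly], `-`)
  Z <- sweep(Z, 2L, sqrt(2 * p[poly] * (1 - p[poly])), `/`)
  list(Z = Z, snp_ids = G$snp_ids[poly], p = p[poly])
}

#' Write / read a plain-text genotype matrix
#'
#' The text format is whitespace-delimited with a header row of SNP ids; each
#' following row is an individual id followed by its dosages.
#'
#' @param G a [genotype_matrix()].
#' @param path file path.
#' @return `write_geno` returns `path` invisibly; `read_geno` returns a
#'   `genotype_matrix`.
#' @export
write_geno <- function(G, path) {
  dt <- data.table::data.table(IID = G$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(G$dosages))
  data.table::fwrite(dt, path, sep = " ")
  invisible(path)
}

#' @rdname write_geno
#' @export
read_geno <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1L]])
  M <- as.matrix(dt[, -1L])
  genotype_matrix(M, sample_ids = ids, snp_ids = colnames(M))
}

#' Read a PLINK `.raw`-dialect dosage file
#'
#' Parses the additive-coding export format: columns `FID IID PAT MAT SEX
#' PHENOTYPE` followed by one column per SNP named `<snp>_<counted allele>`.
#' Missing dosages (`NA`) are not supported.
#'
#' @param path file path to a `.raw` file.
#' @return a [genotype_matrix()] with `coded_allele` filled from the column
#'   name suffixes.
#' @export
read_plink_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  have <- intersect(meta, names(dt))
  if (!("IID" %in% have)) input_error("not a PLINK .raw file: no IID column")
  snp_cols <- setdiff(names(dt), meta)
  if (length(snp_cols) == 0L) input_error("no SNP columns in .raw file")
  M <- as.matrix(dt[, snp_cols, with = FALSE])
  if (anyNA(M)) input_error("missing dosages in .raw file are not supported")
  us <- regexpr("_[^_]+$", snp_cols)
  snp_ids <- ifelse(us > 0, substr(snp_cols, 1L, us - 1L), snp_cols)
  alleles <- ifelse(us > 0, substring(snp_cols, us + 1L), NA_character_)
  genotype_matrix(M, sample_ids = as.character(dt$IID), snp_ids = snp_ids,
                  coded_allele = alleles)
}

#' @rdname read_plink_raw
#' @param G a [genotype_matrix()].
#' @param path file path to write.
#' @export
write_plink_raw <- function(G, path) {
  allele <- G$coded_allele
  if (is.null(allele)) allele <- rep("A", length(G$snp_ids))
  dt <- data.table::data.table(FID = G$sample_ids, IID = G$sample_ids,
                               PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
  body <- data.table::as.data.table(G$dosages)
  data.table::setnames(body, paste0(G$snp_ids, "_", allele))
  data.table::fwrite(cbind(dt, body), path, sep = " ")
  invisible(path)
}
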