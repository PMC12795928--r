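#' Genetic relatedness matrix (GCTA standardization)
#'
#' Computes `A_jk = (1/m) * sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1-p_i))`
#' with `p_i` the sample allele frequency of SNP i. Monomorphic SNPs carry no
#' relatedness information and are excluded; `n_snps_used` reports the count
#' after exclusion. The standardized genotype matrix is retained on the
#' object (field `Z`) so that downstream REML can use a cheap low-rank
#' spectral decomposition when `m < n`.
#'
#' @param G a [genotype_matrix()] with at least 2 individuals.
#' @param keep_z keep the standardized dosage matrix on the result
#'   (default `TRUE`; costs `n * m` doubles).
#' @return An object of class `grm` with fields `sample_ids`, `values`
#'   (symmetric n x n matrix), `n_snps_used`, and optionally `Z`.
#' @export
compute_grm <- function(G, keep_z = TRUE) {
  if (nrow(G$dosages) < 2L) input_error("GRM needs at least 2 individuals")
  sd0 <- standardized_dosages(G)   # errors if all SNPs monomorphic
  m <- ncol(sd0$Z)
  A <- tcrossprod(sd0$Z) / m
  new_grm(G$sample_ids, A, m, Z = if (keep_z) sd0$Z else NULL)
}

#' Wrap an existing relatedness matrix as a `grm`
#'
#' For matrices produced outside [compute_grm()] (e.g. loaded from another
#' tool). The matrix must be symmetric to 1e-12 with finite entries.
#'
#' @param values symmetric numeric matrix.
#' @param sample_ids individual ids (default: rownames or generated).
#' @param n_snps_used SNP count behind the matrix, if known.
#' @return a `grm` object.
#' @export
as_grm <- function(values, sample_ids = rownames(values),
                   n_snps_used = NA_integer_) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    input_error("GRM values must be a square matrix")
  if (any(!is.finite(values))) input_error("GRM entries must be finite")
  if (max(abs(values - t(values))) > 1e-12)
    input_error("GRM values must be symmetric (to 1e-12)")
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(nrow(values)))
  new_grm(sample_ids, values, n_snps_used)
}

new_grm <- function(sample_ids, values, n_snps_used, Z = NULL) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = as.character(sample_ids), values = values,
                 n_snps_used = as.integer(n_snps_used), Z = Z),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d SNPs used, mean diagonal %.4f\n",
              length(x$sample_ids), x$n_snps_used, mean(diag(x$values))))
  invisible(x)
}

#' Subset a GRM by individual ids
#' @param A a [compute_grm()] result.
#' @param ids ids to keep (order respected).
#' @return a `grm` restricted to `ids`.
#' @export
subset_grm <- function(A, ids) {
  idx <- match(ids, A$sample_ids)
  if (anyNA(idx)) input_error("unknown sample ids in GRM subset")
  new_grm(ids, A$values[idx, idx, drop = FALSE], A$n_snps_used,
          Z = if (!is.null(A$Z)) A$Z[idx, , drop = FALSE] else NULL)
}

#' Greedy relatedness pruning
#'
#' Removes individuals until no kept off-diagonal entry exceeds `threshold`
#' in absolute value. At each step the individual participating in the most
#' surviving above-threshold pairs is removed (ties broken toward the lower
#' row index), the usual greedy maximum-degree heuristic.
#'
#' @param A a `grm`.
#' @param threshold positive relatedness cutoff (0.025 is the conventional
#'   "unrelated" bound, roughly second cousins).
#' @return character vector of kept sample ids (original order).
#' @export
prune_related <- function(A, threshold = 0.025) {
  if (threshold <= 0) config_error("threshold must be > 0")
  V <- abs(A$values) > threshold
  diag(V) <- FALSE
  keep <- rep(TRUE, nrow(V))
  deg <- rowSums(V)                # surviving above-threshold pair counts
  while (max(deg) > 0) {
    worst <- which.max(deg)        # which.max takes the first (lowest) index
    nb <- which(V[worst, ] & keep)
    deg[nb] <- deg[nb] - 1L
    deg[worst] <- 0L
    keep[worst] <- FALSE
  }
  A$sample_ids[keep]
}

#' Leading principal components of a GRM
#'
#' @param A a `grm`.
#' @param k number of components, `1 <= k < n`.
#' @return numeric matrix (n x k) of unit-norm eigenvectors ordered by
#'   descending eigenvalue; the largest-magnitude entry of each is positive.
#' @export
grm_principal_components <- function(A, k) {
  n <- length(A$sample_ids)
  if (k < 1L || k >= n) config_error("k must satisfy 1 <= k < n")
  sp <- grm_spectral(A)
  if (k > ncol(sp$U)) config_error("GRM rank too low for requested k")
  V <- sp$U[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- A$sample_ids
  colnames(V) <- paste0("PC", seq_len(k))
  V
}

# Spectral decomposition of the GRM used by REML and PCA.
# Returns U (n x r, orthonormal columns), d (r eigenvalues, descending) and
# n0 = n - r null dimensions (eigenvalue exactly 0, basis never formed).
# When the standardized genotypes Z are available and m < n, the cheap
# route via eigen(Z'Z/m) is taken; A = ZZ'/m shares its nonzero spectrum.
grm_spectral <- function(A) {
  if (!is.null(A$spectral)) return(A$spectral)
  n <- length(A$sample_ids)
  if (!is.null(A$Z) && ncol(A$Z) < n) {
    m <- ncol(A$Z)
    B <- crossprod(A$Z) / m
    eg <- eigen(B, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    d <- eg$values[pos]
    U <- A$Z %*% sweep(eg$vectors[, pos, drop = FALSE], 2L,
                       sqrt(d * m), `/`)
    list(U = U, d = d, n0 = n - length(d), n = n)
  } else {
    eg <- eigen(A$values, symmetric = TRUE)
    list(U = eg$vectors, d = eg$values, n0 = 0L, n = n)
  }
}

# Attach a cached spectral decomposition (internal; avoids recomputing the
# eigendecomposition across the univariate/bivariate fits of one report).
grm_with_spectral <- function(A) {
  A$spectral <- grm_spectral(A)
  A
}

#' Write / read a GRM as text
#'
#' Lower triangle (including the diagonal) as a tab-separated table
#' `id1 id2 value` with 17 significant digits, so that the round trip is
#' bit-exact for doubles.
#'
#' @param A a `grm`; @param path file path.
#' @return `write_grm` returns `path` invisibly; `read_grm` a `grm`.
#' @export
write_grm <- function(A, path) {
  n <- length(A$sample_ids)
  lower <- which(lower.tri(A$values, diag = TRUE), arr.ind = TRUE)
  dt <- data.table::data.table(
    id1 = A$sample_ids[lower[, 1L]],
    id2 = A$sample_ids[lower[, 2L]],
    value = sprintf("%.17g", A$values[lower]),
    n_snps = A$n_snps_used
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = c("id1", "id2")))
  ids <- unique(c(dt$id1, dt$id2))
  n <- length(ids)
  V <- matrix(0, n, n)
  i <- match(dt$id1, ids)
  j <- match(dt$id2, ids)
  v <- as.numeric(dt$value)
  V[cbind(i, j)] <- v
  V[cbind(j, i)] <- v
  new_grm(ids, V, dt$n_snps[1L])
}
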