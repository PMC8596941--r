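## Genetic principal components for population-stratification adjustment.

#' Variance-standardize a dosage matrix
#'
#' Centers each variant column by its sample mean and scales by its
#' sample standard deviation (denominator n-1). Zero-variance columns
#' carry no ancestry information and are dropped and reported.
#'
#' @param dosages a [dosage_matrix()] (or plain numeric matrix), at least
#'   two subjects.
#' @return list with `X` (standardized matrix) and `kept` (variant ids).
#' @export
standardize_genotypes <- function(dosages) {
  X <- unclass(as.matrix(dosages))
  if (nrow(X) < 2) stop_validation("need at least 2 subjects to standardize")
  sds <- apply(X, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop_validation("all variant columns have zero variance")
  if (any(!keep))
    message(sprintf("dropped %d zero-variance variant(s): %s", sum(!keep),
                    paste(colnames(X)[!keep], collapse = ", ")))
  X <- scale(X[, keep, drop = FALSE])
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, kept = colnames(X))
}

#' Genetic relationship matrix
#'
#' `G = X X' / m` over the `m` standardized variants: the
#' variance-standardized relationship matrix whose eigenvectors are the
#' genetic principal components. For unstructured data `mean(diag(G))`
#' is close to 1.
#'
#' @param standardized output matrix of [standardize_genotypes()].
#' @return subjects x subjects symmetric matrix.
#' @export
relationship_matrix <- function(standardized) {
  tcrossprod(standardized) / ncol(standardized)
}

#' Top genetic principal components
#'
#' Eigendecomposition of the relationship matrix of the standardized
#' dosages. Components are unit-norm eigenvectors sorted by descending
#' eigenvalue, with the sign convention that each column's
#' largest-magnitude entry is positive.
#'
#' @param dosages a [dosage_matrix()].
#' @param K number of components (default 6, the conventional number of
#'   stratification covariates in genetic association analyses); `K = 0`
#'   is valid and returns an empty component matrix.
#' @return list of class `pc_result`: `subject_ids`, `components`
#'   (subjects x K), `eigenvalues` (length K), `n_variants_used`.
#' @export
top_pcs <- function(dosages, K = 6) {
  X <- unclass(as.matrix(dosages))
  n <- nrow(X)
  if (K >= n) stop_validation("K (%d) must be smaller than the number of subjects (%d)", K, n)
  std <- standardize_genotypes(X)
  comp <- matrix(numeric(0), n, 0)
  evals <- numeric(0)
  if (K > 0) {
    m <- ncol(std$X)
    if (m < n) {
      # dual route: the nonzero spectrum of G = XX'/m equals that of
      # X'X/m (m x m); eigenvectors lift as u = X v / sqrt(m * lambda).
      # Identical decomposition, O(n m^2) instead of O(n^3).
      if (K > m) stop_validation("K (%d) exceeds the rank bound %d", K, m)
      eig <- eigen(crossprod(std$X) / m, symmetric = TRUE)
      evals <- eig$values[seq_len(K)]
      comp <- std$X %*% eig$vectors[, seq_len(K), drop = FALSE]
      comp <- sweep(comp, 2, sqrt(pmax(m * evals, 1e-300)), "/")
    } else {
      eig <- eigen(relationship_matrix(std$X), symmetric = TRUE)
      evals <- eig$values[seq_len(K)]
      comp <- eig$vectors[, seq_len(K), drop = FALSE]
    }
    for (j in seq_len(K)) {
      i <- which.max(abs(comp[, j]))
      if (comp[i, j] < 0) comp[, j] <- -comp[, j]
    }
  }
  colnames(comp) <- if (K > 0) paste0("PC", seq_len(K)) else character(0)
  structure(list(subject_ids = rownames(X), components = comp,
                 eigenvalues = evals, n_variants_used = length(std$kept)),
            class = "pc_result")
}

#' Write principal components and eigenvalues to TSV
#'
#' @param pcs a `pc_result` from [top_pcs()].
#' @param path output TSV (`subject_id`, `PC1..PCK`); the eigenvalues go
#'   to a `<path>.eigenvalues.tsv` sidecar.
#' @return `path`, invisibly.
#' @export
write_pcs <- function(pcs, path) {
  df <- data.frame(subject_id = pcs$subject_ids, pcs$components,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(component = colnames(pcs$components), eigenvalue = pcs$eigenvalues),
    paste0(path, ".eigenvalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
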