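## Reduced-dimension embeddings in which nearest-neighbor control cells are
## found. RNA: depth-normalize, log, top-variable genes, PCA. ATAC: TF-IDF
## then truncated SVD (LSI) with the depth-correlated first component
## dropped. Exact partial eigendecomposition on the smaller Gram matrix --
## no stochastic solver, so embeddings are deterministic.

## column variances of a sparse matrix without densifying
sparse_col_vars <- function(X) {
  n <- nrow(X)
  mu <- Matrix::colSums(X) / n
  (Matrix::colSums(X^2) - n * mu^2) / (n - 1)
}

## scores of a matrix on its top-d right singular vectors. Small problems
## use an exact eigendecomposition of the smaller Gram matrix; larger ones
## use deterministic subspace iteration with Rayleigh-Ritz rotation
## (initialized from the data itself, so no RNG state is touched and the
## result is reproducible bit-for-bit).
svd_scores <- function(X, d, iters = 10L, oversample = 8L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (min(n, p) <= 500L) {
    if (p <= n) {
      e <- eigen(crossprod(X), symmetric = TRUE)
      return(X %*% e$vectors[, seq_len(d), drop = FALSE])
    }
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    vals <- pmax(e$values[seq_len(d)], 1e-12)
    return(sweep(e$vectors[, seq_len(d), drop = FALSE], 2, sqrt(vals), `*`))
  }
  k <- min(d + oversample, n, p)
  if (p <= n) {
    V <- qr.Q(qr(t(X[seq_len(k), , drop = FALSE])))
    for (i in seq_len(iters))
      V <- qr.Q(qr(crossprod(X, X %*% V)))
    B <- X %*% V
    e <- eigen(crossprod(B), symmetric = TRUE)
    (B %*% e$vectors)[, seq_len(d), drop = FALSE]
  } else {
    U <- qr.Q(qr(X[, seq_len(k), drop = FALSE]))
    for (i in seq_len(iters))
      U <- qr.Q(qr(X %*% crossprod(X, U)))
    T <- crossprod(X, U)
    e <- eigen(crossprod(T), symmetric = TRUE)   # eigenvalues ~ sigma^2
    sig <- sqrt(pmax(e$values, 1e-12))
    (U %*% e$vectors %*% diag(sig))[, seq_len(d), drop = FALSE]
  }
}

#' Embed cells of one modality
#'
#' @param m A [feature_matrix()].
#' @param dims number of components (default 30). For ATAC the first (depth)
#'   component is dropped after the SVD, leaving `dims - 1` coordinates.
#' @param n_features number of top-variable features used for RNA PCA.
#' @param depth_target normalization scale (see [normalize_matrix()]).
#' @return list of class `Embedding`: `modality`, `coords` (cells x d),
#'   `method`.
#' @export
embed_cells <- function(m, dims = 30L, n_features = 2000L, depth_target = 1e4) {
  stopifnot(inherits(m, "FeatureMatrix"))
  nc <- nrow(m$counts)
  if (nc == 0) stop("embed_cells: empty matrix")
  if (dims >= nc)
    stop(sprintf("embed_cells: dims (%d) must be smaller than the number of cells (%d)",
                 dims, nc))
  N <- normalize_matrix(m, depth_target)
  if (m$modality == "RNA") {
    v <- sparse_col_vars(N)
    keep <- order(v, decreasing = TRUE)[seq_len(min(n_features, ncol(N)))]
    X <- as.matrix(N[, keep, drop = FALSE])
    X <- sweep(X, 2, colMeans(X))
    d <- min(dims, ncol(X), nc - 1L)
    coords <- svd_scores(X, d)
    method <- "pca"
  } else {
    d <- min(dims, ncol(N), nc - 1L)
    coords <- svd_scores(as.matrix(N), d)
    coords <- coords[, -1L, drop = FALSE]     # depth component
    method <- "lsi"
  }
  rownames(coords) <- m$barcodes
  structure(list(modality = m$modality, coords = coords, method = method),
            class = "Embedding")
}
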