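## Core containers. Light S3 classes over base/Matrix structures: the
## contracts (non-negative integer counts, unique identifiers, matched
## dimensions) are enforced in constructors so downstream code can assume
## them.

#' Construct a FeatureMatrix
#'
#' A `FeatureMatrix` holds sparse cell x feature counts for one modality
#' (`"RNA"` or `"ATAC"`), with cell barcodes as row names and feature
#' identifiers (gene ids or peak ids) as column names.
#'
#' @param counts matrix-like, cells x features, non-negative integers.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param barcodes character vector of unique cell barcodes (defaults to
#'   `rownames(counts)`).
#' @param features character vector of unique feature ids (defaults to
#'   `colnames(counts)`).
#' @return An object of class `FeatureMatrix`: a list with elements
#'   `modality`, `counts` (`dgCMatrix`), `barcodes`, `features`.
#' @examples
#' m <- feature_matrix(Matrix::Matrix(matrix(0:3, 2, 2), sparse = TRUE),
#'                     "RNA", c("c1", "c2"), c("g1", "g2"))
#' dim(m$counts)
#' @export
feature_matrix <- function(counts, modality = c("RNA", "ATAC"),
                           barcodes = rownames(counts),
                           features = colnames(counts)) {
  modality <- match.arg(modality)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(barcodes) || is.null(features))
    stop("feature_matrix: barcodes and features must be provided or set as dimnames")
  barcodes <- as.character(barcodes)
  features <- as.character(features)
  if (length(barcodes) != nrow(counts))
    stop(sprintf("feature_matrix: %d barcodes for %d matrix rows",
                 length(barcodes), nrow(counts)))
  if (length(features) != ncol(counts))
    stop(sprintf("feature_matrix: %d features for %d matrix columns",
                 length(features), ncol(counts)))
  if (anyDuplicated(barcodes)) stop("feature_matrix: duplicate cell barcodes")
  if (anyDuplicated(features)) stop("feature_matrix: duplicate feature identifiers")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("feature_matrix: counts must be non-negative integers")
  dimnames(counts) <- list(barcodes, features)
  structure(list(modality = modality, counts = counts,
                 barcodes = barcodes, features = features),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d cells x %d features, %d non-zero\n",
              x$modality, nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$counts)

#' Normalize a FeatureMatrix
#'
#' RNA: counts are scaled to a fixed depth per cell (`depth_target`) and
#' transformed to `log2(1 + x)`, so downstream effect sizes are on the log2
#' scale. ATAC: term frequency--inverse document frequency (TF-IDF) weighting
#' as used for latent semantic indexing of accessibility data, then
#' `log2(1 + depth_target * tf * idf)`.
#'
#' @param m A [feature_matrix()].
#' @param depth_target scale factor (default 1e4).
#' @return A sparse `dgCMatrix`, cells x features, normalized values.
#' @export
normalize_matrix <- function(m, depth_target = 1e4) {
  stopifnot(inherits(m, "FeatureMatrix"))
  counts <- m$counts
  depth <- Matrix::rowSums(counts)
  depth[depth == 0] <- 1
  if (m$modality == "RNA") {
    norm <- Matrix::Diagonal(x = depth_target / depth) %*% counts
  } else {
    tf <- Matrix::Diagonal(x = 1 / depth) %*% counts
    n_open <- Matrix::colSums(counts > 0)
    idf <- log(1 + nrow(counts) / (1 + n_open))
    norm <- tf %*% Matrix::Diagonal(x = depth_target * idf)
  }
  norm <- as(norm, "CsparseMatrix")
  norm@x <- log2(1 + norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

#' Validate and build an interval set (BED-style)
#'
#' Intervals use 0-based half-open `[start, end)` coordinates throughout the
#' package. Input is sorted by (chrom, start) with a stable order for ties.
#'
#' @param df data.frame with columns chrom, start, end and optionally name;
#'   extra columns are preserved.
#' @param kind label used in error messages (e.g. "peaks", "tads").
#' @return A `data.table` of class `IntervalSet`, sorted, with a `name`
#'   column (auto-generated when absent).
#' @export
interval_set <- function(df, kind = "intervals") {
  dt <- data.table::as.data.table(df)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", kind, paste(miss, collapse = ", ")))
  if (!is.numeric(dt$start) || !is.numeric(dt$end))
    stop(sprintf("%s: start/end must be numeric", kind))
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop(sprintf("%s: start >= end at row %d (%s:%d-%d)", kind, bad[1],
                 dt$chrom[bad[1]], dt$start[bad[1]], dt$end[bad[1]]))
  if (any(dt$start < 0)) stop(sprintf("%s: negative start coordinate", kind))
  if (!"name" %in% names(dt))
    dt$name <- sprintf("%s_%d", kind, seq_len(nrow(dt)))
  if (anyDuplicated(dt$name))
    stop(sprintf("%s: duplicate interval identifiers", kind))
  dt$start <- as.integer(dt$start); dt$end <- as.integer(dt$end)
  data.table::setorder(dt, chrom, start)
  data.table::setattr(dt, "class", c("IntervalSet", class(dt)))
  dt[]
}

## midpoint anchor used for all peak-position arithmetic
interval_center <- function(iv) as.integer(floor((iv$start + iv$end) / 2))

## point-in-interval membership, 0-based half-open; returns the index of the
## covering interval (first by sort order) or NA. Intervals may overlap.
point_interval_index <- function(chrom, pos, iv) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    si <- which(iv$chrom == ch)
    if (!length(si)) next
    ir <- IRanges::IRanges(start = iv$start[si] + 1L, end = iv$end[si])
    qr <- IRanges::IRanges(start = pos[qi] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(qr, ir, select = "first")
    out[qi] <- si[hits]
  }
  out
}

points_in_regions <- function(chrom, pos, regions) {
  !is.na(point_interval_index(chrom, pos, regions))
}
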