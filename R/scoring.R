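## Per-cell perturbation signatures and scores. The signature contrasts a
## cell's normalized profile with the mean profile of its k nearest control
## cells (non-targeting + safe-harbor) in the embedding -- control cells at a
## similar differentiation state. The score projects the signature onto the
## target's mean signature direction and is z-scored against the control
## population per target and modality.

#' Compute perturbation signatures
#'
#' `signature(cell) = normalized profile(cell) - mean normalized profile of
#' its k nearest control cells` in the embedding. Control cells receive
#' signatures against other controls, excluding themselves.
#'
#' @param m A [feature_matrix()].
#' @param emb An [embed_cells()] result for the same cells.
#' @param guides GuideAssignment covering the matrix barcodes.
#' @param k number of control neighbors (default 20).
#' @param depth_target normalization scale.
#' @return list of class `PerturbationSignature`: `modality`, `sig` (dense
#'   cells x features), `barcodes`, `features`, `k`.
#' @export
perturbation_signature <- function(m, emb, guides, k = 20L, depth_target = 1e4) {
  stopifnot(inherits(m, "FeatureMatrix"), inherits(emb, "Embedding"))
  if (!identical(rownames(emb$coords), m$barcodes))
    stop("perturbation_signature: embedding rows do not match matrix barcodes")
  ga <- data.table::as.data.table(guides)
  cls <- ga$target_class[match(m$barcodes, ga$cell)]
  if (anyNA(cls))
    stop("perturbation_signature: cells missing from the guide table; use align_to_guides()")
  ctrl <- which(cls %in% c("NT", "SAFE"))
  n_ctrl <- length(ctrl)
  if (k > n_ctrl)
    stop(sprintf("perturbation_signature: k (%d) exceeds the number of control cells (%d)",
                 k, n_ctrl))
  N <- normalize_matrix(m, depth_target)
  nc <- nrow(N)

  ## squared distances cell -> control in embedding coordinates
  A <- emb$coords
  a2 <- rowSums(A^2)
  D2 <- outer(a2, a2[ctrl], `+`) - 2 * A %*% t(A[ctrl, , drop = FALSE])

  nb_i <- integer(0); nb_j <- integer(0)
  for (i in seq_len(nc)) {
    d <- D2[i, ]
    self <- match(i, ctrl)
    if (!is.na(self)) d[self] <- Inf
    kk <- if (!is.na(self)) min(k, n_ctrl - 1L) else k
    sel <- ctrl[order(d)[seq_len(kk)]]
    nb_i <- c(nb_i, rep.int(i, kk)); nb_j <- c(nb_j, sel)
  }
  W <- Matrix::sparseMatrix(i = nb_i, j = nb_j, x = 1, dims = c(nc, nc))
  W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  Nd <- as.matrix(N)                      # sparse x dense beats sparse x sparse here
  sig <- Nd - as.matrix(W %*% Nd)
  dimnames(sig) <- dimnames(N)
  structure(list(modality = m$modality, sig = sig, barcodes = m$barcodes,
                 features = m$features, k = as.integer(k)),
            class = "PerturbationSignature")
}

#' Score cells against their target's perturbation direction
#'
#' For each TF target, the direction vector is the unit-normalized mean
#' signature over all cells carrying that target's guides. A cell's raw
#' score is the projection of its signature onto its target's direction;
#' control cells are scored against every TF direction for calibration.
#' z-scores are `(raw - mean_control) / sd_control` per target and modality,
#' so control z-scores have mean 0 and unit variance by construction.
#'
#' @param sig A [perturbation_signature()] result.
#' @param guides GuideAssignment.
#' @return `data.table` of class `PerturbationScoreTable` with columns cell,
#'   modality, guide_id, target, target_class, raw, z. Attributes:
#'   `directions` (features x targets), `ctrl_mean`, `ctrl_sd`.
#' @export
perturbation_score <- function(sig, guides) {
  stopifnot(inherits(sig, "PerturbationSignature"))
  ga <- data.table::as.data.table(guides)
  idx <- match(sig$barcodes, ga$cell)
  tgt <- ga$target[idx]; cls <- ga$target_class[idx]; gid <- ga$guide_id[idx]
  targets <- unique(tgt[cls == "TF"])
  ctrl <- which(cls %in% c("NT", "SAFE"))

  dirs <- matrix(0, length(sig$features), 0)
  kept <- character(0)
  for (tf in targets) {
    rows <- which(tgt == tf & cls == "TF")
    if (!length(rows)) { warning(sprintf("perturbation_score: target %s has no cells; skipped", tf)); next }
    d <- colMeans(sig$sig[rows, , drop = FALSE])
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) { warning(sprintf("perturbation_score: target %s has a zero direction; skipped", tf)); next }
    dirs <- cbind(dirs, d / nrm); kept <- c(kept, tf)
  }
  colnames(dirs) <- kept
  raw_all <- sig$sig %*% dirs                      # cells x targets
  mu <- colMeans(raw_all[ctrl, , drop = FALSE])
  sdv <- apply(raw_all[ctrl, , drop = FALSE], 2, sd)

  rows <- list()
  tf_cells <- which(cls == "TF" & tgt %in% kept)
  rows[[1]] <- data.table::data.table(
    cell = sig$barcodes[tf_cells], modality = sig$modality,
    guide_id = gid[tf_cells], target = tgt[tf_cells], target_class = "TF",
    raw = raw_all[cbind(tf_cells, match(tgt[tf_cells], kept))])
  for (tf in kept) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      cell = sig$barcodes[ctrl], modality = sig$modality,
      guide_id = gid[ctrl], target = tf, target_class = cls[ctrl],
      raw = raw_all[ctrl, tf])
  }
  pst <- data.table::rbindlist(rows)
  pst$z <- (pst$raw - mu[pst$target]) / sdv[pst$target]
  data.table::setattr(pst, "directions", dirs)
  data.table::setattr(pst, "ctrl_mean", mu)
  data.table::setattr(pst, "ctrl_sd", sdv)
  data.table::setattr(pst, "class", c("PerturbationScoreTable", class(pst)))
  pst[]
}

#' Correlate per-guide editing efficiency with perturbation scores
#'
#' @param pst A [perturbation_score()] table (one modality).
#' @param gc Genotype calls (cell, guide_id, edited) as from
#'   [simulate_genotypes()].
#' @return list: `table` (per guide: n_genotyped, pct_edited, median_z) and
#'   `rho` (Spearman rank correlation across guides; `NA` when degenerate).
#' @export
efficiency_correlation <- function(pst, gc) {
  gc <- data.table::as.data.table(gc)
  if (nrow(gc) == 0) stop("efficiency_correlation: empty genotype table")
  eff <- gc[, list(n_genotyped = .N, pct_edited = 100 * mean(edited)),
            by = "guide_id"]
  medz <- data.table::as.data.table(pst)[target_class == "TF",
                                         list(median_z = stats::median(z)),
                                         by = "guide_id"]
  tab <- merge(eff, medz, by = "guide_id")
  dropped <- setdiff(medz$guide_id, tab$guide_id)
  if (length(dropped))
    message(sprintf("efficiency_correlation: %d guide(s) without genotyped cells excluded",
                    length(dropped)))
  if (nrow(tab) < 3)
    stop("efficiency_correlation: need >= 3 guides with both genotype and score data")
  rho <- if (sd(tab$pct_edited) == 0 || sd(tab$median_z) == 0) {
    message("efficiency_correlation: zero variance across guides; correlation undefined")
    NA_real_
  } else cor(tab$pct_edited, tab$median_z, method = "spearman")
  list(table = tab[], rho = rho)
}
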