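## TF-sensitivity calls: a linear model of each feature's normalized value
## on the continuous perturbation level achieved in each single cell, fit
## jointly over the TF's cells and the control pool. The regression
## covariate for feature g excludes g's own contribution to the projection
## score (leave-one-feature-out); with the plain full projection, feature
## g's noise appears on both sides of the regression and inflates the null
## t-statistic, breaking FDR calibration. See the methods vignette.

#' Fit TF-sensitivity for one TF and one modality
#'
#' Per feature: `normalized value ~ intercept + beta * z + log10(depth)`,
#' Wald p on `beta` (ordinary least squares), Benjamini-Hochberg correction
#' across features, and `log2FC = beta_IV * (mean z of TF cells - mean z of
#' control cells)`, where `beta_IV` is the same slope estimated by
#' instrumental-variable regression with the carries-TF-guide indicator as
#' instrument. The per-cell z is a noisy measurement of the perturbation
#' level actually achieved, so the OLS slope is attenuated by regression
#' dilution; the IV slope is not, and `beta_IV * score gap` equals the
#' covariate-adjusted TF-vs-control mean difference on the log2 normalized
#' scale. Zero-variance features get `p = 1`, effect 0, and are kept.
#'
#' @param m [feature_matrix()] of the modality to test.
#' @param sig matching [perturbation_signature()].
#' @param pst matching [perturbation_score()] table.
#' @param guides GuideAssignment.
#' @param tf TF symbol to test.
#' @param alpha BH significance threshold for the sensitive flag.
#' @param depth_covariate include log10 total counts as covariate.
#' @param min_cells minimum cells (TF + controls) required.
#' @param normalized optional precomputed [normalize_matrix()] result for
#'   `m` (avoids renormalizing when fitting many TFs).
#' @return `data.table` of class `SensitivityTable`: feature, modality, tf,
#'   log2fc, z_log2fc, p, q, sensitive.
#' @export
fit_sensitivity <- function(m, sig, pst, guides, tf, alpha = 0.05,
                            depth_covariate = TRUE, min_cells = 50L,
                            normalized = NULL) {
  stopifnot(inherits(m, "FeatureMatrix"), inherits(sig, "PerturbationSignature"))
  dirs <- attr(pst, "directions")
  if (is.null(dirs) || !tf %in% colnames(dirs))
    stop(sprintf("fit_sensitivity: no score direction for target '%s' (no TF cells?)", tf))
  pdt <- data.table::as.data.table(pst)
  tf_rows <- pdt[pdt$target == tf & pdt$target_class == "TF", ]
  ctrl_rows <- pdt[pdt$target == tf & pdt$target_class %in% c("NT", "SAFE"), ]
  if (nrow(tf_rows) == 0)
    stop(sprintf("fit_sensitivity: no cells carry guides for '%s'", tf))
  cells <- c(tf_rows$cell, ctrl_rows$cell)
  n <- length(cells)
  if (n < min_cells)
    stop(sprintf("fit_sensitivity: %d cells for '%s' + controls; need >= %d",
                 n, tf, min_cells))
  ci <- match(cells, m$barcodes)
  if (anyNA(ci)) stop("fit_sensitivity: score table cells missing from matrix")
  is_tf <- seq_len(n) <= nrow(tf_rows)

  if (is.null(normalized)) normalized <- normalize_matrix(m)
  Y <- as.matrix(normalized[ci, , drop = FALSE])
  S <- sig$sig[ci, , drop = FALSE]
  d <- dirs[, tf]
  raw <- c(tf_rows$raw, ctrl_rows$raw)
  ## leave-one-feature-out projection, re-standardized on controls
  R <- matrix(raw, n, ncol(S)) - sweep(S, 2, d, `*`)
  mu <- colMeans(R[!is_tf, , drop = FALSE])
  sdv <- apply(R[!is_tf, , drop = FALSE], 2, sd)
  ok_z <- sdv > 0
  sdv[!ok_z] <- 1
  Z <- sweep(sweep(R, 2, mu), 2, sdv, `/`)

  W <- cbind(intercept = rep(1, n))
  if (depth_covariate) {
    logd <- log10(Matrix::rowSums(m$counts)[ci] + 1)
    W <- cbind(W, logd = logd)
  }
  WtW <- crossprod(W)
  if (rcond(WtW) < 1e-12) stop("fit_sensitivity: singular design matrix")
  proj <- function(M) M - W %*% solve(WtW, crossprod(W, M))
  Yr <- proj(Y); Zr <- proj(Z)
  gr <- proj(matrix(as.numeric(is_tf), n, 1))[, 1]

  szz <- colSums(Zr^2)
  szy <- colSums(Zr * Yr)
  syy <- colSums(Yr^2)
  ok <- ok_z & szz > 1e-10 & syy > 1e-10
  slope <- ifelse(ok, szy / pmax(szz, 1e-10), 0)
  dfree <- n - ncol(W) - 1L
  rss <- pmax(syy - slope * szy, 0)
  se <- sqrt(rss / dfree / pmax(szz, 1e-10))
  tstat <- ifelse(ok & se > 0, slope / se, 0)
  p <- ifelse(ok, 2 * pt(-abs(tstat), dfree), 1)

  ## dilution-free effect size: IV slope (instrument: TF-guide indicator)
  ## times the score gap == adjusted TF-vs-control contrast
  zgap <- colMeans(Z[is_tf, , drop = FALSE]) - colMeans(Z[!is_tf, , drop = FALSE])
  sgz <- colSums(gr * Zr)
  sgy <- colSums(gr * Yr)
  slope_iv <- ifelse(ok & abs(sgz) > 1e-10, sgy / sgz, 0)
  log2fc <- ifelse(ok, slope_iv * zgap, 0)
  q <- p.adjust(p, method = "BH")
  sens <- q < alpha
  zl <- rep(NA_real_, length(p))
  if (sum(sens) >= 2) {
    mfc <- mean(log2fc[sens]); sfc <- sd(log2fc[sens])
    if (sfc > 0) zl <- (log2fc - mfc) / sfc
  }
  out <- data.table::data.table(
    feature = m$features, modality = m$modality, tf = tf,
    log2fc = log2fc, z_log2fc = zl, p = p, q = q, sensitive = sens)
  data.table::setattr(out, "class", c("SensitivityTable", class(out)))
  out[]
}

#' Percent to one decimal
#'
#' `round(100 * n_sensitive / n_total, 1)`, the convention used for the
#' sensitive-feature summary percentages.
#' @param n_sensitive,n_total non-negative counts, `n_sensitive <= n_total`.
#' @return numeric percentage rounded to one decimal.
#' @examples
#' percent_sensitive(50114, 230083)  # 21.8
#' percent_sensitive(8694, 33415)    # 26.0
#' @export
percent_sensitive <- function(n_sensitive, n_total) {
  stopifnot(n_total > 0, n_sensitive >= 0, n_sensitive <= n_total)
  round(100 * n_sensitive / n_total, 1)
}

#' Summarize sensitive features across TFs
#'
#' A feature counts as sensitive when flagged for at least one TF. Reports,
#' per modality, the count, the percentage of the feature universe (to one
#' decimal), and the fraction of sensitive features responding to exactly
#' one TF.
#'
#' @param st A `SensitivityTable` (rows for any number of TFs/modalities).
#' @param n_total optional named vector of universe sizes per modality
#'   (defaults to the number of features tested in the table).
#' @return `data.table`: modality, n_total, n_sensitive, percent,
#'   frac_single_tf.
#' @export
summarize_sensitive <- function(st, n_total = NULL) {
  dt <- data.table::as.data.table(st)
  if (nrow(dt) == 0) stop("summarize_sensitive: empty table")
  out <- dt[, {
    per_feat <- .SD[, list(n_tf = sum(sensitive)), by = "feature"]
    ns <- sum(per_feat$n_tf >= 1L)
    tot <- if (!is.null(n_total) && .BY$modality %in% names(n_total))
      n_total[[.BY$modality]] else nrow(per_feat)
    list(n_total = as.integer(tot), n_sensitive = ns,
         percent = percent_sensitive(ns, tot),
         frac_single_tf = if (ns > 0) mean(per_feat$n_tf[per_feat$n_tf >= 1L] == 1L)
         else NA_real_)
  }, by = "modality"]
  out[]
}

#' Threshold-based group contrast (perturbed vs safe-harbor controls)
#'
#' Wilcoxon rank-sum test of normalized values between cells whose
#' perturbation z-score exceeds `score_threshold` for `target` and
#' safe-harbor control cells, with BH adjustment over `feature_subset`.
#'
#' @param m [feature_matrix()].
#' @param guides GuideAssignment.
#' @param pst [perturbation_score()] table for the same modality.
#' @param target TF symbol.
#' @param feature_subset features to test (default: all).
#' @param score_threshold z cutoff for calling a cell perturbed (default 2).
#' @return `data.table`: feature, log2fc, p, q, n_perturbed, n_control.
#' @export
group_contrast <- function(m, guides, pst, target, feature_subset = NULL,
                           score_threshold = 2) {
  pdt <- data.table::as.data.table(pst)
  keep_p <- pdt[["target"]] == target & pdt[["target_class"]] == "TF" &
    pdt[["z"]] > score_threshold
  pert <- pdt[keep_p, ]$cell
  ga <- data.table::as.data.table(guides)
  ctrl <- ga[ga$target_class == "SAFE", ]$cell
  if (!length(pert))
    stop(sprintf("group_contrast: no '%s' cells with z > %g; lower score_threshold",
                 target, score_threshold))
  if (!length(ctrl)) stop("group_contrast: no safe-harbor control cells")
  if (is.null(feature_subset)) feature_subset <- m$features
  miss <- setdiff(feature_subset, m$features)
  if (length(miss)) stop(sprintf("group_contrast: unknown feature '%s'", miss[1]))
  N <- normalize_matrix(m)
  pi <- match(pert, m$barcodes); ci <- match(ctrl, m$barcodes)
  Yp <- as.matrix(N[pi, feature_subset, drop = FALSE])
  Yc <- as.matrix(N[ci, feature_subset, drop = FALSE])
  p <- vapply(seq_along(feature_subset), function(j) {
    suppressWarnings(wilcox.test(Yp[, j], Yc[, j])$p.value)
  }, 0)
  p[is.na(p)] <- 1
  out <- data.table::data.table(
    feature = feature_subset, log2fc = colMeans(Yp) - colMeans(Yc),
    p = p, q = p.adjust(p, "BH"),
    n_perturbed = length(pert), n_control = length(ctrl))
  out[]
}

#' Replicate concordance of z-scored effect sizes
#'
#' Spearman correlation of z-scored log2FC for one TF over features
#' significant (q < alpha) in both sensitivity tables.
#'
#' @param stA,stB `SensitivityTable`s from two replicates.
#' @param tf TF symbol.
#' @param alpha significance threshold.
#' @param min_shared minimum shared significant features (default 10).
#' @return list: `rho` (NA with a warning when too few shared features), `n`.
#' @export
replicate_concordance <- function(stA, stB, tf, alpha = 0.05, min_shared = 10L) {
  ## precompute logical indices: inside `[.data.table` a bare `tf` would
  ## resolve to the column of the same name, not this function's argument
  a <- data.table::as.data.table(stA)
  keep_a <- a[["tf"]] == tf & a[["q"]] < alpha
  a <- a[keep_a, ]
  b <- data.table::as.data.table(stB)
  keep_b <- b[["tf"]] == tf & b[["q"]] < alpha
  b <- b[keep_b, ]
  sh <- merge(a[, c("feature", "modality", "log2fc")],
              b[, c("feature", "modality", "log2fc")],
              by = c("feature", "modality"), suffixes = c("_a", "_b"))
  if (nrow(sh) < min_shared) {
    warning(sprintf("replicate_concordance: only %d shared significant features for %s",
                    nrow(sh), tf))
    return(list(rho = NA_real_, n = nrow(sh)))
  }
  ## z-scoring log2FC per table is a monotone map, so Spearman rho is
  ## computed directly on the effect sizes
  list(rho = cor(sh$log2fc_a, sh$log2fc_b, method = "spearman"), n = nrow(sh))
}

#' Per-cell module score over a gene set
#'
#' Mean normalized expression over the set, z-scored across all cells; all
#' zero when the across-cell variance is zero.
#'
#' @param m RNA [feature_matrix()].
#' @param gene_set character vector of gene ids (subset of features).
#' @param name module label.
#' @return `data.table`: cell, module, score.
#' @export
module_score <- function(m, gene_set, name = "module") {
  stopifnot(inherits(m, "FeatureMatrix"))
  if (!length(gene_set)) stop("module_score: empty gene set")
  miss <- setdiff(gene_set, m$features)
  if (length(miss))
    stop(sprintf("module_score: gene '%s' not in the matrix", miss[1]))
  N <- normalize_matrix(m)
  s <- Matrix::rowSums(N[, gene_set, drop = FALSE]) / length(gene_set)
  sc <- if (sd(s) == 0) rep(0, length(s)) else (s - mean(s)) / sd(s)
  data.table::data.table(cell = m$barcodes, module = name, score = sc)
}
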