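## Variant-level enrichment: credible-set overlap with region categories
## (plus matched resampling nulls), partitioned heritability enrichment on
## per-SNP contributions, constraint-score ECDFs, and a simplified
## deviation-style per-cell trait-relevance score.

#' Percent of credible sets overlapping a region set
#'
#' A set overlaps when at least one of its variants' positions falls inside
#' at least one region (0-based half-open containment). PIPs are not used.
#'
#' @param cs CredibleSetTable (trait, set_id, snp_id, chrom, pos, pip).
#' @param regions [interval_set()].
#' @return `data.table` per trait: n_sets, n_overlap, percent; attribute
#'   `overall` holds the pooled percent across traits.
#' @export
credible_set_overlap <- function(cs, regions) {
  dt <- data.table::as.data.table(cs)
  if (nrow(dt) == 0) stop("credible_set_overlap: empty credible set table")
  hit <- if (nrow(regions)) points_in_regions(dt$chrom, dt$pos, regions)
  else rep(FALSE, nrow(dt))
  dt$hit <- hit
  per_set <- dt[, list(any_hit = any(hit)), by = c("trait", "set_id")]
  out <- per_set[, list(n_sets = .N, n_overlap = sum(any_hit),
                        percent = 100 * sum(any_hit) / .N), by = "trait"]
  data.table::setattr(out, "overall",
                      100 * sum(per_set$any_hit) / nrow(per_set))
  out[]
}

#' Resampling null for credible-set overlap
#'
#' Draws `n_samples` region sets and recomputes the overlap percent for
#' each. `matching = "length"` samples regions from `pool` (when
#' `target_lengths` is given, each draw matches a target region's length
#' within +/-20%, with replacement); `matching = "random"` places intervals
#' of the target lengths uniformly on a genome of length `genome_length`.
#'
#' @param cs CredibleSetTable.
#' @param pool candidate [interval_set()] (ignored for `"random"`).
#' @param n_regions regions per draw.
#' @param n_samples draws (default 100); SD is `NA` when 1.
#' @param matching `"length"` or `"random"`.
#' @param target_lengths optional lengths of the observed region set.
#' @param genome_length required for `"random"`.
#' @param seed RNG seed.
#' @return list: `null_mean`, `null_sd` (overall percents), `per_trait`
#'   (`data.table` with per-trait null mean/SD), `samples` (overall percent
#'   per draw).
#' @export
sampled_overlap_null <- function(cs, pool, n_regions, n_samples = 100L,
                                 matching = c("length", "random"),
                                 target_lengths = NULL, genome_length = NULL,
                                 seed = 1L) {
  matching <- match.arg(matching)
  set.seed(as.integer(seed))
  if (matching == "length") {
    if (nrow(pool) < n_regions)
      stop(sprintf("sampled_overlap_null: pool (%d) smaller than n_regions (%d)",
                   nrow(pool), n_regions))
    pool_len <- pool$end - pool$start
  } else {
    if (is.null(genome_length))
      stop("sampled_overlap_null: genome_length required for matching='random'")
    if (is.null(target_lengths))
      stop("sampled_overlap_null: target_lengths required for matching='random'")
  }
  draw_regions <- function() {
    if (matching == "length") {
      if (is.null(target_lengths)) {
        pool[sample.int(nrow(pool), n_regions), ]
      } else {
        tl <- rep_len(target_lengths, n_regions)
        idx <- vapply(tl, function(len) {
          cand <- which(pool_len >= 0.8 * len & pool_len <= 1.2 * len)
          if (!length(cand)) cand <- which.min(abs(pool_len - len))
          cand[sample.int(length(cand), 1L)]
        }, 0L)
        pool[idx, ]
      }
    } else {
      tl <- rep_len(target_lengths, n_regions)
      st <- floor(runif(n_regions) * (genome_length - tl))
      interval_set(data.table::data.table(chrom = "chrS", start = st,
                                          end = st + tl), kind = "rand")
    }
  }
  overall <- numeric(n_samples)
  per_trait <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    ov <- credible_set_overlap(cs, draw_regions())
    overall[s] <- attr(ov, "overall")
    per_trait[[s]] <- ov[, c("trait", "percent")]
  }
  pt <- data.table::rbindlist(per_trait)[
    , list(null_mean = mean(percent), null_sd = if (n_samples > 1) sd(percent) else NA_real_),
    by = "trait"]
  list(null_mean = mean(overall),
       null_sd = if (n_samples > 1) sd(overall) else NA_real_,
       per_trait = pt[], samples = overall)
}

#' Partitioned heritability enrichment of a SNP category
#'
#' `enrichment = (share of heritability in category) / (share of SNPs in
#' category)`, on per-SNP heritability contributions.
#'
#' @param h2 SnpHeritabilityTable (snp_id, h2_contribution, ...).
#' @param category_mask logical vector along `h2` rows.
#' @return list: `enrichment`, `pct_snps`, `pct_h2`.
#' @export
heritability_enrichment <- function(h2, category_mask) {
  dt <- data.table::as.data.table(h2)
  stopifnot(nrow(dt) == length(category_mask))
  if (any(dt$h2_contribution < 0))
    stop("heritability_enrichment: negative h2 contribution")
  tot <- sum(dt$h2_contribution)
  if (tot <= 0) stop("heritability_enrichment: total h2 must be positive")
  if (!any(category_mask)) stop("heritability_enrichment: empty category")
  p_snp <- mean(category_mask)
  p_h2 <- sum(dt$h2_contribution[category_mask]) / tot
  list(enrichment = p_h2 / p_snp, pct_snps = 100 * p_snp, pct_h2 = 100 * p_h2)
}

#' Constraint-score ECDFs by category with pairwise KS tests
#'
#' @param records data.frame with `score` and `category` columns (optionally
#'   `region_id`). Categories with fewer than 2 records are excluded with a
#'   message.
#' @return list: `grid` (pooled sorted scores), `ecdf` (matrix grid x
#'   category), `ks` (`data.table` of pairwise two-sample KS D and p).
#' @export
constraint_ecdf <- function(records) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("score", "category") %in% names(dt)))
  if (any(!is.finite(dt$score))) stop("constraint_ecdf: non-finite score")
  sizes <- table(dt$category)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    message(sprintf("constraint_ecdf: excluding category(ies) with < 2 records: %s",
                    paste(small, collapse = ", ")))
    dt <- dt[!dt$category %in% small, ]
  }
  cats <- sort(unique(dt$category))
  if (length(cats) < 2) stop("constraint_ecdf: need >= 2 categories")
  grid <- sort(unique(dt$score))
  E <- vapply(cats, function(cc) ecdf(dt$score[dt$category == cc])(grid),
              numeric(length(grid)))
  colnames(E) <- cats
  pairs <- utils::combn(cats, 2)
  ks <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
    a <- dt$score[dt$category == pairs[1, j]]
    b <- dt$score[dt$category == pairs[2, j]]
    kt <- suppressWarnings(ks.test(a, b))
    data.table::data.table(cat_a = pairs[1, j], cat_b = pairs[2, j],
                           ks_d = unname(kt$statistic), p = kt$p.value)
  }))
  list(grid = grid, ecdf = E, ks = ks[])
}

#' Per-cell trait-relevance score (simplified deviation-style stand-in)
#'
#' For each cell: the observed fraction of ATAC counts falling in the trait
#' peak set, minus the mean of the same fraction over `n_background`
#' accessibility-matched random peak sets of equal size, divided by their
#' SD. Matching is by decile of total per-peak counts. This is a documented
#' simplified alternative to published trait-relevance scores.
#'
#' @param atac ATAC [feature_matrix()].
#' @param trait_peaks character vector of peak ids (subset of features).
#' @param n_background background sets (default 50).
#' @param seed RNG seed.
#' @return `data.table`: cell, trs.
#' @export
trait_relevance_score <- function(atac, trait_peaks, n_background = 50L, seed = 1L) {
  stopifnot(inherits(atac, "FeatureMatrix"))
  if (!length(trait_peaks)) stop("trait_relevance_score: empty trait peak set")
  if (n_background < 1) stop("trait_relevance_score: n_background must be >= 1")
  miss <- setdiff(trait_peaks, atac$features)
  if (length(miss))
    stop(sprintf("trait_relevance_score: peak '%s' not in the matrix", miss[1]))
  set.seed(as.integer(seed))
  counts <- atac$counts
  tot <- Matrix::rowSums(counts); tot[tot == 0] <- 1
  frac_of <- function(set) Matrix::rowSums(counts[, set, drop = FALSE]) / tot
  obs <- frac_of(trait_peaks)
  pk_tot <- Matrix::colSums(counts)
  qs <- unique(quantile(pk_tot, probs = seq(0, 1, 0.1)))
  dec <- findInterval(pk_tot, qs, rightmost.closed = TRUE, all.inside = TRUE)
  by_dec <- split(seq_along(pk_tot), dec)
  t_dec <- dec[match(trait_peaks, atac$features)]
  bg <- matrix(0, nrow(counts), n_background)
  for (b in seq_len(n_background)) {
    set <- vapply(t_dec, function(dd) {
      pool <- by_dec[[as.character(dd)]]
      pool[sample.int(length(pool), 1L)]
    }, 0L)
    bg[, b] <- frac_of(set)
  }
  mu <- rowMeans(bg)
  sdv <- apply(bg, 1, sd)
  sdv[sdv == 0] <- NA_real_
  data.table::data.table(cell = atac$barcodes, trs = (obs - mu) / sdv)
}
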