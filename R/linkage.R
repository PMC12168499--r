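## ACR-gene linkage: pair enumeration by distance, single-cell correlation
## in non-targeting control cells, and enrichment of TF-sensitive pairs in
## CRISPRi-validated links, TAD co-occupancy (with matched resampling
## nulls), and ChIP-peak proximity profiles.

#' Enumerate ACR-gene pairs within a distance window
#'
#' Pairs every peak midpoint with every TSS at most `max_distance` away on
#' the same chromosome. Distance is signed by gene strand: negative =
#' upstream of the TSS.
#'
#' @param peaks [interval_set()] of ACRs.
#' @param genes gene annotation (gene_id, chrom, tss, strand).
#' @param max_distance window in bp (default 50 kb).
#' @return `data.table`: acr, gene_id, chrom, distance.
#' @export
enumerate_pairs <- function(peaks, genes, max_distance = 50000L) {
  stopifnot(nrow(peaks) > 0, nrow(genes) > 0)
  genes <- data.table::as.data.table(genes)
  out <- list()
  for (ch in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    pk <- peaks[peaks$chrom == ch, ]
    ge <- genes[genes$chrom == ch, ]
    ctr <- interval_center(pk)
    o <- order(ctr)
    ctr_s <- ctr[o]; nm_s <- pk$name[o]
    lo <- findInterval(ge$tss - max_distance - 1L, ctr_s) + 1L
    hi <- findInterval(ge$tss + max_distance, ctr_s)
    keep <- which(hi >= lo)
    if (!length(keep)) next
    reps <- hi[keep] - lo[keep] + 1L
    pk_idx <- sequence(reps) + rep(lo[keep] - 1L, reps)
    ge_idx <- rep(keep, reps)
    raw_d <- ctr_s[pk_idx] - ge$tss[ge_idx]
    out[[ch]] <- data.table::data.table(
      acr = nm_s[pk_idx], gene_id = ge$gene_id[ge_idx], chrom = ch,
      distance = as.integer(ifelse(ge$strand[ge_idx] == "-", -raw_d, raw_d)))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0)
    return(data.table::data.table(acr = character(0), gene_id = character(0),
                                  chrom = character(0), distance = integer(0)))
  res[]
}

#' Single-cell ACR-gene correlation in non-targeting control cells
#'
#' Spearman correlation (average ranks for ties) between normalized
#' accessibility and expression across NT cells only.
#'
#' @param rna,atac [feature_matrix()]s over the same cells.
#' @param guides GuideAssignment.
#' @param pairs output of [enumerate_pairs()].
#' @param min_nt minimum NT cells (default 20).
#' @return `pairs` with an added `rho` column (`NA` for zero-variance
#'   members, with a message).
#' @export
pair_correlation <- function(rna, atac, guides, pairs, min_nt = 20L) {
  ga <- data.table::as.data.table(guides)
  nt <- ga[ga$target_class == "NT", ]$cell
  if (length(nt) < min_nt)
    stop(sprintf("pair_correlation: %d NT cells; need >= %d", length(nt), min_nt))
  Ne <- normalize_matrix(rna); Na <- normalize_matrix(atac)
  gi <- match(nt, rna$barcodes); ai <- match(nt, atac$barcodes)
  if (anyNA(gi) || anyNA(ai))
    stop("pair_correlation: NT cells missing from a matrix")
  ug <- unique(pairs$gene_id); ua <- unique(pairs$acr)
  rank_cols <- function(M, cols, idx) {
    X <- as.matrix(M[idx, cols, drop = FALSE])
    apply(X, 2, rank)
  }
  Rg <- rank_cols(Ne, ug, gi); Ra <- rank_cols(Na, ua, ai)
  n <- length(nt)
  ## Pearson on average ranks == Spearman with tie correction
  rho <- rep(NA_real_, nrow(pairs))
  ja <- match(pairs$acr, ua); jg <- match(pairs$gene_id, ug)
  n_degenerate <- 0L
  for (i in seq_len(nrow(pairs))) {
    x <- Ra[, ja[i]]; y <- Rg[, jg[i]]
    if (sd(x) == 0 || sd(y) == 0) { n_degenerate <- n_degenerate + 1L; next }
    rho[i] <- cor(x, y)
  }
  if (n_degenerate > 0)
    message(sprintf("pair_correlation: %d pair(s) with a zero-variance member; rho set NA",
                    n_degenerate))
  out <- data.table::as.data.table(pairs)
  out$rho <- rho
  out[]
}

## shared odds-ratio machinery: sample OR with Haldane-Anscombe correction
## for the CI (and for the point estimate only when a cell is zero)
odds_result <- function(a, b, c, d, p = NA_real_) {
  degenerate <- any(c(a, b, c, d) == 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  ah <- a + 0.5; bh <- b + 0.5; ch <- c + 0.5; dh <- d + 0.5
  se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  or_h <- (ah * dh) / (bh * ch)
  ci <- exp(log(or_h) + c(-1, 1) * 1.96 * se)
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2], p = p,
                 table = c(a = a, b = b, c = c, d = d),
                 degenerate = degenerate),
            class = "OddsResult")
}

#' @export
print.OddsResult <- function(x, ...) {
  cat(sprintf("OR %.3g [%.3g, %.3g], p = %.3g%s\n", x$or, x$ci_low, x$ci_high,
              x$p, if (x$degenerate) " (zero cell; Haldane-corrected CI)" else ""))
  invisible(x)
}

#' Enrichment of TF-sensitive pairs in CRISPRi-validated links
#'
#' Fisher's exact test (two-sided) on the 2x2 table {pair TF-sensitive} x
#' {pair in the validated link set}, over the enumerated pair universe.
#'
#' @param pairs enumerated pairs (acr, gene_id).
#' @param pair_sensitive logical vector along `pairs`.
#' @param validated_links data.frame with acr, gene_id columns (keys drawn
#'   from the enumerated universe).
#' @return An `OddsResult` (sample OR, 95% CI by log-normal approximation
#'   with Haldane correction when a cell is zero, Fisher p).
#' @export
crispri_overlap_or <- function(pairs, pair_sensitive, validated_links) {
  stopifnot(nrow(pairs) == length(pair_sensitive))
  vl <- data.table::as.data.table(validated_links)
  if (nrow(vl) == 0) stop("crispri_overlap_or: empty validated link set")
  key <- paste(pairs$acr, pairs$gene_id)
  vkey <- paste(vl$acr, vl$gene_id)
  in_val <- key %in% vkey
  a <- sum(pair_sensitive & in_val); b <- sum(pair_sensitive & !in_val)
  c <- sum(!pair_sensitive & in_val); d <- sum(!pair_sensitive & !in_val)
  p <- fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
  odds_result(a, b, c, d, p)
}

#' TAD co-occupancy odds of sensitive pairs vs matched resampled nulls
#'
#' Per genomic-distance bin, the odds that a TF-sensitive ACR-gene pair has
#' both anchors (peak midpoint and TSS) strictly inside the same TAD,
#' compared with the distribution of the same odds over non-sensitive pairs
#' matched on accessibility/expression deciles (same count per bin,
#' `n_resamples` draws; null mean and SD reported).
#'
#' @param pairs enumerated pairs (up to the TAD window, e.g. 2 Mb).
#' @param pair_sensitive logical along `pairs`.
#' @param tads non-overlapping [interval_set()].
#' @param peaks,genes coordinate sources for the pair anchors.
#' @param acr_score,gene_score named vectors (mean normalized accessibility
#'   per ACR / expression per gene) used for decile matching.
#' @param breaks distance-bin breakpoints in bp (default: logarithmic from
#'   10 kb to 2 Mb).
#' @param n_resamples number of resampling draws (default 100).
#' @param seed RNG seed.
#' @return `data.table`: bin label, n pairs, odds_sensitive, null_mean,
#'   null_sd, degenerate flag. Bins without sensitive pairs are skipped with
#'   a message.
#' @export
tad_cooccupancy_odds <- function(pairs, pair_sensitive, tads, peaks, genes,
                                 acr_score, gene_score,
                                 breaks = c(0, 10^seq(4, log10(2e6), length.out = 6)),
                                 n_resamples = 100L, seed = 1L) {
  stopifnot(nrow(pairs) == length(pair_sensitive))
  tt <- data.table::as.data.table(tads)
  for (ch in unique(tt$chrom)) {
    tc <- tt[tt$chrom == ch, ]
    if (nrow(tc) > 1 && any(tc$start[-1] < tc$end[-nrow(tc)]))
      stop("tad_cooccupancy_odds: TADs overlap within a chromosome")
  }
  genes <- data.table::as.data.table(genes)
  ctr <- setNames(interval_center(peaks), peaks$name)
  tss <- setNames(genes$tss, genes$gene_id)
  pk_tad <- point_interval_index(pairs$chrom, ctr[pairs$acr], tads)
  ge_tad <- point_interval_index(pairs$chrom, tss[pairs$gene_id], tads)
  in_tad <- !is.na(pk_tad) & !is.na(ge_tad) & pk_tad == ge_tad

  dec <- function(v) {
    qs <- unique(quantile(v, probs = seq(0, 1, 0.1), na.rm = TRUE))
    findInterval(v, qs, rightmost.closed = TRUE, all.inside = TRUE)
  }
  cell2d <- paste(dec(acr_score[pairs$acr]), dec(gene_score[pairs$gene_id]))
  bin <- cut(abs(pairs$distance), breaks = breaks, include.lowest = TRUE)

  odds_of <- function(idx) {
    i <- sum(in_tad[idx]); o <- length(idx) - i
    if (o == 0 || i == 0) (i + 0.5) / (o + 0.5) else i / o
  }
  set.seed(as.integer(seed))
  out <- list()
  for (b in levels(bin)) {
    sel <- which(bin == b)
    s_idx <- sel[pair_sensitive[sel]]
    if (!length(s_idx)) {
      message(sprintf("tad_cooccupancy_odds: bin %s has no sensitive pairs; skipped", b))
      next
    }
    ns_idx <- sel[!pair_sensitive[sel]]
    degenerate <- all(in_tad[s_idx]) || !any(in_tad[s_idx])
    by_cell <- split(ns_idx, cell2d[ns_idx])
    null_odds <- rep(NA_real_, n_resamples)
    if (length(ns_idx)) {
      for (r in seq_len(n_resamples)) {
        draw <- vapply(s_idx, function(i) {
          pool <- by_cell[[cell2d[i]]]
          if (is.null(pool) || !length(pool)) pool <- ns_idx
          pool[sample.int(length(pool), 1L)]
        }, 0L)
        null_odds[r] <- odds_of(draw)
      }
    }
    out[[b]] <- data.table::data.table(
      bin = b, n_sensitive = length(s_idx), n_nonsensitive = length(ns_idx),
      odds_sensitive = odds_of(s_idx),
      null_mean = mean(null_odds), null_sd = sd(null_odds),
      degenerate = degenerate)
  }
  data.table::rbindlist(out)
}

#' ChIP-peak proximity profile of perturbation p-values
#'
#' Assigns each ACR (by midpoint) to a distance bin relative to the nearest
#' ChIP-seq peak center within `window_bp` and reports the mean
#' `-log10(p)` per bin; ACRs beyond the window are excluded.
#'
#' @param st ATAC `SensitivityTable` rows for one TF (one row per ACR).
#' @param peaks [interval_set()] giving ACR coordinates.
#' @param chip_peaks [interval_set()] of ChIP-seq peaks.
#' @param window_bp half-window around ChIP centers.
#' @param n_bins number of equal-width distance bins.
#' @return `data.table`: bin center (bp), n ACRs, mean_neglog10_p.
#' @export
chip_proximity_profile <- function(st, peaks, chip_peaks, window_bp = 5000L,
                                   n_bins = 20L) {
  if (window_bp <= 0) stop("chip_proximity_profile: window_bp must be positive")
  sdt <- data.table::as.data.table(st)
  if (anyDuplicated(sdt$feature))
    stop("chip_proximity_profile: multiple rows per ACR; filter to one TF first")
  idx <- match(sdt$feature, peaks$name)
  if (anyNA(idx)) stop("chip_proximity_profile: ACR missing from the peak set")
  acr_c <- interval_center(peaks)[idx]
  acr_chr <- peaks$chrom[idx]
  dist <- rep(NA_real_, nrow(sdt))
  for (ch in unique(acr_chr)) {
    cc <- sort(interval_center(chip_peaks[chip_peaks$chrom == ch, ]))
    if (!length(cc)) next
    qi <- which(acr_chr == ch)
    pos <- acr_c[qi]
    right <- pmin(findInterval(pos, cc) + 1L, length(cc))
    left <- pmax(right - 1L, 1L)
    d_l <- pos - cc[left]; d_r <- pos - cc[right]
    dist[qi] <- ifelse(abs(d_l) <= abs(d_r), d_l, d_r)
  }
  keep <- which(!is.na(dist) & abs(dist) <= window_bp)
  if (!length(keep)) stop("chip_proximity_profile: no ACR within the window of a ChIP peak")
  brk <- seq(-window_bp, window_bp, length.out = n_bins + 1L)
  bin <- cut(dist[keep], breaks = brk, include.lowest = TRUE)
  nl10 <- -log10(pmax(sdt$p[keep], 1e-300))
  out <- data.table::data.table(bin = bin, nl10 = nl10)[
    , list(n = .N, mean_neglog10_p = mean(nl10)), by = "bin"]
  out$bin_center <- (brk[-length(brk)] + brk[-1])[match(out$bin, levels(bin))] / 1
  data.table::setorder(out, bin_center)
  out[]
}
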