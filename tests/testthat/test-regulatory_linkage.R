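test_that("enumerate_pairs distance arithmetic and windows", {
  peaks <- interval_set(data.frame(
    chrom = "chr1", start = c(59750, 159750), end = c(60250, 160250),
    name = c("pA", "pB")))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000L,
                      strand = "+")
  pr <- enumerate_pairs(peaks, genes, 50000)
  expect_equal(pr$acr, "pA")                 # center 160000 excluded
  expect_equal(pr$distance, -40000L)         # upstream of + gene

  genes_m <- transform(genes, strand = "-")
  expect_equal(enumerate_pairs(peaks, genes_m, 50000)$distance, 40000L)

  peaks0 <- interval_set(data.frame(chrom = "chr1", start = 99800,
                                    end = 100200, name = "pC"))
  expect_equal(nrow(enumerate_pairs(peaks0, genes, 0)), 1)  # center == TSS
  expect_equal(nrow(enumerate_pairs(peaks, genes, 0)), 0)
})

test_that("enumerate_pairs matches the all-pairs brute force", {
  set.seed(13)
  ng <- 100; np <- 500
  genes <- data.frame(gene_id = sprintf("g%03d", 1:ng), chrom = "chrS",
                      tss = sort(sample.int(2e6, ng)),
                      strand = sample(c("+", "-"), ng, TRUE))
  st <- sort(sample.int(2e6, np))
  peaks <- interval_set(data.frame(chrom = "chrS", start = st, end = st + 400,
                                   name = sprintf("p%03d", 1:np)))
  got <- enumerate_pairs(peaks, genes, 50000)

  ctr <- floor((peaks$start + peaks$end) / 2)
  D <- outer(ctr, genes$tss, `-`)
  keep <- which(abs(D) <= 50000, arr.ind = TRUE)
  want <- data.table::data.table(
    acr = peaks$name[keep[, 1]], gene_id = genes$gene_id[keep[, 2]],
    distance = as.integer(D[keep] * ifelse(genes$strand[keep[, 2]] == "-", -1, 1)))
  data.table::setorder(want, acr, gene_id)
  got2 <- got[, c("acr", "gene_id", "distance")]
  data.table::setorder(got2, acr, gene_id)
  expect_equal(as.data.frame(got2), as.data.frame(want))
})

test_that("pair_correlation identities and rank brute force at n = 10", {
  set.seed(3)
  rna_counts <- matrix(rpois(10 * 3, 20), 10, 3)
  atac_counts <- cbind(rna_counts[, 1], matrix(rpois(10 * 2, 4), 10, 2))
  rna <- fm(rna_counts, "RNA"); atac <- fm(atac_counts, "ATAC")
  ga <- validate_guides(data.frame(cell = rna$barcodes, guide_id = "NT_g1",
                                   target = "NT", target_class = "NT"))
  pairs <- data.table::data.table(acr = c("f001", "f002"),
                                  gene_id = c("f001", "f002"))
  out <- pair_correlation(rna, atac, ga, pairs, min_nt = 10)

  ## brute-force Spearman: average ranks + Pearson product-moment formula
  brute <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  Nr <- as.matrix(normalize_matrix(rna)); Na <- as.matrix(normalize_matrix(atac))
  expect_equal(out$rho[1], brute(Na[, 1], Nr[, 1]), tolerance = 1e-12)
  expect_equal(out$rho[2], brute(Na[, 2], Nr[, 2]), tolerance = 1e-12)

  ## accessibility identical to expression with equal per-cell depth -> the
  ## normalizations are monotone per feature and rho = 1
  eq <- cbind(1:10, rep(5L, 10), 30L - (1:10))
  rna_eq <- fm(eq, "RNA"); atac_eq <- fm(eq, "ATAC")
  out_eq <- pair_correlation(rna_eq, atac_eq, ga,
                             data.table::data.table(acr = "f001",
                                                    gene_id = "f001"),
                             min_nt = 10)
  expect_equal(out_eq$rho, 1)

  ## zero variance (identical cells) -> NA with a message
  atac0 <- fm(matrix(rep(c(2L, 4L, 6L), each = 10), 10, 3), "ATAC")
  expect_message(out0 <- pair_correlation(rna, atac0, ga, pairs, min_nt = 10),
                 "zero-variance")
  expect_true(all(is.na(out0$rho)))

  expect_error(pair_correlation(rna, atac, ga, pairs, min_nt = 20), "NT cells")
})

test_that("independent features give near-zero mean pair correlation", {
  set.seed(14)
  n <- 40
  rna <- fm(matrix(rpois(n * 30, 10), n, 30), "RNA")
  atac <- fm(matrix(rpois(n * 30, 3), n, 30), "ATAC")
  ga <- validate_guides(data.frame(cell = rna$barcodes, guide_id = "NT_g1",
                                   target = "NT", target_class = "NT"))
  pairs <- data.table::data.table(acr = sprintf("f%03d", 1:30),
                                  gene_id = sprintf("f%03d", 30:1))
  out <- pair_correlation(rna, atac, ga, pairs)
  expect_lt(abs(mean(out$rho, na.rm = TRUE)), 3 / sqrt(n - 3) / sqrt(30) * 3 + 0.05)
})

test_that("crispri_overlap_or handles balanced, known and degenerate tables", {
  mk_pairs <- function(a, b, c, d) {
    n <- a + b + c + d
    pairs <- data.table::data.table(acr = sprintf("a%03d", 1:n),
                                    gene_id = sprintf("g%03d", 1:n))
    sens <- c(rep(TRUE, a + b), rep(FALSE, c + d))
    val <- pairs[c(seq_len(a), a + b + seq_len(c)), ]
    list(pairs = pairs, sens = sens, val = val)
  }
  x <- mk_pairs(10, 10, 10, 10)
  r <- crispri_overlap_or(x$pairs, x$sens, x$val)
  expect_equal(r$or, 1)
  expect_equal(r$p, 1)
  expect_true(r$ci_low <= 1 && r$ci_high >= 1)

  x2 <- mk_pairs(20, 5, 5, 20)
  r2 <- crispri_overlap_or(x2$pairs, x2$sens, x2$val)
  expect_equal(r2$or, 16)
  ## oracle: full hypergeometric enumeration via choose()
  hyper_p <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    xs <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
    sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
  }
  expect_equal(r2$p, hyper_p(20, 5, 5, 20), tolerance = 1e-9)

  x3 <- mk_pairs(10, 0, 0, 10)
  r3 <- crispri_overlap_or(x3$pairs, x3$sens, x3$val)
  expect_true(is.infinite(r3$or))
  expect_true(r3$degenerate)
  expect_true(is.finite(r3$ci_low) && is.finite(r3$ci_high))

  expect_error(crispri_overlap_or(x$pairs, x$sens, x$val[0, ]), "empty validated")
})

test_that("tad_cooccupancy_odds: degenerate, independent and planted cases", {
  set.seed(6)
  L <- 2e6
  st <- seq(1000, L - 2000, length.out = 200)
  peaks <- interval_set(data.frame(chrom = "chrS", start = st, end = st + 500,
                                   name = sprintf("p%03d", 1:200)))
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chrS",
                      tss = sort(sample.int(L, 100)), strand = "+")
  pairs <- enumerate_pairs(peaks, genes, 2e6)
  acr_score <- stats::setNames(runif(200), peaks$name)
  gene_score <- stats::setNames(runif(100), genes$gene_id)

  ## one genome-spanning TAD: everything co-occupies, flagged degenerate
  tad1 <- interval_set(data.frame(chrom = "chrS", start = 0, end = L + 1,
                                  name = "tadAll"))
  sens <- runif(nrow(pairs)) < 0.2
  out1 <- tad_cooccupancy_odds(pairs, sens, tad1, peaks, genes,
                               acr_score, gene_score, n_resamples = 10)
  expect_true(all(out1$degenerate))

  ## uniform TADs, sensitivity independent of membership: within 4 null SD
  tb <- seq(0, L, by = 250000)
  tads <- interval_set(data.frame(chrom = "chrS", start = tb[-length(tb)],
                                  end = tb[-1],
                                  name = sprintf("t%02d", seq_len(length(tb) - 1))))
  out2 <- tad_cooccupancy_odds(pairs, sens, tads, peaks, genes,
                               acr_score, gene_score, n_resamples = 50, seed = 2)
  dev <- abs(out2$odds_sensitive - out2$null_mean) / pmax(out2$null_sd, 1e-9)
  expect_true(all(dev[out2$n_sensitive >= 10 & out2$null_sd > 0] < 4))

  ## overlapping TADs rejected
  bad <- interval_set(data.frame(chrom = "chrS", start = c(0, 1000),
                                 end = c(5000, 6000), name = c("x", "y")))
  expect_error(tad_cooccupancy_odds(pairs, sens, bad, peaks, genes,
                                    acr_score, gene_score), "overlap")
})

test_that("planted in-TAD links raise sensitive odds above the null", {
  sim <- small_sim()
  lp <- sim$truth$linked_pairs
  pairs <- enumerate_pairs(sim$peaks, sim$genes, 2e6)
  key <- paste(pairs$acr, pairs$gene_id)
  sens <- key %in% paste(lp$acr, lp$gene_id)
  expect_gt(sum(sens), 10)
  acr_score <- Matrix::colMeans(normalize_matrix(sim$atac))
  gene_score <- Matrix::colMeans(normalize_matrix(sim$rna))
  out <- tad_cooccupancy_odds(pairs, sens, sim$truth$tads, sim$peaks,
                              sim$genes, acr_score, gene_score,
                              breaks = c(0, 1e5, 2e6), n_resamples = 30,
                              seed = 4)
  short <- out[1, ]   # linked pairs are within 50 kb, all inside one TAD
  expect_gt(short$odds_sensitive, short$null_mean)
})

test_that("chip_proximity_profile flat and error cases", {
  n <- 400
  st <- seq(0, by = 1000, length.out = n)
  peaks <- interval_set(data.frame(chrom = "chrS", start = st, end = st + 500,
                                   name = sprintf("p%04d", 1:n)))
  chip <- interval_set(data.frame(chrom = "chrS",
                                  start = seq(0, by = 40000, length.out = 10),
                                  end = seq(0, by = 40000, length.out = 10) + 200,
                                  name = sprintf("c%02d", 1:10)))
  stab <- data.table::data.table(feature = peaks$name, p = 0.1)
  prof <- chip_proximity_profile(stab, peaks, chip, window_bp = 5000, n_bins = 4)
  expect_equal(prof$mean_neglog10_p, rep(1, nrow(prof)), tolerance = 1e-12)

  expect_error(chip_proximity_profile(stab, peaks, chip, window_bp = 0),
               "window_bp")
  far_chip <- interval_set(data.frame(chrom = "chr9", start = 1, end = 100,
                                      name = "c"))
  expect_error(chip_proximity_profile(stab, peaks, far_chip, window_bp = 100),
               "no ACR within")
})

test_that("sensitive linked pairs correlate more than unlinked ones", {
  sim <- small_sim()
  pairs <- enumerate_pairs(sim$peaks, sim$genes, 50000)
  pc <- suppressMessages(pair_correlation(sim$rna, sim$atac, sim$guides, pairs))
  lp <- sim$truth$linked_pairs
  linked <- paste(pc$acr, pc$gene_id) %in% paste(lp$acr, lp$gene_id)
  expect_gt(sum(linked), 5)
  expect_gt(mean(abs(pc$rho[linked]), na.rm = TRUE),
            mean(abs(pc$rho[!linked]), na.rm = TRUE))
})
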