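mk_cs <- function(pos_list, chrom = "chrS") {
  data.table::rbindlist(lapply(seq_along(pos_list), function(i)
    data.table::data.table(trait = "t1", set_id = sprintf("cs%02d", i),
                           snp_id = sprintf("cs%02d_v%d", i,
                                            seq_along(pos_list[[i]])),
                           chrom = chrom, pos = pos_list[[i]],
                           pip = 1 / length(pos_list[[i]]))))
}

test_that("credible_set_overlap counts sets by point containment", {
  regions <- interval_set(data.frame(chrom = "chrS", start = 100, end = 200,
                                     name = "r1"))
  ## half-open: 100 inside, 200 outside
  cs <- mk_cs(list(c(100), c(200), c(199, 500)))
  out <- credible_set_overlap(cs, regions)
  expect_equal(out$n_overlap, 2)
  expect_equal(round(out$percent, 1), 66.7)
  expect_equal(round(attr(out, "overall"), 1), 66.7)

  none <- credible_set_overlap(mk_cs(list(50, 60)), regions)
  expect_equal(none$percent, 0)
  all_in <- credible_set_overlap(mk_cs(list(150, c(110, 5))), regions)
  expect_equal(all_in$percent, 100)
})

test_that("credible_set_overlap is monotone under region-set union", {
  set.seed(11)
  cs <- mk_cs(as.list(as.data.frame(matrix(sample.int(1e5, 60), 3))))
  rA <- interval_set(data.frame(chrom = "chrS", start = c(0, 5e4),
                                end = c(1e4, 6e4), name = c("a", "b")))
  rAB <- interval_set(data.frame(chrom = "chrS", start = c(0, 5e4, 8e4),
                                 end = c(1e4, 6e4, 9e4),
                                 name = c("a", "b", "c")))
  expect_gte(attr(credible_set_overlap(cs, rAB), "overall"),
             attr(credible_set_overlap(cs, rA), "overall"))
})

test_that("sampled_overlap_null identity, degenerate and reproducibility", {
  regions <- interval_set(data.frame(
    chrom = "chrS", start = c(10, 500, 900), end = c(110, 600, 1000),
    name = c("a", "b", "c")))
  cs <- mk_cs(list(c(50), c(550), c(2000)))
  obs <- attr(credible_set_overlap(cs, regions), "overall")

  ## pool = tested set, all drawn -> null mean equals observed, SD 0
  nul <- sampled_overlap_null(cs, regions, n_regions = 3, n_samples = 20,
                              matching = "length", seed = 1)
  expect_equal(nul$null_mean, obs)
  expect_equal(nul$null_sd, 0)

  one <- sampled_overlap_null(cs, regions, n_regions = 3, n_samples = 1,
                              matching = "length", seed = 1)
  expect_true(is.na(one$null_sd))

  r1 <- sampled_overlap_null(cs, regions, n_regions = 2, n_samples = 25,
                             matching = "length", target_lengths = c(100, 100),
                             seed = 7)
  r2 <- sampled_overlap_null(cs, regions, n_regions = 2, n_samples = 25,
                             matching = "length", target_lengths = c(100, 100),
                             seed = 7)
  expect_identical(r1$samples, r2$samples)

  expect_error(sampled_overlap_null(cs, regions, n_regions = 10),
               "smaller than n_regions")
  expect_error(sampled_overlap_null(cs, regions, n_regions = 2,
                                    matching = "random", seed = 1),
               "genome_length")
})

test_that("heritability_enrichment arithmetic, identity and errors", {
  h2 <- data.table::data.table(snp_id = sprintf("s%d", 1:100),
                               h2_contribution = c(rep(0.05, 10), rep(0.01, 90)))
  ## 10% of SNPs carry 0.5/1.4 of h2 -> enrichment = (0.5/1.4)/0.1
  out <- heritability_enrichment(h2, seq_len(100) <= 10)
  expect_equal(out$enrichment, (0.5 / 1.4) / 0.1, tolerance = 1e-12)
  expect_equal(out$pct_snps, 10)

  expect_equal(heritability_enrichment(h2, rep(TRUE, 100))$enrichment, 1)
  expect_error(heritability_enrichment(h2, rep(FALSE, 100)), "empty category")

  ## clean 10% / 50% case
  h2b <- data.table::data.table(snp_id = sprintf("s%d", 1:100),
                                h2_contribution = c(rep(0.1, 10), rep(0.1 / 9, 90)))
  expect_equal(heritability_enrichment(h2b, seq_len(100) <= 10)$enrichment, 5,
               tolerance = 1e-12)

  ## complementary-category mixture identity: p E_in + (1-p) E_out = 1
  set.seed(5)
  h2c <- data.table::data.table(snp_id = sprintf("s%d", 1:500),
                                h2_contribution = rexp(500))
  mask <- runif(500) < 0.23
  ein <- heritability_enrichment(h2c, mask)
  eout <- heritability_enrichment(h2c, !mask)
  p <- mean(mask)
  expect_equal(p * ein$enrichment + (1 - p) * eout$enrichment, 1,
               tolerance = 1e-12)
})

test_that("constraint_ecdf identities, exclusions and detection", {
  x <- rnorm(200)
  rec <- data.frame(score = c(x, x), category = rep(c("a", "b"), each = 200))
  out <- constraint_ecdf(rec)
  expect_equal(out$ks$ks_d, 0)
  expect_equal(out$ks$p, 1)
  ## ECDF non-decreasing, ends at 1
  expect_true(all(diff(out$ecdf[, "a"]) >= 0))
  expect_equal(unname(out$ecdf[nrow(out$ecdf), ]), c(1, 1))

  rec2 <- data.frame(score = c(rnorm(200), rnorm(200) + 1),
                     category = rep(c("a", "b"), each = 200))
  out2 <- constraint_ecdf(rec2)
  expect_gt(out2$ks$ks_d, 0.2)
  expect_lt(out2$ks$p, 0.001)

  rec3 <- rbind(rec2, data.frame(score = 0, category = "tiny"))
  expect_message(out3 <- constraint_ecdf(rec3), "tiny")
  expect_false("tiny" %in% colnames(out3$ecdf))
  expect_error(constraint_ecdf(data.frame(score = rnorm(5), category = "a")),
               ">= 2 categories")
  expect_error(constraint_ecdf(data.frame(score = c(1, Inf),
                                          category = c("a", "b"))),
               "non-finite")
})

test_that("trait_relevance_score: null calibration, planted signal, errors", {
  ## heterogeneous peak rates so accessibility deciles are well-populated;
  ## a subset of cells doubles its counts in the trait peaks (a cell-state
  ## signal, not a peak-total outlier)
  set.seed(17)
  lam <- rgamma(400, shape = 2, scale = 2)
  counts <- matrix(rpois(300 * 400, rep(lam, each = 300)), 300, 400)
  boosted <- 1:40
  counts[boosted, 1:40] <- counts[boosted, 1:40] * 2L
  atac <- fm(counts, "ATAC")

  trait <- sprintf("f%03d", 1:40)
  trs <- trait_relevance_score(atac, trait, n_background = 50, seed = 2)
  expect_gt(mean(trs$trs[boosted]), mean(trs$trs[-boosted]) + 0.5)

  ## a random matched set is approximately standard normal
  set.seed(18)
  counts0 <- matrix(rpois(300 * 400, 3), 300, 400)
  atac0 <- fm(counts0, "ATAC")
  rnd <- sample(atac0$features, 40)
  trs0 <- trait_relevance_score(atac0, rnd, n_background = 50, seed = 3)
  expect_lt(abs(mean(trs0$trs)), 0.25)
  expect_gt(sd(trs0$trs), 0.6)
  expect_lt(sd(trs0$trs), 1.6)

  expect_error(trait_relevance_score(atac, character(0)), "empty trait peak")
  expect_error(trait_relevance_score(atac, trait, n_background = 0),
               "n_background")
  expect_error(trait_relevance_score(atac, "nope"), "not in the matrix")
})

test_that("planted GWAS enrichment is visible end-to-end on one seed", {
  sim <- small_sim()
  gw <- simulate_gwas(sim$truth, sim$peaks, enrichment_factor = 8,
                      causal_frac_sensitive = 0.6, seed = 9)
  sens <- sim$peaks[sim$peaks$name %in% unique(sim$truth$sensitive_peaks$peak_id), ]
  obs <- attr(credible_set_overlap(gw$credible_sets, sens), "overall")
  pool <- sim$peaks[!sim$peaks$name %in% sens$name, ]
  nul <- sampled_overlap_null(gw$credible_sets, pool, n_regions = nrow(sens),
                              n_samples = 50, matching = "length",
                              target_lengths = sens$end - sens$start, seed = 5)
  expect_gt(obs, nul$null_mean + 3 * nul$null_sd)
  he <- heritability_enrichment(gw$snp_h2, gw$snp_h2$in_sensitive)
  expect_gt(he$enrichment, 2)
})
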