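## Synthetic multiome generator with planted ground truth. The stated world:
## a pooled knock-out screen of n_tfs TFs (default 19) with 3 guides each
## plus 6 controls (3 non-targeting, 3 safe-harbor), paired NB RNA counts and
## Poisson ATAC counts over one synthetic chromosome, cells spread along a
## differentiation pseudotime, per-guide editing efficiencies, and planted
## TF effects on genes (log2FC) and peaks (logit shifts), with a fraction of
## sensitive peaks linked to sensitive genes within 50 kb and a shared TAD.

PEAK_WIDTH <- 500L
LINK_WINDOW <- 50000L

#' Simulation configuration
#'
#' All parameters of the synthetic multiome world. Defaults follow the
#' screen design this package models: 19 TFs, three guides per TF, six
#' control guides (split between non-targeting and safe-harbor).
#'
#' @param n_cells,n_genes,n_peaks dataset dimensions.
#' @param n_tfs number of perturbed TFs (default 19).
#' @param guides_per_tf guides per TF (default 3).
#' @param n_control_guides control guides, split evenly NT/SAFE (default 6).
#' @param editing_efficiency_range per-guide editing efficiencies are drawn
#'   uniformly within this range.
#' @param n_sensitive_genes_per_tf,n_sensitive_peaks_per_tf planted sensitive
#'   features per TF.
#' @param effect_size_log2fc magnitude scale of planted effects; per-feature
#'   effects are `sign * effect_size_log2fc * U(1 - effect_jitter,
#'   1 + effect_jitter)` (heterogeneous magnitudes, as for real TF targets).
#' @param effect_jitter relative half-width of the planted-magnitude
#'   distribution (default 0.5; 0 plants constant magnitudes).
#' @param frac_linked_pairs fraction of sensitive peaks placed within 50 kb
#'   of a same-TF sensitive gene TSS and inside a shared TAD.
#' @param tad_width_bp,genome_length_bp genome layout (single chromosome).
#' @param nb_dispersion RNA negative binomial dispersion (size = 1/dispersion).
#' @param mean_rna_depth,mean_atac_depth expected per-cell totals.
#' @param frac_program_genes fraction of genes/peaks whose baseline varies
#'   smoothly with differentiation pseudotime.
#' @param seed RNG seed.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 1000L, n_peaks = 2000L,
                       n_tfs = 19L, guides_per_tf = 3L, n_control_guides = 6L,
                       editing_efficiency_range = c(0.4, 0.95),
                       n_sensitive_genes_per_tf = 25L,
                       n_sensitive_peaks_per_tf = 50L,
                       effect_size_log2fc = 1,
                       effect_jitter = 0.5,
                       frac_linked_pairs = 0.5,
                       tad_width_bp = 500000L,
                       genome_length_bp = 2e7,
                       nb_dispersion = 0.5,
                       mean_rna_depth = 10000,
                       mean_atac_depth = 5000,
                       frac_program_genes = 0.2,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks), n_tfs = as.integer(n_tfs),
              guides_per_tf = as.integer(guides_per_tf),
              n_control_guides = as.integer(n_control_guides),
              editing_efficiency_range = as.numeric(editing_efficiency_range),
              n_sensitive_genes_per_tf = as.integer(n_sensitive_genes_per_tf),
              n_sensitive_peaks_per_tf = as.integer(n_sensitive_peaks_per_tf),
              effect_size_log2fc = as.numeric(effect_size_log2fc),
              effect_jitter = as.numeric(effect_jitter),
              frac_linked_pairs = as.numeric(frac_linked_pairs),
              tad_width_bp = as.integer(tad_width_bp),
              genome_length_bp = as.numeric(genome_length_bp),
              nb_dispersion = as.numeric(nb_dispersion),
              mean_rna_depth = as.numeric(mean_rna_depth),
              mean_atac_depth = as.numeric(mean_atac_depth),
              frac_program_genes = as.numeric(frac_program_genes),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos_int <- c("n_cells", "n_genes", "n_peaks", "n_tfs", "guides_per_tf",
               "n_control_guides", "tad_width_bp")
  for (f in pos_int)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("sim_config: field '%s' must be a positive integer", f))
  if (cfg$effect_jitter < 0 || cfg$effect_jitter > 1)
    stop("sim_config: field 'effect_jitter' must be in [0,1]")
  for (f in c("frac_linked_pairs", "frac_program_genes")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("sim_config: field '%s' must be a probability in [0,1]", f))
  }
  r <- cfg$editing_efficiency_range
  if (length(r) != 2L || any(is.na(r)) || any(r < 0) || any(r > 1) || r[1] > r[2])
    stop("sim_config: field 'editing_efficiency_range' must be an increasing pair of probabilities")
  if (cfg$effect_size_log2fc < 0)
    stop("sim_config: field 'effect_size_log2fc' must be non-negative")
  if (cfg$n_sensitive_genes_per_tf < 0 || cfg$n_sensitive_genes_per_tf > cfg$n_genes)
    stop("sim_config: field 'n_sensitive_genes_per_tf' must be in [0, n_genes]")
  if (cfg$n_sensitive_peaks_per_tf < 0 || cfg$n_sensitive_peaks_per_tf > cfg$n_peaks)
    stop("sim_config: field 'n_sensitive_peaks_per_tf' must be in [0, n_peaks]")
  if (cfg$nb_dispersion <= 0)
    stop("sim_config: field 'nb_dispersion' must be positive")
  if (cfg$mean_rna_depth <= 0 || cfg$mean_atac_depth <= 0)
    stop("sim_config: fields 'mean_rna_depth'/'mean_atac_depth' must be positive")
  if (cfg$genome_length_bp < cfg$n_peaks * 2L * PEAK_WIDTH)
    stop("sim_config: field 'genome_length_bp' too small for n_peaks non-overlapping peaks")
  invisible(cfg)
}

## Genome layout + planted effects: everything shared between noise
## replicates of the same world.
build_ground_truth <- function(cfg) {
  L <- cfg$genome_length_bp
  np <- cfg$n_peaks; ng <- cfg$n_genes
  slot_p <- floor(L / np)
  peak_start <- as.integer((seq_len(np) - 1L) * slot_p +
                             floor(runif(np) * (slot_p - PEAK_WIDTH)))
  peaks <- interval_set(data.table::data.table(
    chrom = "chrS", start = peak_start, end = peak_start + PEAK_WIDTH,
    name = sprintf("peak_%05d", seq_len(np))), kind = "peaks")
  peaks$base_logit <- qlogis(0.05) + rnorm(np, 0, 1)
  peaks$program_slope <- ifelse(runif(np) < cfg$frac_program_genes,
                                sample(c(-2, 2), np, replace = TRUE), 0)

  slot_g <- floor(L / ng)
  tss <- as.integer((seq_len(ng) - 1L) * slot_g + floor(runif(ng) * slot_g))
  genes <- data.table::data.table(
    gene_id = sprintf("gene_%05d", seq_len(ng)), chrom = "chrS", tss = tss,
    strand = sample(c("+", "-"), ng, replace = TRUE),
    base_mean = rlnorm(ng, meanlog = 1, sdlog = 1),
    program_slope = ifelse(runif(ng) < cfg$frac_program_genes,
                           sample(c(-1, 1), ng, replace = TRUE), 0))

  tad_start <- seq(0, L - 1, by = cfg$tad_width_bp)
  tads <- interval_set(data.table::data.table(
    chrom = "chrS", start = as.integer(tad_start),
    end = as.integer(pmin(tad_start + cfg$tad_width_bp, L)),
    name = sprintf("tad_%03d", seq_along(tad_start))), kind = "tads")

  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  n_nt <- ceiling(cfg$n_control_guides / 2)
  guide_info <- data.table::rbindlist(list(
    data.table::data.table(
      guide_id = sprintf("%s_g%d", rep(tf_names, each = cfg$guides_per_tf),
                         rep(seq_len(cfg$guides_per_tf), cfg$n_tfs)),
      target = rep(tf_names, each = cfg$guides_per_tf), target_class = "TF"),
    data.table::data.table(
      guide_id = sprintf("NT_g%d", seq_len(n_nt)), target = "NT", target_class = "NT"),
    data.table::data.table(
      guide_id = sprintf("SAFE_g%d", seq_len(cfg$n_control_guides - n_nt)),
      target = "SAFE", target_class = "SAFE")))
  eff <- runif(nrow(guide_info), cfg$editing_efficiency_range[1],
               cfg$editing_efficiency_range[2])
  guide_info$efficiency <- ifelse(guide_info$target_class == "TF", eff, 0)

  ## planted effects: sensitive genes drawn from the upper half of baseline
  ## expression (TF targets are expressed genes); magnitudes heterogeneous
  high_expr <- which(genes$base_mean >= stats::median(genes$base_mean))
  peak_center <- interval_center(peaks)
  tad_of_peak <- point_interval_index(peaks$chrom, peak_center, tads)
  tad_of_tss <- point_interval_index(genes$chrom, genes$tss, tads)

  sens_genes <- list(); sens_peaks <- list(); links <- list()
  for (tf in tf_names) {
    gi <- sample(high_expr, min(cfg$n_sensitive_genes_per_tf, length(high_expr)))
    delta <- sample(c(-1, 1), length(gi), replace = TRUE) *
      cfg$effect_size_log2fc *
      runif(length(gi), 1 - cfg$effect_jitter, 1 + cfg$effect_jitter)
    sens_genes[[tf]] <- data.table::data.table(tf = tf, gene_id = genes$gene_id[gi],
                                               delta = delta)
    n_sp <- cfg$n_sensitive_peaks_per_tf
    n_link <- round(cfg$frac_linked_pairs * n_sp)
    used <- logical(np); pk <- integer(0)
    link_rows <- list()
    for (j in seq_along(gi)) {
      if (length(pk) >= n_link) break
      cand <- which(!used & abs(peak_center - genes$tss[gi[j]]) <= LINK_WINDOW &
                      tad_of_peak == tad_of_tss[gi[j]])
      cand <- cand[!is.na(cand)]
      if (!length(cand)) next
      sel <- cand[sample.int(length(cand), 1L)]
      used[sel] <- TRUE; pk <- c(pk, sel)
      link_rows[[length(link_rows) + 1L]] <- data.table::data.table(
        tf = tf, acr = peaks$name[sel], gene_id = genes$gene_id[gi[j]],
        gene_delta = delta[j])
    }
    rest <- sample(which(!used), n_sp - length(pk))
    lr <- data.table::rbindlist(link_rows)
    shift_sign <- c(if (nrow(lr)) sign(lr$gene_delta),
                    sample(c(-1, 1), length(rest), replace = TRUE))
    all_pk <- c(pk, rest)
    sens_peaks[[tf]] <- data.table::data.table(
      tf = tf, peak_id = peaks$name[all_pk],
      logit_shift = shift_sign * cfg$effect_size_log2fc * log(2) *
        runif(length(all_pk), 1 - cfg$effect_jitter, 1 + cfg$effect_jitter))
    links[[tf]] <- lr
  }

  ## linked pairs are co-regulated at baseline: both members follow a shared
  ## differentiation program, so their accessibility/expression correlate in
  ## control cells (what an enhancer-gene link looks like without
  ## perturbation)
  all_links <- data.table::rbindlist(links, fill = TRUE)
  if (nrow(all_links)) {
    for (i in seq_len(nrow(all_links))) {
      gi_ <- match(all_links$gene_id[i], genes$gene_id)
      pi_ <- match(all_links$acr[i], peaks$name)
      if (genes$program_slope[gi_] == 0)
        genes$program_slope[gi_] <- sample(c(-1, 1), 1L)
      peaks$program_slope[pi_] <- 2 * genes$program_slope[gi_]
    }
  }

  structure(list(config = cfg,
                 genes = genes, peaks = peaks, tads = tads,
                 guide_info = guide_info,
                 sensitive_genes = data.table::rbindlist(sens_genes),
                 sensitive_peaks = data.table::rbindlist(sens_peaks),
                 linked_pairs = data.table::rbindlist(links, fill = TRUE)),
            class = "GroundTruth")
}

#' Simulate a paired multiome dataset with planted ground truth
#'
#' Draws guide assignments (one guide per cell, uniform multinomial), edited
#' flags per the guide's efficiency, a per-cell differentiation pseudotime in
#' \[0,1\], negative binomial RNA counts and Poisson ATAC counts. In edited
#' cells, planted sensitive gene means are multiplied by `2^delta` and
#' sensitive peak open-probability logits shifted. Deterministic given the
#' seed.
#'
#' @param config A [sim_config()].
#' @param truth optional `GroundTruth` from a previous call: reuse the same
#'   genome layout and planted effects and only redraw cells/counts (a
#'   "biological replicate"); requires `noise_seed`.
#' @param noise_seed seed for the count noise when `truth` is supplied.
#' @return list with elements `rna`, `atac` ([feature_matrix()]s), `guides`
#'   (GuideAssignment), `genes`, `peaks`, `truth` (GroundTruth including the
#'   realized per-cell `cells` table with edited flags and pseudotime).
#' @export
simulate_dataset <- function(config, truth = NULL, noise_seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  validate_sim_config(config)
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- build_ground_truth(config)
  } else {
    stopifnot(inherits(truth, "GroundTruth"))
    if (is.null(noise_seed))
      stop("simulate_dataset: noise_seed required when reusing a GroundTruth")
    set.seed(as.integer(noise_seed))
  }
  cfg <- config
  gi <- truth$guide_info
  if (cfg$n_cells < nrow(gi))
    stop(sprintf("simulate_dataset: n_cells (%d) < number of guides (%d); every guide must be assignable",
                 cfg$n_cells, nrow(gi)))

  nc <- cfg$n_cells
  barcodes <- sprintf("cell_%06d", seq_len(nc))
  gidx <- sample.int(nrow(gi), nc, replace = TRUE)
  cells <- data.table::data.table(
    cell = barcodes, guide_id = gi$guide_id[gidx], target = gi$target[gidx],
    target_class = gi$target_class[gidx],
    edited = rbinom(nc, 1L, gi$efficiency[gidx]) == 1L,
    pseudotime = runif(nc))

  genes <- truth$genes; peaks <- truth$peaks
  ng <- nrow(genes); np <- nrow(peaks)

  ## RNA: log2 rate = baseline + pseudotime program + planted effect
  log2rate <- matrix(rep(log2(genes$base_mean), each = nc), nc, ng)
  log2rate <- log2rate + outer(cells$pseudotime - 0.5, genes$program_slope)
  for (tfn in unique(truth$sensitive_genes$tf)) {
    rows <- which(cells$target == tfn & cells$edited)
    if (!length(rows)) next
    sg <- truth$sensitive_genes[truth$sensitive_genes$tf == tfn, ]
    cols <- match(sg$gene_id, genes$gene_id)
    log2rate[rows, cols] <- log2rate[rows, cols] +
      rep(sg$delta, each = length(rows))
  }
  rate <- 2^log2rate
  sf <- rlnorm(nc, meanlog = -0.3^2 / 2, sdlog = 0.3)
  mu <- rate / rowSums(rate) * (sf * cfg$mean_rna_depth)
  rna_counts <- matrix(rnbinom(nc * ng, mu = mu, size = 1 / cfg$nb_dispersion),
                       nc, ng)
  rna <- feature_matrix(Matrix::Matrix(rna_counts, sparse = TRUE), "RNA",
                        barcodes, genes$gene_id)

  ## ATAC: logit open-probability, Poisson counts at normalized depth
  logit <- matrix(rep(peaks$base_logit, each = nc), nc, np)
  logit <- logit + outer(cells$pseudotime - 0.5, peaks$program_slope)
  for (tfn in unique(truth$sensitive_peaks$tf)) {
    rows <- which(cells$target == tfn & cells$edited)
    if (!length(rows)) next
    sp <- truth$sensitive_peaks[truth$sensitive_peaks$tf == tfn, ]
    cols <- match(sp$peak_id, peaks$name)
    logit[rows, cols] <- logit[rows, cols] + rep(sp$logit_shift, each = length(rows))
  }
  open <- plogis(logit)
  sfa <- rlnorm(nc, meanlog = -0.3^2 / 2, sdlog = 0.3)
  mua <- open / rowSums(open) * (sfa * cfg$mean_atac_depth)
  atac_counts <- matrix(rpois(nc * np, lambda = mua), nc, np)
  atac <- feature_matrix(Matrix::Matrix(atac_counts, sparse = TRUE), "ATAC",
                         barcodes, peaks$name)

  truth_out <- truth
  truth_out$cells <- cells
  guides <- validate_guides(cells[, c("cell", "guide_id", "target", "target_class")])
  list(rna = rna, atac = atac, guides = guides,
       genes = genes[, c("gene_id", "chrom", "tss", "strand")],
       peaks = peaks, truth = truth_out)
}

#' Simulate pooled single-cell genotyping calls
#'
#' Each TF-targeted cell is genotyped with probability `coverage`; the called
#' edited flag equals the true flag with probability `1 - call_error`.
#' Control-guide cells receive no target-site call.
#'
#' @param truth GroundTruth with realized `cells` (from [simulate_dataset()]).
#' @param guides GuideAssignment.
#' @param call_error,coverage probabilities.
#' @param seed RNG seed.
#' @return `data.table` (cell, guide_id, edited, amplicon).
#' @export
simulate_genotypes <- function(truth, guides, call_error = 0.02,
                               coverage = 0.9, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"), !is.null(truth$cells))
  for (p in c(call_error, coverage))
    if (p < 0 || p > 1) stop("simulate_genotypes: call_error and coverage must be in [0,1]")
  set.seed(as.integer(seed))
  cells <- truth$cells[truth$cells$target_class == "TF", ]
  cells <- cells[cells$cell %in% guides$cell, ]
  got <- runif(nrow(cells)) < coverage
  cells <- cells[got, ]
  flip <- runif(nrow(cells)) < call_error
  data.table::data.table(cell = cells$cell, guide_id = cells$guide_id,
                         edited = xor(cells$edited, flip),
                         amplicon = paste0(cells$target, "_site"))
}

#' Simulate fine-mapped credible sets and per-SNP heritability contributions
#'
#' Background SNPs are placed uniformly on the genome plus preferentially
#' inside peaks; SNPs falling in TF-sensitive peaks have their effect-size
#' variance multiplied by `enrichment_factor`, so the expected partitioned
#' heritability enrichment of that category equals `enrichment_factor`.
#' Credible sets hold one causal SNP (PIP 0.6) plus LD companions within
#' +/- 25 kb sharing the remaining PIP mass uniformly.
#'
#' @param truth GroundTruth (supplies sensitive peak union and genome length).
#' @param peaks IntervalSet of all peaks.
#' @param n_traits,n_sets_per_trait,snps_per_set credible-set design.
#' @param enrichment_factor variance multiplier for SNPs in sensitive peaks.
#' @param n_background_snps SNP panel size for the heritability table.
#' @param frac_in_sensitive fraction of panel SNPs placed in sensitive peaks
#'   (controls the category's SNP share).
#' @param frac_in_peaks fraction of panel SNPs placed in (non-sensitive) peaks.
#' @param causal_frac_sensitive probability a credible set's causal SNP lies
#'   in a sensitive peak.
#' @param h2_total total heritability mass of the panel.
#' @param seed RNG seed.
#' @return list(`credible_sets`, `snp_h2`) data.tables.
#' @export
simulate_gwas <- function(truth, peaks, n_traits = 3L, n_sets_per_trait = 50L,
                          snps_per_set = 5L, enrichment_factor = 5,
                          n_background_snps = 20000L,
                          frac_in_sensitive = 0.01, frac_in_peaks = 0.3,
                          causal_frac_sensitive = 0.5,
                          h2_total = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (enrichment_factor <= 0) stop("simulate_gwas: enrichment_factor must be > 0")
  if (is.null(peaks) || nrow(peaks) == 0)
    stop("simulate_gwas: zero peaks supplied with nonzero enrichment_factor")
  set.seed(as.integer(seed))
  L <- truth$config$genome_length_bp
  sens_ids <- unique(truth$sensitive_peaks$peak_id)
  sens <- peaks[peaks$name %in% sens_ids, ]
  other <- peaks[!peaks$name %in% sens_ids, ]

  rand_pos_in <- function(iv, n) {
    if (n == 0 || nrow(iv) == 0) return(integer(0))
    i <- sample.int(nrow(iv), n, replace = TRUE)
    as.integer(iv$start[i] + floor(runif(n) * (iv$end[i] - iv$start[i])))
  }
  n <- as.integer(n_background_snps)
  n_s <- if (nrow(sens)) round(frac_in_sensitive * n) else 0L
  n_p <- round(frac_in_peaks * n)
  n_u <- n - n_s - n_p
  pos <- c(rand_pos_in(sens, n_s), rand_pos_in(other, n_p),
           as.integer(floor(runif(n_u) * L)))
  in_sens <- points_in_regions(rep("chrS", n), pos, sens)
  beta <- rnorm(n, 0, sqrt(ifelse(in_sens, enrichment_factor, 1)))
  h2 <- beta^2
  h2 <- h2 / sum(h2) * h2_total
  snp_h2 <- data.table::data.table(
    snp_id = sprintf("snp_%06d", seq_len(n)), chrom = "chrS", pos = pos,
    h2_contribution = h2, in_sensitive = in_sens)

  cs <- list()
  k <- as.integer(snps_per_set)
  for (tr in seq_len(n_traits)) {
    for (s in seq_len(n_sets_per_trait)) {
      causal <- if (nrow(sens) && runif(1) < causal_frac_sensitive)
        rand_pos_in(sens, 1L) else as.integer(floor(runif(1) * L))
      comp <- as.integer(pmin(pmax(causal + round(runif(k - 1L, -25000, 25000)), 0), L - 1))
      pip <- c(0.6, rep(0.4 / max(k - 1L, 1L), k - 1L))[seq_len(k)]
      cs[[length(cs) + 1L]] <- data.table::data.table(
        trait = sprintf("trait_%d", tr), set_id = sprintf("t%d_cs%03d", tr, s),
        snp_id = sprintf("t%d_cs%03d_v%d", tr, s, seq_len(k)),
        chrom = "chrS", pos = c(causal, comp), pip = pip)
    }
  }
  list(credible_sets = data.table::rbindlist(cs), snp_h2 = snp_h2)
}
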