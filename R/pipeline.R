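## End-to-end orchestration: simulate (optional) -> score -> sensitivity ->
## link -> enrich, with one global seed deterministically deriving per-stage
## seeds, TSV outputs per stage, a JSON summary, and a MANIFEST marking
## completeness.

#' Pipeline configuration
#'
#' Either fixture mode (`sim` is a [sim_config()]; all inputs are generated)
#' or path mode (`paths` names existing input files).
#'
#' @param outdir output directory.
#' @param sim optional [sim_config()] for fixture mode.
#' @param paths optional named list of input paths (rna_dir, atac_dir,
#'   guides, genes, peaks, tads).
#' @param k,dims neighbor count and embedding dimensions.
#' @param alpha BH threshold for sensitivity calls.
#' @param pair_window ACR-gene enumeration window (bp).
#' @param tad_window pair window for the TAD analysis (bp).
#' @param resamples resampling draws for nulls.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(outdir, sim = NULL, paths = NULL, k = 20L,
                            dims = 30L, alpha = 0.05, pair_window = 50000L,
                            tad_window = 2e6, resamples = 100L, seed = 1L) {
  if (is.null(sim) && is.null(paths))
    stop("pipeline_config: provide either sim (fixture mode) or paths")
  if (!is.null(sim)) stopifnot(inherits(sim, "SimConfig"))
  if (!is.null(paths)) {
    for (nm in names(paths))
      if (!file.exists(paths[[nm]]))
        stop(sprintf("pipeline_config: input '%s' not found at %s", nm, paths[[nm]]))
  }
  structure(list(outdir = outdir, sim = sim, paths = paths, k = as.integer(k),
                 dims = as.integer(dims), alpha = alpha,
                 pair_window = as.integer(pair_window),
                 tad_window = tad_window, resamples = as.integer(resamples),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic hash of stage name + global seed, kept below 2^31 so stages
#' can be re-run in isolation.
#' @param global_seed integer.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  v <- as.numeric(utf8ToInt(stage))
  h <- sum(v * seq_along(v)) * 2654435
  as.integer((as.numeric(global_seed) * 1000003 + h) %% 2147483647)
}

#' Validate pipeline inputs
#'
#' Cross-checks barcode consistency between RNA, ATAC and the guide table,
#' coordinate sanity of interval inputs, and schema conformance. Report-only:
#' returns pass/fail with itemized issues, never errors.
#'
#' @param rna,atac [feature_matrix()]s.
#' @param guides GuideAssignment.
#' @param peaks,genes optional coordinate tables.
#' @return list: `pass` (logical), `issues` (character vector).
#' @export
validate_inputs <- function(rna, atac, guides, peaks = NULL, genes = NULL) {
  issues <- character(0)
  note <- function(fmt, ...) issues <<- c(issues, sprintf(fmt, ...))
  if (!setequal(rna$barcodes, atac$barcodes))
    note("RNA and ATAC barcodes differ: %d only-RNA, %d only-ATAC",
         length(setdiff(rna$barcodes, atac$barcodes)),
         length(setdiff(atac$barcodes, rna$barcodes)))
  n_unguided <- sum(!rna$barcodes %in% guides$cell)
  if (n_unguided > 0)
    note("%d RNA cells have no guide assignment", n_unguided)
  if (anyDuplicated(guides$cell))
    note("guide table assigns multiple guides to one cell")
  if (!is.null(peaks)) {
    bad <- which(peaks$start >= peaks$end)
    if (length(bad)) note("peaks: start >= end at row %d", bad[1])
    if (!is.null(genes) && !all(genes$chrom %in% unique(peaks$chrom)))
      note("genes reference chromosomes absent from the peak set")
  }
  list(pass = length(issues) == 0, issues = issues)
}

#' Run the full pipeline
#'
#' Executes simulate (fixture mode) -> score -> sensitivity -> link ->
#' enrich, writing each stage's TSV under `config$outdir` plus
#' `summary.json`, a log, and a `MANIFEST` listing outputs (marked
#' incomplete on stage failure). Re-running with the same config reproduces
#' all outputs bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return list with the stage results and the summary (invisibly also
#'   written to disk).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "pipeline.log")
  manifest <- file.path(config$outdir, "MANIFEST")
  written <- character(0)
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", "perturbscope", sprintf(fmt, ...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  emit <- function(dt, fname) {
    path <- file.path(config$outdir, fname)
    write_table_headered(dt, path)
    written <<- c(written, fname)
  }
  finish_manifest <- function(complete) {
    writeLines(c(sprintf("complete: %s", tolower(complete)), written), manifest)
  }
  unlink(logf)
  log_line("seed=%d k=%d dims=%d alpha=%g", config$seed, config$k,
           config$dims, config$alpha)
  stage <- "simulate"
  res <- tryCatch({
    ## ---- simulate / load ----
    if (!is.null(config$sim)) {
      simc <- config$sim
      simc$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_dataset(simc)
    } else {
      p <- config$paths
      sim <- list(rna = read_matrix(p$rna_dir, "RNA"),
                  atac = read_matrix(p$atac_dir, "ATAC"),
                  guides = read_guides(p$guides),
                  genes = read_genes(p$genes),
                  peaks = read_bed(p$peaks, "peaks"),
                  truth = NULL)
      if (!is.null(p$tads)) sim$tads <- read_bed(p$tads, "tads")
    }
    v <- validate_inputs(sim$rna, sim$atac, sim$guides, sim$peaks, sim$genes)
    if (!v$pass) log_line("validation issues: %s", paste(v$issues, collapse = "; "))
    log_line("simulate: %d cells, %d genes, %d peaks",
             nrow(sim$rna$counts), ncol(sim$rna$counts), ncol(sim$atac$counts))

    ## ---- score ----
    stage <- "score"
    set.seed(stage_seed(config$seed, "score"))
    tfs <- unique(sim$guides$target[sim$guides$target_class == "TF"])
    score_one <- function(m) {
      emb <- embed_cells(m, dims = config$dims)
      s <- perturbation_signature(m, emb, sim$guides, k = config$k)
      list(sig = s, pst = perturbation_score(s, sim$guides))
    }
    rna_sc <- score_one(sim$rna)
    atac_sc <- score_one(sim$atac)
    scores <- data.table::rbindlist(list(rna_sc$pst, atac_sc$pst))
    emit(scores, "scores.tsv")
    log_line("score: %d rows", nrow(scores))

    ## ---- sensitivity ----
    stage <- "sensitivity"
    st <- data.table::rbindlist(lapply(tfs, function(tf) {
      data.table::rbindlist(list(
        fit_sensitivity(sim$rna, rna_sc$sig, rna_sc$pst, sim$guides, tf,
                        alpha = config$alpha),
        fit_sensitivity(sim$atac, atac_sc$sig, atac_sc$pst, sim$guides, tf,
                        alpha = config$alpha)))
    }))
    emit(st, "sensitivity.tsv")
    summ <- summarize_sensitive(st)
    log_line("sensitivity: %s", paste(sprintf("%s %.1f%%", summ$modality,
                                              summ$percent), collapse = ", "))

    ## ---- link ----
    stage <- "link"
    pairs <- enumerate_pairs(sim$peaks, sim$genes, config$pair_window)
    pairs <- pair_correlation(sim$rna, sim$atac, sim$guides, pairs)
    emit(pairs, "pairs.tsv")
    sens_acr <- unique(st[st$modality == "ATAC" & st$sensitive, ]$feature)
    sens_gene <- unique(st[st$modality == "RNA" & st$sensitive, ]$feature)
    pair_sens <- pairs$acr %in% sens_acr & pairs$gene_id %in% sens_gene
    link_summary <- list(n_pairs = nrow(pairs), n_pair_sensitive = sum(pair_sens))
    if (!is.null(sim$truth) && nrow(sim$truth$linked_pairs) > 0) {
      or <- crispri_overlap_or(pairs, pair_sens,
                               sim$truth$linked_pairs[, c("acr", "gene_id")])
      link_summary$validated_or <- or$or
      link_summary$validated_p <- or$p
      tads <- sim$truth$tads
      wide <- enumerate_pairs(sim$peaks, sim$genes, config$tad_window)
      wide_sens <- wide$acr %in% sens_acr & wide$gene_id %in% sens_gene
      acr_mean <- Matrix::colSums(normalize_matrix(sim$atac)) / nrow(sim$atac$counts)
      gene_mean <- Matrix::colSums(normalize_matrix(sim$rna)) / nrow(sim$rna$counts)
      tad_odds <- tad_cooccupancy_odds(
        wide, wide_sens, tads, sim$peaks, sim$genes, acr_mean, gene_mean,
        n_resamples = config$resamples,
        seed = stage_seed(config$seed, "link"))
      emit(tad_odds, "tad_odds.tsv")
    }
    log_line("link: %d pairs, %d sensitive", nrow(pairs), sum(pair_sens))

    ## ---- enrich ----
    stage <- "enrich"
    enrich_summary <- NULL
    if (!is.null(sim$truth)) {
      gw <- simulate_gwas(sim$truth, sim$peaks,
                          seed = stage_seed(config$seed, "enrich"))
      sens_regions <- sim$peaks[sim$peaks$name %in% sens_acr, ]
      if (nrow(sens_regions) > 0) {
        ov <- credible_set_overlap(gw$credible_sets, sens_regions)
        nonsens_pool <- sim$peaks[!sim$peaks$name %in% sens_acr, ]
        nul <- sampled_overlap_null(
          gw$credible_sets, nonsens_pool, n_regions = nrow(sens_regions),
          n_samples = config$resamples, matching = "length",
          target_lengths = sens_regions$end - sens_regions$start,
          seed = stage_seed(config$seed, "enrich_null"))
        mask <- gw$snp_h2$in_sensitive
        he <- if (any(mask)) heritability_enrichment(gw$snp_h2, mask) else NULL
        emit(ov, "credible_overlap.tsv")
        emit(gw$snp_h2, "snp_h2.tsv")
        enrich_summary <- list(
          overlap_percent = attr(ov, "overall"),
          null_mean = nul$null_mean, null_sd = nul$null_sd,
          h2_enrichment = if (!is.null(he)) he$enrichment else NA,
          pct_snps = if (!is.null(he)) he$pct_snps else NA)
        log_line("enrich: overlap %.1f%% (null %.1f +/- %.1f)",
                 enrich_summary$overlap_percent, nul$null_mean, nul$null_sd)
      }
    }

    summary <- list(
      seed = config$seed,
      n_cells = nrow(sim$rna$counts),
      sensitive = as.list(setNames(summ$percent, summ$modality)),
      link = link_summary, enrich = enrich_summary)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    written <- c(written, "summary.json")
    finish_manifest(TRUE)
    list(sim = sim, scores = scores, sensitivity = st, summary = summary,
         pairs = pairs)
  }, error = function(e) {
    finish_manifest(FALSE)
    stop(sprintf("run_all: stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
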