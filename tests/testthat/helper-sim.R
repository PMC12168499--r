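## Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_cfg <- function(...) {
  defaults <- list(n_cells = 600L, n_genes = 300L, n_peaks = 500L, n_tfs = 4L,
                   editing_efficiency_range = c(0.85, 0.95), seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() cached("small_sim", simulate_dataset(small_cfg()))

## embedding + signature + scores + normalized matrix for one modality
score_modality <- function(sim, modality, key = NULL) {
  build <- function() {
    m <- if (modality == "RNA") sim$rna else sim$atac
    emb <- embed_cells(m, dims = 30)
    s <- perturbation_signature(m, emb, sim$guides, k = 20)
    list(m = m, emb = emb, sig = s, pst = perturbation_score(s, sim$guides),
         N = normalize_matrix(m))
  }
  if (is.null(key)) build() else cached(key, build())
}

small_scored_rna <- function() score_modality(small_sim(), "RNA", "small_rna")
small_scored_atac <- function() score_modality(small_sim(), "ATAC", "small_atac")

## fit all TFs of a sim for one modality
fit_all_tfs <- function(sim, sc, alpha = 0.05) {
  tfs <- unique(sim$guides$target[sim$guides$target_class == "TF"])
  data.table::rbindlist(lapply(tfs, function(tfn)
    fit_sensitivity(sc$m, sc$sig, sc$pst, sim$guides, tfn, alpha = alpha,
                    normalized = sc$N)))
}

## a tiny FeatureMatrix from a dense integer matrix
fm <- function(mat, modality = "RNA", prefix = "c") {
  feature_matrix(Matrix::Matrix(mat, sparse = TRUE), modality,
                 sprintf("%s%03d", prefix, seq_len(nrow(mat))),
                 sprintf("f%03d", seq_len(ncol(mat))))
}
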