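## Readers/writers for the on-disk formats: MatrixMarket triplets with
## barcode/feature sidecars, BED, and headered TSV tables. All TSV outputs
## carry a single header line prefixed "#"; readers strip it. Validation
## errors name the offending file, line or field.

#' Write a FeatureMatrix as MatrixMarket triplet + sidecar TSVs
#'
#' Creates `matrix.mtx` (1-based coordinate format), `barcodes.tsv` and
#' `features.tsv` under `dir`.
#'
#' @param m A [feature_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(m, dir) {
  stopifnot(inherits(m, "FeatureMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(m$features, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a FeatureMatrix written by [write_matrix()]
#'
#' @param dir directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' @param modality `"RNA"` or `"ATAC"`.
#' @return A [feature_matrix()]. Round-trips [write_matrix()] output exactly.
#' @export
read_matrix <- function(dir, modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop(sprintf("read_matrix: %s not found", mtx))
  counts <- Matrix::readMM(mtx)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  if (length(barcodes) != nrow(counts))
    stop(sprintf("read_matrix: barcodes.tsv has %d rows but matrix has %d rows",
                 length(barcodes), nrow(counts)))
  if (length(features) != ncol(counts))
    stop(sprintf("read_matrix: features.tsv has %d rows but matrix has %d columns",
                 length(features), ncol(counts)))
  feature_matrix(counts, modality, barcodes, features)
}

#' Read a BED file into an IntervalSet
#'
#' BED3+ with tab-separated fields, 0-based half-open coordinates. Extra
#' columns beyond chrom/start/end/name are preserved. Malformed lines are
#' rejected with their line number.
#'
#' @param path BED file path.
#' @param kind label for ids/error messages.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, kind = "intervals") {
  if (!file.exists(path)) stop(sprintf("read_bed: %s not found", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop(sprintf("read_bed: %s is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("read_bed: line %d of %s has %d field(s); BED needs >= 3",
                 which(nf < 3)[1], path, min(nf)))
  chrom <- vapply(parts, `[[`, "", 1L)
  s_chr <- vapply(parts, `[[`, "", 2L)
  e_chr <- vapply(parts, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("read_bed: non-numeric coordinate at line %d of %s", bad[1], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("read_bed: start >= end at line %d of %s", bad[1], path))
  df <- data.table::data.table(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) df$name <- vapply(parts, `[[`, "", 4L)
  if (all(nf >= 6)) {
    df$score <- vapply(parts, `[[`, "", 5L)
    df$strand <- vapply(parts, `[[`, "", 6L)
  }
  interval_set(df, kind = kind)
}

#' Write an IntervalSet as BED
#' @param iv An [interval_set()].
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(iv))
  data.table::fwrite(iv[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a headered TSV with schema validation
#'
#' Expects one header line (optionally prefixed `#`) then tab-separated rows.
#' `schema` maps required column names to types (`"character"`, `"integer"`,
#' `"numeric"`, `"logical"`); missing columns or uncoercible values are
#' rejected naming the column.
#'
#' @param path TSV path.
#' @param schema named character vector, e.g. `c(cell = "character")`.
#' @return `data.table` with at least the schema columns, coerced.
#' @export
read_table_checked <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("read_table_checked: %s not found", path))
  header <- readLines(path, n = 1L)
  header <- sub("^#", "", header)
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = strsplit(header, "\t", fixed = TRUE)[[1]])
  for (col in names(schema)) {
    if (!col %in% names(dt))
      stop(sprintf("%s: missing required column '%s'", path, col))
    cast <- switch(schema[[col]],
                   character = as.character, integer = as.integer,
                   numeric = as.numeric, logical = as.logical,
                   stop(sprintf("unknown schema type '%s'", schema[[col]])))
    val <- suppressWarnings(cast(dt[[col]]))
    if (anyNA(val) && !anyNA(dt[[col]]))
      stop(sprintf("%s: column '%s' not coercible to %s", path, col, schema[[col]]))
    data.table::set(dt, j = col, value = val)
  }
  dt
}

#' Write a table as headered TSV (header line prefixed with `#`)
#' @param dt data.frame.
#' @param path output path.
#' @export
write_table_headered <- function(dt, path) {
  writeLines(paste0("#", paste(names(dt), collapse = "\t")), path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Read a guide-to-cell assignment table
#'
#' Columns: cell, guide_id, target, target_class (`TF`, `NT` or `SAFE`).
#' At most one guide per cell; TF rows must carry a target symbol.
#'
#' @param path TSV path (headered as written by [write_table_headered()]).
#' @return `data.table` of class `GuideAssignment`.
#' @export
read_guides <- function(path) {
  dt <- read_table_checked(path, c(cell = "character", guide_id = "character",
                                   target = "character", target_class = "character"))
  validate_guides(dt)
}

validate_guides <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (anyDuplicated(dt$cell))
    stop("guides: more than one guide assigned to the same cell")
  if (!all(dt$target_class %in% c("TF", "NT", "SAFE")))
    stop("guides: target_class must be one of TF, NT, SAFE")
  bad <- dt$target_class == "TF" & (is.na(dt$target) | dt$target == "")
  if (any(bad)) stop("guides: TF rows must have a non-empty target symbol")
  data.table::setattr(dt, "class", c("GuideAssignment", class(dt)))
  dt[]
}

#' Read gene annotations (gene_id, chrom, tss, strand)
#' @param path TSV path.
#' @return `data.table` sorted by (chrom, tss).
#' @export
read_genes <- function(path) {
  dt <- read_table_checked(path, c(gene_id = "character", chrom = "character",
                                   tss = "integer", strand = "character"))
  if (!all(dt$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be '+' or '-'", path))
  if (anyDuplicated(dt$gene_id)) stop(sprintf("%s: duplicate gene ids", path))
  data.table::setorder(dt, chrom, tss)
  dt[]
}

## Drop cells absent from the guide table (undetected sgRNA), with a count.
align_to_guides <- function(m, guides) {
  keep <- m$barcodes %in% guides$cell
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("align_to_guides: dropping %d/%d cells without a guide assignment",
                    n_drop, length(keep)))
  feature_matrix(m$counts[keep, , drop = FALSE], m$modality,
                 m$barcodes[keep], m$features)
}
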