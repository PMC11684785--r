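#' Write a counts matrix as a 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx` (features x barcodes, as 10x does), `barcodes.tsv`
#' and `features.tsv` into `dir_path`, plus `cell_metadata.tsv` when cell
#' metadata is supplied and a `manifest.json` carrying the seed and a
#' config hash for provenance.
#'
#' @param counts Sparse cells x genes integer matrix with dimnames.
#' @param cell_meta Optional per-cell metadata tibble (must contain
#'   `barcode`).
#' @param dir_path Output directory (created if needed).
#' @param seed,config_hash Optional provenance fields for the manifest.
#' @return `dir_path`, invisibly.
#' @export
write_tenx <- function(counts, cell_meta = NULL, dir_path,
                       seed = NULL, config_hash = NULL) {
  assert_that(all(counts@x >= 0) && all(counts@x == round(counts@x)),
              "counts must be non-negative integers")
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(counts), file.path(dir_path, "matrix.mtx"))
  writeLines(as.character(rownames(counts)),
             file.path(dir_path, "barcodes.tsv"))
  features <- data.frame(id = colnames(counts), name = colnames(counts),
                         type = "Gene Expression")
  readr::write_tsv(features, file.path(dir_path, "features.tsv"),
                   col_names = FALSE)
  if (!is.null(cell_meta)) {
    readr::write_tsv(cell_meta, file.path(dir_path, "cell_metadata.tsv"))
  }
  manifest <- list(
    format = "tenx_triplet",
    n_cells = nrow(counts), n_genes = ncol(counts),
    seed = seed, config_hash = config_hash,
    written_by = paste0("clonepick ", as.character(utils::packageVersion("clonepick")))
  )
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir_path)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Inverse of [write_tenx()]: reproduces the matrix, barcode order and
#' feature order exactly.
#'
#' @param dir_path Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` (and optionally `cell_metadata.tsv`).
#' @return List with `counts` (sparse cells x genes) and `cell_meta`
#'   (tibble or `NULL`).
#' @export
read_tenx <- function(dir_path) {
  mtx <- file.path(dir_path, "matrix.mtx")
  assert_that(file.exists(mtx), paste("no matrix.mtx in", dir_path))
  header <- readLines(mtx, n = 1)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", header)) {
    abort(sprintf("malformed MatrixMarket header at line 1 of %s: '%s'",
                  mtx, header))
  }
  m <- Matrix::t(Matrix::readMM(mtx))
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  barcodes <- readLines(file.path(dir_path, "barcodes.tsv"))
  features <- readr::read_tsv(file.path(dir_path, "features.tsv"),
                              col_names = c("id", "name", "type"),
                              col_types = "ccc", progress = FALSE)
  assert_that(nrow(m) == length(barcodes),
              "barcode count does not match matrix rows")
  assert_that(ncol(m) == nrow(features),
              "feature count does not match matrix columns")
  dimnames(m) <- list(barcodes, features$id)
  meta_path <- file.path(dir_path, "cell_metadata.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  list(counts = m, cell_meta = cell_meta)
}

#' Write contig records in a standard V(D)J dialect
#'
#' `tenx_csv` mirrors Cell Ranger's `filtered_contig_annotations.csv`
#' (booleans as "True"/"False", `raw_clonotype_id` left empty);
#' `airr_tsv` uses AIRR Rearrangement field names (booleans as "T"/"F"),
#' with `is_cell`/`high_confidence` carried as extension fields so that
#' either dialect round-trips through [read_contigs()] to identical
#' records.
#'
#' @param contigs Contig tibble as produced by [generate_dataset()].
#' @param path Output file path.
#' @param dialect "tenx_csv" or "airr_tsv".
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, dialect = c("tenx_csv", "airr_tsv")) {
  if (length(dialect) == 1 && !dialect %in% c("tenx_csv", "airr_tsv")) {
    abort(sprintf("unknown contig dialect '%s'", dialect))
  }
  dialect <- match.arg(dialect)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = contigs$barcode,
      is_cell = ifelse(contigs$is_cell, "True", "False"),
      contig_id = contigs$contig_id,
      high_confidence = ifelse(contigs$high_confidence, "True", "False"),
      chain = contigs$chain,
      v_gene = contigs$v_gene,
      j_gene = contigs$j_gene,
      c_gene = contigs$c_gene,
      full_length = contigs$full_nt,
      productive = ifelse(contigs$productive, "True", "False"),
      cdr3 = contigs$cdr3_aa,
      cdr3_nt = contigs$cdr3_nt,
      reads = contigs$reads,
      umis = contigs$umis,
      raw_clonotype_id = rep("", nrow(contigs))
    )
    readr::write_csv(out, path, progress = FALSE)
  } else {
    out <- data.frame(
      cell_id = contigs$barcode,
      sequence_id = contigs$contig_id,
      locus = contigs$chain,
      v_call = contigs$v_gene,
      j_call = contigs$j_gene,
      c_call = contigs$c_gene,
      junction = contigs$cdr3_nt,
      junction_aa = contigs$cdr3_aa,
      sequence = contigs$full_nt,
      productive = ifelse(contigs$productive, "T", "F"),
      consensus_count = contigs$umis,
      duplicate_count = contigs$reads,
      is_cell = ifelse(contigs$is_cell, "T", "F"),
      high_confidence = ifelse(contigs$high_confidence, "T", "F")
    )
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}
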