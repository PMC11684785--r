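#' Per-cell quality-control metrics
#'
#' Computes the three QC metrics used for outlier detection: library size
#' (total counts), number of expressed genes, and mitochondrial fraction.
#' Mitochondrial genes are matched by exact feature-name membership. Cells
#' with zero library size get a mitochondrial fraction of 0 (and are
#' always flagged by [flag_outliers()]).
#'
#' @param counts Sparse cells x genes count matrix with dimnames.
#' @param mito_gene_names Mitochondrial feature names.
#' @return Tibble with `barcode`, `library_size`, `n_genes`,
#'   `mito_fraction`.
#' @export
compute_qc <- function(counts, mito_gene_names = default_mito_genes()) {
  assert_that(all(counts@x >= 0), "counts must be non-negative")
  lib <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito_present <- intersect(mito_gene_names, colnames(counts))
  if (length(mito_present) == 0) {
    warn("no mitochondrial gene found in the feature set; mito_fraction set to 0")
    mito <- rep(0, nrow(counts))
  } else {
    mito <- Matrix::rowSums(counts[, mito_present, drop = FALSE])
  }
  frac <- ifelse(lib > 0, mito / lib, 0)
  tibble(barcode = rownames(counts), library_size = as.numeric(lib),
         n_genes = as.integer(n_genes), mito_fraction = unname(frac))
}

mad_bound <- function(x, n_mads, side, scale_mad) {
  med <- median(x)
  mad <- median(abs(x - med))
  if (scale_mad) mad <- mad * 1.4826
  bound <- if (side == "lower") med - n_mads * mad else med + n_mads * mad
  list(median = med, mad = mad, bound = bound)
}

flag_one_metric <- function(x, n_mads, side, scale_mad) {
  b <- mad_bound(x, n_mads, side, scale_mad)
  if (b$mad == 0) {
    # degenerate spread: any deviation on the tested side counts
    if (side == "lower") x < b$median else x > b$median
  } else {
    if (side == "lower") x < b$bound else x > b$bound
  }
}

#' Flag QC outlier cells by the median-absolute-deviation rule
#'
#' A cell is an outlier when it lies more than `n_mads` median absolute
#' deviations from the median of any of the three metrics, on the tested
#' side: library size and number of expressed genes are tested on the
#' log10(x+1) scale, lower side only; mitochondrial fraction on the
#' natural scale, upper side only. The MAD is the unscaled median of
#' absolute deviations from the median (set `scale_mad = TRUE` for the
#' 1.4826 consistency constant). When a metric's MAD is zero, any cell
#' deviating from the median on the tested side is flagged for it.
#' Zero-library cells are always flagged.
#'
#' @param metrics QC tibble from [compute_qc()].
#' @param n_mads Number of MADs defining the threshold (default 5).
#' @param scale_mad Apply the 1.4826 normal-consistency constant.
#' @param two_sided Also test the untested side of each metric.
#' @return `metrics` plus logical columns `outlier_library_size`,
#'   `outlier_n_genes`, `outlier_mito`, `outlier`, and a `reason` string.
#'   Thresholds used are attached as the `thresholds` attribute.
#' @export
flag_outliers <- function(metrics, n_mads = 5, scale_mad = FALSE,
                          two_sided = FALSE) {
  if (n_mads <= 0) abort("n_mads must be > 0")
  assert_that(nrow(metrics) >= 2, "need at least 2 cells")
  log_lib <- log10(metrics$library_size + 1)
  log_genes <- log10(metrics$n_genes + 1)
  f_lib <- flag_one_metric(log_lib, n_mads, "lower", scale_mad)
  f_genes <- flag_one_metric(log_genes, n_mads, "lower", scale_mad)
  f_mito <- flag_one_metric(metrics$mito_fraction, n_mads, "upper", scale_mad)
  if (two_sided) {
    f_lib <- f_lib | flag_one_metric(log_lib, n_mads, "upper", scale_mad)
    f_genes <- f_genes | flag_one_metric(log_genes, n_mads, "upper", scale_mad)
    f_mito <- f_mito | flag_one_metric(metrics$mito_fraction, n_mads, "lower",
                                       scale_mad)
  }
  zero_lib <- metrics$library_size == 0
  f_lib <- f_lib | zero_lib
  out <- metrics |>
    mutate(outlier_library_size = f_lib,
           outlier_n_genes = f_genes,
           outlier_mito = f_mito,
           outlier = f_lib | f_genes | f_mito)
  reasons <- cbind(
    ifelse(out$outlier_library_size, "low_library_size", NA),
    ifelse(out$outlier_n_genes, "low_n_genes", NA),
    ifelse(out$outlier_mito, "high_mito_fraction", NA)
  )
  out$reason <- apply(reasons, 1, function(r) {
    paste(r[!is.na(r)], collapse = ";")
  })
  attr(out, "thresholds") <- list(
    n_mads = n_mads, scale_mad = scale_mad, two_sided = two_sided,
    log10_library_size = mad_bound(log_lib, n_mads, "lower", scale_mad),
    log10_n_genes = mad_bound(log_genes, n_mads, "lower", scale_mad),
    mito_fraction = mad_bound(metrics$mito_fraction, n_mads, "upper",
                              scale_mad)
  )
  out
}

#' Remove multiplexing doublets
#'
#' Default rule: drop cells carrying more than one sample hashing tag
#' (tags separated by ";" in `hash_tag`). Optionally also drop cells
#' flagged as multi-chain on both TCR loci (possible cell doublets).
#'
#' @param cell_meta Per-cell metadata tibble; `hash_tag` column optional.
#' @param drop_multi_chain Also drop cells with `multi_tra & multi_trb`.
#' @return Retained rows of `cell_meta`; the `doublet_log` attribute
#'   records the rule applied and the number of cells dropped.
#' @export
remove_doublets <- function(cell_meta, drop_multi_chain = FALSE) {
  drop <- rep(FALSE, nrow(cell_meta))
  if ("hash_tag" %in% names(cell_meta)) {
    drop <- drop | grepl(";", cell_meta$hash_tag)
  }
  n_hash <- sum(drop)
  n_chain <- 0L
  if (drop_multi_chain &&
      all(c("multi_tra", "multi_trb") %in% names(cell_meta))) {
    chain_dbl <- cell_meta$multi_tra & cell_meta$multi_trb
    n_chain <- sum(chain_dbl & !drop)
    drop <- drop | chain_dbl
  }
  out <- cell_meta[!drop, , drop = FALSE]
  attr(out, "doublet_log") <- list(
    rule = if (drop_multi_chain) "hash_tag + multi_chain" else "hash_tag",
    n_hash_doublets = n_hash, n_chain_doublets = n_chain,
    n_dropped = sum(drop)
  )
  out
}

#' Library-size normalisation with log transform
#'
#' Per cell: `ln(1 + count * target_sum / library_size)`. Zero-library
#' cells must be removed upstream.
#'
#' @param counts Sparse cells x genes count matrix (QC-passing cells).
#' @param target_sum Counts each cell is scaled to (default 10,000).
#' @return Sparse cells x genes matrix of normalised values.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  lib <- Matrix::rowSums(counts)
  if (any(lib == 0)) {
    abort("internal error: zero library size cell reached normalize_log")
  }
  scaled <- Matrix::Diagonal(x = target_sum / lib) %*% counts
  out <- log1p(scaled)
  dimnames(out) <- dimnames(counts)
  as(as(out, "CsparseMatrix"), "generalMatrix")
}
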