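#' Construct an annotated single-cell experiment container
#'
#' A light container holding the sparse counts matrix alongside per-cell
#' metadata and, as the pipeline proceeds, normalised values, PC scores,
#' a 2-D embedding, cluster labels and clonotype assignments.
#'
#' @param counts Sparse cells x genes count matrix with dimnames.
#' @param cell_meta Per-cell metadata tibble with a `barcode` column
#'   covering every row of `counts`.
#' @return A `tcx` object.
#' @export
tcx_experiment <- function(counts, cell_meta) {
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry barcode and gene dimnames")
  assert_that("barcode" %in% names(cell_meta),
              "cell_meta must have a barcode column")
  assert_that(all(rownames(counts) %in% cell_meta$barcode),
              "cell_meta must cover every barcode in counts")
  cells <- as_tibble(cell_meta)[match(rownames(counts), cell_meta$barcode), ]
  structure(
    list(counts = counts, cells = cells, normalized = NULL, pca = NULL,
         embedding = NULL, clonotypes = NULL, log = list()),
    class = "tcx"
  )
}

#' @export
print.tcx <- function(x, ...) {
  cat(sprintf("<tcx> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  extras <- c(
    if (!is.null(x$normalized)) "normalized",
    if (!is.null(x$pca)) sprintf("pca(%d)", ncol(x$pca)),
    if (!is.null(x$embedding)) "embedding",
    if (!is.null(x$clonotypes)) sprintf("clonotypes(%d)", nrow(x$clonotypes))
  )
  if (length(extras)) cat("  layers:", paste(extras, collapse = ", "), "\n")
  if ("cluster" %in% names(x$cells)) {
    cat("  clusters:", length(unique(x$cells$cluster)), "\n")
  }
  invisible(x)
}

# subset a tcx to a barcode set, keeping layers aligned
tcx_subset <- function(x, barcodes) {
  keep <- rownames(x$counts) %in% barcodes
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$cells <- x$cells[keep, , drop = FALSE]
  if (!is.null(x$normalized)) out$normalized <- x$normalized[keep, , drop = FALSE]
  if (!is.null(x$pca)) out$pca <- x$pca[rownames(x$pca) %in% barcodes, , drop = FALSE]
  if (!is.null(x$embedding)) {
    out$embedding <- x$embedding[rownames(x$embedding) %in% barcodes, , drop = FALSE]
  }
  out
}

#' Attach clonotype calls to an expression container
#'
#' Reconciles barcode namespaces between the expression and V(D)J sides
#' (both are normalised by stripping a configurable trailing suffix,
#' "-<digits>" by default), labels cells found in both, marks
#' expression-only cells "unassigned", and drops V(D)J-only barcodes. A
#' reconciliation report (counts of each class) is stored in the object's
#' log and emitted as a message.
#'
#' @param x A [tcx_experiment()].
#' @param clonotypes Clonotype table from [call_clonotypes()].
#' @param suffix_pattern Regex stripped from barcodes before matching.
#' @return `x` with a `clonotype_id` cell column and the clonotype table
#'   attached.
#' @export
attach_clonotypes <- function(x, clonotypes, suffix_pattern = "-[0-9]+$") {
  cell_map <- attr(clonotypes, "cell_map")
  assert_that(!is.null(cell_map), "clonotypes must come from call_clonotypes()")
  strip <- function(b) sub(suffix_pattern, "", b)
  expr_norm <- strip(x$cells$barcode)
  vdj_norm <- strip(cell_map$barcode)
  idx <- match(expr_norm, vdj_norm)
  n_both <- sum(!is.na(idx))
  if (n_both == 0 && nrow(cell_map) > 0) {
    abort("no overlapping barcodes between expression and V(D)J data; check the barcode suffix rule")
  }
  x$cells$clonotype_id <- ifelse(is.na(idx), "unassigned",
                                 cell_map$clonotype_id[idx])
  report <- list(
    n_expression = nrow(x$cells),
    n_vdj = nrow(cell_map),
    n_both = n_both,
    n_expression_only = nrow(x$cells) - n_both,
    n_vdj_only = sum(!(vdj_norm %in% expr_norm))
  )
  inform(sprintf(
    "barcode reconciliation: %d expression cells, %d with clonotype, %d unassigned, %d V(D)J-only dropped",
    report$n_expression, report$n_both, report$n_expression_only,
    report$n_vdj_only))
  x$clonotypes <- clonotypes
  x$log$reconciliation <- report
  x
}

# run HVG -> PCA -> cluster -> embed on a tcx with normalized values
cluster_expression <- function(x, n_hvgs = 2000, n_pcs = 30,
                               k_neighbors = 15,
                               resolutions = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                               seed = 1, compute_embedding = TRUE) {
  assert_that(!is.null(x$normalized), "normalize the experiment first")
  hvgs <- select_hvgs(x$normalized, n_hvgs)
  n_pcs <- min(n_pcs, min(nrow(x$normalized), length(hvgs)) - 1)
  x$pca <- embed_pca(x$normalized[, hvgs, drop = FALSE], n_pcs)
  scan <- resolution_scan(x$pca, resolutions = resolutions,
                          k_neighbors = k_neighbors, seed = seed)
  x$cells$cluster <- scan$clusters$cluster[
    match(x$cells$barcode, scan$clusters$barcode)]
  if (compute_embedding) {
    x$embedding <- embed_2d(x$pca, seed = seed, n_neighbors = k_neighbors)
    x$cells$dim1 <- x$embedding[match(x$cells$barcode, rownames(x$embedding)), 1]
    x$cells$dim2 <- x$embedding[match(x$cells$barcode, rownames(x$embedding)), 2]
  }
  x$log$clustering <- list(hvgs = hvgs, n_pcs = n_pcs,
                           k_neighbors = k_neighbors, seed = seed,
                           resolution = scan$resolution,
                           silhouette = scan$silhouette, scan = scan$scan)
  x
}

#' Subset cells and recluster
#'
#' Filters cells by a predicate over the cell metadata, then re-runs the
#' expression pipeline (HVG selection, PCA, clustering, embedding) on the
#' subset. The pre-subset cluster labels are preserved under
#' `cluster_full` (and `dim1_full`/`dim2_full`).
#'
#' @param x A clustered [tcx_experiment()].
#' @param predicate Unquoted logical expression over cell metadata
#'   columns, e.g. `tetramer == "tet_pos"`.
#' @param min_cells Refuse to recluster below this many cells.
#' @param ... Passed on to the internal clustering step (`n_hvgs`,
#'   `n_pcs`, `k_neighbors`, `resolutions`, `seed`).
#' @return A new `tcx` restricted to the subset, with fresh clusters.
#' @export
subset_recluster <- function(x, predicate, min_cells = 50, ...) {
  keep <- rlang::eval_tidy(rlang::enquo(predicate), data = x$cells)
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < min_cells) {
    abort(sprintf("subset retains %d cells, below the floor of %d",
                  sum(keep), min_cells))
  }
  sub <- tcx_subset(x, x$cells$barcode[keep])
  if ("cluster" %in% names(sub$cells)) {
    sub$cells$cluster_full <- sub$cells$cluster
  }
  if ("dim1" %in% names(sub$cells)) {
    sub$cells$dim1_full <- sub$cells$dim1
    sub$cells$dim2_full <- sub$cells$dim2
  }
  cluster_expression(sub, ...)
}

assigned_cells <- function(x) {
  assert_that("clonotype_id" %in% names(x$cells),
              "attach clonotypes before computing clonotype statistics")
  x$cells[x$cells$clonotype_id != "unassigned", , drop = FALSE]
}

#' Clonal expansion table
#'
#' Per clonotype: size among the container's cells, frequency over all
#' clonotype-assigned cells, and counts per cluster or per sample.
#' Conservation invariants (frequencies sum to 1; per-group counts sum to
#' clonotype sizes row-wise and to group sizes column-wise) are asserted
#' on every run.
#'
#' @param x A `tcx` with clonotypes attached.
#' @param by Grouping for the count columns: "cluster" or "sample".
#' @return Tibble ordered by decreasing size with columns `clonotype_id`,
#'   `size`, `frequency` and one `n_<group>` column per group level.
#' @export
expansion_table <- function(x, by = c("cluster", "sample")) {
  by <- match.arg(by)
  cells <- assigned_cells(x)
  assert_that(nrow(cells) > 0, "no clonotype-assigned cells")
  assert_that(by %in% names(cells), sprintf("no '%s' column in cell metadata", by))
  counts <- cells |>
    mutate(group = paste0("n_", .data[[by]])) |>
    dplyr::count(.data$clonotype_id, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  group_cols <- sort(setdiff(names(counts), "clonotype_id"))
  out <- counts |>
    mutate(size = rowSums(across(all_of(group_cols)))) |>
    mutate(frequency = .data$size / sum(.data$size)) |>
    arrange(desc(.data$size), .data$clonotype_id) |>
    select("clonotype_id", "size", "frequency", all_of(group_cols))
  # conservation invariants, asserted on every run
  stopifnot(
    abs(sum(out$frequency) - 1) < 1e-8,
    all(rowSums(out[, group_cols, drop = FALSE]) == out$size),
    all(colSums(out[, group_cols, drop = FALSE]) ==
          table(factor(paste0("n_", cells[[by]]), levels = group_cols)))
  )
  attr(out, "by") <- by
  attr(out, "group_cols") <- group_cols
  out
}

#' Clonal diversity statistics
#'
#' Shannon entropy, Gini coefficient and D50 over clonotype frequencies.
#' Shannon is `-sum(f log f)` (natural log); Gini is the mean absolute
#' frequency difference normalised by twice the mean frequency; D50 is
#' the fraction of clonotypes needed to cover 50% of assigned cells.
#'
#' @param expansion Expansion table from [expansion_table()].
#' @param metric One of "shannon", "gini", "d50".
#' @return A single number.
#' @export
diversity <- function(expansion, metric = c("shannon", "gini", "d50")) {
  metric <- match.arg(metric)
  f <- expansion$frequency
  assert_that(length(f) >= 1, "need at least one clonotype")
  switch(metric,
    shannon = {
      f <- f[f > 0]
      -sum(f * log(f))
    },
    gini = {
      n <- length(f)
      sum(abs(outer(f, f, "-"))) / (2 * n^2 * mean(f))
    },
    d50 = {
      sorted <- sort(f, decreasing = TRUE)
      m <- which(cumsum(sorted) >= 0.5)[1]
      m / length(f)
    }
  )
}

#' Marker expression profile per clonotype
#'
#' For each clonotype with at least `min_cells` member cells: the mean
#' normalised expression of each requested gene over member cells, and
#' the detection fraction (share of member cells with a nonzero count).
#'
#' @param x A `tcx` with clonotypes attached and normalised values.
#' @param genes Genes to profile; missing genes are dropped with a
#'   warning.
#' @param min_cells Minimum clonotype size to profile.
#' @return Long tibble: `clonotype_id`, `n_cells`, `gene`, `mean_norm`,
#'   `det_fraction`.
#' @export
marker_profile <- function(x, genes, min_cells = 3) {
  assert_that(!is.null(x$normalized), "normalize the experiment first")
  missing <- setdiff(genes, colnames(x$counts))
  if (length(missing) > 0) {
    warn(paste("genes absent from the feature set, omitted:",
               paste(missing, collapse = ", ")))
    genes <- setdiff(genes, missing)
  }
  assert_that(length(genes) > 0, "no requested gene present in the feature set")
  cells <- assigned_cells(x)
  sizes <- table(cells$clonotype_id)
  keep_ids <- names(sizes)[sizes >= min_cells]
  if (length(keep_ids) == 0) {
    warn(sprintf("no clonotype has at least %d cells; empty profile", min_cells))
    return(tibble(clonotype_id = character(0), n_cells = integer(0),
                  gene = character(0), mean_norm = numeric(0),
                  det_fraction = numeric(0)))
  }
  out <- lapply(keep_ids, function(id) {
    bcs <- cells$barcode[cells$clonotype_id == id]
    norm <- x$normalized[bcs, genes, drop = FALSE]
    raw <- x$counts[bcs, genes, drop = FALSE]
    tibble(clonotype_id = id, n_cells = length(bcs), gene = genes,
           mean_norm = as.numeric(Matrix::colMeans(norm)),
           det_fraction = as.numeric(Matrix::colMeans(raw > 0)))
  })
  bind_rows(out) |> arrange(.data$clonotype_id, .data$gene)
}

#' Differential expression of one clonotype against the rest
#'
#' Per-gene Wilcoxon rank-sum test on normalised values, clonotype member
#' cells versus all other clonotype-assigned cells in the container (or
#' versus another clonotype with `versus`). Genes detected in fewer than
#' `min_detect` of cells in both groups are skipped. Effect size is
#' `log2((mean_in + eps) / (mean_out + eps))`; q-values are
#' Benjamini-Hochberg over the tested genes.
#'
#' @param x A `tcx` with clonotypes attached and normalised values.
#' @param clonotype_id Clonotype whose cells form the "in" group.
#' @param min_cells Minimum size of the "in" group.
#' @param versus Optional clonotype_id to compare against instead of all
#'   other assigned cells.
#' @param min_detect Detection floor below which genes are skipped.
#' @param eps Pseudocount protecting the fold-change ratio.
#' @return Tibble (`gene`, `effect`, `p`, `q`, `det_in`, `det_out`)
#'   ordered by p-value.
#' @export
clonotype_de <- function(x, clonotype_id, min_cells = 10, versus = NULL,
                         min_detect = 0.01, eps = 1e-9) {
  cells <- assigned_cells(x)
  in_bc <- cells$barcode[cells$clonotype_id == clonotype_id]
  out_bc <- if (is.null(versus)) {
    cells$barcode[cells$clonotype_id != clonotype_id]
  } else {
    cells$barcode[cells$clonotype_id == versus]
  }
  if (length(in_bc) < min_cells) {
    abort(sprintf("clonotype %s has %d cells, below min_cells = %d",
                  clonotype_id, length(in_bc), min_cells))
  }
  if (length(out_bc) < 2 || length(in_bc) < 2) {
    abort("degenerate comparison groups (fewer than 2 cells)")
  }
  norm_in <- x$normalized[in_bc, , drop = FALSE]
  norm_out <- x$normalized[out_bc, , drop = FALSE]
  det_in <- Matrix::colMeans(norm_in > 0)
  det_out <- Matrix::colMeans(norm_out > 0)
  tested <- which(det_in >= min_detect | det_out >= min_detect)
  res <- lapply(tested, function(j) {
    a <- norm_in[, j]
    b <- norm_out[, j]
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    tibble(gene = colnames(x$normalized)[j],
           effect = log2((mean(a) + eps) / (mean(b) + eps)),
           p = p, det_in = det_in[j], det_out = det_out[j])
  })
  out <- bind_rows(res)
  out$p[is.na(out$p)] <- 1
  out$q <- p.adjust(out$p, method = "BH")
  out |>
    select("gene", "effect", "p", "q", "det_in", "det_out") |>
    arrange(.data$p, .data$gene)
}
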