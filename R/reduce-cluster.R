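#' Select highly variable genes
#'
#' Ranks genes by simple variance of the normalised values and returns the
#' top `n_top`, ties broken by gene name. When every variance is zero the
#' first `n_top` genes in lexicographic order are returned with a warning.
#'
#' @param normalized Sparse cells x genes matrix of normalised values.
#' @param n_top Number of genes to keep (capped at the panel size).
#' @return Character vector of gene names.
#' @export
select_hvgs <- function(normalized, n_top = 2000) {
  n_top <- min(n_top, ncol(normalized))
  mu <- Matrix::colMeans(normalized)
  mu2 <- Matrix::colMeans(normalized^2)
  n <- nrow(normalized)
  v <- (mu2 - mu^2) * n / max(n - 1, 1)
  if (all(v <= 0)) {
    warn("all gene variances are zero; returning the first genes lexicographically")
  }
  genes <- colnames(normalized)
  ord <- order(-v, genes)
  genes[ord][seq_len(n_top)]
}

#' Principal component scores
#'
#' PCA on the centered cells x genes submatrix (no scaling), returning the
#' per-cell scores of the leading components.
#'
#' @param x Cells x genes matrix (typically normalised values restricted
#'   to highly variable genes).
#' @param n_components Number of components (must not exceed
#'   `min(cells, genes)`).
#' @return Numeric matrix cells x components with barcodes as rownames.
#' @export
embed_pca <- function(x, n_components = 30) {
  if (n_components > min(dim(x))) {
    abort(sprintf("n_components (%d) exceeds min(cells, genes) = %d",
                  n_components, min(dim(x))))
  }
  dense <- as.matrix(x)
  fit <- prcomp(dense, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- fit$x
  rownames(scores) <- rownames(x)
  scores
}

knn_graph <- function(pc_scores, k_neighbors) {
  n <- nrow(pc_scores)
  k <- min(k_neighbors, n - 1)
  nn <- RANN::nn2(pc_scores, k = k + 1)$nn.idx
  edges <- cbind(rep(seq_len(n), k), as.vector(nn[, -1, drop = FALSE]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster cells by community detection on a kNN graph
#'
#' Builds a k-nearest-neighbour graph in principal-component space and
#' applies modularity-based (Louvain) community detection. Labels are
#' relabelled by decreasing cluster size, starting at 0.
#'
#' @param pc_scores Cells x components score matrix with barcode rownames.
#' @param k_neighbors Neighbours per cell (default 15).
#' @param resolution Modularity resolution parameter.
#' @param seed Seed for the (stochastic) community detection.
#' @return Tibble with `barcode` and integer `cluster` (0-based,
#'   contiguous).
#' @export
cluster_graph <- function(pc_scores, k_neighbors = 15, resolution = 0.8,
                          seed = 1) {
  g <- knn_graph(pc_scores, k_neighbors)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  tibble(
    barcode = rownames(pc_scores) %||% as.character(seq_len(nrow(pc_scores))),
    cluster = as.integer(relabel[as.character(raw)])
  )
}

#' Two-dimensional embedding for visualisation
#'
#' UMAP on the principal-component scores (via \pkg{uwot} when installed;
#' otherwise the first two PCs are returned with a message). Deterministic
#' given the seed.
#'
#' @param pc_scores Cells x components score matrix.
#' @param seed Seed for the stochastic layout.
#' @param n_neighbors UMAP neighbourhood size.
#' @return Cells x 2 matrix with columns `DIM1`, `DIM2`.
#' @export
embed_2d <- function(pc_scores, seed = 1, n_neighbors = 15) {
  if (requireNamespace("uwot", quietly = TRUE)) {
    coords <- with_seed(seed, uwot::umap(
      pc_scores, n_neighbors = min(n_neighbors, nrow(pc_scores) - 1),
      n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  } else {
    inform("uwot not installed; using the first two principal components as the 2-D embedding")
    coords <- pc_scores[, 1:2, drop = FALSE]
  }
  colnames(coords) <- c("DIM1", "DIM2")
  rownames(coords) <- rownames(pc_scores)
  coords
}

#' Choose a clustering resolution by silhouette
#'
#' Clusters at each candidate resolution and computes the mean silhouette
#' width in principal-component space; returns the assignment maximising
#' it (ties go to the smaller resolution). If every resolution yields a
#' single cluster it is returned with an undefined silhouette and a
#' warning.
#'
#' @param pc_scores Cells x components score matrix.
#' @param resolutions Candidate resolutions (at least 2).
#' @param k_neighbors Neighbours for the kNN graph.
#' @param seed Seed passed to each clustering.
#' @return List with `resolution`, `clusters` (tibble), `silhouette`
#'   (mean width, `NA` when undefined) and `scan` (per-resolution tibble).
#' @export
resolution_scan <- function(pc_scores,
                            resolutions = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                            k_neighbors = 15, seed = 1) {
  assert_that(length(resolutions) >= 2, "need at least 2 candidate resolutions")
  d <- dist(pc_scores)
  results <- lapply(resolutions, function(res) {
    cl <- cluster_graph(pc_scores, k_neighbors, resolution = res, seed = seed)
    k <- length(unique(cl$cluster))
    sil <- if (k >= 2) {
      mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
    } else {
      NA_real_
    }
    list(resolution = res, clusters = cl, k = k, silhouette = sil)
  })
  scan <- tibble(
    resolution = vapply(results, `[[`, numeric(1), "resolution"),
    n_clusters = vapply(results, `[[`, numeric(1), "k"),
    silhouette = vapply(results, `[[`, numeric(1), "silhouette")
  )
  if (all(is.na(scan$silhouette))) {
    warn("all candidate resolutions yield a single cluster; silhouette undefined")
    best <- results[[1]]
  } else {
    best_i <- which(scan$silhouette == max(scan$silhouette, na.rm = TRUE))[1]
    best <- results[[best_i]]
  }
  list(resolution = best$resolution, clusters = best$clusters,
       silhouette = best$silhouette, scan = scan)
}
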