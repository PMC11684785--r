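toy_linked <- function() {
  withr::with_seed(17, {
    n <- 30
    counts <- Matrix::Matrix(
      matrix(rpois(n * 4, 3) + 1, n, 4,
             dimnames = list(sprintf("BC%02d-1", 1:n),
                             c("Mki67", "Ifng", "Sell", "G1"))),
      sparse = TRUE)
    meta <- tibble::tibble(barcode = rownames(counts),
                           sample = "tet_pos_immunized",
                           cluster = rep(0:1, 15))
    cells <- tibble::tibble(
      barcode = rownames(counts)[1:20],
      tra_cdr3_nt = rep(c("AAA", "CCC", "GGG", "TTT"), c(8, 6, 4, 2)),
      trb_cdr3_nt = rep(c("TTT", "GGG", "CCC", "AAA"), c(8, 6, 4, 2)),
      tra_cdr3_aa = "K", trb_cdr3_aa = "F",
      tra_v_gene = "V", tra_j_gene = "J",
      trb_v_gene = "V", trb_j_gene = "J",
      tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
      multi_tra = FALSE, multi_trb = FALSE)
    x <- tcx_experiment(counts, meta)
    x$normalized <- normalize_log(counts, 100)
    ct <- call_clonotypes(cells)
    list(x = suppressMessages(attach_clonotypes(x, ct)), clonotypes = ct)
  })
}

test_that("attach_clonotypes reconciles barcode namespaces", {
  tl <- toy_linked()
  x <- tl$x
  expect_equal(sum(x$cells$clonotype_id != "unassigned"), 20)
  expect_equal(x$log$reconciliation$n_expression_only, 10)

  # suffix stripping: V(D)J side without "-1" still matches
  cells2 <- tibble::tibble(
    barcode = "BC01", tra_cdr3_nt = "AAA", trb_cdr3_nt = "TTT",
    tra_cdr3_aa = "K", trb_cdr3_aa = "F", tra_v_gene = "V",
    tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
    tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
    multi_tra = FALSE, multi_trb = FALSE)
  ct2 <- call_clonotypes(cells2)
  y <- tcx_experiment(x$counts, x$cells[, c("barcode", "sample", "cluster")])
  y2 <- suppressMessages(attach_clonotypes(y, ct2))
  expect_equal(sum(y2$cells$clonotype_id != "unassigned"), 1)

  # fully disjoint namespaces are a hard error
  cells3 <- cells2
  cells3$barcode <- "ZZZZ"
  expect_error(suppressMessages(attach_clonotypes(y, call_clonotypes(cells3))),
               "no overlapping barcodes")
})

test_that("expansion table satisfies its conservation invariants", {
  tl <- toy_linked()
  et <- expansion_table(tl$x, by = "cluster")
  expect_equal(et$size, c(8L, 6L, 4L, 2L))
  expect_equal(sum(et$frequency), 1)
  expect_equal(et$frequency, et$size / 20)
  gc <- attr(et, "group_cols")
  # column sums equal cluster sizes among assigned cells (brute rebuild)
  assigned <- tl$x$cells[tl$x$cells$clonotype_id != "unassigned", ]
  want <- table(paste0("n_", assigned$cluster))
  got <- colSums(et[, gc])
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))
  expect_equal(unname(rowSums(et[, gc])), as.numeric(et$size))
})

test_that("expansion invariants hold on random linked data", {
  withr::with_seed(12, {
    for (i in 1:10) {
      n <- sample(30:120, 1)
      counts <- Matrix::Matrix(
        matrix(rpois(n * 3, 2) + 1, n, 3,
               dimnames = list(sprintf("C%03d", 1:n), c("g1", "g2", "g3"))),
        sparse = TRUE)
      meta <- tibble::tibble(barcode = rownames(counts),
                             cluster = sample(0:3, n, replace = TRUE))
      cells <- random_receptor_table(n)
      cells$barcode <- rownames(counts)[seq_len(n)]
      ct <- call_clonotypes(cells)
      x <- tcx_experiment(counts, meta)
      x <- suppressMessages(attach_clonotypes(x, ct))
      et <- expansion_table(x, "cluster")  # internal stopifnot() asserts
      expect_equal(sum(et$size), sum(ct$size))
    }
  })
})

test_that("diversity metrics match their closed forms", {
  eq <- tibble::tibble(clonotype_id = paste0("clonotype", 1:8),
                       size = rep(5L, 8), frequency = rep(1 / 8, 8))
  expect_equal(diversity(eq, "shannon"), log(8))
  expect_equal(diversity(eq, "gini"), 0)
  one <- tibble::tibble(clonotype_id = "clonotype1", size = 10L,
                        frequency = 1)
  expect_equal(diversity(one, "shannon"), 0)
  expect_equal(diversity(one, "d50"), 1)
})

test_that("diversity matches independent formula recomputation", {
  withr::with_seed(5, {
    for (i in 1:10) {
      k <- sample(2:40, 1)
      f <- rgamma(k, 1)
      f <- f / sum(f)
      et <- tibble::tibble(clonotype_id = paste0("c", 1:k), size = 1L,
                           frequency = f)
      expect_equal(diversity(et, "shannon"), -sum(f * log(f)))
      n <- length(f)
      g <- sum(abs(rep(f, each = n) - rep(f, n))) / (2 * n^2 * mean(f))
      expect_equal(diversity(et, "gini"), g)
      s <- sort(f, decreasing = TRUE)
      expect_equal(diversity(et, "d50"),
                   which(cumsum(s) >= 0.5)[1] / n)
    }
  })
})

test_that("shannon is maximal exactly at uniform frequencies", {
  withr::with_seed(6, {
    k <- 12
    uni <- tibble::tibble(clonotype_id = paste0("c", 1:k), size = 1L,
                          frequency = rep(1 / k, k))
    h_max <- diversity(uni, "shannon")
    for (i in 1:20) {
      f <- rgamma(k, 1)
      f <- f / sum(f)
      pert <- uni
      pert$frequency <- f
      expect_lte(diversity(pert, "shannon"), h_max + 1e-12)
    }
  })
})

test_that("marker profiles are per-clonotype means and detection fractions", {
  counts <- Matrix::Matrix(
    rbind(c(2, 0), c(4, 0), c(0, 1), c(0, 3)), sparse = TRUE,
    dimnames = list(paste0("BC", 1:4), c("Mki67", "Ifng")))
  meta <- tibble::tibble(barcode = rownames(counts), cluster = 0L)
  cells <- tibble::tibble(
    barcode = rownames(counts),
    tra_cdr3_nt = rep(c("AAA", "CCC"), each = 2),
    trb_cdr3_nt = rep(c("TTT", "GGG"), each = 2),
    tra_cdr3_aa = "K", trb_cdr3_aa = "F", tra_v_gene = "V",
    tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
    tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
    multi_tra = FALSE, multi_trb = FALSE)
  x <- tcx_experiment(counts, meta)
  x$normalized <- counts  # identity "normalisation" keeps arithmetic exact
  x <- suppressMessages(attach_clonotypes(x, call_clonotypes(cells)))
  prof <- marker_profile(x, c("Mki67", "Ifng", "NotAGene"), min_cells = 2) |>
    suppressWarnings()
  c1 <- prof[prof$gene == "Mki67" & prof$clonotype_id == "clonotype1", ]
  expect_equal(c1$mean_norm, 3)
  expect_equal(c1$det_fraction, 1)
  c2 <- prof[prof$gene == "Mki67" & prof$clonotype_id == "clonotype2", ]
  expect_equal(c2$mean_norm, 0)
  expect_equal(c2$det_fraction, 0)
  expect_warning(marker_profile(x, c("Mki67", "Nope"), min_cells = 2),
                 "omitted")
  expect_warning(empty <- marker_profile(x, "Mki67", min_cells = 10),
                 "no clonotype")
  expect_equal(nrow(empty), 0)
})

test_that("clonotype DE is calibrated under the null and finds planted markers", {
  withr::with_seed(23, {
    n_in <- 60
    n_out <- 140
    n_genes <- 1000
    counts <- Matrix::Matrix(
      matrix(rpois((n_in + n_out) * n_genes, 2), n_in + n_out, n_genes,
             dimnames = list(sprintf("BC%03d", 1:(n_in + n_out)),
                             sprintf("g%04d", 1:n_genes))), sparse = TRUE)
    meta <- tibble::tibble(barcode = rownames(counts), cluster = 0L)
    cells <- tibble::tibble(
      barcode = rownames(counts),
      tra_cdr3_nt = rep(c("AAA", "CCC"), c(n_in, n_out)),
      trb_cdr3_nt = rep(c("TTT", "GGG"), c(n_in, n_out)),
      tra_cdr3_aa = "K", trb_cdr3_aa = "F", tra_v_gene = "V",
      tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
      tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
      multi_tra = FALSE, multi_trb = FALSE)
    x <- tcx_experiment(counts, meta)
    x$normalized <- normalize_log(counts, 1e4)
    x <- suppressMessages(attach_clonotypes(x, call_clonotypes(cells)))
    de <- clonotype_de(x, "clonotype2")  # the 60-cell group vs the rest
    # identical distributions: type-I error near alpha
    alpha <- 0.05
    typei <- mean(de$p < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(de))
    expect_lt(abs(typei - alpha), 2 * se + 1e-9)
    # BH matches the brute-force step-up construction
    expect_equal(de$q, oracle_bh(de$p))
  })
})

test_that("constant genes are skipped and planted effects rank on top", {
  withr::with_seed(29, {
    n <- 120
    base <- matrix(rpois(n * 20, 2), n, 20)
    base[, 20] <- 0                       # constant zero gene
    base[1:30, 1] <- rpois(30, 8)         # 4-fold planted marker in clone
    counts <- Matrix::Matrix(base, sparse = TRUE,
                             dimnames = list(sprintf("BC%03d", 1:n),
                                             sprintf("g%02d", 1:20)))
    meta <- tibble::tibble(barcode = rownames(counts), cluster = 0L)
    cells <- tibble::tibble(
      barcode = rownames(counts),
      tra_cdr3_nt = rep(c("AAA", "CCC"), c(30, 90)),
      trb_cdr3_nt = rep(c("TTT", "GGG"), c(30, 90)),
      tra_cdr3_aa = "K", trb_cdr3_aa = "F", tra_v_gene = "V",
      tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
      tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
      multi_tra = FALSE, multi_trb = FALSE)
    x <- tcx_experiment(counts, meta)
    x$normalized <- normalize_log(counts, 1e4)
    x <- suppressMessages(attach_clonotypes(x, call_clonotypes(cells)))
    de <- clonotype_de(x, "clonotype2", min_cells = 10)
    expect_false("g20" %in% de$gene)
    expect_equal(de$gene[1], "g01")
    expect_gt(de$effect[1], 0.1)  # enrichment on the log-normalised scale
    expect_error(clonotype_de(x, "clonotype2", min_cells = 500), "below")
  })
})
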