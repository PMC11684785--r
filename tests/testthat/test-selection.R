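mk_profile <- function(df) {
  # df: clonotype_id, gene[, det_fraction] (mean_norm irrelevant for gates)
  if (is.null(df$det_fraction)) df$det_fraction <- 0
  df$mean_norm <- df$det_fraction
  df$n_cells <- 10L
  tibble::as_tibble(df[, c("clonotype_id", "n_cells", "gene", "mean_norm",
                           "det_fraction")])
}

mk_expansion <- function(sizes, ids = paste0("clonotype", seq_along(sizes))) {
  out <- tibble::tibble(clonotype_id = ids, size = as.integer(sizes),
                        frequency = sizes / sum(sizes),
                        n_0 = as.integer(sizes))
  attr(out, "by") <- "cluster"
  attr(out, "group_cols") <- "n_0"
  out
}

test_that("gates pass and fail by threshold arithmetic", {
  crit <- selection_criteria(positive = c("Mki67", "Ifng"),
                             negative = "Sell")
  prof <- mk_profile(expand.grid(
    clonotype_id = c("clonotype1", "clonotype2"),
    gene = c("Mki67", "Ifng", "Sell"), stringsAsFactors = FALSE))
  prof$det_fraction <- c(0.8, 0.8, 0.8, 0.3, 0.02, 0.02)
  g <- gate_clonotypes(prof, crit)
  g1 <- g[g$clonotype_id == "clonotype1", ]
  expect_true(all(g1$pass))
  g2 <- g[g$clonotype_id == "clonotype2", ]
  expect_false(g2$pass[g2$gene == "Ifng"])  # 0.3 below the 0.5 gate
  expect_equal(g1$margin[g1$gene == "Sell"], 0.08)
  expect_error(gate_clonotypes(prof, selection_criteria(positive = "Xcl1")),
               "Xcl1")
})

test_that("ranking orders eligible clones by score with size tie-breaks", {
  crit <- selection_criteria(positive = "Mki67", min_clone_size = 2)
  prof <- mk_profile(data.frame(
    clonotype_id = c("clonotype1", "clonotype2"),
    gene = "Mki67", det_fraction = c(0.9, 0.9)))
  exp_tbl <- mk_expansion(c(40, 4))
  rep_ <- rank_clonotypes(exp_tbl, gate_clonotypes(prof, crit), crit)
  expect_equal(rep_$selected, "clonotype1")
  expect_equal(rep_$ranking$clonotype_id[1], "clonotype1")
  expect_true(all(rep_$ranking$eligible[1:2]))

  # single eligible clone ranks first under any weighting
  crit1 <- selection_criteria(positive = "Mki67", expansion_weight = 1)
  prof1 <- mk_profile(data.frame(
    clonotype_id = c("clonotype1", "clonotype2"), gene = "Mki67",
    det_fraction = c(0.2, 0.9)))
  rep1 <- rank_clonotypes(mk_expansion(c(40, 4)),
                          gate_clonotypes(prof1, crit1), crit1)
  expect_equal(rep1$selected, "clonotype2")
  expect_equal(rep1$ranking$clonotype_id, c("clonotype2", "clonotype1"))
  expect_match(rep1$ranking$reason[2], "gate")
})

test_that("zero eligible clones yields an empty selection with diagnostics", {
  crit <- selection_criteria(positive = "Mki67")
  prof <- mk_profile(data.frame(
    clonotype_id = c("clonotype1", "clonotype2"), gene = "Mki67",
    det_fraction = c(0.1, 0.2)))
  rep_ <- rank_clonotypes(mk_expansion(c(10, 5)),
                          gate_clonotypes(prof, crit), crit)
  expect_true(is.na(rep_$selected))
  expect_equal(nrow(rep_$ranking), 2)
  expect_true(all(!rep_$ranking$eligible))
  expect_true(all(nzchar(rep_$ranking$reason)))
})

test_that("ranking is invariant to input clonotype order", {
  crit <- selection_criteria(positive = "Mki67", negative = "Sell")
  ids <- paste0("clonotype", 1:6)
  withr::with_seed(44, {
    prof <- mk_profile(expand.grid(clonotype_id = ids,
                                   gene = c("Mki67", "Sell"),
                                   stringsAsFactors = FALSE))
    prof$det_fraction <- runif(nrow(prof))
    exp_tbl <- mk_expansion(c(50, 30, 20, 10, 5, 2), ids)
    base <- rank_clonotypes(exp_tbl, gate_clonotypes(prof, crit), crit)
    for (i in 1:5) {
      perm <- sample(nrow(exp_tbl))
      exp_p <- exp_tbl[perm, ]
      attr(exp_p, "by") <- "cluster"
      attr(exp_p, "group_cols") <- "n_0"
      prof_p <- prof[sample(nrow(prof)), ]
      got <- rank_clonotypes(exp_p, gate_clonotypes(prof_p, crit), crit)
      expect_equal(got$ranking$clonotype_id, base$ranking$clonotype_id)
      expect_equal(got$selected, base$selected)
    }
  })
})

test_that("removing a positive gate never shrinks the eligible set", {
  withr::with_seed(45, {
    ids <- paste0("clonotype", 1:8)
    genes <- c("Mki67", "Ifng", "Cd69")
    prof <- mk_profile(expand.grid(clonotype_id = ids, gene = genes,
                                   stringsAsFactors = FALSE))
    prof$det_fraction <- runif(nrow(prof))
    exp_tbl <- mk_expansion(8:1 * 5, ids)
    full_crit <- selection_criteria(positive = genes)
    red_crit <- selection_criteria(positive = genes[-1])
    full <- rank_clonotypes(exp_tbl, gate_clonotypes(prof, full_crit),
                            full_crit)
    red <- rank_clonotypes(exp_tbl, gate_clonotypes(prof, red_crit),
                           red_crit)
    full_ok <- full$ranking$clonotype_id[full$ranking$eligible]
    red_ok <- red$ranking$clonotype_id[red$ranking$eligible]
    expect_true(all(full_ok %in% red_ok))
  })
})

test_that("cluster restriction gates on where the clone's cells sit", {
  crit <- selection_criteria(positive = "Mki67", restrict_to_clusters = 0)
  prof <- mk_profile(data.frame(
    clonotype_id = c("clonotype1", "clonotype2"), gene = "Mki67",
    det_fraction = 0.9))
  exp_tbl <- tibble::tibble(
    clonotype_id = c("clonotype1", "clonotype2"), size = c(10L, 8L),
    frequency = c(10, 8) / 18, n_0 = c(9L, 1L), n_1 = c(1L, 7L))
  attr(exp_tbl, "by") <- "cluster"
  attr(exp_tbl, "group_cols") <- c("n_0", "n_1")
  rep_ <- rank_clonotypes(exp_tbl, gate_clonotypes(prof, crit), crit)
  expect_equal(rep_$selected, "clonotype1")
  expect_match(rep_$ranking$reason[rep_$ranking$clonotype_id == "clonotype2"],
               "restricted")
})

selection_fixture <- function(full_nt_tra = "ATGAAACCC") {
  cells <- tibble::tibble(
    barcode = c("BC1", "BC2", "BC3"),
    tra_cdr3_nt = "TGTGCA", trb_cdr3_nt = "TGTGCC",
    tra_cdr3_aa = "CA", trb_cdr3_aa = "CA",
    tra_v_gene = "TRAV3", tra_j_gene = "TRAJ5",
    trb_v_gene = "TRBV13", trb_j_gene = "TRBJ2-1",
    tra_full_nt = full_nt_tra, trb_full_nt = "ATGCCCGGG",
    tra_umis = 1L, trb_umis = 1L, multi_tra = FALSE, multi_trb = FALSE)
  ct <- call_clonotypes(cells)
  crit <- selection_criteria(positive = "Mki67")
  prof <- mk_profile(data.frame(clonotype_id = "clonotype1", gene = "Mki67",
                                det_fraction = 0.9))
  rep_ <- rank_clonotypes(mk_expansion(3), gate_clonotypes(prof, crit), crit)
  list(report = rep_, clonotypes = ct, cells = cells)
}

test_that("export writes sequences plus machine- and human-readable reports", {
  fx <- selection_fixture()
  d <- withr::local_tempdir()
  export_selection(fx$report, fx$clonotypes, fx$cells, d,
                   provenance = list(seed = 1))
  fasta <- readLines(file.path(d, "selected_tcr.fasta"))
  expect_length(fasta, 4)
  expect_match(fasta[1], "^>clonotype1_TRA TRAV3 TRAJ5")
  expect_equal(fasta[2], "ATGAAACCC")
  js <- jsonlite::read_json(file.path(d, "selection.json"))
  expect_equal(js$selected, "clonotype1")
  expect_equal(js$provenance$seed, 1)
  expect_length(js$warnings, 0)
  expect_match(readLines(file.path(d, "selection.md"))[3], "clonotype1")
})

test_that("a SalI site in the consensus triggers warnings in both reports", {
  fx <- selection_fixture(full_nt_tra = "ATGGTCGACCCC")
  d <- withr::local_tempdir()
  expect_warning(
    export_selection(fx$report, fx$clonotypes, fx$cells, d), "SalI")
  js <- jsonlite::read_json(file.path(d, "selection.json"))
  expect_match(js$warnings[[1]], "GTCGAC")
  expect_true(any(grepl("SalI", readLines(file.path(d, "selection.md")))))
})

test_that("an empty selection refuses sequences but writes diagnostics", {
  crit <- selection_criteria(positive = "Mki67")
  prof <- mk_profile(data.frame(clonotype_id = "clonotype1", gene = "Mki67",
                                det_fraction = 0.1))
  rep_ <- rank_clonotypes(mk_expansion(3), gate_clonotypes(prof, crit), crit)
  fx <- selection_fixture()
  d <- withr::local_tempdir()
  export_selection(rep_, fx$clonotypes, fx$cells, d)
  expect_false(file.exists(file.path(d, "selected_tcr.fasta")))
  expect_true(file.exists(file.path(d, "selection.json")))
  js <- jsonlite::read_json(file.path(d, "selection.json"))
  expect_null(js$selected)
})
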