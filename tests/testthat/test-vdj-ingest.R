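test_that("read_contigs handles degenerate and mixed-chain inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_contigs(toy_contigs()[0, ], f, "tenx_csv")
  expect_equal(nrow(read_contigs(f)), 0)

  write_contigs(toy_contigs(), f, "tenx_csv")
  recs <- read_contigs(f)
  expect_equal(nrow(recs), 3)
  expect_equal(sum(recs$chain == "other"), 1)
})

test_that("read_contigs reports missing columns and bad boolean tokens", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_contigs(toy_contigs(), f, "tenx_csv")
  lines <- readLines(f)
  # drop the chain column
  broken <- vapply(strsplit(lines, ","), function(x) {
    paste(x[-5], collapse = ",")
  }, character(1))
  writeLines(broken, f)
  # readr also notices the ragged rows; only the package error matters here
  suppressWarnings(expect_error(read_contigs(f, "tenx_csv"), "chain"))

  write_contigs(toy_contigs(), f, "tenx_csv")
  lines <- readLines(f)
  lines[3] <- sub(",True,", ",yes,", lines[3], fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_contigs(f, "tenx_csv"), "row 2")
})

test_that("filter_contigs equals a direct predicate scan", {
  withr::with_seed(42, {
    recs <- toy_contigs()[sample(3, 10, replace = TRUE), ]
    recs$productive <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    recs$is_cell <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    recs$high_confidence <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  })
  kept <- filter_contigs(recs)
  manual <- recs[recs$productive & recs$is_cell & recs$high_confidence &
                   recs$chain %in% c("TRA", "TRB"), ]
  expect_identical(kept, manual)
  one <- toy_contigs()[1, ]
  one$productive <- FALSE
  expect_equal(nrow(filter_contigs(one)), 0)
  trg <- toy_contigs()[3, ]  # all flags true but chain TRG
  expect_equal(nrow(filter_contigs(trg)), 0)
})

test_that("pair_chains selects by UMIs with reads then CDR3 tie-breaks", {
  recs <- tibble::tibble(
    barcode = c("BC1", "BC1", "BC1", "BC2"),
    contig_id = paste0("c", 1:4),
    chain = c("TRA", "TRA", "TRB", "TRB"),
    v_gene = paste0("V", 1:4), j_gene = paste0("J", 1:4),
    c_gene = "", cdr3_aa = c("CA1", "CA2", "CB1", "CB2"),
    cdr3_nt = c("AAA", "CCC", "GGG", "TTT"),
    full_nt = "", umis = c(10L, 3L, 6L, 1L), reads = c(1L, 99L, 5L, 5L),
    productive = TRUE, high_confidence = TRUE, is_cell = TRUE
  )
  paired <- pair_chains(recs)
  bc1 <- paired[paired$barcode == "BC1", ]
  expect_equal(bc1$tra_cdr3_nt, "AAA")   # umis 10 beats 3 despite fewer reads
  expect_true(bc1$multi_tra)
  expect_false(bc1$multi_trb)
  bc2 <- paired[paired$barcode == "BC2", ]
  expect_true(is.na(bc2$tra_cdr3_nt))    # only TRB present

  # tie on umis -> reads decides; tie on both -> smaller cdr3_nt
  ties <- recs
  ties$umis <- 5L
  ties$reads <- c(7L, 7L, 1L, 1L)
  expect_equal(pair_chains(ties)$tra_cdr3_nt[1], "AAA")
})

test_that("call_clonotypes matches the brute-force grouping oracle", {
  cells <- tibble::tibble(
    barcode = paste0("BC", 1:5),
    tra_cdr3_nt = c("A", "A", "A", "C", "E"),
    trb_cdr3_nt = c("B", "B", "B", "D", "F"),
    tra_cdr3_aa = c("a", "a", "a", "c", "e"),
    trb_cdr3_aa = c("b", "b", "b", "d", "f"),
    tra_v_gene = "V", tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
    tra_full_nt = "", trb_full_nt = "", tra_umis = 1L, trb_umis = 1L,
    multi_tra = FALSE, multi_trb = FALSE
  )
  ct <- call_clonotypes(cells)
  expect_equal(ct$size, c(3L, 1L, 1L))
  expect_equal(ct$clonotype_id, paste0("clonotype", 1:3))
  expect_equal(ct$key[1], "A|B")

  withr::with_seed(99, {
    for (i in 1:25) {
      cells <- random_receptor_table(sample(5:200, 1))
      for (strategy in c("paired_nt", "paired_aa", "paired_nt_vj")) {
        got <- call_clonotypes(cells, strategy)
        want <- oracle_clonotypes(cells, strategy)
        expect_identical(got$key, want$key)
        expect_identical(as.integer(got$size), want$size)
      }
    }
  })
})

test_that("clonotype partition and coarsening invariants hold", {
  withr::with_seed(7, cells <- random_receptor_table(150))
  ct <- call_clonotypes(cells)
  both <- sum(!is.na(cells$tra_cdr3_nt) & !is.na(cells$trb_cdr3_nt))
  expect_equal(sum(ct$size), both)
  cm <- attr(ct, "cell_map")
  expect_false(anyDuplicated(cm$barcode) > 0)
  expect_equal(length(attr(ct, "excluded_barcodes")), nrow(cells) - both)

  n_vj <- nrow(call_clonotypes(cells, "paired_nt_vj"))
  n_nt <- nrow(call_clonotypes(cells, "paired_nt"))
  n_aa <- nrow(call_clonotypes(cells, "paired_aa"))
  expect_gte(n_vj, n_nt)
  expect_gte(n_nt, n_aa)

  empty <- call_clonotypes(cells[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("single-chain cells can join clonotypes with a placeholder key", {
  cells <- random_receptor_table(40)
  cells$tra_cdr3_nt[1:5] <- NA
  ct <- call_clonotypes(cells, require_both_chains = FALSE)
  has_any <- !is.na(cells$tra_cdr3_nt) | !is.na(cells$trb_cdr3_nt)
  expect_equal(sum(ct$size), sum(has_any))
  expect_true(any(grepl("<none>", ct$key)))
})

test_that("consensus takes the positional majority of modal-length members", {
  cells <- tibble::tibble(
    barcode = c("BC1", "BC2", "BC3"),
    tra_cdr3_nt = "TGTGCA", trb_cdr3_nt = "TGTGCC",
    tra_cdr3_aa = "CA", trb_cdr3_aa = "CA",
    tra_v_gene = "TRAV1", tra_j_gene = "TRAJ1",
    trb_v_gene = "TRBV1", trb_j_gene = "TRBJ1",
    tra_full_nt = c("ATGAAA", "ATGAAA", "ATGAAG"),  # one mismatch at pos 6
    trb_full_nt = c("ATGCCC", "ATGCCC", "ATGCCC"),
    tra_umis = 1L, trb_umis = 1L, multi_tra = FALSE, multi_trb = FALSE
  )
  ct <- call_clonotypes(cells)
  cons <- consensus_sequences(ct, "clonotype1", cells)
  expect_equal(cons$consensus_nt[cons$chain == "TRA"], "ATGAAA")
  expect_equal(cons$match_fraction[cons$chain == "TRA"], 2 / 3)
  expect_equal(cons$match_fraction[cons$chain == "TRB"], 1)
  expect_equal(cons$consensus_aa[cons$chain == "TRB"], "MP")

  # absent full_nt falls back to cdr3_nt and is excluded from the tally
  cells2 <- cells
  cells2$tra_full_nt <- c("", "", "")
  cons2 <- consensus_sequences(call_clonotypes(cells2), "clonotype1", cells2)
  expect_equal(cons2$consensus_nt[cons2$chain == "TRA"], "TGTGCA")

  cells3 <- cells
  cells3$trb_full_nt <- ""
  cells3$trb_cdr3_nt <- NA
  ct3 <- call_clonotypes(cells3, require_both_chains = FALSE)
  expect_error(consensus_sequences(ct3, "clonotype1", cells3), "TRB")
})

test_that("positional ties resolve to the first member in barcode order", {
  cells <- tibble::tibble(
    barcode = c("BC2", "BC1"),  # deliberately unsorted
    tra_cdr3_nt = "TGTGCA", trb_cdr3_nt = "TGTGCC",
    tra_cdr3_aa = "CA", trb_cdr3_aa = "CA",
    tra_v_gene = "V", tra_j_gene = "J", trb_v_gene = "V", trb_j_gene = "J",
    tra_full_nt = c("ATGAAT", "ATGAAC"),  # 1-1 tie at position 6
    trb_full_nt = "ATGCCC",
    tra_umis = 1L, trb_umis = 1L, multi_tra = FALSE, multi_trb = FALSE
  )
  cons <- consensus_sequences(call_clonotypes(cells), "clonotype1", cells)
  # BC1's base (C) wins the tie
  expect_equal(cons$consensus_nt[cons$chain == "TRA"], "ATGAAC")
})
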