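# Independent brute-force oracles and small fixtures shared across tests.

# brute-force clonotype grouping: a plain dictionary over key strings,
# independent of call_clonotypes' dplyr path
oracle_clonotypes <- function(cells, strategy, require_both_chains = TRUE) {
  ph <- function(x) ifelse(is.na(x), "<none>", x)
  if (require_both_chains) {
    cells <- cells[!is.na(cells$tra_cdr3_nt) & !is.na(cells$trb_cdr3_nt), ]
  } else {
    cells <- cells[!is.na(cells$tra_cdr3_nt) | !is.na(cells$trb_cdr3_nt), ]
  }
  key <- switch(strategy,
    paired_nt = paste(ph(cells$tra_cdr3_nt), ph(cells$trb_cdr3_nt), sep = "|"),
    paired_aa = paste(ph(cells$tra_cdr3_aa), ph(cells$trb_cdr3_aa), sep = "|"),
    paired_nt_vj = paste(ph(cells$tra_cdr3_nt), ph(cells$tra_v_gene),
                         ph(cells$tra_j_gene), ph(cells$trb_cdr3_nt),
                         ph(cells$trb_v_gene), ph(cells$trb_j_gene),
                         sep = "|"))
  groups <- split(cells$barcode, key)
  sizes <- vapply(groups, length, integer(1))
  ord <- order(-sizes, names(groups))
  data.frame(key = names(groups)[ord], size = unname(sizes[ord]),
             stringsAsFactors = FALSE)
}

# direct median/MAD recomputation of the outlier rule
oracle_flags <- function(lib, genes, mito, n_mads = 5) {
  one <- function(x, side) {
    med <- median(x)
    mad <- median(abs(x - med))
    if (mad == 0) {
      if (side == "lower") x < med else x > med
    } else if (side == "lower") {
      x < med - n_mads * mad
    } else {
      x > med + n_mads * mad
    }
  }
  one(log10(lib + 1), "lower") | (lib == 0) |
    one(log10(genes + 1), "lower") |
    one(mito, "upper")
}

# textbook Benjamini-Hochberg, computed by sorting and the step-up rule
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# random receptor table for oracle-equivalence tests
random_receptor_table <- function(n_cells, n_keys = max(2, n_cells %/% 4)) {
  tra <- replicate(n_keys, paste(sample(c("A", "C", "G", "T"), 9,
                                        replace = TRUE), collapse = ""))
  trb <- replicate(n_keys, paste(sample(c("A", "C", "G", "T"), 12,
                                        replace = TRUE), collapse = ""))
  idx <- sample(n_keys, n_cells, replace = TRUE)
  out <- tibble::tibble(
    barcode = sprintf("BC%04d", seq_len(n_cells)),
    tra_cdr3_nt = tra[idx], trb_cdr3_nt = trb[idx],
    tra_cdr3_aa = substr(tra[idx], 1, 3), trb_cdr3_aa = substr(trb[idx], 1, 4),
    tra_v_gene = sample(c("TRAV1", "TRAV2"), n_cells, replace = TRUE),
    tra_j_gene = sample(c("TRAJ1", "TRAJ2"), n_cells, replace = TRUE),
    trb_v_gene = sample(c("TRBV1", "TRBV2"), n_cells, replace = TRUE),
    trb_j_gene = sample(c("TRBJ1", "TRBJ2"), n_cells, replace = TRUE),
    tra_full_nt = "", trb_full_nt = "",
    tra_umis = 1L, trb_umis = 1L,
    multi_tra = FALSE, multi_trb = FALSE
  )
  # some cells missing one chain
  drop_a <- sample(n_cells, max(0, n_cells %/% 10))
  drop_b <- sample(setdiff(seq_len(n_cells), drop_a), max(0, n_cells %/% 10))
  out$tra_cdr3_nt[drop_a] <- NA
  out$tra_cdr3_aa[drop_a] <- NA
  out$trb_cdr3_nt[drop_b] <- NA
  out$trb_cdr3_aa[drop_b] <- NA
  out
}

# tiny hand-built contig tibble
toy_contigs <- function() {
  tibble::tibble(
    barcode = c("BC1", "BC1", "BC2"),
    contig_id = c("BC1_1", "BC1_2", "BC2_1"),
    chain = c("TRA", "TRB", "TRG"),
    v_gene = c("TRAV1", "TRBV2", "TRGV1"),
    j_gene = c("TRAJ1", "TRBJ1", "TRGJ1"),
    c_gene = c("TRAC", "TRBC1", "TRGC1"),
    cdr3_aa = c("CAV", "CASS", "CAL"),
    cdr3_nt = c("TGTGCTGTT", "TGTGCTTCTTCT", "TGTGCTTTA"),
    full_nt = c("ATGTGTGCTGTT", "ATGTGTGCTTCTTCT", "ATGTGTGCTTTA"),
    umis = c(5L, 7L, 2L),
    reads = c(100L, 120L, 30L),
    productive = TRUE, high_confidence = TRUE, is_cell = TRUE
  )
}

# the default scenario pipeline run, computed once per test session
default_run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(default_run_cache$run)) {
    sim <- generate_dataset(default_cd8_scenario(seed = 1))
    default_run_cache$sim <- sim
    default_run_cache$run <- suppressMessages(run_pipeline(
      sim$counts, sim$cell_meta, sim$contigs,
      params = pipeline_params(compute_embedding = FALSE)))
  }
  list(sim = default_run_cache$sim, run = default_run_cache$run)
}
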