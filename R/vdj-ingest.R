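parse_bool <- function(x, true_tokens, false_tokens, column, file) {
  out <- rep(NA, length(x))
  out[x %in% true_tokens] <- TRUE
  out[x %in% false_tokens] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "parse error in %s: inconsistent boolean token '%s' in column '%s' at data row %d",
      file, x[bad[1]], column, bad[1]))
  }
  out
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("parse error in %s: missing mandatory column(s): %s",
                  file, paste(missing, collapse = ", ")))
  }
}

#' Read V(D)J contig annotations
#'
#' Supports the 10x Cell Ranger `filtered_contig_annotations.csv` dialect
#' and the AIRR Rearrangement TSV dialect, with auto-detection from the
#' header. Chains other than TRA/TRB are preserved as "other".
#'
#' @param path Path to the contig file.
#' @param dialect "tenx_csv", "airr_tsv" or "auto".
#' @return A contig tibble, one row per input row, with columns
#'   `barcode`, `contig_id`, `chain`, `v_gene`, `j_gene`, `c_gene`,
#'   `cdr3_aa`, `cdr3_nt`, `full_nt`, `umis`, `reads`, `productive`,
#'   `high_confidence`, `is_cell`.
#' @export
read_contigs <- function(path, dialect = c("auto", "tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste("file not found:", path))
  header <- readLines(path, n = 1)
  if (dialect == "auto") {
    fields <- strsplit(header, "[,\t]")[[1]]
    dialect <- if (all(c("barcode", "chain") %in% fields)) {
      "tenx_csv"
    } else if (all(c("cell_id", "locus") %in% fields)) {
      "airr_tsv"
    } else {
      abort(sprintf("cannot auto-detect contig dialect of %s from header", path))
    }
  }
  if (dialect == "tenx_csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    require_columns(df, c("barcode", "is_cell", "high_confidence", "chain",
                          "v_gene", "j_gene", "productive", "cdr3",
                          "cdr3_nt", "reads", "umis"), path)
    out <- tibble(
      barcode = df$barcode,
      contig_id = df$contig_id %||% paste0(df$barcode, "_", seq_len(nrow(df))),
      chain = ifelse(df$chain %in% c("TRA", "TRB"), df$chain, "other"),
      v_gene = df$v_gene,
      j_gene = df$j_gene,
      c_gene = df$c_gene %||% rep("", nrow(df)),
      cdr3_aa = df$cdr3,
      cdr3_nt = df$cdr3_nt,
      full_nt = df$full_length %||% rep("", nrow(df)),
      umis = as.integer(df$umis),
      reads = as.integer(df$reads),
      productive = parse_bool(df$productive, "True", "False", "productive", path),
      high_confidence = parse_bool(df$high_confidence, "True", "False",
                                   "high_confidence", path),
      is_cell = parse_bool(df$is_cell, "True", "False", "is_cell", path)
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    require_columns(df, c("cell_id", "locus", "v_call", "j_call", "junction",
                          "junction_aa", "productive", "consensus_count"),
                    path)
    n <- nrow(df)
    out <- tibble(
      barcode = df$cell_id,
      contig_id = df$sequence_id %||% paste0(df$cell_id, "_", seq_len(n)),
      chain = ifelse(df$locus %in% c("TRA", "TRB"), df$locus, "other"),
      v_gene = df$v_call,
      j_gene = df$j_call,
      c_gene = df$c_call %||% rep("", n),
      cdr3_aa = df$junction_aa,
      cdr3_nt = df$junction,
      full_nt = df$sequence %||% rep("", n),
      umis = as.integer(df$consensus_count),
      reads = if ("duplicate_count" %in% names(df)) {
        as.integer(df$duplicate_count)
      } else {
        as.integer(df$consensus_count)
      },
      productive = parse_bool(df$productive, "T", "F", "productive", path),
      high_confidence = if ("high_confidence" %in% names(df)) {
        parse_bool(df$high_confidence, "T", "F", "high_confidence", path)
      } else {
        rep(TRUE, n)
      },
      is_cell = if ("is_cell" %in% names(df)) {
        parse_bool(df$is_cell, "T", "F", "is_cell", path)
      } else {
        rep(TRUE, n)
      }
    )
  }
  out$c_gene[is.na(out$c_gene)] <- ""
  out$full_nt[is.na(out$full_nt)] <- ""
  out
}

#' Filter contig records on platform quality flags
#'
#' Keeps records with every required flag true and chain TRA or TRB,
#' preserving input order.
#'
#' @param contigs Contig tibble (see [read_contigs()]).
#' @param require Character vector of flag columns that must be TRUE;
#'   any subset of `is_cell`, `high_confidence`, `productive`.
#' @return Filtered contig tibble.
#' @export
filter_contigs <- function(contigs,
                           require = c("is_cell", "high_confidence",
                                       "productive")) {
  require <- match.arg(require, several.ok = TRUE)
  keep <- contigs$chain %in% c("TRA", "TRB")
  for (flag in require) keep <- keep & contigs[[flag]]
  contigs[keep, , drop = FALSE]
}

#' Resolve one alpha and one beta chain per cell
#'
#' Per barcode and chain, selects the contig with the most UMIs; ties are
#' broken by read count, then by lexicographically smallest CDR3
#' nucleotide sequence. `multi_tra`/`multi_trb` record whether more than
#' one candidate contig existed for that chain.
#'
#' @param contigs Filtered contig tibble (see [filter_contigs()]).
#' @return One row per barcode with `tra_*` and `trb_*` columns
#'   (`cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`, `full_nt`, `umis`) — `NA`
#'   when the chain is absent — plus `multi_tra` and `multi_trb`.
#' @export
pair_chains <- function(contigs) {
  contigs <- contigs[contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  picked <- contigs |>
    group_by(.data$barcode, .data$chain) |>
    arrange(desc(.data$umis), desc(.data$reads), .data$cdr3_nt,
            .by_group = TRUE) |>
    summarise(
      cdr3_nt = .data$cdr3_nt[1], cdr3_aa = .data$cdr3_aa[1],
      v_gene = .data$v_gene[1], j_gene = .data$j_gene[1],
      full_nt = .data$full_nt[1], umis = .data$umis[1],
      multi = n() > 1, .groups = "drop"
    )
  wide <- tidyr::pivot_wider(
    picked,
    id_cols = "barcode", names_from = "chain",
    values_from = c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "full_nt",
                    "umis", "multi"),
    names_glue = "{tolower(chain)}_{.value}"
  )
  for (col in c(paste0("tra_", c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
                                 "full_nt", "umis", "multi")),
                paste0("trb_", c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
                                 "full_nt", "umis", "multi")))) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  wide |>
    mutate(multi_tra = !is.na(.data$tra_multi) & .data$tra_multi,
           multi_trb = !is.na(.data$trb_multi) & .data$trb_multi) |>
    select(-"tra_multi", -"trb_multi") |>
    arrange(.data$barcode)
}

clonotype_key <- function(cells, strategy) {
  placeholder <- function(x) ifelse(is.na(x), "<none>", x)
  switch(strategy,
    paired_nt = paste(placeholder(cells$tra_cdr3_nt),
                      placeholder(cells$trb_cdr3_nt), sep = "|"),
    paired_aa = paste(placeholder(cells$tra_cdr3_aa),
                      placeholder(cells$trb_cdr3_aa), sep = "|"),
    paired_nt_vj = paste(placeholder(cells$tra_cdr3_nt),
                         placeholder(cells$tra_v_gene),
                         placeholder(cells$tra_j_gene),
                         placeholder(cells$trb_cdr3_nt),
                         placeholder(cells$trb_v_gene),
                         placeholder(cells$trb_j_gene), sep = "|"),
    abort(sprintf("unknown clonotype strategy '%s'", strategy))
  )
}

#' Call clonotypes from per-cell receptor pairs
#'
#' Groups cells into clonotypes under the chosen key: `paired_nt` (both
#' CDR3 nucleotide sequences, the default), `paired_aa` (both CDR3 amino
#' acid sequences) or `paired_nt_vj` (nucleotide key plus V/J gene calls
#' of both chains). Clonotype ids are assigned in descending size, ties
#' broken by lexicographic key. By default cells lacking either chain are
#' excluded (and reported via the `excluded_barcodes` attribute); with
#' `require_both_chains = FALSE` the missing chain enters the key as a
#' placeholder.
#'
#' @param cells Receptor tibble from [pair_chains()].
#' @param strategy Clonotype key strategy.
#' @param require_both_chains Exclude cells lacking a TRA or TRB chain.
#' @return Tibble with `clonotype_id`, `key`, `size`, representative chain
#'   columns of the first member in barcode order, and a `barcodes`
#'   list-column. The `cell_map` attribute maps barcode to clonotype_id.
#' @export
call_clonotypes <- function(cells,
                            strategy = c("paired_nt", "paired_aa",
                                         "paired_nt_vj"),
                            require_both_chains = TRUE) {
  strategy <- match.arg(strategy)
  if (nrow(cells) == 0) {
    out <- tibble(clonotype_id = character(0), key = character(0),
                  size = integer(0), barcodes = list())
    attr(out, "cell_map") <- tibble(barcode = character(0),
                                    clonotype_id = character(0))
    attr(out, "excluded_barcodes") <- character(0)
    return(out)
  }
  if (require_both_chains) {
    has_both <- !is.na(cells$tra_cdr3_nt) & !is.na(cells$trb_cdr3_nt)
    excluded <- cells$barcode[!has_both]
    cells <- cells[has_both, , drop = FALSE]
  } else {
    has_any <- !is.na(cells$tra_cdr3_nt) | !is.na(cells$trb_cdr3_nt)
    excluded <- cells$barcode[!has_any]
    cells <- cells[has_any, , drop = FALSE]
  }
  cells$.key <- clonotype_key(cells, strategy)
  grouped <- cells |>
    arrange(.data$barcode) |>
    group_by(key = .data$.key) |>
    summarise(
      size = n(),
      barcodes = list(.data$barcode),
      tra_cdr3_nt = .data$tra_cdr3_nt[1], trb_cdr3_nt = .data$trb_cdr3_nt[1],
      tra_cdr3_aa = .data$tra_cdr3_aa[1], trb_cdr3_aa = .data$trb_cdr3_aa[1],
      tra_v_gene = .data$tra_v_gene[1], tra_j_gene = .data$tra_j_gene[1],
      trb_v_gene = .data$trb_v_gene[1], trb_j_gene = .data$trb_j_gene[1],
      .groups = "drop"
    ) |>
    arrange(desc(.data$size), .data$key) |>
    mutate(clonotype_id = paste0("clonotype", row_number())) |>
    select("clonotype_id", "key", "size", dplyr::everything())
  cell_map <- grouped |>
    select("clonotype_id", "barcodes") |>
    tidyr::unnest_longer("barcodes", values_to = "barcode") |>
    select("barcode", "clonotype_id")
  stopifnot(sum(grouped$size) == nrow(cells),
            !anyDuplicated(cell_map$barcode))
  attr(grouped, "cell_map") <- cell_map
  attr(grouped, "excluded_barcodes") <- excluded
  attr(grouped, "strategy") <- strategy
  grouped
}

majority_vote <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

consensus_one_chain <- function(seqs, barcodes, chain) {
  have <- nzchar(seqs) & !is.na(seqs)
  if (!any(have)) {
    abort(sprintf("export error: no member has any sequence for chain %s",
                  chain))
  }
  seqs <- seqs[have]
  barcodes <- barcodes[have]
  ord <- order(barcodes)
  seqs <- seqs[ord]
  lens <- nchar(seqs)
  len_tab <- table(lens)
  modal_len <- as.integer(names(len_tab)[len_tab == max(len_tab)])
  modal_len <- min(modal_len)
  used <- lens == modal_len
  mat <- do.call(rbind, strsplit(seqs[used], ""))
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else col[match(TRUE, col %in% top)]
  }, character(1))
  consensus <- paste(cons, collapse = "")
  list(consensus = consensus,
       n_members = length(have), n_with_seq = length(seqs),
       n_used = sum(used),
       match_fraction = mean(seqs[used] == consensus))
}

#' Consensus TRA/TRB sequences for a clonotype
#'
#' Per chain, takes the members' full-length nucleotide sequences (falling
#' back to the CDR3 nucleotide sequence when the full sequence is absent),
#' restricts to the modal length, and takes the per-position majority
#' base; positional ties resolve to the base of the first member in
#' barcode-sorted order. Reports the fraction of tallied members matching
#' the consensus exactly.
#'
#' @param clonotypes Clonotype table from [call_clonotypes()].
#' @param clonotype_id Id of the clonotype to summarise.
#' @param cells Receptor tibble from [pair_chains()].
#' @return Tibble with one row per chain: `chain`, `consensus_nt`,
#'   `consensus_aa`, `v_gene`, `j_gene`, `n_members`, `n_used`,
#'   `match_fraction`.
#' @export
consensus_sequences <- function(clonotypes, clonotype_id, cells) {
  row <- clonotypes[clonotypes$clonotype_id == clonotype_id, ]
  assert_that(nrow(row) == 1, paste("unknown clonotype:", clonotype_id))
  members <- cells[cells$barcode %in% row$barcodes[[1]], , drop = FALSE]
  assert_that(nrow(members) > 0, "clonotype has no member cells")
  out <- list()
  for (ch in c("tra", "trb")) {
    full <- members[[paste0(ch, "_full_nt")]]
    cdr3 <- members[[paste0(ch, "_cdr3_nt")]]
    seqs <- ifelse(is.na(full) | !nzchar(full),
                   ifelse(is.na(cdr3), "", cdr3), full)
    res <- consensus_one_chain(seqs, members$barcode, toupper(ch))
    nt <- res$consensus
    aa <- if (nchar(nt) %% 3 == 0) translate_nt(nt) else NA_character_
    out[[ch]] <- tibble(
      chain = toupper(ch),
      consensus_nt = nt,
      consensus_aa = aa,
      v_gene = majority_vote(members[[paste0(ch, "_v_gene")]]),
      j_gene = majority_vote(members[[paste0(ch, "_j_gene")]]),
      n_members = nrow(members),
      n_used = res$n_used,
      match_fraction = res$match_fraction
    )
  }
  bind_rows(out)
}

#' Export a clonotype table as TSV
#'
#' @param clonotypes Clonotype table from [call_clonotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(clonotypes, path) {
  flat <- clonotypes |> select(-"barcodes")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
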