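#' Pipeline parameters
#'
#' Collects every tunable stage parameter with its default. Unknown
#' parameter names are rejected.
#'
#' @param n_mads QC outlier threshold in MADs.
#' @param target_sum Normalisation target library size.
#' @param n_hvgs Highly variable genes retained.
#' @param n_pcs Principal components retained.
#' @param k_neighbors kNN graph neighbours.
#' @param resolutions Candidate clustering resolutions for the
#'   silhouette scan.
#' @param clonotype_strategy Clonotype key: "paired_nt", "paired_aa" or
#'   "paired_nt_vj".
#' @param min_subset_cells Floor for [subset_recluster()].
#' @param drop_multi_chain Also drop multi-TRA-and-TRB cells as doublets.
#' @param mito_gene_names Mitochondrial feature names for QC.
#' @param target_sample Sample whose cells are subset for selection.
#' @param compute_embedding Compute the 2-D embedding (disable for
#'   headless batch runs where only the selection matters).
#' @param seed Seed used by every stochastic stage.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(n_mads = 5, target_sum = 1e4, n_hvgs = 2000,
                            n_pcs = 30, k_neighbors = 15,
                            resolutions = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                            clonotype_strategy = "paired_nt",
                            min_subset_cells = 50,
                            drop_multi_chain = FALSE,
                            mito_gene_names = default_mito_genes(),
                            target_sample = "tet_pos_immunized",
                            compute_embedding = TRUE,
                            seed = 1) {
  if (n_mads <= 0) abort("n_mads must be > 0")
  list(n_mads = n_mads, target_sum = target_sum, n_hvgs = n_hvgs,
       n_pcs = n_pcs, k_neighbors = k_neighbors, resolutions = resolutions,
       clonotype_strategy = clonotype_strategy,
       min_subset_cells = min_subset_cells,
       drop_multi_chain = drop_multi_chain,
       mito_gene_names = mito_gene_names,
       target_sample = target_sample,
       compute_embedding = compute_embedding, seed = as.integer(seed))
}

#' Run the full clone-selection pipeline
#'
#' Chains every stage: QC (MAD outliers, doublet removal), normalisation,
#' clustering of the full dataset, contig filtering / chain pairing /
#' clonotype calling, clonotype attachment, subsetting to the target
#' (tetramer-positive) sample with reclustering, marker profiling,
#' expansion, gating, ranking, and consensus extraction for the selected
#' clone.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param cell_meta Per-cell metadata tibble (`barcode`, `sample`,
#'   `tetramer`, optionally `hash_tag`).
#' @param contigs Contig tibble (from [read_contigs()] or
#'   [generate_dataset()]).
#' @param criteria A [selection_criteria()]; defaults to
#'   [default_selection_criteria()].
#' @param params A [pipeline_params()] list.
#' @return A `clonepick_run` object: list with `full` and `subset` `tcx`
#'   objects, `receptors`, `clonotypes`, `expansion`, `profile`,
#'   `report`, `qc`, and `params`.
#' @export
run_pipeline <- function(counts, cell_meta, contigs,
                         criteria = default_selection_criteria(),
                         params = pipeline_params()) {
  # --- QC ---
  qc <- compute_qc(counts, params$mito_gene_names)
  qc <- flag_outliers(qc, n_mads = params$n_mads)
  cell_meta <- left_join(cell_meta, qc, by = "barcode")

  # --- V(D)J side ---
  kept_contigs <- filter_contigs(contigs)
  receptors <- pair_chains(kept_contigs)
  cell_meta <- left_join(
    cell_meta,
    receptors[, c("barcode", "multi_tra", "multi_trb")], by = "barcode")
  cell_meta$multi_tra[is.na(cell_meta$multi_tra)] <- FALSE
  cell_meta$multi_trb[is.na(cell_meta$multi_trb)] <- FALSE

  retained <- remove_doublets(cell_meta[!cell_meta$outlier, , drop = FALSE],
                              drop_multi_chain = params$drop_multi_chain)
  doublet_log <- attr(retained, "doublet_log")

  # --- expression side ---
  x <- tcx_experiment(counts[retained$barcode, , drop = FALSE], retained)
  x$normalized <- normalize_log(x$counts, params$target_sum)
  x <- cluster_expression(x, n_hvgs = params$n_hvgs, n_pcs = params$n_pcs,
                          k_neighbors = params$k_neighbors,
                          resolutions = params$resolutions,
                          seed = params$seed,
                          compute_embedding = params$compute_embedding)

  # --- clonotypes on retained cells ---
  clonotypes <- call_clonotypes(
    receptors[receptors$barcode %in% retained$barcode, , drop = FALSE],
    strategy = params$clonotype_strategy)
  x <- attach_clonotypes(x, clonotypes)

  # --- target subset, reclustered ---
  target <- params$target_sample
  in_target <- x$cells$sample == target
  sub <- subset_recluster(
    x, in_target, min_cells = params$min_subset_cells,
    n_hvgs = params$n_hvgs, n_pcs = params$n_pcs,
    k_neighbors = params$k_neighbors, resolutions = params$resolutions,
    seed = params$seed, compute_embedding = params$compute_embedding)

  # --- selection ---
  gate_genes <- c(names(criteria$positive), names(criteria$negative))
  profile <- marker_profile(sub, gate_genes,
                            min_cells = criteria$min_clone_size)
  expansion <- expansion_table(sub, by = "cluster")
  gates <- gate_clonotypes(profile, criteria)
  report <- rank_clonotypes(expansion, gates, criteria)
  report$provenance <- modifyList(report$provenance, list(
    seed = params$seed,
    params_hash = config_hash(params),
    n_cells_input = nrow(counts),
    n_cells_retained = nrow(retained),
    n_qc_outliers = sum(cell_meta$outlier),
    doublet_log = doublet_log,
    full_resolution = x$log$clustering$resolution,
    subset_resolution = sub$log$clustering$resolution
  ))
  consensus <- if (!is.na(report$selected)) {
    consensus_sequences(clonotypes, report$selected, receptors)
  } else {
    NULL
  }
  structure(
    list(full = x, subset = sub, receptors = receptors,
         clonotypes = clonotypes, expansion = expansion, profile = profile,
         report = report, consensus = consensus, qc = qc, params = params,
         criteria = criteria),
    class = "clonepick_run"
  )
}

#' @export
print.clonepick_run <- function(x, ...) {
  cat("<clonepick_run>\n")
  cat(sprintf("  full dataset: %d cells, %d clusters\n",
              nrow(x$full$counts), length(unique(x$full$cells$cluster))))
  cat(sprintf("  %s subset: %d cells, %d clusters\n",
              x$params$target_sample, nrow(x$subset$counts),
              length(unique(x$subset$cells$cluster))))
  cat(sprintf("  clonotypes: %d (largest %d cells)\n",
              nrow(x$clonotypes), max(x$clonotypes$size)))
  print(x$report)
  invisible(x)
}

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level keys `paths` (`expression_dir`, `contig_file`,
#' `output_dir`), `params` (any [pipeline_params()] argument) and
#' `criteria` (any [selection_criteria()] argument). Unknown keys are
#' rejected.
#'
#' @param path Path to the YAML config.
#' @return List with `paths`, `params`, `criteria`, `hash`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("config not found:", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("paths", "params", "criteria"))
  if (length(unknown) > 0) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  par_args <- cfg$params %||% list()
  bad <- setdiff(names(par_args), names(formals(pipeline_params)))
  if (length(bad) > 0) {
    abort(paste("unknown params key(s):", paste(bad, collapse = ", ")))
  }
  crit_args <- cfg$criteria %||% list()
  bad <- setdiff(names(crit_args), names(formals(selection_criteria)))
  if (length(bad) > 0) {
    abort(paste("unknown criteria key(s):", paste(bad, collapse = ", ")))
  }
  for (k in c("positive", "negative")) {
    if (!is.null(crit_args[[k]])) crit_args[[k]] <- unlist(crit_args[[k]])
  }
  params <- do.call(pipeline_params, par_args)
  criteria <- if (length(crit_args) > 0) {
    do.call(selection_criteria, crit_args)
  } else {
    default_selection_criteria()
  }
  list(paths = cfg$paths %||% list(), params = params, criteria = criteria,
       hash = config_hash(cfg))
}

#' Run the pipeline from files on disk
#'
#' Reads a 10x triplet directory and a contig file, runs
#' [run_pipeline()], and writes every artifact (QC report, cluster
#' assignments, clonotype table, expansion table, selection reports and
#' sequences, and a provenance record) into the output directory.
#' Partial outputs from a failed run are quarantined under `failed/`.
#'
#' @param config A config list from [read_run_config()].
#' @return The `clonepick_run` object, invisibly.
#' @export
run_pipeline_files <- function(config) {
  paths <- config$paths
  for (k in c("expression_dir", "contig_file", "output_dir")) {
    assert_that(!is.null(paths[[k]]), paste("config paths must set", k))
  }
  out_dir <- paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- tryCatch({
    tenx <- read_tenx(paths$expression_dir)
    assert_that(!is.null(tenx$cell_meta),
                "expression dir must include cell_metadata.tsv")
    contigs <- read_contigs(paths$contig_file)
    run_pipeline(tenx$counts, tenx$cell_meta, contigs,
                 criteria = config$criteria, params = config$params)
  }, error = function(e) {
    quarantine <- file.path(out_dir, "failed")
    dir.create(quarantine, showWarnings = FALSE, recursive = TRUE)
    existing <- setdiff(list.files(out_dir, full.names = TRUE),
                        quarantine)
    file.copy(existing, quarantine, recursive = TRUE)
    unlink(existing, recursive = TRUE)
    writeLines(conditionMessage(e), file.path(quarantine, "error.txt"))
    abort(paste("pipeline failed; partial outputs quarantined under failed/:",
                conditionMessage(e)))
  })
  write_run_artifacts(run, out_dir, config)
  invisible(run)
}

write_run_artifacts <- function(run, out_dir, config) {
  readr::write_tsv(run$qc, file.path(out_dir, "qc_report.tsv"))
  readr::write_tsv(run$full$cells[, intersect(
    c("barcode", "sample", "tetramer", "cluster", "dim1", "dim2",
      "clonotype_id"), names(run$full$cells))],
    file.path(out_dir, "clusters_full.tsv"))
  readr::write_tsv(run$subset$cells[, intersect(
    c("barcode", "cluster_full", "cluster", "dim1", "dim2", "clonotype_id"),
    names(run$subset$cells))],
    file.path(out_dir, "clusters_subset.tsv"))
  write_clonotypes(run$clonotypes, file.path(out_dir, "clonotypes.tsv"))
  readr::write_tsv(run$expansion, file.path(out_dir, "expansion.tsv"))
  readr::write_tsv(run$profile, file.path(out_dir, "marker_profile.tsv"))
  export_selection(run$report, run$clonotypes, run$receptors, out_dir,
                   provenance = list(config_hash = config$hash))
  checksums <- list()
  for (k in c("contig_file")) {
    f <- config$paths[[k]]
    if (!is.null(f) && file.exists(f)) {
      checksums[[k]] <- unname(tools::md5sum(f))
    }
  }
  provenance <- list(
    config_hash = config$hash,
    seed = run$params$seed,
    package_version = as.character(utils::packageVersion("clonepick")),
    input_checksums = checksums,
    effective_params = run$params,
    selected = run$report$selected
  )
  jsonlite::write_json(provenance, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(out_dir)
}
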