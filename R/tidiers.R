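#' Tidy an experiment container into a per-cell tibble
#'
#' @param x A `tcx`.
#' @param ... Unused.
#' @return The per-cell metadata tibble (one row per cell).
#' @method tidy tcx
#' @export
tidy.tcx <- function(x, ...) {
  as_tibble(x$cells)
}

#' One-row summary of an experiment container
#'
#' @param x A `tcx`.
#' @param ... Unused.
#' @return Tibble with cell/gene/cluster/clonotype counts.
#' @method glance tcx
#' @export
glance.tcx <- function(x, ...) {
  tibble(
    n_cells = nrow(x$counts),
    n_genes = ncol(x$counts),
    n_clusters = if ("cluster" %in% names(x$cells)) {
      length(unique(x$cells$cluster))
    } else {
      NA_integer_
    },
    n_clonotypes = if (!is.null(x$clonotypes)) nrow(x$clonotypes) else NA_integer_,
    resolution = x$log$clustering$resolution %||% NA_real_,
    silhouette = x$log$clustering$silhouette %||% NA_real_
  )
}

#' Tidy a selection report into its ranking table
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return The ranking tibble, one row per clonotype.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  x$ranking
}

#' One-row summary of a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return Tibble with the selected clonotype and eligibility counts.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  sel <- x$ranking[match(x$selected, x$ranking$clonotype_id), ]
  tibble(
    selected = x$selected,
    selected_size = if (nrow(sel) == 1) sel$size else NA_integer_,
    selected_frequency = if (nrow(sel) == 1) sel$frequency else NA_real_,
    n_ranked = nrow(x$ranking),
    n_eligible = sum(x$ranking$eligible)
  )
}

#' Tidy a full pipeline run
#'
#' @param x A `clonepick_run`.
#' @param ... Unused.
#' @return The selection ranking tibble.
#' @method tidy clonepick_run
#' @export
tidy.clonepick_run <- function(x, ...) {
  tidy(x$report)
}

#' One-row summary of a full pipeline run
#'
#' @param x A `clonepick_run`.
#' @param ... Unused.
#' @return Tibble combining dataset, clustering and selection summaries.
#' @method glance clonepick_run
#' @export
glance.clonepick_run <- function(x, ...) {
  tibble(
    n_cells_retained = nrow(x$full$counts),
    n_clusters_full = length(unique(x$full$cells$cluster)),
    n_cells_subset = nrow(x$subset$counts),
    n_clusters_subset = length(unique(x$subset$cells$cluster)),
    n_clonotypes = nrow(x$clonotypes),
    shannon = diversity(x$expansion, "shannon"),
    gini = diversity(x$expansion, "gini"),
    d50 = diversity(x$expansion, "d50"),
    selected = x$report$selected
  )
}
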