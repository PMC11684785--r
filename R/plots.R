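#' Plot the 2-D embedding of an experiment
#'
#' @param object A `tcx` with an embedding.
#' @param colour_by Cell metadata column used for colour (default
#'   `cluster`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcx
#' @export
autoplot.tcx <- function(object, colour_by = "cluster", ...) {
  assert_that(!is.null(object$embedding), "no embedding computed yet")
  assert_that(colour_by %in% names(object$cells),
              sprintf("no '%s' column in cell metadata", colour_by))
  df <- object$cells
  df$.colour <- factor(df[[colour_by]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$.colour)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Highlight one clonotype on the embedding
#'
#' @param x A `tcx` with clonotypes attached and an embedding.
#' @param clonotype_id Clonotype to highlight.
#' @return A ggplot object.
#' @export
plot_clonotype_projection <- function(x, clonotype_id) {
  assert_that(!is.null(x$embedding), "no embedding computed yet")
  df <- x$cells
  df$highlight <- df$clonotype_id == clonotype_id
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(data = df[!df$highlight, ], colour = "grey80",
                        size = 0.6) +
    ggplot2::geom_point(data = df[df$highlight, ], colour = "firebrick",
                        size = 1.2) +
    ggplot2::labs(title = clonotype_id, x = "dimension 1",
                  y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Stacked clonotype-frequency plot per group
#'
#' Shows, per cluster (or sample), the share of cells taken by the
#' largest clonotypes versus the rest.
#'
#' @param expansion Expansion table from [expansion_table()].
#' @param top_n Clonotypes drawn individually; smaller ones are pooled.
#' @return A ggplot object.
#' @export
plot_expansion <- function(expansion, top_n = 10) {
  group_cols <- attr(expansion, "group_cols")
  long <- expansion |>
    mutate(clone = ifelse(row_number() <= top_n, .data$clonotype_id,
                          "other")) |>
    tidyr::pivot_longer(all_of(group_cols), names_to = "group",
                        values_to = "n") |>
    mutate(group = sub("^n_", "", .data$group)) |>
    group_by(.data$group, .data$clone) |>
    summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$n,
                                     fill = .data$clone)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = attr(expansion, "by"), y = "fraction of cells",
                  fill = "clonotype") +
    ggplot2::theme_minimal()
}

#' Marker dot plot per clonotype
#'
#' Dot size encodes the detection fraction, colour the mean normalised
#' expression — the standard way "+"/"-" marker calls are read off.
#'
#' @param profile Marker profile from [marker_profile()].
#' @return A ggplot object.
#' @export
plot_markers <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$gene,
                                        y = .data$clonotype_id)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$det_fraction,
                                     colour = .data$mean_norm)) +
    ggplot2::scale_size_area(max_size = 6, limits = c(0, 1)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, size = "detected",
                  colour = "mean expr") +
    ggplot2::theme_minimal()
}

#' Plot a selection report's ranking
#'
#' @param object A `selection_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- object$ranking |> filter(.data$eligible)
  if (nrow(df) == 0) {
    abort("no eligible clonotype to plot")
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$clonotype_id, .data$score),
    y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composite score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
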