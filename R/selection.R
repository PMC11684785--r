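#' Clone-selection criteria
#'
#' Operationalises the qualitative "+"/"-" marker calls used to pick a
#' clone for transgenesis as detection-fraction gates: a positive gate
#' passes when the clonotype's detection fraction for the gene is at or
#' above its threshold; a negative gate when at or below.
#'
#' @param positive Positive markers: character vector (default threshold
#'   0.5) or named numeric vector of per-gene thresholds.
#' @param negative Negative markers: character vector (default threshold
#'   0.1) or named numeric vector.
#' @param min_clone_size Smallest clonotype considered (>= 2).
#' @param restrict_to_clusters Optional integer cluster set; a clonotype
#'   is eligible only if the majority of its cells lie in these clusters.
#' @param expansion_weight Weight of the expansion term in the composite
#'   score, in [0, 1]; the remainder weighs the mean gate margin. The
#'   default 1 makes the gates hard filters with expansion deciding among
#'   eligible clones — the lexicographic "expanded AND phenotype-positive"
#'   rule. Weights below 1 trade expansion rank against how far inside
#'   the gates a clone sits, which lets sampling noise in the margins
#'   override large expansion differences between clones of similar rank;
#'   use them only when near-threshold phenotype strength genuinely
#'   matters more than expansion.
#' @return A `selection_criteria` object.
#' @export
selection_criteria <- function(positive = character(0),
                               negative = character(0),
                               min_clone_size = 3,
                               restrict_to_clusters = NULL,
                               expansion_weight = 1) {
  as_thresholds <- function(x, default) {
    if (is.numeric(x)) {
      assert_that(!is.null(names(x)), "numeric marker thresholds must be named")
      x
    } else {
      setNames(rep(default, length(x)), x)
    }
  }
  positive <- as_thresholds(positive, 0.5)
  negative <- as_thresholds(negative, 0.1)
  assert_that(all(c(positive, negative) >= 0 & c(positive, negative) <= 1),
              "thresholds must lie in [0, 1]")
  assert_that(min_clone_size >= 2, "min_clone_size must be >= 2")
  assert_that(expansion_weight >= 0 && expansion_weight <= 1,
              "expansion_weight must lie in [0, 1]")
  structure(
    list(positive = positive, negative = negative,
         min_clone_size = as.integer(min_clone_size),
         restrict_to_clusters = restrict_to_clusters,
         expansion_weight = expansion_weight),
    class = "selection_criteria"
  )
}

#' The default activated/memory-capable marker gate set
#'
#' Requires proliferation (Mki67+), cytokine production (Ifng+),
#' activation (Cd69+) and memory potential (Tcf7+, Sell-).
#'
#' @param ... Overrides passed to [selection_criteria()].
#' @return A `selection_criteria` object.
#' @export
default_selection_criteria <- function(...) {
  selection_criteria(
    positive = c("Mki67", "Ifng", "Cd69", "Tcf7"),
    negative = "Sell",
    ...
  )
}

#' Gate clonotypes on marker detection fractions
#'
#' Evaluates every positive and negative marker gate of `criteria`
#' against a clonotype marker profile. Margins measure how far inside
#' the gate a clonotype sits (clipped to [0, 1]).
#'
#' @param profiles Marker profile from [marker_profile()].
#' @param criteria A [selection_criteria()].
#' @return Long tibble: `clonotype_id`, `gene`, `direction`, `threshold`,
#'   `det_fraction`, `pass`, `margin`.
#' @export
gate_clonotypes <- function(profiles, criteria) {
  gates <- bind_rows(
    tibble(gene = names(criteria$positive), direction = "positive",
           threshold = unname(criteria$positive)),
    tibble(gene = names(criteria$negative), direction = "negative",
           threshold = unname(criteria$negative))
  )
  assert_that(nrow(gates) > 0, "criteria define no marker gates")
  absent <- setdiff(gates$gene, unique(profiles$gene))
  if (length(absent) > 0) {
    abort(paste("criteria reference gene(s) absent from the profile:",
                paste(absent, collapse = ", ")))
  }
  out <- profiles |>
    dplyr::inner_join(gates, by = "gene") |>
    mutate(
      pass = ifelse(.data$direction == "positive",
                    .data$det_fraction >= .data$threshold,
                    .data$det_fraction <= .data$threshold),
      margin = pmin(pmax(ifelse(.data$direction == "positive",
                                .data$det_fraction - .data$threshold,
                                .data$threshold - .data$det_fraction),
                         0), 1)
    ) |>
    select("clonotype_id", "gene", "direction", "threshold",
           "det_fraction", "pass", "margin") |>
    arrange(.data$clonotype_id, desc(.data$direction), .data$gene)
  attr(out, "criteria") <- criteria
  out
}

#' Rank gated clonotypes and select a clone
#'
#' Eligible clonotypes (all gates passed, size at least
#' `min_clone_size`, and — when `restrict_to_clusters` is set — a
#' majority of cells in the allowed clusters) are scored as
#' `expansion_weight * frequency percentile + (1 - expansion_weight) *
#' mean gate margin` and ranked by decreasing score; ties go to the
#' larger clone, then to the lexicographically smaller id. Ineligible
#' clonotypes are listed below all eligible ones, ordered by size. The
#' top-ranked eligible clonotype is selected; when none is eligible the
#' report says so and selects nothing.
#'
#' @param expansion Expansion table from [expansion_table()].
#' @param gates Gate results from [gate_clonotypes()].
#' @param criteria The [selection_criteria()] used for the gates.
#' @return A `selection_report` object: list with `ranking` (tibble),
#'   `selected` (clonotype_id or `NA`), `gates`, `criteria`,
#'   `provenance`.
#' @export
rank_clonotypes <- function(expansion, gates, criteria) {
  gate_summary <- gates |>
    group_by(.data$clonotype_id) |>
    summarise(gates_passed = all(.data$pass),
              n_gates_failed = sum(!.data$pass),
              gate_margin = mean(.data$margin), .groups = "drop")
  n_clones <- nrow(expansion)
  ranking <- expansion |>
    mutate(freq_percentile = rank(.data$frequency, ties.method = "average") /
             n_clones) |>
    left_join(gate_summary, by = "clonotype_id")
  # clones too small for a profile carry no gate rows: ineligible
  ranking$gates_passed[is.na(ranking$gates_passed)] <- FALSE
  ranking$gate_margin[is.na(ranking$gate_margin)] <- 0
  ranking$n_gates_failed[is.na(ranking$n_gates_failed)] <- NA_integer_

  ranking$eligible <- ranking$gates_passed &
    ranking$size >= criteria$min_clone_size
  reason <- ifelse(!ranking$gates_passed,
                   ifelse(is.na(ranking$n_gates_failed), "no marker profile",
                          paste0(ranking$n_gates_failed, " gate(s) failed")),
                   "")
  reason <- ifelse(ranking$size < criteria$min_clone_size,
                   trimws(paste(reason, "below min_clone_size")), reason)
  if (!is.null(criteria$restrict_to_clusters)) {
    allowed_cols <- paste0("n_", criteria$restrict_to_clusters)
    present <- intersect(allowed_cols, names(ranking))
    in_allowed <- if (length(present) > 0) {
      rowSums(ranking[, present, drop = FALSE])
    } else {
      rep(0, nrow(ranking))
    }
    ok <- in_allowed > ranking$size / 2
    reason <- ifelse(ranking$eligible & !ok, "outside restricted clusters",
                     reason)
    ranking$eligible <- ranking$eligible & ok
  }
  ranking$reason <- reason
  w <- criteria$expansion_weight
  ranking$score <- ifelse(
    ranking$eligible,
    w * ranking$freq_percentile + (1 - w) * ranking$gate_margin,
    NA_real_)
  eligible <- ranking |>
    filter(.data$eligible) |>
    arrange(desc(.data$score), desc(.data$size), .data$clonotype_id)
  ineligible <- ranking |>
    filter(!.data$eligible) |>
    arrange(desc(.data$size), .data$clonotype_id)
  ranked <- bind_rows(eligible, ineligible) |>
    mutate(rank = row_number()) |>
    select("rank", "clonotype_id", "size", "frequency", "freq_percentile",
           "gate_margin", "eligible", "score", "reason",
           dplyr::starts_with("n_"))
  selected <- if (nrow(eligible) > 0) eligible$clonotype_id[1] else NA_character_
  structure(
    list(ranking = ranked, selected = selected, gates = gates,
         criteria = criteria,
         provenance = list(n_clonotypes = n_clones,
                           expansion_by = attr(expansion, "by"))),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  if (is.na(x$selected)) {
    cat("  no clonotype passes all gates\n")
  } else {
    top <- x$ranking[x$ranking$clonotype_id == x$selected, ]
    cat(sprintf("  selected: %s (size %d, frequency %.3f, score %.3f)\n",
                x$selected, top$size, top$frequency, top$score))
  }
  cat(sprintf("  %d clonotypes ranked, %d eligible\n",
              nrow(x$ranking), sum(x$ranking$eligible)))
  invisible(x)
}

sali_site <- "GTCGAC"

write_fasta <- function(headers, seqs, path) {
  stopifnot(length(headers) == length(seqs))
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", headers[i]), seqs[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export the selected clonotype's sequences and reports
#'
#' Writes `selected_tcr.fasta` (consensus TRA/TRB nucleotide sequences)
#' and `selected_tcr_aa.fasta` (translations), a human-readable
#' `selection.md` and a machine-readable `selection.json` with the full
#' ranking, gates, criteria and provenance. Warns — in both reports and
#' as an R warning — when a consensus sequence contains a SalI
#' recognition site (GTCGAC), which would interfere with SalI-based
#' cloning of the synthesis fragment. When nothing was selected, the
#' diagnostic reports are still written but no sequences are exported.
#'
#' @param report A [rank_clonotypes()] selection report.
#' @param clonotypes Clonotype table from [call_clonotypes()].
#' @param cells Receptor tibble from [pair_chains()].
#' @param out_dir Output directory (created if needed).
#' @param provenance Optional named list merged into the report
#'   provenance (e.g. seed, config hash).
#' @return Invisibly, the consensus tibble (or `NULL` when nothing was
#'   selected).
#' @export
export_selection <- function(report, clonotypes, cells, out_dir,
                             provenance = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- modifyList(report$provenance, provenance)
  warnings_out <- character(0)
  consensus <- NULL
  if (!is.na(report$selected)) {
    consensus <- consensus_sequences(clonotypes, report$selected, cells)
    hits <- consensus$chain[grepl(sali_site, consensus$consensus_nt, fixed = TRUE)]
    if (length(hits) > 0) {
      msg <- sprintf(
        "SalI recognition site (%s) found in consensus %s sequence(s); SalI-based cloning will cut inside the insert",
        sali_site, paste(hits, collapse = ", "))
      warn(msg)
      warnings_out <- c(warnings_out, msg)
    }
    headers <- sprintf("%s_%s %s %s match_fraction=%.3f",
                       report$selected, consensus$chain, consensus$v_gene,
                       consensus$j_gene, consensus$match_fraction)
    write_fasta(headers, consensus$consensus_nt,
                file.path(out_dir, "selected_tcr.fasta"))
    write_fasta(paste0(headers, " aa"), consensus$consensus_aa,
                file.path(out_dir, "selected_tcr_aa.fasta"))
  }
  json <- list(
    selected = if (is.na(report$selected)) NULL else report$selected,
    ranking = report$ranking,
    gates = report$gates,
    criteria = list(
      positive = as.list(report$criteria$positive),
      negative = as.list(report$criteria$negative),
      min_clone_size = report$criteria$min_clone_size,
      restrict_to_clusters = report$criteria$restrict_to_clusters,
      expansion_weight = report$criteria$expansion_weight
    ),
    consensus = consensus,
    warnings = warnings_out,
    provenance = prov
  )
  jsonlite::write_json(json, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  md <- c(
    "# Clonotype selection report", "",
    if (is.na(report$selected)) {
      "**No clonotype passed all gates.** See the ranking below for per-gate diagnostics."
    } else {
      sprintf("**Selected clonotype:** %s", report$selected)
    }, "",
    if (length(warnings_out)) c("## Warnings", paste("-", warnings_out), ""),
    "## Ranking", "",
    paste(utils::capture.output(print(as.data.frame(
      report$ranking[, c("rank", "clonotype_id", "size", "frequency",
                         "eligible", "score", "reason")]
    ), row.names = FALSE)), collapse = "\n")
  )
  writeLines(unlist(md), file.path(out_dir, "selection.md"))
  invisible(consensus)
}
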