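#' Define a phenotype program for the synthetic generator
#'
#' A phenotype program is a named expression state (e.g. naive, effector)
#' defined by multiplicative shifts on a set of marker genes over a shared
#' negative-binomial baseline.
#'
#' @param name Program label, unique within a scenario.
#' @param marker_means Named numeric vector mapping gene name to a strictly
#'   positive mean-expression multiplier.
#' @param baseline_mean Mean counts per gene for unlisted genes (counts).
#' @param dispersion Negative-binomial size parameter (inverse dispersion,
#'   larger = less overdispersed). Must be > 0.
#' @return A `phenotype_program` list.
#' @export
#' @examples
#' phenotype_program("naive", c(Sell = 4, Tcf7 = 3))
phenotype_program <- function(name, marker_means, baseline_mean = 2,
                              dispersion = 2) {
  assert_that(is.character(name) && length(name) == 1L, "name must be a single string")
  assert_that(length(marker_means) > 0 && !is.null(names(marker_means)),
              "marker_means must be a named numeric vector")
  assert_that(all(marker_means > 0), "marker multipliers must be strictly positive")
  assert_that(baseline_mean > 0, "baseline_mean must be > 0")
  assert_that(dispersion > 0, "dispersion must be > 0")
  structure(
    list(name = name, marker_means = marker_means,
         baseline_mean = baseline_mean, dispersion = dispersion),
    class = "phenotype_program"
  )
}

#' Define a planted clone for the synthetic generator
#'
#' @param clone_id Clone label (e.g. "C1").
#' @param n_cells Number of cells carrying this clone's receptor.
#' @param program_weights Named numeric vector of probabilities over program
#'   names; must sum to 1.
#' @param tra,trb Chain descriptions: lists with elements `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `full_nt`. `cdr3_nt` must be in frame (length
#'   divisible by 3) and `cdr3_aa` its standard-genetic-code translation.
#'   Use [random_tcr_chain()] to draw one.
#' @param sample Sample the clone's cells belong to.
#' @return A `clone_plan` list.
#' @export
clone_plan <- function(clone_id, n_cells, program_weights, tra, trb,
                       sample = "tet_pos_immunized") {
  assert_that(n_cells >= 1, "n_cells must be positive")
  assert_that(abs(sum(program_weights) - 1) < 1e-8,
              "program_weights must sum to 1")
  for (ch in list(tra, trb)) {
    assert_that(nchar(ch$cdr3_nt) %% 3 == 0,
                "cdr3_nt length must be divisible by 3")
    assert_that(identical(translate_nt(ch$cdr3_nt), ch$cdr3_aa),
                "cdr3_aa must be the translation of cdr3_nt")
  }
  structure(
    list(clone_id = clone_id, n_cells = as.integer(n_cells),
         program_weights = program_weights, tra = tra, trb = trb,
         sample = sample),
    class = "clone_plan"
  )
}

# codons of the standard genetic code minus the three stop codons
non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

random_codons <- function(n) {
  paste(sample(non_stop_codons(), n, replace = TRUE), collapse = "")
}

#' Draw a random TCR chain description
#'
#' Generates an in-frame random CDR3 nucleotide string, its translation, a
#' longer in-frame full-length sequence containing the CDR3, and V/J gene
#' labels from a small fixed mouse-like vocabulary. The labels are opaque:
#' no germline recombination is simulated because downstream logic only
#' tests sequence equality.
#'
#' @param chain "TRA" or "TRB".
#' @return A list with `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `full_nt`.
#' @export
random_tcr_chain <- function(chain = c("TRA", "TRB")) {
  chain <- match.arg(chain)
  if (chain == "TRA") {
    v <- sprintf("TRAV%d", sample(1:14, 1))
    j <- sprintf("TRAJ%d", sample(1:30, 1))
    n_cod <- sample(4:6, 1)
  } else {
    v <- sprintf("TRBV%d", sample(1:19, 1))
    j <- sprintf("TRBJ%d-%d", sample(1:2, 1), sample(1:6, 1))
    n_cod <- sample(4:7, 1)
  }
  cdr3 <- random_codons(n_cod)
  full <- paste0(random_codons(20), cdr3, random_codons(12))
  list(v_gene = v, j_gene = j, cdr3_nt = cdr3,
       cdr3_aa = translate_nt(cdr3), full_nt = full)
}

scenario_samples <- c("tet_pos_immunized", "tet_neg_immunized", "naive")

#' Assemble a synthetic-data scenario configuration
#'
#' A scenario fixes everything the generator needs: sample sizes, phenotype
#' programs, planted clones, background program mixtures per sample, the
#' fraction of non-clone cells that carry unique receptors, mitochondrial
#' gene names, planted QC outliers and the seed. Generation is a pure
#' function of the configuration.
#'
#' @param n_cells_per_sample Named integer vector over the samples
#'   `tet_pos_immunized`, `tet_neg_immunized`, `naive`.
#' @param programs List of [phenotype_program()] objects.
#' @param clones List of [clone_plan()] objects.
#' @param background_weights Named list mapping sample name to a named
#'   probability vector over programs, used for non-clone cells.
#' @param singleton_fraction Fraction of non-clone cells that carry a unique
#'   random receptor; the remainder get no V(D)J contigs (receptor dropout).
#' @param mito_gene_names Mitochondrial gene names included in the panel.
#' @param n_qc_outliers Planted outlier cells per class (`low_size`,
#'   `high_mito`).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param n_background_genes Number of unstructured background genes.
#' @param marker_off_multiplier Multiplier applied to a gene that is a marker
#'   of some program in programs that do not list it (the "off" state).
#' @param n_hash_doublets Cells planted with two sample hashing tags
#'   (simulated multiplexing doublets); 0 by default.
#' @param genes Optional explicit gene panel; must contain every program
#'   marker gene and every mitochondrial gene.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_cells_per_sample, programs, clones,
                            background_weights,
                            singleton_fraction = 0.8,
                            mito_gene_names = default_mito_genes(),
                            n_qc_outliers = 0, seed = 1,
                            n_background_genes = 120,
                            marker_off_multiplier = 0.03,
                            n_hash_doublets = 0,
                            genes = NULL) {
  assert_that(all(names(n_cells_per_sample) %in% scenario_samples),
              paste("sample names must be drawn from:",
                    paste(scenario_samples, collapse = ", ")))
  assert_that(all(n_cells_per_sample > 0), "cell counts must be positive")
  prog_names <- vapply(programs, `[[`, character(1), "name")
  assert_that(!anyDuplicated(prog_names), "program names must be unique")
  names(programs) <- prog_names
  for (cl in clones) {
    assert_that(all(names(cl$program_weights) %in% prog_names),
                sprintf("clone %s references unknown program", cl$clone_id))
    assert_that(cl$sample %in% names(n_cells_per_sample),
                sprintf("clone %s placed in unknown sample", cl$clone_id))
  }
  for (s in names(background_weights)) {
    assert_that(all(names(background_weights[[s]]) %in% prog_names),
                "background_weights references unknown program")
    assert_that(abs(sum(background_weights[[s]]) - 1) < 1e-8,
                "background_weights must sum to 1 per sample")
  }
  marker_genes <- unique(unlist(lapply(programs, function(p) names(p$marker_means))))
  if (is.null(genes)) {
    genes <- c(marker_genes, mito_gene_names,
               sprintf("Gene%03d", seq_len(n_background_genes)))
  } else {
    missing <- setdiff(c(marker_genes, mito_gene_names), genes)
    if (length(missing) > 0) {
      abort(paste0("configuration error: genes absent from panel: ",
                   paste(missing, collapse = ", ")))
    }
  }
  assert_that(!anyDuplicated(genes), "gene panel contains duplicates")
  structure(
    list(n_cells_per_sample = n_cells_per_sample, programs = programs,
         clones = clones, background_weights = background_weights,
         singleton_fraction = singleton_fraction,
         mito_gene_names = mito_gene_names,
         n_qc_outliers = as.integer(n_qc_outliers), seed = as.integer(seed),
         marker_off_multiplier = marker_off_multiplier,
         n_hash_doublets = as.integer(n_hash_doublets),
         genes = genes, marker_genes = marker_genes),
    class = "scenario_config"
  )
}

default_mito_genes <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
    "mt-Atp6", "mt-Cytb", "mt-Nd4")
}

#' The canonical CD8 immunization scenario
#'
#' Emulates the three sorted samples of a spike-immunization experiment:
#' CD8+ tetramer-positive cells from an immunized mouse, CD8+
#' tetramer-negative cells from an immunized mouse, and total CD8 T cells
#' from a naive mouse. Four phenotype programs (naive, memory-like,
#' effector, proliferating effector) structure the expression space; the
#' tetramer-positive sample draws only from the memory/effector/
#' proliferating programs and carries one dominant clone "C1" (40% of its
#' cells) split across the two activated programs, plus smaller clones and
#' a singleton background. 2% of cells are planted QC outliers.
#'
#' @param seed Integer seed; structure is identical across seeds, receptor
#'   draws differ.
#' @return A [scenario_config()].
#' @export
#' @examples
#' cfg <- default_cd8_scenario(seed = 1)
#' names(cfg$programs)
default_cd8_scenario <- function(seed = 1) {
  effector_core <- c(Ifng = 4, Cd69 = 3, Nr4a1 = 3, Gzmb = 5, Cd44 = 3,
                     Tcf7 = 1.5, Klrg1 = 4, Cx3cr1 = 4, Id2 = 3, Prf1 = 4,
                     Ccl5 = 4, Mki67 = 0.5)
  programs <- list(
    phenotype_program("naive",
      c(Sell = 4, Tcf7 = 3, Lef1 = 4, Ccr7 = 4, Bach2 = 3, Il7r = 3)),
    phenotype_program("memory",
      c(Cd44 = 4, Tcf7 = 2.5, Il7r = 3, Bcl2 = 4, Cxcr3 = 4, Eomes = 3)),
    phenotype_program("effector", effector_core),
    phenotype_program("prolif_effector",
      c(effector_core[setdiff(names(effector_core), "Mki67")],
        Mki67 = 5, Bhlhe40 = 3, Tbx21 = 3, Top2a = 5, Ccnb1 = 4,
        Birc5 = 4, Stmn1 = 4))
  )
  clones <- with_seed(seed, {
    specs <- list(
      list(id = "C1", n = 400, w = c(effector = 0.5, prolif_effector = 0.5)),
      list(id = "C2", n = 80,  w = c(effector = 0.6, prolif_effector = 0.4)),
      list(id = "C3", n = 40,  w = c(memory = 0.7, effector = 0.3)),
      list(id = "C4", n = 20,  w = c(effector = 1)),
      list(id = "C5", n = 10,  w = c(memory = 1))
    )
    lapply(specs, function(s) {
      clone_plan(s$id, s$n, s$w,
                 tra = random_tcr_chain("TRA"),
                 trb = random_tcr_chain("TRB"))
    })
  })
  scenario_config(
    n_cells_per_sample = c(tet_pos_immunized = 1000,
                           tet_neg_immunized = 1000, naive = 1000),
    programs = programs,
    clones = clones,
    background_weights = list(
      tet_pos_immunized = c(effector = 0.4, prolif_effector = 0.3, memory = 0.3),
      tet_neg_immunized = c(naive = 0.5, memory = 0.3, effector = 0.2),
      naive = c(naive = 0.8, memory = 0.2)
    ),
    singleton_fraction = 0.8,
    n_qc_outliers = 30,
    seed = seed
  )
}

# per-program mean vector over the gene panel
program_means <- function(config, program) {
  p <- config$programs[[program]]
  mu <- rep(p$baseline_mean, length(config$genes))
  names(mu) <- config$genes
  off <- setdiff(config$marker_genes, names(p$marker_means))
  mu[off] <- p$baseline_mean * config$marker_off_multiplier
  mu[names(p$marker_means)] <- p$baseline_mean * p$marker_means
  mu
}

#' Generate a paired expression + V(D)J dataset from a scenario
#'
#' Each cell is assigned exactly one sample and one phenotype program (from
#' its clone's program weights, or the sample's background mixture).
#' Counts are negative-binomial with program multipliers applied to marker
#' genes. Every clone or singleton cell carries exactly one TRA and one TRB
#' contig; singleton cells get unique random CDR3s; the remaining
#' "background" cells carry no contigs (receptor dropout). Planted QC
#' outliers have their library thinned to 5% (`low_size`) or their
#' mitochondrial fraction raised to at least 0.5 (`high_mito`).
#'
#' @param config A [scenario_config()].
#' @return A list with `counts` (sparse cells x genes integer matrix,
#'   dimnames barcode x gene), `cell_meta` (tibble: barcode, sample,
#'   tetramer, hash_tag, program, clone_id, planted_outlier), `contigs`
#'   (tibble of contig records), and `config`.
#' @export
#' @examples
#' cfg <- default_cd8_scenario(seed = 1)
#' sim <- generate_dataset(cfg)
#' dim(sim$counts)
generate_dataset <- function(config) {
  assert_that(inherits(config, "scenario_config"),
              "config must be a scenario_config")
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  samples <- names(config$n_cells_per_sample)
  plan <- list()
  for (s in samples) {
    n_total <- config$n_cells_per_sample[[s]]
    cls <- Filter(function(cl) cl$sample == s, config$clones)
    n_clone <- sum(vapply(cls, `[[`, integer(1), "n_cells"))
    assert_that(n_clone <= n_total,
                sprintf("clones exceed sample size for %s", s))
    n_rest <- n_total - n_clone
    n_single <- round(config$singleton_fraction * n_rest)
    n_bg <- n_rest - n_single
    rows <- list()
    for (cl in cls) {
      rows[[length(rows) + 1L]] <-
        tibble(sample = s, clone_id = cl$clone_id,
               receptor = "clone", n = cl$n_cells)
    }
    rows[[length(rows) + 1L]] <-
      tibble(sample = s, clone_id = NA_character_,
             receptor = c("singleton", "none"), n = c(n_single, n_bg))
    plan[[s]] <- bind_rows(rows)
  }
  plan <- bind_rows(plan) |> filter(.data$n > 0)
  cells <- plan[rep(seq_len(nrow(plan)), plan$n), c("sample", "clone_id", "receptor")]
  n_cells <- nrow(cells)
  cells$barcode <- sprintf("CELL%05d-1", seq_len(n_cells))
  if (anyDuplicated(cells$barcode)) abort("internal error: duplicate barcode")

  # program assignment: clone weights, or sample background mixture
  prog <- character(n_cells)
  for (cl in config$clones) {
    idx <- which(!is.na(cells$clone_id) & cells$clone_id == cl$clone_id)
    prog[idx] <- sample(names(cl$program_weights), length(idx),
                        replace = TRUE, prob = cl$program_weights)
  }
  for (s in samples) {
    idx <- which(cells$sample == s & is.na(cells$clone_id))
    bw <- config$background_weights[[s]]
    prog[idx] <- sample(names(bw), length(idx), replace = TRUE, prob = bw)
  }
  cells$program <- prog

  # NB counts, drawn per program block
  genes <- config$genes
  counts <- matrix(0L, nrow = n_cells, ncol = length(genes),
                   dimnames = list(cells$barcode, genes))
  for (p in names(config$programs)) {
    idx <- which(cells$program == p)
    if (length(idx) == 0) next
    mu <- program_means(config, p)
    disp <- config$programs[[p]]$dispersion
    block <- rnbinom(length(idx) * length(genes), size = disp,
                     mu = rep(mu, each = length(idx)))
    counts[idx, ] <- matrix(as.integer(block), nrow = length(idx))
  }

  # planted QC outliers, disjoint cell sets per class
  cells$planted_outlier <- "none"
  n_out <- config$n_qc_outliers
  if (n_out > 0) {
    picked <- sample(n_cells, 2L * n_out)
    low <- picked[seq_len(n_out)]
    high <- picked[n_out + seq_len(n_out)]
    counts[low, ] <- matrix(
      rbinom(length(low) * length(genes), size = counts[low, , drop = FALSE],
             prob = 0.05),
      nrow = length(low))
    mito_idx <- match(config$mito_gene_names, genes)
    for (i in high) {
      non_mito <- sum(counts[i, -mito_idx])
      target <- ceiling(1.1 * max(non_mito, 20))
      counts[i, mito_idx] <-
        as.integer(rmultinom(1, target, rep(1, length(mito_idx))))
    }
    cells$planted_outlier[low] <- "low_size"
    cells$planted_outlier[high] <- "high_mito"
  }

  # hashing tags; optional planted multiplexing doublets
  tag_map <- setNames(sprintf("HTO%d", seq_along(samples)), samples)
  cells$hash_tag <- unname(tag_map[cells$sample])
  if (config$n_hash_doublets > 0) {
    dbl <- sample(which(cells$planted_outlier == "none"),
                  config$n_hash_doublets)
    other <- vapply(cells$sample[dbl], function(s) {
      unname(tag_map[sample(setdiff(samples, s), 1)])
    }, character(1))
    cells$hash_tag[dbl] <- paste(cells$hash_tag[dbl], other, sep = ";")
  }

  cells$tetramer <- ifelse(cells$sample == "tet_pos_immunized",
                           "tet_pos", "tet_neg")

  contigs <- make_contigs(cells, config)

  cell_meta <- as_tibble(cells)[, c("barcode", "sample", "tetramer",
                                    "hash_tag", "program", "clone_id",
                                    "receptor", "planted_outlier")]
  list(counts = as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
       cell_meta = cell_meta,
       contigs = contigs,
       config = config)
}

make_contigs <- function(cells, config) {
  clone_map <- setNames(config$clones,
                        vapply(config$clones, `[[`, character(1), "clone_id"))
  seen_cdr3 <- new.env(parent = emptyenv())
  for (cl in config$clones) {
    assign(cl$tra$cdr3_nt, TRUE, envir = seen_cdr3)
    assign(cl$trb$cdr3_nt, TRUE, envir = seen_cdr3)
  }
  fresh_chain <- function(chain) {
    repeat {
      d <- random_tcr_chain(chain)
      if (!exists(d$cdr3_nt, envir = seen_cdr3, inherits = FALSE)) {
        assign(d$cdr3_nt, TRUE, envir = seen_cdr3)
        return(d)
      }
    }
  }
  idx_rec <- which(cells$receptor != "none")
  if (length(idx_rec) == 0) return(empty_contig_table())
  chains <- lapply(idx_rec, function(i) {
    if (cells$receptor[i] == "clone") {
      cl <- clone_map[[cells$clone_id[i]]]
      list(cl$tra, cl$trb)
    } else {
      list(fresh_chain("TRA"), fresh_chain("TRB"))
    }
  })
  field <- function(k, pos) {
    vapply(chains, function(ch) ch[[pos]][[k]], character(1))
  }
  n <- length(idx_rec)
  one_locus <- function(pos, locus, c_gene) {
    umis <- rpois(n, 12) + 1L
    tibble(
      barcode = cells$barcode[idx_rec],
      contig_id = paste0(cells$barcode[idx_rec], "_", locus),
      chain = locus,
      v_gene = field("v_gene", pos), j_gene = field("j_gene", pos),
      c_gene = c_gene,
      cdr3_aa = field("cdr3_aa", pos), cdr3_nt = field("cdr3_nt", pos),
      full_nt = field("full_nt", pos),
      umis = umis, reads = umis * 25L + rpois(n, 40),
      productive = TRUE, high_confidence = TRUE, is_cell = TRUE
    )
  }
  out <- bind_rows(one_locus(1, "TRA", "TRAC"), one_locus(2, "TRB", "TRBC1"))
  out[order(match(out$barcode, cells$barcode)), , drop = FALSE]
}

empty_contig_table <- function() {
  tibble(
    barcode = character(0), contig_id = character(0), chain = character(0),
    v_gene = character(0), j_gene = character(0), c_gene = character(0),
    cdr3_aa = character(0), cdr3_nt = character(0), full_nt = character(0),
    umis = integer(0), reads = integer(0),
    productive = logical(0), high_confidence = logical(0),
    is_cell = logical(0)
  )
}
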