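---
title: "Rational TCR clone selection from paired single-cell expression and V(D)J data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational TCR clone selection from paired single-cell expression and V(D)J data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Building a TCR transgenic mouse requires choosing one clone from a
polyclonal antigen-specific response and synthesising its TCRα/TCRβ
chains. Historically the choice came from hybridoma screens that read out
little more than CD69 upregulation or IL-2 secretion, and regularly
produced transgenic lines whose T cells respond poorly in vivo. Paired
single-cell RNA sequencing and V(D)J repertoire sequencing of sorted
responders offers a rationalized alternative: clonal expansion identifies
clones that actually proliferated in the animal, and the transcriptome of
each clone's cells reports whether they were activated, cytokine-producing
and capable of memory formation. clonepick implements that selection
procedure as a tested, reproducible pipeline: ingest → QC → cluster →
link clonotypes → gate on markers → rank → export sequences for synthesis.

The experimental design the pipeline expects is three sorted CD8 T cell
samples from a tetramer sort: tetramer-positive cells from an immunized
animal (`tet_pos_immunized`), tetramer-negative cells from the same
immunization (`tet_neg_immunized`), and total CD8 T cells from a naive
animal (`naive`) as a phenotype backdrop.

## Quality control

Three per-cell metrics drive outlier removal: library size, number of
expressed genes, and mitochondrial fraction. A cell is discarded when it
lies more than `n_mads` (default 5) median absolute deviations from the
median of any metric. Two details matter and are deliberate defaults,
both switchable:

* library size and gene count are tested on the `log10(x + 1)` scale and
  on the **low** side only; the mitochondrial fraction is tested on the
  natural scale and on the **high** side only. This is the sidedness used
  by the standard scran/scater QC workflow the field uses for this rule;
  a `two_sided` flag widens it.
* the MAD is left **unscaled** (no 1.4826 normal-consistency constant).
  With the constant the same nominal `n_mads` flags less; `scale_mad =
  TRUE` enables it, and the thresholds actually applied are stored in the
  result's `thresholds` attribute so a run is always auditable.

When a metric's MAD is zero the rule would never flag, so any deviation
on the tested side counts. Zero-library cells are always flagged.
Multiplexing doublets are removed by the hashing rule — more than one
sample hashing tag on a barcode — because hashing antibodies are part of
the expected design; expression-based doublet scoring is out of scope,
but cells flagged multi-chain on both TCR loci can optionally be dropped
too (`drop_multi_chain`).

## Expression pipeline

Normalisation is library-size scaling to `target_sum` (default 10,000)
followed by `log1p`. Highly variable genes are ranked by simple variance
of the normalised values (default top 2000, capped at the panel size;
ties break lexicographically so the choice is deterministic). PCA is run
on the centered HVG submatrix (default 30 components, capped at the data
dimensions). Cells are clustered by Louvain modularity optimisation on an
unweighted k-nearest-neighbour graph in PC space (default k = 15).

The resolution parameter is not reported by comparable studies, so the
package scans a candidate grid (default 0.1–1.0) and keeps the assignment
with the highest mean silhouette width in PC space, ties going to the
smaller resolution; if every candidate yields one cluster, that trivial
assignment is returned with a warning. Cluster labels are always
relabelled 0, 1, 2, … by decreasing size. Every stochastic step (graph
clustering, UMAP) takes an explicit seed and is reproducible given it.

## Clonotypes

Contigs are read from the 10x `filtered_contig_annotations.csv` dialect
or an AIRR Rearrangement TSV, filtered on `is_cell`, `high_confidence`
and `productive`, and resolved to at most one TRA and one TRB per cell
(most UMIs, then most reads, then lexicographically smallest CDR3
nucleotide sequence; multi-chain cells are flagged). The clonotype key is
configurable because the upstream platform's definition is not
standardised across studies:

* `paired_nt` (default): exact match of both CDR3 nucleotide sequences;
* `paired_aa`: both CDR3 amino-acid sequences (a coarsening of
  `paired_nt`);
* `paired_nt_vj`: the nucleotide key plus the V and J gene calls of both
  chains (a refinement).

Cells lacking either chain are excluded from clonotypes by default —
a transgene needs both chains — and reported; `require_both_chains =
FALSE` keys on the available chain plus a placeholder. Clonotype ids are
assigned by descending size with a lexicographic tie-break, so
`clonotype1` is always the largest clone and the labelling is a pure
function of the data.

Consensus sequences per chain take the members' full-length nucleotide
sequences (falling back to CDR3 when absent), restrict to the modal
length, and vote per position; ties resolve to the first member in
barcode order, and the fraction of members matching the consensus exactly
is reported so a heterogeneous "clone" is visible at export time.

## Expansion, profiles and differential expression

The expansion table counts each clonotype per cluster (or per sample) and
asserts its own conservation invariants on every call: frequencies sum
to 1 over assigned cells, per-group counts sum to clone sizes row-wise
and to group sizes column-wise. Diversity statistics are Shannon entropy
(natural log), the Gini coefficient of clone frequencies, and D50 (the
fraction of clonotypes covering half the cells).

Marker profiles report, per clonotype and gene, the mean normalised
expression and the detection fraction (share of member cells with a
nonzero count). The detection fraction is what operationalises a
qualitative "Mki67⁺" or "Sell⁻" call read off a feature plot.

Clonotype differential expression is a per-gene Wilcoxon rank-sum test of
one clone's cells against all other clonotype-assigned cells in the
current subset (clone-vs-clone via `versus=`). Genes detected in fewer
than 1% of cells in both groups are skipped; the effect size is
`log2((mean_in + ε)/(mean_out + ε))` with ε = 1e−9 guarding empty means;
q-values are Benjamini–Hochberg. The comparison group ("vs rest") is a
design choice: it is the contrast that answers "what distinguishes this
clone from the response it sits in".

## Selection

Selection happens on the tetramer-positive subset after reclustering.
Gates are detection-fraction thresholds: positive markers must reach
their threshold (default 0.5), negative markers must stay below theirs
(default 0.1). The default gate set — Mki67⁺, Ifng⁺, Cd69⁺, Tcf7⁺,
Sell⁻ — encodes "proliferating, cytokine-producing, activated, with
memory potential". Eligible clones (all gates passed, size ≥
`min_clone_size`, optionally majority-resident in a restricted cluster
set) are scored

```
score = w · (frequency percentile) + (1 − w) · (mean gate margin)
```

with margins clipped to [0, 1] and `expansion_weight` w = 1 by default:
the gates act as hard filters and expansion decides among eligible
clones, which is exactly the qualitative "expanded AND
phenotype-positive" procedure the pipeline formalises. The composite
form exists for studies where near-threshold phenotype strength should
trade off against expansion rank, but it deserves a caution that drove
the default: the frequency *percentile* compresses even huge expansion
differences between the top clones into near-ties, so at intermediate
weights sampling noise in the detection-fraction margins — a few
percent on an 80-cell clone — can overturn a 20-fold expansion
difference. Weight it down only deliberately.
Ties break to the larger clone, then the lexicographically smaller id, so
the ranking is a total order independent of input order. Export writes
the consensus TRA/TRB sequences as FASTA plus machine- and human-readable
reports, and screens the sequences for the SalI site GTCGAC — the
restriction route commonly used to move such synthesis fragments into a
CD4 expression vector — warning (never failing) on a hit.

## The synthetic study

`default_cd8_scenario()` generates the statistical structure the analysis
assumes, so every stage is testable without any download. Counts are
negative binomial per gene (size 2 — overdispersion in the range typical
of UMI data), baseline mean 2 counts/gene over a ~190-gene panel.
Four phenotype programs shape the expression space: naive (Sell, Tcf7,
Lef1, Ccr7, Bach2, Il7r), memory-like (Cd44, Tcf7, Il7r, Bcl2, Cxcr3,
Eomes), effector (Ifng, Cd69, Nr4a1, Gzmb, Klrg1, Cx3cr1, Id2, Prf1,
Ccl5) and proliferating effector (effector plus Mki67, Bhlhe40, Tbx21,
Top2a, Ccnb1, Birc5, Stmn1), with multipliers 3–6 — effect sizes in the
range activation programs show in real CD8 data. A gene that is a marker
of some program is nearly off (multiplier 0.03) in programs that do not
list it, which is what makes detection-fraction gates meaningful.
The effector program carries a low level of Mki67 (multiplier 0.5):
activated effectors are not strictly Ki-67-negative, and a clone spread
over both activated states should still gate Mki67⁺.

Three samples of 1000 cells each mirror the tetramer sort. The
tetramer-positive sample draws only from the memory/effector/
proliferating programs and carries clone C1 at 40% of its cells, split
evenly between the two activated programs, plus four smaller clones
(80/40/20/10 cells) of varying phenotype; 80% of the remaining cells are
singletons with unique random receptors and the rest carry no contigs at
all (V(D)J dropout), exercising the "unassigned" path. The clone-size
distribution is a package choice — no comparable published distribution
exists for this design — fixed once at a level where the dominant clone
is unambiguous but not trivial. 2% of cells are planted QC outliers:
library thinned to 5% (binomial), or mitochondrial counts inflated to
≥50% of the cell — defects planted only on the side the QC rule tests.
CDR3s are random in-frame nucleotide strings (no stop codons) with V/J
labels from a small fixed mouse-like vocabulary; no germline
recombination biology is simulated, because downstream logic only tests
sequence equality and pretending otherwise would be fake realism.

What the generator does **not** emulate — ambient RNA, batch effects,
doublet transcriptomes, UMI saturation, realistic gene–gene correlation,
CDR3 convergence — bounds what green tests mean: they demonstrate the
procedure is implemented correctly and recovers planted structure under
the stated statistical assumptions, not that it is robust to every
artifact of real chromium data.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on
3000-cell simulations (about 10 s per run without the 2-D embedding),
repeat the end-to-end clone recovery over 20 seeds, check clonotype
calling against a brute-force oracle on 100 random repertoires, the MAD
rule against direct recomputation on 100 random tables, and the DE
p-values against a 1000-gene null. Identical configuration (including
seed) reproduces every output byte-for-byte; seeds are surfaced in every
provenance record together with a config hash.

## Known limitations

* No batch integration across samples; the three samples are clustered
  jointly on raw normalised values.
* Clonotype keys are exact-match; no edit-distance merging of convergent
  CDR3s.
* The 2-D embedding is visualisation only; no statistic is computed from
  it.
* BCR data and chains other than TRA/TRB are carried as "other" and
  excluded from analysis.
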