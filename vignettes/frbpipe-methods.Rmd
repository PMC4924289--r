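---
title: "Methods: fuzzy reciprocal best-hit surveys, model reconciliation and Dollo gain/loss mapping"
author: "frbpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy reciprocal best-hit surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, and what the validation experiments do and do not show.

## The problem

Given seed proteins from a reference species with a gold-standard
annotation, and a panel of target species with draft genomes, the task
is to decide for every (gene, species) pair whether a homologue is
present, and on what evidence.  Draft annotations fail in stereotyped
ways — truncated models, one gene split over several models, several
genes fused into one model, models missing although the locus is in
the assembly, and loci missing from the assembly itself — so presence
calls based on published gene models alone systematically undercount.
`frbpipe` layers three evidence streams, keeps the best one per cell,
and only then interprets the resulting phylogenetic profile.

## Fuzzy reciprocal best hit (FRB)

Classical reciprocal best hit declares orthology when the seed's best
hit in the target proteome points back at the seed.  That is brittle
under recent duplication: two near-identical co-orthologues split the
score and one direction picks the "wrong" copy.  FRB relaxes both
directions: with fuzz factor $f \in (0, 1]$, the fuzzy best-hit set of
a query is every subject with bitscore $\ge f \cdot B_{\max}$, and a
subject $s$ is a member of the call for seed $g$ iff

$$s \in \mathrm{fuzzy}_f(g \to \text{proteome}) \;\wedge\;
  g \in \mathrm{fuzzy}_f(s \to \text{seed proteome}).$$

Two or more members in one species flag a co-orthologous (recent
duplication) relationship.  With $f = 1$ and unique maxima FRB is
exactly classical RBH; decreasing $f$ can only enlarge member sets
(the monotone-nesting property, tested exhaustively).

Design choices:

* **Fuzziness operates on bitscores**, not E-values: bitscores are
  length-stable and comparable across databases of different size.
* **$f$ defaults to 0.9** and is logged on every run.  The literature
  behind the approach does not pin a value; 0.9 tolerates the score
  split produced by a recent duplicate (a few percent divergence)
  without admitting genuinely weaker paralogues.
* **Admission filters** before the reciprocal test: E-value
  $\le 10^{-5}$ and query coverage $\ge 0.3$.  These are deliberately
  permissive — no single alignment-score threshold separates good from
  bad models, so final judgement is deferred to the refinement tiers.

## Internal alignment

The internal search is affine-gap Smith–Waterman (BLOSUM62, gap open
−11, extend −1 per residue), with bitscores
$(\lambda S - \ln K)/\ln 2$ at the standard gapped constants
$\lambda = 0.267$, $K = 0.041$, so internal scores are commensurate
with external tabular hit files, which the pipeline accepts
interchangeably.  The dynamic programme is delegated to
`Biostrings::pairwiseAlignment()`; the traceback tie-break among
co-optimal paths is therefore Biostrings' deterministic internal rule
(the reported score, the quantity every downstream decision uses, is
tie-break-independent).  Only the single best local alignment per pair
is kept: FRB needs the top-scoring relationship, and multi-HSP logic
belongs to the external tools whose output can be ingested instead.
E-values use the pairwise search space $K m n e^{-\lambda S}$.
Reciprocal searches exploit score symmetry: the reverse table is the
forward table with roles and coordinates swapped, not a second DP run.

## Refinement tiers

When an external protein-to-genome aligner proposes a model where the
published annotation already has one, both proteins are aligned to the
seed and compared by *coverage* — the fraction of seed residues inside
the alignment's query interval.  With
$\Delta = \mathrm{cov}_{new} - \mathrm{cov}_{pub}$:

| outcome | rule |
|---|---|
| `published_ok` | one overlapped published model, $\Delta < 0.05$ |
| `minor_refinement` | one overlapped model, $0.05 \le \Delta < 0.15$ |
| `major_refinement` | one overlapped model, $\Delta \ge 0.15$; or $\ge 2$ overlapped models (*split*); or none (*novel locus*) |
| `merged` flag | one published model overlapped by $\ge 2$ predictions |

The deltas are **additive percentage points**, not relative ratios —
the natural reading for coverage fractions — and the boundaries are
**inclusive** ("5 points greater" includes exactly 5).  A $10^{-9}$
epsilon guards the comparisons against floating-point representation
of coverage differences.  Genomic overlap requires the same contig and
strand (antisense overlaps are distinct loci) and at least
`min_shared = 30` shared bases (~10 residues): one codon is too
permissive given assembly noise, and the floor is configurable.

## Read-depth rescue

A gene can be absent from annotation and assembly yet present in the
organism; the raw reads still carry it.  Reads enter as protein-space
tabular alignments against the seed (translation/frame handled by the
upstream aligner, keeping this module aligner-agnostic).  `pileup()`
counts per-residue depth; a candidate profile is **supported** iff

* coverage $\ge$ `min_coverage` (default 0.8), and
* $|\tilde d_{cand} - \mathrm{median}(\tilde d_{ref})| \le k \cdot
  \mathrm{MAD}(\tilde d_{ref})$ with $k =$ `depth_k` (default 3),

where the reference set is the FRB-confirmed homologues of the same
species, MAD is the scaled median absolute deviation
(`stats::mad`, consistency constant 1.4826) with a floor of 1 so that
an unnaturally tight reference set cannot reject everything.  The
qualitative judgement "depth and coverage consistent with confirmed
homologues" is thereby made explicit and tunable.  A species with no
confirmed homologue has no reference distribution; the package then
falls back to the coverage-only rule (and `consistency_test()` itself
raises a configuration error saying so).  Borderline candidates whose
median depth sits just outside $k$ MADs are rejected — visible
occasionally in the synthetic benchmark as a missed `model_absent`
rescue.

## Evidence matrix and Dollo gain/loss

Each cell takes the best case over streams under
`published_ok > minor_refinement > major_refinement > novel >
read_only > absent`; a positive FRB call contributes `published_ok`
(the published model matched as-is), so a cell is coloured by
refinement only when FRB failed on the published proteome.

Presence profiles are mapped on the species tree under **Dollo
parsimony**: one gain at the MRCA of the present leaves, losses = the
maximal all-absent subtrees below it, one loss edge each.  That count
is minimal under the single-gain constraint (verified against an
exhaustive oracle over every single-gain/any-loss assignment on every
binary rooted shape up to 8 leaves, and on multifurcating trees).
Dollo rather than free Fitch parsimony is imposed deliberately: for a
gene family anchored by a reference-species seed, "arose once, lost
repeatedly" is the hypothesis being scored, and the reconstruction is
deterministic.  Forward re-simulation of (gain, losses) reproduces the
input pattern exactly — an invariant under test.

A limitation worth knowing: a loss on the branch separating the
reference from everything else (the gene survives only in the
reference) leaves no signal for a single-gain reconstruction — the
gain is simply placed on the reference lineage with zero losses.  Such
planted losses are unrecoverable in principle, and they are the main
contributor to loss-branch recall sitting a few points below 1 in the
benchmark.

`collapse_low_support()` contracts internal edges with bootstrap
support below a threshold into polytomies (children promoted, child
branch lengths absorb the contracted edge so root-to-tip distances are
preserved; edges without a support value are kept).  Support is read
from numeric internal node labels on the 0–100 scale; all-fractional
input is auto-detected and rescaled with a warning, since both Newick
dialects occur.

## The synthetic world

`simulate_truth_set()` generates the inputs the pipeline assumes, with
full ground truth:

* **Tree**: a random ingroup topology with the reference attached as
  outgroup.  Rooting on the reference lineage matches the seed-centric
  design — every gene exists in the reference by construction, so the
  single gain sits at the root.  Internal nodes are labelled `N1…` so
  loss edges are nameable.
* **Presence**: single origin at the root, then Bernoulli(loss_rate)
  per ingroup branch, irreversible.
* **Sequences**: seed proteins drawn uniformly over the 20-letter
  alphabet (lengths 150–400 aa); per-branch uniform substitution at
  `mutation_rate = 0.02` per residue (no indels), keeping leaf
  divergence (~5–10%) comfortably inside FRB's working range — the
  generator isolates pipeline logic from alignment-sensitivity
  questions on purpose.
* **Duplications**: with probability `duplication_rate` per present
  (gene, species), a near-identical copy (1% divergence) with its own
  locus and published model — the co-orthologue truth.
* **Genomes**: single-exon loci, fixed 3:1 nucleotide:protein
  correspondence, random 200–500 bp spacers; enough to exercise
  overlap/split/merge logic without a splice model.
* **Corruption** of published models per present cell (reference cells
  stay intact): `intact`; `truncated_minor` (coverage gap drawn from
  [5%, 15%)); `truncated_major` ([15%, 50%]); `split` (two half
  models); `merged` (two seed genes fused into one two-exon model —
  merged genes are paired within a species, an unpaired draw reverts
  to intact); `model_absent` (locus in the genome, no published *and*
  no predicted model — emulating a region that defeats the aligners,
  recoverable only from reads).
* **Predicted models**: one faithful model per present locus except
  `model_absent` — the stand-in for the external aligners' GFF output,
  which real runs ingest instead.
* **Reads**: protein-space intervals of 33 residues (~100 bp),
  Poisson-distributed counts at mean depth `read_depth = 20` per
  residue, uniform starts.
* **Decoys**: `decoy_rate × n_genes` random non-seed proteins per
  species as negative controls for FRB false positives.

What the generator does **not** emulate: realistic molecular evolution
(codon models, indels, domain shuffling, rate variation), paralogous
gene families that confuse the reciprocal test, splice structure,
sequencing error, or assembly-specific coverage biases.  Passing the
synthetic benchmark therefore shows the pipeline's *logic* is correct
under its stated assumptions, not that the default thresholds are
optimal for any particular real genome panel.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle:
local alignment against exhaustive enumeration of monotone residue
matchings (with affine gaps the internal gap cost separates per
sequence, which makes full enumeration cheap) on 500 random pairs of
length ≤ 8 over a 4-letter alphabet; FRB against the literal
membership definition on 1000 random hit-table pairs (≤ 6 × 6), with
monotone nesting across fuzz values; the tier grid at
Δ ∈ {0, 0.049, 0.05, 0.149, 0.15, 0.5}; Dollo against the bitmask
oracle for every pattern on every binary rooted shape with ≤ 8 leaves;
collapse against clade-set filtering on 200 random support-annotated
trees.  The end-to-end benchmark runs the defaults (12 species, 40
genes — 480 cells) and requires presence/absence accuracy ≥ 0.95,
planted-vs-assigned mode agreement ≥ 0.90 on corrupted cells and
loss-branch precision/recall ≥ 0.90; byte-identical rerun determinism
is checked on a 6-species, 10-gene configuration.  These sizes are the
package's validation design: large enough that every corruption mode
and a realistic number of losses occur, small enough to run in a few
minutes on one CPU.

## Interfaces

The pipeline is a library: `run_all()` over a bundle directory is the
orchestrated path, and the per-stage functions (`stage_search`,
`stage_frb`, `stage_reconcile`, `stage_depth`, `build_matrix`,
`stage_dollo`) compose to exactly the same result — an invariant under
test.  `scripts/acceptance.R` is the scripted entry point for the
benchmark experiment.  All file formats pass through strict readers
and writers (FASTA; GFF3 with mRNA/CDS and 1-based inclusive
coordinates converted to the internal 0-based half-open convention at
the boundary; 12-column tabular hits with percent identity stored as a
fraction internally; Newick with numeric internal support labels), and
every writer's output is re-parseable by the corresponding reader.
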