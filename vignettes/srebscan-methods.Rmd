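---
title: "Methods: models, parameters and design choices in srebscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in srebscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srebscan)
```

# Scope

`srebscan` re-implements, as a reusable desk-scale pipeline, the comparative
analyses used to characterize the SREB family of orphan class-A GPCRs
(GPR27/SREB1, GPR85/SREB2, GPR173/SREB3A and the fish-specific sreb3b)
across fish genomes: candidate verification, paralog-cluster assignment,
alignment conservation profiling, microsynteny presence/absence calling and
qPCR relative quantification. Every stage can be exercised on synthetic
data with planted ground truth, so the statistical machinery is testable
without any downloads. This vignette records the models, the tunable
parameters, and the choices made where the design was genuinely open.

# The synthetic-data generator

The generator is first-class, tested code: its defaults define the study
conditions under which the pipeline's guarantees are stated.

## Species tree and family layout

The default world has 80 species in 10 order-like clades of 8 (names such
as `cyprinodontiformes_05`), arranged on a deterministic ultrametric
balanced tree of depth 1; `tree = "random(b)"` substitutes a birth-only
random tree. Four paralog clusters evolve over the full tree; configured
loss events delete species-by-cluster gene copies and duplication events
add a second copy. The default event set mirrors the comparative dataset
the analyses target:

* SREB1 lost in 4 species, one 6-TM quality failure — 75 analysis-grade;
* SREB2 duplicated in 2 species, two failures (5 and 6 TM) — 80;
* SREB3A lost across the entire Cyprinodontiformes-like clade of 8, three
  8-TM failures — 69;
* SREB3B absent from three early-branching clades (24 species) plus one
  assembly-gap case, one 5-TM failure — 54;
* three highly divergent outgroup-like sequences (hagfish/lamprey/shark
  analogues) that belong to no cluster.

The seven failures carry transmembrane counts 5, 6, 8, 8, 8, 6, 5 — the
counts of the seven sequences the screening tier is designed to demote.

## Protein architecture

Each protein is 375 aa: a 40-residue N-terminal region, seven 21-residue
transmembrane (TM) runs separated by 22-residue loops, and a 56-residue
C-terminal tail. TM residues are drawn from the strongly hydrophobic set
{I, L, V, F}; loops, tails and the N-terminus from the strongly
hydrophilic set {N, Q, E, D, K, R, H}. The hydrophobic set is deliberately
narrower than the full Kyte–Doolittle-positive alphabet: with window 19
and threshold 1.6 these pools make detection of exactly seven runs a
deterministic property of every generated protein, including runs that
host motif residues such as W and P, and they keep adjacent runs from
merging across loops. Quality failures rewrite this architecture
(`tm_count(k)` converts runs to loop residues or plants an extra run at
positions 350–370; `truncated_orf` emits only the first 150 codons).

## Sequence evolution

Sites evolve i.i.d. along branches: on a branch of length *b* a mutable
site substitutes with probability 1 − (1 − p)^b, drawing a replacement
from its region's pool, where *p* is the cluster's per-site substitution
probability per unit tree depth (defaults 0.030/0.015/0.040/0.060 for
SREB1/2/3A/3B, putting SREB2 at the top of the conservation ordering).
Proteins are reverse-translated with a fixed most-frequent-codon table,
given a terminal stop codon and short ATG-free untranslated flanks, so the
longest open reading frame is the planted one by construction.

Three classes of sites are held immutable:

* the initiator methionine;
* the three canonical GPCR motifs, planted at reference positions 148
  (DRY), 266 (CWxP) and 320 (NPxxY) with the family's characteristic
  deviations: D→T at the DRY position everywhere except one designated
  sequence (giving a pooled T conservation of 277/278 = 99.6%), C→L at the
  CWxP position outside SREB1, and Y→C at the NPxxY position, replaced by
  S in SREB1 of the five "derived" clades;
* the planted cluster-specific sites: by default eight SREB3B-diagnostic
  positions at 132, 165, 184, 217, 292, 293, 296 and 372 in reference
  numbering, with hydrophobic pairs (V→F) inside TM runs, N→K in loops and
  C→Y in the tail.

## Why planted-site precision and recall are exactly 1

Between-cluster separation does not come from independent ancestral
divergence (which would occasionally fake the planted pattern) but from a
pool of 120 diagnostic sites at each of which **exactly one pair** of
clusters differs, cycling over all six pairs. At such a site the three
"background" clusters can never share a single modal residue while the
target differs, for any choice of target — so no unplanted site can pass
the specific-site rules, while drift within a cluster can only push a
column out of the conserved set, never into a fake diagnostic state.
One further structural guard: each cluster's ancestor is placed at the
species tree's first split, so the two deepest edges carry no change.
Otherwise a coincidental pair of same-residue substitutions on those two
edges could make an entire cluster monomorphic for a non-ancestral
residue and mimic a planted site; with ancestors at the first split such
an event needs at least three independent same-residue substitutions on
deep branches, vanishingly rare at the default rates.
Detection of the planted sites is therefore exact, which is what the
recovery tests assert (50 seeds in the suite, 20 in the acceptance script
— sizes chosen to keep the default run comfortably fast on one CPU).

## What the generator does not emulate

Indels (all sequences are equal length; alignment "import" is exact),
codon-usage structure, rate heterogeneity beyond the planted/mutable
dichotomy, paralog-specific gene conversion, and assembly noise beyond the
binary gene-loss/assembly-gap distinction. Passing tests therefore show
that the statistical rules are implemented exactly; they do not show
robustness to alignment error in real data, which should be assessed with
an externally computed alignment via import mode.

# Screening

`find_longest_orf()` scans all six frames for ATG-initiated,
stop-terminated frames, preferring the longest, then the earlier start,
then the plus strand. The 50-codon floor and the tie rules are package
conventions (the underlying method leaves them open); the floor is a
parameter so degenerate examples remain reachable. `predict_tm()` is a
deterministic Kyte–Doolittle sliding-window detector (window 19, threshold
1.6, minimum segment 15 after window expansion, merge gap 3): the
analysis only ever consumes the *count* of transmembrane segments, so a
hidden-Markov TM posterior would add nothing the filters use.
`apply_filters()` implements the two tiers: presence evidence
(length in 314–426 aa, ≥ 5 runs) and analysis grade (length window and
exactly 7 runs). The 314–426 window operationalizes "about 370 aa" as
±15% with integer floor/ceiling.

# Cluster assignment

Distances are p-distances (mismatches over both-ungapped columns; pairs
with no comparable columns get distance 1 with a warning). Trees are
neighbor-joining (negative branches clamped to zero), rooted on a
designated outgroup or at the midpoint. `bootstrap_clusters()` resamples
columns with replacement (default 100 replicates) and records, per
candidate cluster, the fraction of replicates in which its members are
monophyletic; a sequence keeps its hinted cluster at support ≥ 0.7, and
everything else — including outgroup-like sequences — is UNASSIGNED. The
0.7 threshold and the 100-replicate default are package choices, both
configurable; an externally computed tree can be supplied by building the
assignment from its clades instead. Maximum-likelihood tree inference is
deliberately out of scope: the downstream stages need cluster labels and
support, nothing else.

# Conservation profiling

`profile_columns()` computes, per column and cluster (plus pooled), the
modal residue (ties alphabetical), the divergent count and a conserved
flag (≤ 3 divergent rows). Gaps count as divergent under the default
policy — a deletion is not conservation of the modal residue — with
`gap_policy = "ignore"` available. The ≤3 rule implies per-cluster
minimum conservation percentages of 96.0, 96.3, 95.7 and 94.4 at cluster
sizes 75, 80, 69 and 54 (`min_conservation_pct()`, rounded half-up to one
decimal — half-up matching the printed convention, e.g. 96.25 → 96.3).
Columns before the reference's TM1 are masked
(`mask_nterminal()`) because N-terminal regions are hypervariable and may
contain alternative starts. `find_cluster_specific_sites()` requires, in
strict mode, every background cluster conserved with one shared modal
residue, the target conserved, and the target's residue different; a
relaxed mode drops the shared-residue requirement. `scan_motifs()`
reports per-cluster and pooled conservation at anchored DRY/CWxP/NPxxY
positions, flagging non-wildcard deviations; anchors are supplied, not
inferred, because motif placement is canonical structural knowledge.
Both per-cluster and pooled figures are reported since printed
conservation percentages can refer to either.

# Microsynteny

`presence_matrix()` distinguishes present (any presence-grade hit),
incomplete (only failing hits, still usable as presence evidence) and
absent. `call_synteny()` abstracts flanker homology as symbol equivalence
(case-folded, "-like" stripped, a single trailing paralog letter stripped
from one side only — so suv39h1a matches suv39h1 but sreb3a never matches
sreb3b), with a user-editable synonym table. Both flankers intact with no
target between them — and no target anywhere in the genome — is a loss; a
missing or split flanker is an assembly gap; overlapping, unordered or
over-spanned flankers (defaults: 50 genes or 2 Mb, the field has no
standard window) are inconclusive. A target found anywhere in the genome
is never called lost.

# qPCR quantification

Standard curves are ordinary least squares of Ct on log10 relative
quantity over all pooled replicate points (four to six dilution points);
efficiency is E = 10^(−1/slope) − 1, with a QC window of 90–100% ± 2
percentage points for "approximately". Quantities interpolated from the
curve are normalized in one of three modes — reference-gene ratio, equal
fixed RNA input, or per-microgram of input RNA — and then scaled so the
calibrator group's mean is exactly 1. The relative-standard-curve ratio
method is the primary implementation because a curve exists for every
assay; with all inputs equal the fixed-input and per-microgram modes agree
up to the input mass (the `raw` column exposes the pre-calibration
quantities where that 2.5× proportionality is visible). Candidate
reference genes are screened by one-way ANOVA of log quantities across
groups (unstable below p = 0.05). Group comparisons use natural-log
values — the tests are invariant to the log base — with a Welch t-test for
two groups or one-way ANOVA plus Tukey HSD and a compact letter display
(insert-and-absorb over the Tukey p-value matrix; sharing a letter means
not significantly different at α = 0.05). Non-detects are excluded, never
imputed. Replicate wells are averaged on the Ct scale before
quantification.

# Numerical conventions and degenerate inputs

Half-up rounding everywhere a percentage is printed; an epsilon of 1e−9
guards binary-representation edge cases. Modal ties break alphabetically.
Empty clusters are dropped from profiling with a warning. Curves with
non-negative slope or non-monotone dilution series warn rather than fail.
All simulators run under a single seed with a saved-and-restored RNG
state, so a fixed configuration yields byte-identical FASTA/TSV/CSV
output and calls are order-stable.

# Known limitations

The cluster stand-in is distance-based; deep or rate-heterogeneous
phylogenies that require model-based inference should import an external
tree. Symbol-level flanker matching cannot recognize unannotated or
renamed flankers. The generator's no-indel assumption means import-mode
alignments are exact, so alignment-quality effects on the conservation
scans are untested here. Sub-cluster outliers (sequences that belong to a
cluster but sit on long branches) are retained with their hint rather
than resolved, mirroring the unresolved status of slightly divergent
cluster members in real data.
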