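---
title: "Methods: NLR repertoire annotation, typing, clustering and comparative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR repertoire annotation, typing, clustering and comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrscape)
```

This vignette documents the models and procedures implemented in
`nlrscape`, the parameters that matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## Domain-hit resolution

Profile-HMM searches against several profile collections produce
overlapping, competing annotations for the same protein region.
`resolve_competing_hits()` treats two hits on the same gene as competing
when their amino-acid intervals overlap by at least `overlap_fraction`
of the *shorter* interval. The default is 0.5: a majority of the smaller
domain must be covered before the hits are considered alternative
annotations of one region rather than adjacent domains. Connected
components of the pairwise overlap graph form one competition each, so
chains of partially overlapping hits are settled together; the
components are computed the same way regardless of input row order, and
the output is sorted, so resolution is permutation-invariant.

Competitions are settled in two stages:

1. **Source priority.** Hits from the highest-priority collection
   present win outright: curated fungal-NLR N-terminal profiles
   (`wojciechowski`) over order-specific profiles
   (`sordariales_specific`) over generic Pfam-A (`pfam_a`). Priority
   encodes specificity of the profile to the protein family, not
   statistical strength, which is why it precedes any E-value
   comparison.
2. **Squared-E-value margin.** Among surviving same-source hits, the
   lowest-E-value hit is retained only if its E-value is strictly below
   the *square* of every competitor's E-value — a deliberately
   conservative margin demanding that the best hit be better on a
   log-scale factor of two than everything it displaces, applied
   best-versus-every-competitor rather than best-versus-second-best.
   When the margin fails, the outcome depends on the domain class: an
   NB-region competition yields a single call with status
   `undetermined` (the evidence supports *an* NB domain without
   settling its type), while competitions among other classes keep all
   predictions (`multiple`).

E-values of exactly zero are floored at 1e-300 before squaring so the
comparison never degenerates. Nested (fully contained) hits satisfy any
overlap fraction and always compete with their container.

## NLR calling and architecture classes

A candidate NLR must encode at least one NB-class call and at least one
canonical C-terminal call (Ankyrin, TPR, WD40 or HEAT) C-terminal of the
NB, on a gene strictly longer than 1000 bp. Because no annotation
carries an explicit N/C label, a call's side is decided by its midpoint
relative to the NB region midpoint — the simplest rule that is
monotone, symmetric and independent of call lengths.

`classify_architecture()` labels each flank: `canonical` (one canonical
category), `mixed` (two or more distinct canonical categories),
`noncanonical`, `missing` (no call and the flank is shorter than 20 aa
on the N side or 50 aa on the C side — a truncated receptor has no room
for a domain), or `undetermined` (no call on a flank long enough to
hold one). The thresholds differ because canonical C-terminal repeats
are physically longer than the shortest N-terminal effector domains.
The combined class gives precedence to `mixed` over the `missing-*`
classes over `non-canonical` over `undetermined`; two canonical flanks
make the receptor `tripartite`.

The profile-to-category map merges `sesA` into HeLo-like and `NAD1`
into Goodbye-like (their annotated sets overlap extensively) and pools
all amyloid-motif profiles into a single `amyloid` category. Unknown
profiles pass through as non-canonical under their own name, so novel
integrated domains are never silently dropped.

## NB typing by degenerate motifs

The motif engine (`match_motif()`) supports literal residues, bracketed
residue classes, `x` (any residue) and `h` (hydrophobic). The
hydrophobic set defaults to A, C, F, I, L, M, V, W, Y — the standard
P-loop NTPase convention — and is configurable everywhere. An `X` in a
scanned sequence matches only `x` positions: an ambiguous residue is
never evidence for a constrained position.

Typing composes two decisions:

* **Walker B.** The NACHT lineage is recognised by `hhhhD[GAS]hDE`; a
  first aspartate directly followed by another acidic residue marks
  NB-ARC, operationalised as `hhhhD[DE]`. NACHT takes precedence, and
  the leftmost match of the winning consensus is used; the NB-ARC motif
  is only consulted when no NACHT instance exists anywhere, so a
  NACHT-positive sequence is never demoted by an incidental acidic
  pair. No match of either consensus leaves the NB type undetermined.
* **HETHS subtype.** Among NACHT sequences, a NAIP-like consensus
  `FhHxxhQE[YF]hxA` in the helical-third region defines the rare
  N-NACHT subtype; its absence the common TLP1-like T-NACHT. The search
  window runs from the end of the Walker B to the sequence end, because
  the HETHS region lies C-terminal of the core P-loop domain; a
  NAIP-like instance upstream of the Walker B is not evidence of the
  subtype.

`split_nb_fragments()` cuts an NB sequence at the start of the Walker B
into the two fragments used for ordination, so their concatenation
reconstructs the input exactly.

## Alignment-free distances and ordination

Two metrics compare NB fragments without alignment. The k-mer Google
distance on word size `k` (default 3) is
`d = (|A| + |B| - 2|A∩B|) / (|A| + |B| - |A∩B|)` over the fragments'
distinct k-mer sets — 0 for identical, 1 for disjoint sets. Word size 3
balances specificity (20³ = 8000 possible words) against the ~200–300
aa length of NB fragments; it is configurable. The Lempel–Ziv distance
uses the LZ76 exhaustive-history component count `C(·)` in the
normalized form
`d = max(C(s1 s2) - C(s1), C(s2 s1) - C(s2)) / max(C(s1), C(s2))`,
symmetric and non-negative by construction. The component count is
computed from the definition — a component extends while it can be
copied from the already-seen prefix (self-overlap allowed) — with a
binary search over the extension length, since reproducibility is
monotone. The BLOSUM62 distance index for aligned pairs is
`1 - S12 / max(S11, S22)` over gap-free columns, with `Sxy` the summed
BLOSUM62 scores of the column pairs; scores come from the Biostrings
BLOSUM62 matrix.

`pcoa()` performs classical scaling (double-centred −½ squared
distances, eigendecomposition, coordinates scaled by the square roots
of positive eigenvalues) via `stats::cmdscale`; negative eigenvalues —
possible for non-Euclidean inputs — are reported and their axes
dropped. On Euclidean inputs the embedding reproduces the input
distances to numerical precision, which the tests assert at 1e-9.

The qualitative ordination claim — NB-ARC and NACHT fragments separate
on the first principal coordinate — is quantified with a mean
silhouette width along that axis (`group_silhouette()`): positive means
between-type differences exceed within-type differences.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with planted
ground truth designed to be *exactly* recoverable when corruption is
off:

* `simulate_gene_table()` lays out genes per contig with uniform
  lengths and intergenic gaps, then plants cluster blocks, head-to-head
  pairs and isolated NLRs. Blocks are separated by at least nine filler
  genes so no unplanted cluster can form under any intervening
  threshold up to eight; planted non-head-to-head 2-gene clusters never
  receive the divergent (−,+) orientation, so head-to-head flags
  identify exactly the planted pairs. The spec is validated up front:
  within-cluster separations implied by the gene-length and gap ranges
  must fit inside `within_cluster_gap_bp`, which itself may not exceed
  40 kb.
* `simulate_nb_protein()` plants a Walker A (`GxxxxGK[ST]`, the
  classical P-loop; positions 30), a type-specific Walker B (position
  120) and, for NACHT types, a HETHS block (position 220) in a 350-aa
  protein — realistic relative positions for an NB domain. For T-NACHT
  the planted HETHS block has the consensus glutamine replaced so the
  NAIP motif cannot match; `corrupt_motif` mutates the Walker B's first
  aspartate to lysine, breaking both consensi. The uniform background
  is resampled until no spurious motif instance occurs outside the
  planted windows — this rejection step is what makes 100% recovery a
  well-defined property of finite random sequences. The background is
  uniform over the 20 standard amino acids so that the spurious-match
  rate is quantifiable.
* `simulate_nb_family()` additionally models within-type homology: all
  members derive from one ancestral sequence by independent per-site
  substitutions (default divergence 0.35, about 65% within-family
  identity — a realistic within-family figure). This matters for the
  ordination property: with fully independent backgrounds the handful
  of planted motif residues cannot dominate an alignment-free distance
  over ~230 background positions, and no separation appears; real NB
  fragments of one type are homologs, and the family generator is the
  honest synthetic counterpart of that situation.
* `simulate_domain_hits()` draws E-values log-uniformly from
  [1e-30, 1e-4], spanning realistic hmmsearch magnitudes and
  exercising the squared-E-value rule on both sides; plan rows may
  carry fixed E-values to plant decoys with controlled ratios.
* `simulate_brownian_traits()` draws the predictor i.i.d. standard
  normal per tip and the residual multivariate normal with covariance
  `sigma2` times the tree's shared-branch-length matrix, via the
  Cholesky factor — the exact generating model of PGLS.

What the generators do **not** emulate: intron structure and
nucleotide-level gene models, repeat-induced point mutation, assembly
fragmentation and annotation error, profile-specific score
distributions, or the long-tailed orthogroup size distributions of real
repertoires. Passing the planted-recovery tests therefore demonstrates
the correctness of the decision rules, not robustness to noisy gene
models or profile search errors on real assemblies.

## Cluster detection and calibration

Two consecutive NLRs are linked when their facing-boundary gap (start
of the downstream gene minus end of the upstream gene minus one;
overlapping genes count as gap 0) is at most `max_gap_bp` *and* the
number of non-NLR genes between them is at most `max_intervening`.
Clusters are maximal linked runs of two or more NLRs and never span
contigs. Thresholds are inclusive by default, matching the calibration
grid semantics in which a grid value names the largest admissible gap;
`strict = TRUE` switches to exclusive comparisons. The standard
parameterisation is 40 kb and eight intervening genes.

`permutation_null()` relabels, per replicate, a uniform random gene
subset of the observed NLR count (drawn without replacement over *all*
genes, including the true NLRs — no exclusion is warranted when the
null asks how ordinary gene sets of that size behave) and recounts
clustered genes. `calibrate_params()` scans a grid of 27 gap values
(0–200 kb) by nine intervening counts (0–8), scores each grid point by
the fraction of genomes at which it attains that genome's maximal
excess of observed over null-mean clustered counts, and selects the
highest-scoring point, breaking ties towards the smaller gap and then
the smaller intervening count — the most conservative parameterisation
among equals. The same random subsets are reused across all grid points
of a genome (common random numbers): grid points that behave
identically on the data then receive exactly equal excess, and the
deterministic tie-break decides, rather than Monte-Carlo noise in
independently drawn nulls.

Head-to-head pairs are 2-member clusters whose upstream gene lies on
the minus strand and downstream gene on the plus strand — divergent
5′-to-5′ orientation, the arrangement in which two receptors can share
a promoter region.

## PGLS

`pgls_fit()` estimates `y ~ x` by generalized least squares with
residual covariance `V(λ)`: the Brownian shared-branch-length matrix
with off-diagonals multiplied by Pagel's λ ∈ [0, 1] and diagonals
unchanged. λ is profiled by maximum likelihood with `stats::optimize`
(Brent's method — golden-section search with parabolic refinement) at
tolerance 1e-6, with the boundary values 0 and 1 checked explicitly
since Brent never evaluates the interval endpoints. Estimation whitens
through the Cholesky factor of `V(λ)` and solves ordinary least squares
in the whitened space; the slope's two-sided p-value uses a t
distribution with n − 2 degrees of freedom. The adjusted R² is computed
from residual and total sums of squares in the whitened space, against
the GLS intercept-only model, so that λ = 0 reduces exactly to the OLS
R². The tests verify the λ = 0 reduction to closed-form OLS at 1e-8,
agreement with `nlme::gls` under a fixed Pagel correlation, and slope
recovery under the generating model.

## Summaries and the inflation plateau

`summarize_repertoire()` rounds half away from zero — NB-type shares to
one decimal, cross-tab shares to integers — matching the reporting
conventions of repertoire tables (base `round()` would round halves to
even). `combination_space()` reports possible and observed counts for
the pairwise and tripartite architecture spaces and the realized
tripartite proportion of its actual inputs. `plateau_select_inflation()`
returns the *first* inflation value of the earliest run of three
consecutive equal counts — "the value at which the plateau was reached"
read as the plateau's first member; with no plateau it warns and
returns `NA` rather than guessing.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a single CPU:
1000 simulated proteins per NB type for typing recovery, 20 synthetic
genomes for calling and cluster recovery, 200 random ≤50-gene tables
for the exhaustive cluster oracle, 100 Brownian replicates on a 64-tip
tree for slope recovery, a 74-fragment ordination (50 T-NACHT, 20
NB-ARC, 4 N-NACHT), and a 6-genome calibration cohort at 30
permutations per genome. The full acceptance run completes in about a
minute; the suite in under two.

## Known limitations

* The motif classifiers are consensus-based; real divergent Walker B
  instances that violate the hydrophobic tetrad are typed
  `undetermined` rather than rescued by profile context.
* The alignment-free distances fix one explicit formula per metric;
  numeric agreement with other alignment-free toolkits'
  parameterisations is not a goal — the ordination's qualitative
  structure is the assertable output.
* The N/C side assignment by midpoint can misassign a call that
  straddles the NB region in a way no simple positional rule resolves.
* PGLS assumes complete cases and one observation per tip; measurement
  error models and multi-predictor fits are out of scope.
* The calibration score ("fraction of genomes attaining their maximal
  excess") follows the argmax reading of the published selection rule;
  other aggregations over genomes are conceivable and would be easy to
  add, but are not implemented.
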