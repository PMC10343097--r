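---
title: "Methods: progressive alignment, consistency and iterative refinement in msaframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive alignment, consistency and iterative refinement in msaframe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

msaframe decomposes progressive multiple protein sequence alignment into
five interchangeable stages and lets every combination be run and compared
on equal footing.  This vignette explains the model behind each stage, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The five-stage pipeline

**Stage 1 — similarity scoring.** All `n(n-1)/2` sequence pairs are scored
on a common 0–100 scale, giving the `sim_matrix` that drives clustering.
Five scorers are available:

* `F` (FULL): identity percentage of the optimal global affine-gap (Gotoh)
  alignment.  The identity denominator is the number of columns where
  *neither* sequence has a gap; this convention is pinned by tests because
  "identity of the alignment" is ambiguous about gap columns.
* `Q` (QUICK): shared *distinct* k-tuples over the tuple positions of the
  shorter sequence, `k = 1` by default (the classic fast scorer for
  proteins).
* `L` (LCS): longest-common-subsequence length over the shorter sequence
  length, computed with a two-row linear-space DP.
* `K` (KMERS): MUSCLE-style fractional k-mer identity, `k = 3` by default:
  for each distinct k-mer the smaller of its two occurrence counts is
  shared, and the sum is divided by `min(L1, L2) - k + 1`.  The
  `-k+1` denominator is MUSCLE's own; it is what keeps the score in
  `[0, 100]` with equality exactly for identical sequences.
* `P` (PROBA): the value of the maximum-expected-accuracy alignment over
  pair-HMM posterior match probabilities, divided by the shorter length.
  Note that posteriors measure confidence of *being aligned*, not of being
  identical, so `P` runs systematically higher than the other four scorers
  and never reaches exactly 100 even for identical sequences (a pair-HMM
  with a nonzero gap probability always leaves mass off the diagonal).

The pair-HMM is the standard three-state model (match `M`, two inserts),
with `M→insert = δ` (default 0.02), insert self-loop `ε` (default 0.80),
no direct insert↔insert transitions and no end state.  Match emissions are
derived from half-bit BLOSUM62 scores as `q_ij ∝ p_i p_j 2^{S_ij/2}` with
the background frequencies bundled in
`inst/extdata/pairhmm_default.yaml`; insert emissions are the marginals of
`q`.  All parameters are overridable through that file or
`pair_hmm_params()`.  Forward–backward runs in log space, so no scaling
tricks are needed and underflow cannot occur.

**Stage 2 — guide trees.** Four agglomerative builders over the similarity
matrix.  The averaging builder (called UPGMA, following common usage in
alignment tools, although the plain average of the two removed scores is
technically the WPGMA update) repeatedly joins the most similar pair;
SLMIN propagates the *maximum* of the two removed scores and SLMAX the
*minimum* — the names are kept as the framework convention spells them,
inverted relative to similarity intuition, and the documentation flags
rather than "fixes" this.  Neighbor-Joining runs on the distance transform
`d = (100 - M)/100`, clamps negative branch lengths to zero, reduces until
two clusters remain and roots at the midpoint of the final connecting edge
(progressive alignment needs a root; midpoint rooting of the last join is
the natural choice and mirrors Clustal-like behaviour).  All builders are
deterministic: equal-best candidates are resolved by the lexicographically
smallest pair of cluster representative ids.  Tests cross-check the
agglomerators against `hclust` (mcquitty/single/complete on the distance
transform) and NJ against `ape::nj` on additive matrices.

**Stage 3 — consistency.** The constraint library stores, per sequence
pair, non-negative weights on residue-position pairs: pair-HMM posteriors
thresholded at `ε = 0.01` by default (an alignment-derived mode is
available for speed, weighting matched pairs by the pairwise identity).
The library source is deliberately decoupled from the Stage-1 scorer: all
consistency classes use the posterior library regardless of which scorer
built the similarity matrix.  A single round of triplet extension
reinforces each pair with evidence routed through every third sequence,
`W'(i_x, j_y) = W(i_x, j_y) + Σ_z Σ_k min(W(i_x, z_k), W(z_k, j_y))`;
one round is the established default for this transformation.  During
profile alignment the library weight is rescaled so the library maximum
maps to the largest substitution-matrix entry (times `λ`, default 1);
this keeps the bonus commensurate with the DP match scores so gap
penalties stay meaningful, and `λ = 0` reproduces the progressive-only
classes bit for bit.

**Stage 4 — profile alignment.** Clustal W-style: sequence weights come
from the guide tree (each leaf sums branch length over its root path
divided by the number of leaves sharing that branch, normalized to mean
1), the column-pair score is the weight-normalized sum of substitution
scores over residue pairs (gap residues contribute nothing) plus the
averaged library bonus, and gap opening is position-specific: multiplier
0.3 at positions touching a gap-containing column, 0.5 within 2 columns
of one, 1 elsewhere, with terminal gap runs free by default.  Gap runs
cost `open × mult + (g − 1) × extend` with defaults 10/0.2 for profiles
and 10/0.5 for Stage-1 pairwise scoring.  The substitution matrix is
chosen adaptively per merge from the mean cross-profile similarity:
BLOSUM80 at ≥ 60%, BLOSUM62 at ≥ 40%, BLOSUM45 below (a fixed matrix can
be configured instead).  Hydrophilic-stretch and residue-specific gap
modifiers are not implemented; the two rules above capture the mechanism
that matters for gap placement.  Delayed alignment (reordering merges away
from the guide tree) is deliberately absent so that the tree choice's
effect stays observable.  DP ties prefer the diagonal, then the vertical,
then the horizontal move, which makes every alignment byte-reproducible.
Because gaps are only ever inserted as whole columns into one profile,
gaps committed at an early merge persist to the final alignment — the
classic "once a gap, always a gap" behaviour that Stages 3 and 5 exist to
mitigate.

**Stage 5 — iterative refinement.** Tree-restricted partitioning: each
sweep visits every guide-tree edge, deepest first, cuts it, splits the
alignment rows into the leaves below the edge and the rest, removes
all-gap columns on each side, realigns the two profiles with the Stage-4
engine (including the library for the CI class), and accepts the
candidate only if its weighted sum-of-pairs
`WSP(A) = Σ_l Σ_{i<j} w_ij S(a_il, a_jl)` is *strictly* higher than the
best so far (strictness guarantees termination; comparison is always
against the global best, matching a best-so-far reading of the acceptance
rule).  `w_ij` is the product of the Clustal weights normalized to mean 1
over pairs; an SP mode sets all weights to 1.  Pairs involving a gap
contribute zero — the objective has no affine term, the simplest faithful
reading of the column-sum definition.  Sweeps stop when one finds no
improvement or after `max_iterations` sweeps (default 100; the cap counts
full sweeps because the per-edge steps are the inside of one iteration).
Improving WSP does not imply improving alignment quality against a
reference — the harness therefore always records both WSP and Developer
Score and never asserts that refinement helps the latter.

## Strategies and the comparison harness

Five scorers × four tree builders give 20 variations; each variation runs
as one of four classes — P (Stages 1–2–4), C (adds Stage 3), I (adds
Stage 5), CI (adds both) — for 80 strategies.  A workspace caches Stage
1/2 artifacts and the extended library, so strategies sharing a variation
never recompute them.

Evaluation uses the Developer Score: the fraction of reference-aligned
residue pairs, taken from reference columns whose gap fraction is
strictly below 20%, that share a column in the test alignment.  Instances
are grouped by the reference's mean pairwise identity (matched residues
over non-gap-gap columns, averaged over pairs) into bands `[0, 20)`,
`[20, 40)`, `[40, 80)`; the boundaries are half-open because the printed
band edges do not state inclusivity, and values ≥ 80 are tagged `high`
and excluded from band-style comparisons.

Class comparisons use one-sided paired Wilcoxon signed-rank tests
(alternative "A > B") per variation, six hypotheses per variation
(C>P, I>P, C>I, CI>P, CI>I, CI>C).  Zero differences are dropped (the
classic convention); with ≤ 25 non-zero differences the p-value is exact,
computed by convolving the rank-sum distribution over doubled midranks so
ties are handled exactly; larger samples use the normal approximation
with tie correction and continuity correction.  An all-zero difference
vector returns p = 1 by convention.  A Shapiro–Wilk screen
(`shapiro_normality`) is provided for the normality check that motivates
the non-parametric choice.  No multiple-testing correction is applied
across the six hypotheses, matching the harness this package reproduces.

## The synthetic-data generator

`generate_family()` evolves a root sequence (drawn from BLOSUM-derived
stationary frequencies, length 100 by default) down a random binary tree
(branch lengths uniform on 0.5–1.5) with per-site substitution probability
`sub_rate × branch length` (redraws from the stationary distribution, so a
fraction of "substitutions" silently resample the same residue, as in
Jukes–Cantor-style models) and Poisson indel events of geometric length
(mean 1.5, rate 0.02 events per site per unit branch).  Every residue
carries a column key inherited from its parent; insertions mint fresh keys
placed between their neighbours, so homology — and hence the true multiple
alignment — is tracked exactly and never spuriously merged across
lineages.  `generate_band_suite()` rejection-samples families until the
reference identity lands in the requested band, with substitution-rate
presets 0.37/0.24/0.12 for bands 1/2/3 chosen so that typical leaf-to-leaf
paths land near the band centres.

What the generator does *not* emulate: domain and motif architecture,
rate heterogeneity across sites, long terminal extensions, and the
structural constraints behind curated benchmark references.  Passing the
recovery tests on these families therefore demonstrates that the pipeline
is internally correct and recovers tractable homology, not that it matches
hand-curated structural alignments on real protein families.

## Numerical choices and problem sizes

* The affine-gap DP keeps full tables with traceback; a rolling-two-row
  linear-space scorer cross-checks the full table in the tests.  At the
  family sizes this package targets (tens of sequences, hundreds of
  residues) quadratic space is a few megabytes.
* Forward–backward, MEA, LCS and the triplet extension run in compiled
  code; posteriors below 0.01 are dropped from the library to keep it
  sparse in content.
* Degenerate inputs: empty sequences, all-gap alignments and libraries
  with no mass are rejected with informative errors rather than silently
  scored 0; a family whose lineage loses (nearly) all residues is
  regenerated, up to a bounded number of retries.
* Test and acceptance runs use deliberately small problem sizes — oracle
  checks enumerate complete search spaces at lengths ≤ 5 (alignments),
  ≤ 4 (HMM paths) and n ≤ 10 (sign assignments), and the end-to-end
  recovery suite uses 10 band-3 families of 6 sequences × ~100 residues —
  chosen so the complete suite exercises every kernel against brute force
  while remaining quick to run.

## Known limitations

* Guide trees are strictly binary; multifurcating input Newick is
  rejected rather than resolved arbitrarily.
* The Clustal W gap-modifier constants (0.3 within, 0.5 adjacent, reach
  2) are this package's pinned defaults, exposed in `gap_model()`; other
  implementations use different constants and will not be reproduced
  bit-for-bit.
* The adaptive matrix ladder uses BLOSUM80/62/45; there is no very-low
  identity rung below BLOSUM45.
* PROBA similarity and the posterior library share one pair-HMM; tools
  that train pair-specific transition probabilities will differ.
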