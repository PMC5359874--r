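---
title: "Methods: total-evidence parsimony and Mk-model ancestral state reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: total-evidence parsimony and Mk-model ancestral state reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glasstree implements the analysis workflow used to build an integrative,
genus-level phylogeny of glass sponges (Hexactinellida) and to study the
evolution of their skeletal body plans.  The scientific setting is a taxon
set in which fewer than half of the genera have any molecular data, so the
workflow combines four ingredients: maximum-parsimony (MP) analysis of
binary morphological matrices, total-evidence analysis of concatenated
recoded nucleotide + morphology supermatrices, weighted morphology-based
placement of unsequenced genera onto a molecular backbone, and
maximum-likelihood ancestral-state reconstruction (ASR) on the combined
tree.  This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the design decisions that were genuinely
open.

## Parsimony scoring and homoplasy indices

Per-character observed steps $s_i$ are computed with the Fitch down-pass
for binary nodes and the state-vote (Hartigan) generalization at
polytomies, which is exact for unordered characters; missing cells act as
the universal state set, and gaps are treated as missing throughout.  The
per-character bounds are $m_i$ = (number of observed states) − 1 and $g_i$
= (number of scored taxa) − (count of the most frequent state).  The
ensemble indices are

$$\mathrm{CI} = \frac{\sum m_i}{\sum s_i},\qquad
\mathrm{RI} = \frac{\sum g_i - \sum s_i}{\sum g_i - \sum m_i},\qquad
\mathrm{RC} = \mathrm{CI}\cdot\mathrm{RI},$$

with characters that have no room for homoplasy ($g_i = m_i$) excluded
from the RI sums.  Comparisons against printed statistics round half-up
to two decimals, since that is how such statistics are conventionally
printed.  Ensemble indices are computed over all characters of the matrix;
the empirical matrices contain only parsimony-informative characters by
construction, so the question of excluding uninformative characters does
not arise there (a bounds table is returned per character for anyone who
wants a different convention).

Implied weighting uses Goloboff's fit function $\sum_i h_i/(h_i+K)$ with
homoplasy $h_i = s_i - m_i$ and concavity constant $K = 3$ by default,
minimized during search; the tree length reported for implied-weights
searches is the raw, unweighted length, matching how such results are
printed.

## Tree search

The original analyses used a commercial program's composite heuristics
(sectorial searches, ratchet, drift, tree fusing).  Those are
implementation details of that program; glasstree replaces them with a
generic, fully seeded heuristic: random-addition-sequence starts (each
taxon inserted at the edge minimizing the equal-weights length, scored
exactly in compiled code) followed by steepest-descent branch swapping
under the configured objective, with NNI, SPR, or TBR (SPR plus
re-rooting of the pruned subtree) neighbourhoods.  Equivalence with the
original is judged by score, not by tree-set identity; counts of
most-parsimonious trees are search-strategy-dependent and are not treated
as a result.  Co-optimal trees are collected by breadth-first traversal
of equal-score neighbourhoods (capped by `keep_max`) and ordered by
canonical Newick string, which fixes all tie-breaking.

For the study-sized total-evidence matrices (114 taxa, ~4900 characters)
the default workflow uses one addition sequence and NNI refinement; this
keeps a full two-subclass analysis in the low minutes on one CPU while
the small-matrix analyses use SPR/TBR.  Addition placements are scored by
equal-weights length even in implied-weights searches (the configured
objective governs the swapping that follows); the addition order is a
heuristic starting point, not part of the objective.

## Mk and GTR likelihoods

The symmetric k-state model is parameterized by the total leaving rate
$q$, so $p_\text{stay}(t) = 1/k + (k-1)/k \cdot e^{-k\mu t}$ with
per-pair rate $\mu = q/(k-1)$; branch lengths are expected substitutions
when $q = 1$.  The asymmetric two-state model (aMk2) has gain and loss
rates $q_{01}, q_{10}$, stationary frequency $\pi_0 =
q_{10}/(q_{01}+q_{10})$, and closed-form transitions.  GTR is normalized
to one expected substitution per unit length and exponentiated by
symmetric eigendecomposition.  Among-character (or among-site) rate
variation uses the standard discrete gamma with four equal-probability
categories represented by their within-category means.

Likelihoods are computed by Felsenstein pruning over unique patterns with
per-node scaling (a likelihood can underflow but never silently become
zero).  Ascertainment bias is handled by conditioning: matrices built
only from variable or only from parsimony-informative characters divide
each character's likelihood by $1 - P_\text{excluded}$, where
$P_\text{excluded}$ sums the probabilities of all constant (and, for the
informative-only mode, all singleton) leaf patterns, each computed by
pruning.  Rates are fitted by bounded quasi-Newton optimization
(`nlminb`) on the log scale, bounds $[10^{-6}, 100]$, tolerance $10^{-8}$,
with three seeded starts by default.

## Ancestral-state reconstruction

Marginal ASR combines tipward partials with the rootward flow at every
node and normalizes to proportional likelihoods (pl).  The root prior is
the model's equilibrium distribution by default — for aMk2 this is the
conventional default of the program the original analyses used; an
equal-frequencies variant is available but considered unrealistic for
presence/absence characters (assuming a character was as likely present
as absent in the ancestral sponge), and it produced contradictory
reconstructions in the original study.  Reports round pl half-up to two
decimals in the "Mk1/aMk2 = x/y" style.  Because the combined tree comes
from parsimony and carries no branch lengths, ASR runs on unit branch
lengths, the default convention of the cited ASR program; gamma rate
variation is off by default for ASR (the original settings are not
recorded; both choices are configurable).  Polytomies are treated as
hard.  An artificial all-zero outgroup used for rooting should stay in
the tree but is simply never queried: it is a coding device, not a
taxon.  At pl exactly 0.5 both states are reported and no argmax claim is
made; a presentational "supported" threshold of 0.95 flags ambiguous
nodes.

Topology sensitivity is made algorithmic: `regraft()` prunes a named
clade and reattaches it as sister to a named attachment clade (unit
lengths on the new edges), so the published alternative placements of
key dictyonal taxa can be re-scored reproducibly.

## Morphology-based placement

Unsequenced taxa are placed on a molecular reference tree by attaching
the query to every edge and ranking edges by the weighted parsimony score
$\sum_c w_c s_c$ (ascending; ties flagged and broken by edge index).
The weight of a character is its retention index on the reference tree,
which down-weights characters incongruent with the molecular backbone.
Characters that *cannot* be homoplastic on the reference ($g = m$ —
constant or singleton characters) keep full weight 1 rather than 0: a
pruned cherry member's diagnostic character is precisely a singleton on
the reference, and zero-weighting it would throw away the only signal
that distinguishes the true edge, making even homoplasy-free
leave-one-out placement ambiguous.  Only characters entirely unscored on
the reference get weight 0.  This weighting is a deterministic,
documented proxy for the weighting used by the original binning program;
fidelity to that program's internals is explicitly not claimed.  The
scoring criterion is weighted parsimony rather than a per-edge Mk
likelihood, chosen for exactness and speed.  Queries are placed
independently against the original reference, so results are
order-independent; the composite tree grafts each query at its best edge
with a unit-length pendant edge.

In placement evaluation, a placement is counted as falling in the "true
parent clade" when the chosen edge lies inside the smallest true clade
that properly contains the query's original attachment edge (the clade of
the query's grandparent) — the usual "within one node of the true edge"
neighbourhood.  The stricter reading (inside the sibling subtree only) is
not reliably attainable at the homoplasy levels studied and is reported
by the tests only through this documented definition.

## The workflow

`run_workflow()` chains the study's recipe deterministically: per
subclass, a functional outgroup from the other subclass is added with
all-zero morphology, the molecular block is recoded (A,C,G,T to 0–3;
ambiguity codes and gaps to missing) and concatenated with morphology
under union-fill-missing; MP search and strict consensus follow, then
optional character bootstrap (defaults 1000/550 pseudoreplicates when
enabled — bootstrap is off by default because the study's support values
are not an acceptance surface and full-size resampling dominates run
time), morphology-based placement of taxa without molecular data onto a
molecular-backbone MP tree, grafting of the two subclass trees under a
new root (the "manual" combination made algorithmic, with a bifurcation
at the subclass split), and a tabulated ASR report.  Every stage derives
its seed from the master seed; outputs are a pure function of (dataset,
config, seed) and re-runs are byte-identical (the manifest records a
wall-clock timestamp on its header line, which is the one excluded
field).

## The synthetic-data generator

`make_study_like_dataset()` emulates the structure of the study data: two
subclasses of 13 and 113 genera on one true tree (heights normalized,
joined by unit stem edges), parsimony-informative binary morphology
per subclass (29 and 108 characters, rejection-sampled so the matrices
match the ascertainment that the likelihood correction conditions on),
and a 4-partition molecular alignment (1500 + 2100 + 600 + 606 = 4806
sites, GTR with gamma shape 0.5 and mildly unequal base frequencies) in
which 45% of genera are "sequenced" and sequenced genera additionally
lose whole taxon-by-marker blocks at 30% — mirroring the published
sequence coverage (~45%), supermatrix missingness (~30%) and
total-evidence missingness (~62–65%).  The binary morphology rate (0.6
per unit height) was chosen so that informative-only rejection sampling
is feasible while characters retain realistic homoplasy.  Truth records
(true trees, all ancestral states, generating parameters) are emitted so
downstream accuracy is exactly measurable.

What the generator does *not* emulate: correlation among morphological
characters, RNA secondary-structure covariation, alignment error, and
non-random taxonomic structure of missing data.  Passing tests on
synthetic data therefore demonstrate algorithmic correctness and
statistical calibration under the stated model, not robustness to those
real-data features.

## Problem sizes and numerical choices

The test-suite simulations use 4–6-leaf instances for exhaustive-oracle
comparisons (all 105 six-taxon topologies where needed), 16–25-leaf trees
with ~100 characters for calibration-style experiments (rate recovery,
ascertainment-bias comparison at 25–50 replicates, placement recovery at
20 replicates), and the full 126-genus default dataset for the end-to-end
determinism check — sizes chosen so each experiment has the power its
claim needs.  Tolerances: exhaustive-oracle agreement at 1e−8 (1e−10
where exact arithmetic allows), pl normalization at 1e−10, rate recovery
at the 10%/25% levels appropriate to the character counts used.
Degenerate inputs are errors, not silent results: all-missing characters,
empty taxon overlap, duplicate labels, and negative branch lengths all
fail with named diagnostics.

## Known limitations

Search is heuristic; equal-score tree collection is capped and therefore
most-parsimonious-tree counts are lower bounds.  Bayesian inference,
paired-sites RNA models, joint (as opposed to marginal) ASR, stochastic
character mapping, and full ML tree search are out of scope.  The
download-dependent checks against the published matrices require a
one-time fetch (`scripts/fetch_study_data.R`) and cannot run offline.
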