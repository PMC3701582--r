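---
title: "Ligand-based target fishing with Parzen-Rosenblatt scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based target fishing with Parzen-Rosenblatt scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

targetfishR predicts which protein targets a small molecule is likely to
modulate, using nothing but the structures of ligands already known to be
active against each target. This vignette describes the model, the curation
pipeline around it, the numerical choices the implementation makes, and what
the synthetic benchmark used by the test suite does and does not demonstrate.

## The data model: three stages of family curation

A *family* is a set of compound identifiers associated with one target.
Bioactivity databases associate compounds with targets whenever any
experimental record links them — including records demonstrating
*inactivity*. The pipeline therefore distinguishes three stages:

* **original** — every compound with any record against the target;
* **filtered** — only compounds with at least one record that qualifies as
  *active* under the rule table below;
* **refined** — subsets of a filtered family that share a structural
  scaffold, obtained by parameter-free clustering.

Refined families are the scoring unit: a target bound by two unrelated
chemotypes is represented as two families, so a query need only resemble one
chemotype to be retrieved.

## Activity rules

Eight assay read-outs are supported. Concentration-type read-outs use upper
bounds (lower = more potent); the two percent-type read-outs use lower
bounds. The thresholds, with their exact strict/non-strict directions:

| read-out | active when | unit |
|---|---|---|
| IC50 | value ≤ 50 | µM |
| Ki | value < 20 | µM |
| Kd | value ≤ 10 | µM |
| EC50 | value ≤ 40 | µM |
| ED50 | value ≤ 10 | µM |
| Potency | value ≤ 10 | µM |
| Activity | value ≥ 40 | % |
| Inhibition | value ≥ 45 | % |

Concentrations are normalized internally to nM before comparison; percent
values pass through unchanged.

Records carry a relation qualifier (`=`, `<`, `<=`, `>`, `>=`, or
unspecified, treated as `=`). `classify_record()` resolves censoring by
interval logic: the relation and value define the feasible interval for the
true measurement, and the record is labelled `active` (or `inactive`) only
when the *entire* interval falls on one side of the threshold; anything
compatible with both sides is `indeterminate` and never promotes a compound
into a filtered family. One consequence worth noting: for the strictly
thresholded Ki rule, a record "Ki ≤ 20 µM" is indeterminate, because Ki
exactly 20 µM would be inactive. An explicit active/inactive label on the
record overrides the numeric rule — curated labels are treated as stronger
evidence than a single numeric comparison. When one compound has several
records against one target, it is active if *any* record is active
("any-active"): membership is defined by the existence of qualifying
evidence, not by consensus.

## Fingerprints and similarity

Molecules are represented as sparse sets of hashed circular-substructure
identifiers (the Morgan/ECFP construction): each atom contributes the
identifier of its environment at radius 0, 1, ..., r, where the radius-0
invariant combines atomic number, heavy-atom degree, bond-order sum, formal
charge and implicit hydrogen count, and each iteration hashes the atom's
identifier together with the sorted (bond order, neighbour identifier)
pairs. The default radius 2 corresponds to ECFP4-style diameter-4
environments. Feature sets are kept sparse rather than folded to a fixed bit
length, so Tanimoto similarity

$$t(x_i, x_j) = \frac{|A \cap B|}{|A \cup B|}$$

is unaffected by folding collisions; `fold_fingerprint()` provides 1024- or
2048-bit folding for interoperability with bit-vector tools. SMILES/SDF
parsing and canonicalization go through OpenBabel (via ChemmineR and
ChemmineOB); every molecule is canonicalized before its graph is built, which
makes feature sets invariant to the atom order of the input and pins down a
deterministic kekulized form for aromatic systems. Hydrogens are implicit
and stereochemistry is ignored.

## From similarity to probability, and the PR-score

Random pairs of molecules are overwhelmingly dissimilar, so a raw Tanimoto
value is hard to interpret. The package models the exceedance probability of
a random pairwise similarity with a Gaussian kernel:

$$p(X > t) = \exp\!\left(-\frac{t^2}{2h^2}\right)$$

with bandwidth (smoothing factor) h, default **0.125** — the value that fits
the exceedance curve of all-against-all similarities in a large bioactivity
database; `fit_smoothing_factor()` re-fits h to any sample of similarities
by least squares between the empirical exceedance fraction and the model on
a fixed grid (x from 0.01 to 0.99 in steps of 0.01, optimized over h in
(0.001, 2)). At h = 0.125, p(0) = 1, p(h√2) = e⁻¹ and p(1) = e⁻³² — the
closed-form anchors the test suite checks.

The similarity of a query molecule $x_i$ to a family
$\omega = \{x_1, \dots, x_n\}$ is the Parzen-Rosenblatt mean of the
pairwise exceedance probabilities:

$$f(x_i, \omega) = \frac{1}{n} \sum_{j=1}^{n} p\!\left(X > t(x_i, x_j)\right)$$

Lower scores are more significant. The family-level "p-value" and the
PR-score are the same number; the code says `pr_score` throughout. A
prediction is called *significant* at `pr_score <= alpha`, default
alpha = 0.05. When the query is itself a member of a family, its fingerprint
is removed from that family before scoring (self-exclusion), mirroring
held-out validation semantics; a family emptied by self-exclusion is omitted
and reported rather than scored against nothing. Ranking ties are broken by
family id so output order is deterministic.

## Parameter-free clustering

Refined families come from a PFClust-style procedure (`pfclust()`) that
chooses its own similarity threshold and cluster count:

1. **Threshold candidates by randomization.** 100 rounds (seeded) of random
   subsets of the items; each round records the subset's mean pairwise
   similarity. Fixed percentiles (50, 60, 70, 75, 80, 85, 90, 95, 97, 99) of
   that empirical distribution become candidate thresholds.
2. **Agglomerative construction per candidate.** Seed a cluster with the
   most similar unassigned pair (required to be at or above the threshold
   *and strictly positive* — zero similarity is never cohesion); repeatedly
   absorb the unassigned item with the highest mean similarity to the
   cluster while that mean stays at or above the threshold. Unabsorbed items
   become singletons.
3. **Model selection by silhouette.** Each candidate partition is scored by
   the silhouette computed from the similarity matrix (distance 1 − s), with
   singleton items participating as their own groups. The *reported*
   `quality` is the mean silhouette of items in clusters of size ≥ 2. The
   *selection* criterion averages over all items with singletons
   contributing 0 (the standard silhouette convention for singleton
   groups); without this, a candidate could look better merely by demoting
   borderline items to singletons, since dropped items leave the clustered-
   only average. Ties (within 1e−12) go to the candidate with fewer
   clusters. A partition with a single group has no defined separation and
   scores 0.

Degenerate cases: one item gives one singleton; an all-zero off-diagonal
matrix gives all singletons. `refine_families()` runs this per filtered
family on the members' Tanimoto matrix; every structural cluster and every
singleton becomes one refined family carrying the parent's id, so the union
of a parent's refined families reproduces its membership exactly. Each
family derives its own RNG stream from the master seed, so results do not
depend on the order in which families are processed.

## Validation protocol

`monte_carlo_cv()` implements Monte Carlo (random-subsampling)
cross-validation: each of the (default) 5 runs independently holds out
⌈10%⌉ of every family's members as queries — "fivefold" here means five
independent 10% resampling runs, not a 5-fold partition, matching the usual
Monte Carlo CV convention. Families with fewer than 2 members are never
queried (holding out the only member would leave nothing to score against)
but still compete in rankings; they are listed in the report's `skipped`
field. When a held-out query is scored, the query compound is removed from
*every* family's training membership, consistent with `predict_targets()`
self-exclusion.

Retrieval is summarized as top-1 and top-4 hit rates (parent family ranked
first, or within the first four). For the Matthews correlation coefficient,

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

the confusion accounting treats each query as one positive prediction — its
top-ranked family. A correct top-1 is a TP; otherwise the query contributes
one FP (the wrong family) and one FN (the missed parent); every other family
ranked for that query contributes a TN. This is an interpretive choice (the
counting of TN/FN is not uniquely determined by "hits to other families are
false positives") and is stated here prominently for that reason. A zero
denominator factor yields MCC = 0, the standard convention.

## Profiling a compound panel

`profile_matrix()` scores every panel compound against every family (rows =
families, columns = compounds). Panels can then be clustered two ways and
the groupings compared with `cluster_concordance()`:

* **by structure** — `pfclust` on the panel's Tanimoto matrix;
* **by activity profile** — each compound's column of PR-scores is a
  position vector; pairwise Euclidean distances d between columns are mapped
  to similarities s = 1/(1 + d) and clustered. The map is monotone, bounded
  in (0, 1] and parameter-free; the specific form is a design choice, as
  only "a similarity matrix" is prescribed by the method. Families that
  cannot be scored for a compound (emptied by self-exclusion) enter the
  column as 1, i.e. maximally insignificant.

## The synthetic benchmark

`generate_library()` builds libraries with *planted* ground truth so the
whole pipeline is testable without any external database. Design choices:

* **Chemistry.** Each planted scaffold is a fixed core of 12–16 heavy atoms
  carrying an attachment amine; members append one of 16 small (1–4 heavy
  atoms, deliberately size-homogeneous) substituents, like a congeneric
  series. The 12 family cores and 6 decoy cores were chosen once, by
  maximizing the minimum cross-core fingerprint distance over a larger
  candidate pool of ring systems spread across chemotypes (carboaromatics,
  azines, five-membered heteroaromatics, aliphatic ring systems, sulfones,
  lactams). Measured at radius 2, cross-core Tanimoto stays at or below
  about 0.34 against family cores while within-scaffold similarity stays
  above about 0.55 — separable, but far from trivially so.
* **Activities.** Each active member gets one record with the value placed
  at threshold × (1 − noise·u) on the active side (mirrored for inactive
  records and for the percent rules), u uniform in (0.2, 1), noise default
  0.5; units alternate between µM and nM so unit normalization is always
  exercised. Inactive noise members are structurally unrelated decoys with
  inactive-side records: they join original families but must disappear
  from filtered ones.
* **Defaults.** 3 families × 2 scaffolds × 8 members, no noise — a
  configuration in which filtering plus refinement should recover exactly
  the 6 planted scaffold series. The stage-ordering benchmark adds 30%
  inactive decoys, which degrade original-family retrieval but not
  filtered/refined retrieval.
* **Problem sizes.** The test suite and acceptance script run at these
  sizes (tens of molecules, thousands of scored pairs), which exercise every
  code path while keeping the default test run fast.

What passing these benchmarks does *not* show: real bioactivity data has
overlapping chemotypes shared across targets, assay noise that correlates
with neither structure nor family, family sizes spanning four orders of
magnitude, and a far flatter similarity landscape. Absolute retrieval rates
on the synthetic libraries (near 100%) say nothing about absolute rates on
real databases; only the *relative* behaviours (refined ≥ filtered ≥
original, chance-level MCC under label shuffling, parameter recovery) are
meaningful, and those are the properties the tests assert.

## Numerical and degenerate-input choices

* All randomness flows from explicit integer seeds; per-family and per-run
  sub-seeds are derived by hashing the master seed with a stream label, so
  results are independent of iteration order and reproducible to the byte.
* Tanimoto on two empty feature sets is an error (not 0/0 = NaN); a
  fingerprint radius mismatch is an error rather than a silent comparison.
* `fit_smoothing_factor()` refuses degenerate samples (fewer than 100
  values, or all values equal).
* `mcc()` refuses all-zero counts and returns 0 on a zero denominator
  factor.
* Families must be non-empty; refined families must name their parent;
  family JSON round-trips are membership-order-insensitive.

## Known limitations

* OpenBabel's kekulized SDF output is the structural ground truth; exotic
  tautomer/aromaticity edge cases follow OpenBabel's perception.
* The hashed-identifier space (31-bit) can in principle collide; sparse
  sets make this rarer than in folded fingerprints but not impossible.
* The PFClust threshold-candidate scheme is a published-outline
  reconstruction with all free constants pinned (rounds, percentiles) and
  exposed as arguments; other constants would give slightly different
  refined partitions.
* Scoring a query against singleton refined families reduces the PR-score
  to a single pairwise p-value; these predictions are supported but rest on
  one known ligand.
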