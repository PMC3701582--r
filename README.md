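# targetfishR

Ligand-based protein target prediction ("target fishing") for
cheminformatics and early drug discovery. Given the ligands already known to
be active against each protein target, targetfishR predicts which targets a
query molecule is likely to modulate — including off-target,
polypharmacology-style predictions for whole compound panels.

## What it does

Bioactivity databases associate compounds with targets through heterogeneous
experimental records (IC50, Ki, Kd, EC50, ED50, potency, % activity,
% inhibition), including records that demonstrate *inactivity*. targetfishR
implements the full curation-and-scoring pipeline around that reality:

1. **Filter** — rule-based thresholds (e.g. IC50 ≤ 50 µM, Ki < 20 µM,
   Inhibition ≥ 45%) turn raw records into active/inactive/indeterminate
   labels, with censored relations (`<`, `>`, ...) resolved conservatively
   by interval logic. Per target, the compounds with at least one qualifying
   active record form a *filtered family*.
2. **Refine** — a parameter-free clustering (PFClust-style: randomized
   threshold candidates + silhouette model selection, no cluster count ever
   supplied) splits each filtered family into scaffold-coherent *refined
   families* from the members' circular-fingerprint Tanimoto matrix.
3. **Score** — a Tanimoto similarity t is transformed into an exceedance
   probability p(X > t) = exp(−t²/2h²) with bandwidth h = 0.125, and the
   query-family **PR-score** is the Parzen-Rosenblatt mean over the n family
   members:

   f(xᵢ, ω) = (1/n) Σⱼ p(X > t(xᵢ, xⱼ))

   Lower is more significant; predictions at PR-score ≤ 0.05 are flagged.
4. **Validate** — Monte Carlo cross-validation (5 runs × 10% holdout per
   family) with top-1/top-4 retrieval rates and the Matthews correlation
   coefficient, comparable across original / filtered / refined family
   definitions.
5. **Profile** — PR-score matrices for compound panels, plus clustering of
   the panel by structure and by predicted-activity profile, and the
   concordance between the two groupings.

A synthetic-library generator with planted scaffold families makes the whole
pipeline testable end to end with no external database. See
`vignettes/targetfishing.Rmd` for the model, its assumptions and the design
choices.

## Worked example

```r
library(targetfishR)

dir <- tempfile("demo")
lib <- generate_library(synth_config(seed = 42), dir)   # 3 planted families x 2 scaffolds x 8 members
mols <- read_molecules(lib$paths$molecules)
records <- read_activity_table(lib$paths$activities)
fps <- compute_fingerprints(mols, radius = 2)

filtered <- build_filtered_families(records)
refined <- refine_families(filtered, fps, seed = 42)
filtered
#> <family_set: 3 families (filtered=3)>
refined
#> <family_set: 6 families (refined=6)>
refined[["FAM02.c1"]]
#> <family FAM02.c1 [refined] parent=FAM02: 8 members>
```

Filtering found the 3 planted targets; refinement split each into its 2
planted scaffold series. Now rank all refined families for a query analogue
of one series:

```r
query <- compute_fingerprint("CC1CCC2CCC(F)CC2C1CCNCCO", compound_id = "query1")
preds <- predict_targets(query, refined, fps, activities = records)
head(preds, 4)
#>   query_id family_id  target_name pr_score rank significant known_activity
#> 1   query1  FAM02.c2 target-FAM02 6.96e-07    1        TRUE       untested
#> 2   query1  FAM01.c2 target-FAM01 6.74e-01    2       FALSE       untested
#> 3   query1  FAM03.c1 target-FAM03 6.99e-01    3       FALSE       untested
#> 4   query1  FAM02.c1 target-FAM02 7.13e-01    4       FALSE       untested
```

The query's scaffold series is retrieved at rank 1 with PR-score ≈ 7×10⁻⁷
(far below the 0.05 significance cut-off); every other refined family —
including the *sibling* scaffold of the same target, FAM02.c1 — is correctly
insignificant. Cross-validate retrieval over the whole library:

```r
monte_carlo_cv(refined, fps, runs = 5, fraction = 0.1, seed = 7)
#> <cv_report [refined]: 5 runs>
#>  run queries top1_hits top4_hits TP FP TN FN mcc
#>    1       6         6         6  6  0 30  0   1
#>    ...
#> mean top-1 100.0%  mean top-4 100.0%  mean MCC 1.000
```

On this separable synthetic benchmark retrieval is perfect; the vignette
discusses why absolute rates on real data are a different matter.

## Command line

A thin shim over the same functions is installed at
`inst/cli/targetfish` (`system.file("cli", "targetfish", package = "targetfishR")`):

```sh
targetfish simulate --out sim --seed 7
targetfish filter   --activities sim/activities.csv --out filtered.json
targetfish refine   --families filtered.json --molecules sim/lib.smi --seed 7 --out refined.json
targetfish predict  --query query.smi --families refined.json --molecules sim/lib.smi --out predictions.csv
targetfish validate --families refined.json --molecules sim/lib.smi --runs 5 --seed 7 --out report.json
targetfish profile  --panel panel.smi --families refined.json --molecules sim/lib.smi --out matrix.csv --clusters clusters.json
```

Every artifact embeds (directly or via its `.manifest.json` sidecar) the
tool version, seed and parameter snapshot; a fixed seed reproduces every
artifact byte for byte.

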