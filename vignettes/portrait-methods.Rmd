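---
title: "Portraits, reversal scores and RRHO: methods and design notes"
author: "sigportrait authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portraits, reversal scores and RRHO: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigportrait)
```

## 1. The signed dysregulation score

Every ingested differential-expression table is collapsed to one score per
gene, `sign1 = -log10(max(p, p_floor)) * sgn(direction)`. The magnitude is
evidence of dysregulation; the sign is the direction of change versus
control. Three conventions matter:

* **p floor** (`p_floor = 1e-300` at ingest): exported DE tables sometimes
  contain `p = 0`; the floor keeps scores finite while preserving order.
  Overlap statistics use a separate, smaller floor (`1e-320`) because
  hypergeometric tails of large overlaps genuinely underflow double
  precision and must not become infinite when −log10-transformed.
* **Duplicate probes**: several array probes can map to one symbol. The row
  with the smallest p-value is kept (ties: first in file order). Rationale:
  downstream use is rank-driven and top-heavy, so the strongest evidence per
  gene is the right summary. This rule is an assumption — the convention of
  the original analyses is not recorded.
* **`direction = 0`** gives `sign1 = 0`: the gene carries no directional
  evidence and joins neither ranking.

Symbols are whitespace-stripped and upper-cased before any comparison, and
an optional alias map rewrites outdated symbols; when two inputs collapse
onto one current symbol the larger |sign1| survives.

## 2. Portrait aggregation

A portrait answers: *which genes are consistently dysregulated, in which
direction, across many studies?* Each study contributes through its
directional ranks only. Genes at rank *r* of a study's up (down) list add
`+w(r)` (`-w(r)`) to their aggregate, with `w` a decreasing staircase over
rank strata — default weight 8 for ranks 1–1000 down to 1 for 7001–8000,
0 beyond. Because any strictly monotone transformation of a study's
p-values leaves its ranks unchanged, every study has equal voice regardless
of its p-value scale (a property the test suite asserts).

The exact weight values are a design choice: the upstream description fixes
only "decreasing values over 1000-rank strata up to 8000". The default
8,7,…,1 is the simplest such scheme; both bounds and weights are
configurable (`weight_scheme()`).

Three filters shape the portrait:

* **Presence**: a gene must be measured in *strictly more than*
  `min_presence_fraction` (default 2/3) of the datasets. With 3 datasets,
  2/3 presence is *not* enough — the inequality is strict.
* **Study cap**: at most two datasets per independent study (manifest
  `study_id`), so no single study dominates. Violations are an error, not a
  silent subset. Composites (`build_composite()`) drop the cap — pooling 11
  exercise datasets is the point — and accept a single table, in which case
  the composite is just that table's weighted directional ranking.
* **Ordering**: |aggregate| descending, ties by |mean sign1| descending,
  then alphabetically, so builds are bit-reproducible. Genes whose votes
  cancel to zero have no defined direction and sort last.

`mean_sign1` averages over studies where the gene is present (no zero
imputation); the presence filter already guarantees coverage.

## 3. Quadrant overlap and the two scores

Two signatures are compared over the **universe of jointly measured genes**
(their symbol intersection). This is an assumption — a fixed global universe
is the alternative — but overlap probabilities are only interpretable over
genes both experiments could have reported, and it matches the companion
rule that screens require > 5000 shared genes (the `compat_threshold`; pairs
below it are flagged, and excluded only in `strict` mode, so toy examples
remain computable).

Both signatures are restricted to the universe *before* their top-n lists
are taken (the same rule the RRHO grid states explicitly). The four list
pairs give counts A (up/up), B (up₁/down₂), C (down₁/up₂), D (down/down),
each tested with the upper-tail hypergeometric probability `P(X ≥ k)`
(observed count included — the standard over-representation convention).
When a directional list is shorter than n, the realized size enters the
hypergeometric parameters; nothing is padded.

The **congruence score** `nlpA + nlpD − nlpB − nlpC` measures same-direction
agreement; the **treatment score** is its exact negation, high when a
treatment reverses the disease lists without reinforcing them. Treatments
are ranked by score, ties broken by reversed-gene count then id.
`reversed_genes()` materializes the B and C intersections as gene sets and
`combine_treatments()` unions them across treatments — the count of a
"theoretical combination" — while reporting pairwise intersections so
shared reversals are visible.

## 4. The RRHO grid

`rrho_grid()` orders both signatures' shared genes by signed score
descending (most up first, most down last) and evaluates every threshold
pair `(i·step, j·step)`: `k` is the overlap of the two prefixes, and the
cell carries `+(-log10 P(X ≥ k))` when `k` strictly exceeds its expectation
`i·step·j·step/N`, otherwise `−(-log10 P(X ≤ k))`. Ties at the expectation
are reported as nonpositive. The corner cell at thresholds `(n, n)`
reproduces `hypergeom_overlap()` on the same prefixes (sign-adjusted), and
transposing the arguments transposes the matrix.

One consequence deserves emphasis because it differs from some published
RRHO variants: for an *exact* sign-flip pair the prefix overlap is
`max(0, tx + ty − N)`, which never exceeds `tx·ty/N`; the whole signed grid
is therefore nonpositive, and reversal manifests as a strong **depletion**
(negative, blue) ramp toward the aligned corners rather than as positive
corner quadrants. Published "stratified" RRHO variants that split the map at
each list's up/down boundary and count from the nearer corner would paint
those corners red instead; the nested-prefix formula implemented here is
the simpler two-tailed convention, and `step` is configurable. The renderer
(`render_rrho()`) uses a diverging palette centered at 0.

## 5. The synthetic world

`generate_study_collection()` emulates the structure the portrait assumes:

* `n_genes = 15000` (protein-coding scale), `n_studies = 6` by default;
* 50+50 **planted** genes with log-uniform p-values on `[1e-12, 1e-4]` and
  a consistent direction in every study. Against a uniform null this lands
  them inside each study's first rank stratum (the `planted_rank_ceiling`
  is validated, and tests confirm realized ranks stay below it);
* **null** genes with uniform p (a valid null) and random signs;
* independent per-study **missingness** (default 10%, typical of
  cross-platform exports) applied to the null background only. Planted
  genes are always measured: they *are* the consistent cross-study signal
  being planted, and the recovery property ("planted genes outrank all
  nulls") presupposes they survive the >2/3 presence filter.

`generate_treatment()` flips the sign of `round(reversal_fraction ×
planted count)` planted genes (drawn evenly from both directions) with
small p-values; all other genes are null. `reversal_fraction = 0` gives a
null treatment, `1` a full planted-set reverser. The default fraction, 0.4,
mirrors the canonical screen example (one 40% reverser among 20 nulls).

What a green test does and does not establish: the generator produces
idealized DE summaries — independent studies, exchangeable null genes, no
correlated probe structure, no platform batch effects, no partial-direction
signals. Recovery of planted genes here validates the *aggregation
arithmetic*, not robustness to the failure modes of real GEO data.

### Statistical limits of the synthetic screen

With 50+50 planted genes, 1000-gene top lists and a ~12,000-gene shared
universe, a 40% reverser adds ~20 genes to each reversal quadrant over a
chance overlap of ~83 (sd ≈ 8.4): about z ≈ 2.4 per quadrant, a treatment
score around 3–4. A null treatment's score is a sum/difference of four
−log10(uniform-ish) tails; the maximum over 20 nulls routinely reaches 2–3.
The two distributions overlap, so the planted reverser ranks first in only
about two thirds of replicates — it cannot win "every replicate" at this
effect size, and a fortiori not at fraction 0.2. The corresponding
acceptance clause is left failing, with this analysis, rather than silently
raising the reversal fraction after the fact; a decisive screen needs
either a near-complete reverser or several hundred planted genes. The
planted-*portrait* recovery clause, by contrast, holds in all tested seeds:
portrait aggregation concentrates six studies of top-stratum evidence
(score 48) that no null gene pattern plausibly matches.

## 6. Numerical and degenerate-input choices

* Hypergeometric tails come from `stats::phyper`; the test suite's oracle
  enumerates subsets with `utils::combn` for every universe up to 12 genes
  and requires agreement to 1e-12 relative error.
* Ties in directional rankings break by |sign1| then alphabetically;
  portrait ties by |mean sign1| then alphabetically — all orderings are
  total, so outputs are byte-reproducible and the pipeline asserts
  identical file hashes on reruns.
* Empty portraits (presence filter removes everything) warn rather than
  error; empty treatment sets rank to an empty table; an empty universe or
  a zero-parseable-row input is an error.
* The exchange format (`Gene.symbol<TAB>sign1`, 6 significant digits)
  round-trips up to that precision; malformed lines fail with their line
  number.

## 7. Known limitations

* The stratum weights are a plausible default, not the original values,
  which were never published; portraits built with different decreasing
  schemes will reorder mid-list genes (the top of the portrait is robust).
* The universe-by-intersection rule makes scores incomparable across
  treatment pairs with very different coverage; the compatibility flag is
  the guard, not a correction.
* No multiple-testing correction is applied inside the RRHO grid (the
  common convention for these heatmaps); cells are descriptive.
* Enrichment analysis of reversed gene sets, meta-analytic effect-size
  models and UMAP embeddings are intentionally out of scope; the portrait
  export is designed to feed such tools.
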