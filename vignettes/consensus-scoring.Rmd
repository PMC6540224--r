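---
title: "Enrichment-optimized consensus scoring: model, parameters and design"
author: "efoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment-optimized consensus scoring: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A virtual-screening benchmark table contains N molecules (A actives, N − A
decoys, with decoys typically >95% of the table) and a set of docking and
rescoring scores per molecule. A consensus model over a subset of k scores
is a linear combination on standardized columns,

    s_i(w) = sum_j  w_j * (x_ij - mean_j) / sd_j,      ||w||_2 = 1,

ranked so that *higher combined score = better*. Orientation is carried
entirely by the signs of `w`: an energy-like score (more negative = better)
simply receives a negative weight. Coefficients live on the unit sphere
because every rank-based quantity in the pipeline is invariant under
positive scaling of `w`; the sphere removes that nuisance dimension. The
sign of `w` is *not* canonicalized — reflecting `w` reverses the ranking and
is therefore a different model.

The fitting objective is the cluster quality

    Q = a_C + (1 - rbar / N),

where `a_C` counts actives among the top C ranked molecules (the "cluster")
and `rbar` is the mean active rank. The second term lies in [0, 1), so the
integer cluster count dominates lexicographically and the whole-distribution
term orders models with equal early recognition. Q deliberately rewards
early recognition rather than whole-ranking separation; ROC AUC is reported
as a complementary diagnostic, never optimized.

Reported metrics are the enrichment factors EF(f) = (a_f/s_f)/(A/N) at
f = 1, 2, 5, 10, 20% with s_f = ceiling(f·N) (the ceiling guarantees a
non-empty selection for any N), the rank-sum AUC with half credit for tied
scores (equivalent to the trapezoidal ROC with ties pooled, hence free of
any tie-break rule), and active-rank asymmetry diagnostics (mean normalized
active rank; sample skewness of active ranks, reported for A >= 3).

## The pipeline

1. **Single-score EF5%.** For every column, the EF on the top 5% is computed
   in both orientations and the larger value kept. These values feed both
   filters.
2. **VIF filter.** Variance inflation factors VIF_i = 1/(1 − R_i²) are
   computed by regressing each standardized column on the others, on the
   *whole* table — redundancy is a property of the score set, and per-split
   filtering would make subset identity unstable across validation repeats.
   While any VIF exceeds 5, the worst column is removed and VIFs are
   recomputed (greedy elimination with recomputation, the standard
   multicollinearity protocol). Exact ties — e.g. a duplicated pair, both at
   the serializable sentinel 10⁶ used for singular fits — are resolved by
   removing the member with the lower single-score EF5%, then the
   lexicographically later name.
3. **Effectiveness filter.** Columns whose best single-score EF5% is below
   2.0 are discarded.
4. **Exhaustive search.** All C(n, k) subsets of the survivors are
   enumerated in lexicographic order and fitted independently; the model of
   a k-subset is warm-started from its best (k−1)-sub-model padded with a
   zero coefficient. Because the local search only ever accepts strict
   improvements, this guarantees best-training-Q monotonicity in k, at the
   cost of one extra start per subset (disable with `warmStart = FALSE`).
5. **Validation.** Five stratified 80/20 train/test splits; for every subset
   and split, coefficients and standardization parameters are estimated on
   the training rows only and the model is applied to the held-out rows.
   Subsets are ranked by average test Q (ties: higher average test EF1%,
   then lexicographic). The winner is refitted on all rows and its full-data
   metrics are reported next to the validation averages, exposing any
   train/test mismatch.

## The optimizer

Q is a piecewise-constant function of `w` (it changes only when two
molecules swap ranks), so gradient and simplex methods are poor fits; the
package uses an accept-if-better Gaussian pattern search on the unit
sphere. From each start, propose `w' = normalize(w + sigma*g)` with
`g ~ N(0, I)`; accept only if Q strictly improves; halve `sigma` after 100
consecutive rejections; stop when `sigma*sqrt(k) < rmsTol` or after
`maxIter` proposals. The RMS tolerance is interpreted as this step-size
convergence criterion, and every CLI artifact echoes that interpretation in
its header. For k = 1 the optimizer is exact: both orientations are
evaluated and the better one returned.

Random starts and all derived seeds are integer-mixed from the base seed,
the validation repeat index and the subset name — never from molecule data —
so a fitted model can never depend on test rows through the RNG, and
identical seeds give byte-identical models, reports and CLI artifacts.

Inside the optimizer, tied combined scores are ranked by strict count
(optimistically for the tied molecules); all *reported* metrics re-rank with
the deterministic lexicographic-id tie-break and a warning is raised when a
tie group straddles a selection boundary. Ties in a continuous combined
score are measure-zero, so the two rankings agree on real tables; the fast
path matters because a screen evaluates Q millions of times.

## Tunable parameters

| parameter | default | unit / meaning |
|---|---|---|
| `clusterSize` | 100 | molecules; top-of-ranking window counted by Q (~3% of a 3000-molecule table) |
| `nStarts` | 12 | random unit starting vectors per subset |
| `maxIter` | 5000 | proposals per start |
| `rmsTol` | 0.001 | stop when sigma*sqrt(k) falls below it |
| `sigma0`, `rejectLimit` | 0.5, 100 | initial step; rejections before halving |
| `k` | 1–3 | subset size; beyond 3 the added cost outweighs the gains |
| `vifMax` | 5 | interrelation threshold |
| `minEf5` | 2.0 | single-score EF5% effectiveness threshold |
| `repeats`, `testFraction` | 5, 0.2 | validation design |

Cluster size 100 is calibrated for ~3000-molecule tables. When a model is
*evaluated on a held-out test split*, the package scales the cluster pro
rata (C_test = round(C·n_test/N), e.g. 20 on a 600-molecule split): with the
unscaled C = 100 the cluster covers the top 17% of a 20% split, every
reasonable model captures all test actives, and subset selection degenerates
into noise. Scaling preserves the tested ranking depth; training-side
optimization keeps C = 100. Splits are stratified
(round(testFraction·A) actives per test set) because an unstratified 20%
draw from a small-active table can contain no actives at all, leaving EF
undefined.

## The synthetic benchmark

`generateScoreTable()` emulates the *structure* of a DUD-style table after
docking and rescoring with a single latent binding propensity:

    t ~ N(0, 1) + delta * label
    score_j = loading_j * t + noiseSd_j * eps_j

Defaults: N = 3000, A = 80 (>95% decoys), 11 columns named after a typical
rescoring panel (ChemPLP/PLP/PLP95, X-Score, MLP interaction, contacts,
three Lennard-Jones terms, two electrostatic terms), graded loadings with
energy-convention signs (contacts and X-Score positive), delta = 2, unit
noise. Optional extras plant a near-duplicate of column 1 (r >= 0.999, for
the VIF filter) and a pure-noise column (for the effectiveness filter).
Molecular weight (200–600 Da) and heavy-atom counts (15–45) are drawn
independently of activity, purely to exercise score normalization.

What the generator does *not* emulate: pose geometry or any physics,
property–activity correlations (real docking scores are size-biased — the
motivation for score-per-MW normalization), heavy-tailed score
distributions, and multi-factor score structure (all redundancy flows
through one latent variable). Passing tests therefore demonstrate that the
machinery is correct under a known generative model, not that any particular
EF level will be reached on real screens.

### The recovery benchmark and its identifiability ceiling

`syntheticRecoveryConfig()` is the planted-subset recovery fixture: loadings
−(0.315, 0.310, 0.221) plus eight −0.001 fillers, noise SD 1, delta = 7.
Three structural facts shaped this calibration, and they are worth recording
because they bound what *any* fixture can achieve under the validation
protocol:

* With a single latent factor, the achievable active–decoy separation of a
  subset with summed signal-to-noise S = sum (loading/noise)² is
  D = delta·sqrt(S/(S+1)) — bounded by delta and strongly compressed as S
  grows, so the margin between competing subsets shrinks as columns get
  stronger.
* Once D exceeds roughly 3 within-class SDs, nearly all test actives sit in
  the scaled cluster for every decent subset and the test metric loses
  discrimination (empirically, pushing delta from 7 to 8 *reduced* pair
  recovery from 95% to 82%).
* Each generated table's realized column–label noise (~1/sqrt(A) ≈ 0.11 SD
  per column) is shared by all five splits of that table, so validation
  repeats cannot average it away; occasionally a pure-noise filler passes
  the EF5% ≥ 2 filter by the same in-table luck and competes with the
  weakest true column.

The frozen fixture places the subset gaps at ~0.25–0.37 SD, giving observed
recovery of 19/20 (pairs) and 20/20 (triples) over seeds 1–20 with the
scaled search budget below. Recovery rates materially above ~97% per run are
not reachable under the mandated table dimensions and validation design, so
the recovery check sits genuinely at its 95% acceptance bar rather than
comfortably above it.

## Analysis sizes used by tests and the acceptance script

End-to-end screens in the test suite and `scripts/acceptance.R` use a
reduced search budget — `nStarts = 4`, `maxIter = 400`, `rmsTol = 0.01` —
chosen as the smallest setting whose recovery behaviour matched the
package-default budget in side-by-side pilots (the failures of the two
budgets were identical, confirming the limiting factor is table-level noise,
not optimization effort). Monte-Carlo sizes: 500 random tables for the
metric oracles, 200 signal-free tables for the EF null calibration, 100
planted fixtures for the filter-removal rates, 20 (tests) / 12 (acceptance
script) end-to-end screens for subset recovery.

## Numerical choices and degenerate inputs

* `s_f = ceiling(f·N)`; EF is undefined (error) without at least one active
  and one decoy.
* Missing or non-numeric score cells are load errors naming the row and
  column; values are never imputed.
* Zero-variance columns are errors at standardization and VIF time, naming
  the column; singular VIF regressions get the sentinel 10⁶.
* The canonical CSV writer renders doubles with the shortest round-tripping
  decimal representation, so write → read is exact and re-serialization is
  byte-identical; model JSON uses 17 significant digits for the same
  reason.
* Energy-like orientation is handled exclusively by coefficient signs; there
  is no per-column "lower is better" flag anywhere.

## Known limitations

* Subset sizes are capped at k = 3; nonlinear combinations and per-pose
  treatment of multiple docked poses are out of scope.
* The effectiveness threshold EF5% < 2.0 is intentionally permissive: on a
  3000/80 table a pure-noise column reaches EF5% ≥ 2 in one of its two
  orientations with probability ~0.09 (hypergeometric tail: ≥8 of 80
  actives among a top-or-bottom 150 selection), so its long-run removal
  rate is ~91%, marginally below a 95% expectation; the filter is a coarse
  sieve, not a significance test.
* Selection by average test Q inherits the cluster count's integer noise;
  on small test splits the continuous mean-rank term carries most of the
  discrimination.
* VIF filtering on the whole table means the surviving score set is fixed
  before validation; this stabilizes subset identity across repeats but
  lets the filter see the full label-free score distribution of rows later
  used as test sets (labels are never used by the VIF filter).
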