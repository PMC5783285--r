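---
title: "Re-ranking docking decoys with ranking-SVM ensembles and Schulze consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-ranking docking decoys with ranking-SVM ensembles and Schulze consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DecoyRank)
```

## The problem

Protein–protein docking programs generate hundreds of candidate poses
("decoys") per complex, of which at most a handful are near-native. Scoring
functions must order these decoys so that a near-native pose appears as close
to the top of the list as possible. DecoyRank treats this as a *learning to
rank* problem, the same formulation used by web search engines: each complex
is a query, its decoys are the documents, and the CAPRI quality categories
(incorrect < acceptable < medium < high) provide a partial order of
relevance. Crucially, scores only matter *relative to other decoys of the
same complex* — a near-native of one complex need not outscore an incorrect
decoy of another — which rules out plain classification or regression across
pooled complexes.

## Data model

A `DecoySet` holds one complex's decoys: a feature matrix (one row per
decoy), CAPRI labels, the docking engine's original ranking, and optional
per-decoy receptor/ligand C$\alpha$ coordinates. The default `FeatureSchema`
has 91 columns: 82 slots for externally computed physicochemical descriptors
(statistical potentials, energy terms, etc. — their computation is out of
scope; they arrive as TSV columns) plus 9 cluster-size columns. Cluster sizes
are obtained by single-linkage clustering of ligand C$\alpha$ positions after
superposing every decoy's receptor onto a common reference, at cutoffs 3.0–7.0 Å
in 0.5 Å steps; each decoy's feature is the size of its own cluster at that
cutoff. Large clusters of geometrically similar poses are a classic indicator
of a favourable binding funnel.

Preprocessing follows three rules:

* **Truncation.** Only the docking program's top 500 poses are kept
  (`truncateToTop()`); the number of pairwise training constraints grows
  quadratically with decoys per complex. Complexes whose only near-natives
  fall below the cutoff are flagged and excluded from retrieval statistics.
* **Imputation.** Missing descriptor values are replaced by the column mean
  pooled over all decoys of the collection passed in
  (`imputeMissing()`). Callers group by docking method first, so the pool is
  per-method.
* **Normalization.** Features are z-scored with per-column mean and
  *population* standard deviation fitted on the training pool
  (`fitNormalizer()`); held-out and new decoys are always transformed with
  the previously fitted parameters, never their own. Constant columns
  (σ = 0) are flagged with a warning and transform to zeros rather than
  erroring, which keeps degenerate fixtures usable.

Whether z-score parameters should be fitted per docking method or pooled
across methods is genuinely open; since all training here is per-method, the
per-method pool is used.

## The ranking SVM

For every pair of decoys $(i, j)$ of the same complex $k$ in *different*
CAPRI categories, with $i$ the better one, a perfect linear ranker
$w$ would satisfy $w \cdot d_{ik} > w \cdot d_{jk}$ on the descriptor
vectors. Because real categories are not linearly separable, each constraint
receives a slack $\xi_{ijk} \ge 0$:

$$w \cdot d_{ik} \ge w \cdot d_{jk} + 1 - \xi_{ijk}$$

and the trained model solves

$$\arg\min_{w, \xi \ge 0} \tfrac12\lVert w\rVert^2 + c \sum \xi_{ijk}.$$

Rearranged as $w\,(d_{ik} - d_{jk}) \ge 1 - \xi_{ijk}$, this is an ordinary
soft-margin SVM without intercept on the pair *difference vectors*
(`buildPairs()`). Within-category pairs generate no constraints, and no
per-pair cost weighting is applied. The trade-off constant $c$ is the first
metaparameter: large $c$ chases perfect training rankings, small $c$ favours
a wide margin between categories even at the cost of misranking some decoys
(tolerating, e.g., alternative binding modes mislabelled as incorrect).

The solver is an exact dual coordinate-descent (compiled), sweeping the pair
constraints in shuffled order with a projected-gradient stopping rule
(default tolerance `1e-6`, generous epoch budget, error on
non-convergence). Any method reaching the convex optimum is acceptable;
correctness is defined by the objective value, which the test suite
sandwiches between a dense interior-point QP's primal value and its dual
lower bound on small random instances. Decoys are ranked by descending
projection $w \cdot d$ (`rankByProjection()`), with exact ties broken by the
docking engine's initial rank so the all-zero model reproduces the engine's
ordering.

## Scoring and selecting models

Each trained model is scored on its model-selection complexes with a
cluster-aware logarithmic score. Decoys are single-linkage-clustered at
3.5 Å; clusters are ranked by their best-scoring member; $r$ is the rank of
the first cluster whose *top-ranked member* is near-native (acceptable or
better), and

$$s_i = \frac{\log_{10} n_c - \log_{10} r}{\log_{10} n_c}$$

ranges from 1 ($r = 1$) to 0 ($r = n_c$), and is set to 0 when no cluster is
topped by a near-native. The logarithm rewards movement near the top of the
list: rank 11 → 1 gains far more than rank 411 → 401. Degenerate case
$n_c = 1$ (a single cluster) avoids 0/0 by scoring 1 if that cluster's top
decoy is near-native and 0 otherwise, consistent with the score's endpoints.

A model's total score is ensemble-relative:
$S = \sum_i (s_i - \bar{s}_i)$ with $\bar{s}_i$ the mean score for complex
$i$ over all models scored on it. This favours models that succeed on
complexes the rest of the ensemble finds hard and penalises failures on easy
ones; summed over a shared selection set, $S$ telescopes to zero across the
ensemble. The top-$n$ models by $S$ (ties broken by model creation index)
form the ensemble, $n$ being the second metaparameter. Under protocol B,
where selection sets differ between models, $\bar{s}_i$ is taken over the
models whose selection set contains complex $i$ — the paper-level definition
does not pin this case down, so the choice is recorded here as this
package's own.

## Schulze consensus

The selected models each rank a new complex's decoys; the rankings are
aggregated by the Schulze electoral method. A complete digraph over decoys
weights edge $(a, b)$ by the number of rankings placing $a$ above $b$
(`buildPreferenceGraph()`). The strength of a directed path is its minimum
edge weight; `strongestPaths()` computes all-pairs widest paths with the
$O(n^3)$ Floyd–Warshall-style relaxation (vectorized base R — at
$n \le 500$ decoys this is desk-scale and needs no sparse tricks). Decoy $a$
beats $b$ when $\mathrm{strength}(a,b) > \mathrm{strength}(b,a)$; this
relation is transitive, so a total order follows. Pairs with equal strengths
— not addressed by the method itself — are broken by lower mean rank across
the ensemble, then by initial rank, keeping the output deterministic.

## Training protocols and the metaparameter grid

Two validation protocols are provided (`makeSplits()`):

* **A** — the base benchmark is split 2:1 into training and model-selection
  sets (default 200 repeats); a fixed held-out update set is the test set.
* **B** — all complexes are split 2:1:1 into training, model-selection and
  test sets (default 800 repeats, so each complex is in roughly a quarter of
  the test sets). A complex is only ever ranked by models whose training
  *and* selection sets exclude it; the test suite asserts this purity over
  every grid cell of a full run.

Split sizes are floor-allocated with remainders given to the selection set
first, then test, then training (176 complexes under 2:1 gives 117/59; 8
under 2:1:1 gives 4/2/2). Because protocol B draws test membership at
random, a small run may leave a complex with fewer candidate models than the
requested ensemble size; the effective ensemble is then capped at the
available candidates rather than failing, and at the default 800 repeats the
shortfall does not arise.

The metaparameter grid (`defaultMetaparameterGrid()`) samples $c$
logarithmically 50 times over $[10^{-4}, 10^3]$ inclusive and
$n = 1..50$: 50 × 50 cells. For each test complex,
leave-one-out selection (`looMetaparameters()`) sums the per-complex scores
$s_i$ of the *other* complexes in every cell and applies the argmax cell
(ties to smallest $c$, then smallest $n$; a single-complex input falls back
to the global argmax). The summed quantity is the absolute per-complex score
$s_i$ of the consensus ranking — the source description does not state
whether the relative or absolute score is summed, and the absolute score is
the quantity defined per complex. A "retrained-server" mode
(`metaparameters = "mode"`) instead applies the single most frequently
chosen cell to every complex, as a production server retrained on the full
benchmark would.

## The synthetic benchmark generator

Real benchmark decoys require four docking programs and a battery of
descriptor computations, so the package ships a generator
(`syntheticSpec()`, `generateDecoySets()`) that emulates the *shape* of that
data with known ground truth:

* CAPRI categories drawn per decoy from fixed fractions — defaults 95%
  incorrect, 3% acceptable, 1.5% medium, 0.5% high, reflecting how sparsely
  docking samples near-natives; a latent quality is drawn uniformly within
  fixed per-category bands (incorrect [0, 0.25), acceptable [0.25, 0.5),
  medium [0.5, 0.75), high [0.75, 1]).
* Descriptor features are $q \cdot w^*/\lVert w^*\rVert + \mathcal N(0,
  \sigma)$ with a planted unit weight vector $w^*$ over the 82 descriptor
  slots and isotropic noise (default $\sigma = 0.1$).
* Ligand poses are point clouds around planted cluster centres (default 10
  clusters, 1 Å intra-cluster spread, 20 Å centre separation, so
  single linkage at 3.5 Å recovers the planted partition exactly); each
  decoy's receptor+ligand pair additionally receives a random rigid motion,
  exercising the superposition path. Pose-cluster membership is drawn
  independently of quality, so the cluster-size columns carry no planted
  signal.
* Initial ranks order decoys by $q + \mathcal N(0, 0.5)$: informative but
  far from perfect, as real engine rankings are.

What the generator does *not* emulate: correlated descriptors, heavy-tailed
descriptor errors, near-native poses concentrating in large clusters, and
any physical energetics. Passing tests on this benchmark therefore
demonstrate that the machinery (pair construction, optimization, scoring,
aggregation, protocol bookkeeping) is correct and that planted signal is
recovered — not that the paper-scale success rates on real decoys are
reproduced, which would need the external descriptor sets.

### A note on measuring parameter recovery

Recovery of $w^*$ is measured on a strongly regularized model
($c = 10^{-3}$) trained on the raw descriptor block. Two distortions are
deliberately avoided. First, z-scoring a rank-one signal rescales each
column by a signal-dependent $\sigma_j$, so the z-space weight vector is a
warped image of $w^*$ even for a perfect model — a coordinate artifact
(rankings are unaffected). Second, because adjacent quality bands touch,
boundary pairs have vanishing signal margin, and at large $c$ the optimizer
separates them using noise directions; the strongly regularized regime
instead averages over all pairs, whose mean difference vector is an unbiased
estimate of the $w^*$ direction. The raw cluster-size columns are excluded
from the comparison because their scale (counts up to the decoy number)
dwarfs the descriptors and $w^*$ is zero there by construction.

## Numerical and design choices

* CAPRI thresholds default to the community criteria (acceptable:
  fnat ≥ 0.1 and (L-RMSD ≤ 10 or I-RMSD ≤ 4); medium: fnat ≥ 0.3 and
  (L-RMSD ≤ 5 or I-RMSD ≤ 2); high: fnat ≥ 0.5 and (L-RMSD ≤ 1 or
  I-RMSD ≤ 1)), exposed as configuration (`capriThresholds()`); an explicit
  `label` column wins over supplied fnat/RMSD metrics.
* Single-linkage ties at exactly the cutoff merge (inclusive `<=`), matching
  connected-component semantics; cluster ids are assigned by first member
  index, so labels are deterministic and order-invariant up to relabelling.
* The superposition reference receptor defaults to the first decoy's
  receptor; any reference (e.g. the unbound input structure) may be passed.
* All randomness flows from a single integer seed expanded into per-repeat
  substreams; identical seeds give bit-identical plans, models and
  consensus rankings.
* The Wilcoxon signed-rank comparison of before/after near-native ranks uses
  the standard zero-difference discard; with fewer than two non-zero pairs
  the result is flagged undefined rather than fabricated.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on synthetic benchmarks of 6–20
complexes with 40–200 decoys each, grids of 2–3 values of $c$ and ensemble
sizes up to 5, and 8–16 split repeats; oracle-equivalence suites use ≥ 50
random QP instances (≤ 20 pairs), ≥ 100 random preference graphs (≤ 6
nodes) and ≥ 100 random distance matrices (≤ 25 decoys). These sizes
exercise every code path while keeping the default test run fast; the
package itself handles the full-scale configuration (500 decoys, 50 × 50
grid, hundreds of repeats) through the same functions.

## Known limitations

* Descriptor computation is out of scope; the package consumes descriptor
  tables and computes only the cluster-size features itself.
* Only linear ranking functions (no kernels) and full, untruncated ballots
  in the consensus step.
* Interface RMSD and fnat are accepted as inputs for labelling but are not
  computed from structures; geometric handling is limited to C$\alpha$
  superposition and ligand RMSD.
* Protocol A's test set is fixed by design; assessing variability across
  update sets is the caller's responsibility.
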