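---
title: "Suite conformers from low-detail coordinates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suite conformers from low-detail coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery in `rnaprecis`, the
assumptions behind it, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Representations

**High detail.** A suite — the sugar-to-sugar backbone unit spanning two
adjacent residues — is summarised by seven dihedral angles (δ of the first
residue, then ε, ζ, α, β, γ across the phosphate, then δ of the second
residue), each an angle on a circle, so a suite is a point on the 7-torus.
The flat torus metric (root sum of squared minimal wrapped differences, each
component in [0°, 180°]) compares suites. Angles are degrees in [0, 360) in
all interfaces; radians appear only inside trigonometric internals.

**Low detail.** Only five atom positions are trusted: the glycosidic
nitrogen and C1′ of both residues and the central phosphorus. Their
size-and-shape is captured by the multicentred constrained size-and-shape
(MUCCSS) coordinates `W = (d2, d3, α, s1, s2)`:

* `d2`, `d3` — the pseudo-bond lengths P→C1′ (Å), carrying size;
* `α` — the opening angle at P, in (0, π) strictly (a collinear triangle is
  rejected as degenerate);
* `s1`, `s2` — the two glycosidic bond *directions* as unit vectors in the
  canonical frame that maps the P/C1′/C1′ triangle into the (x, y)-plane
  with both C1′ at equal positive y and the later C1′ at larger x.

The measured glycosidic bond vectors are normalised to unit length rather
than asserted to equal a fixed constant (~1.47 Å): bond lengths are nearly
invariant chemically, so only the directions carry conformational
information, and normalisation keeps noisy inputs on the sphere by
construction. Both representations have exactly seven degrees of freedom.

The space of `W` is a direct product, and its metric is the unweighted
product metric: squared differences of the flat coordinates plus squared
great-circle distances on the two spheres. The great-circle distance is
computed as `atan2(‖a × b‖, a·b)` rather than `acos(a·b)`; the two agree
analytically but the arccosine form loses half the floating-point digits
near coincident directions, which matters because rigid-motion invariance is
asserted at 1e−9.

## 2. Fréchet means, tangent space, covariance

Cluster centres are Fréchet means: minimisers of the mean squared product
distance. On the flat factors the minimiser is the arithmetic mean, used
exactly. On each sphere factor the intrinsic mean is computed by the
standard log/exp fixed-point iteration, initialised at the normalised
chordal (extrinsic) mean, iterated until the tangent-mean norm falls below
1e−10 (cap 1000 iterations, error on non-convergence). For the concentrated
clusters this package works with, the mean is unique and the iteration
converges in a handful of steps; the solver and tolerance are this package's
choices, as is the deterministic initialisation.

Tangent-space coordinates at a base point `W*` are the flat differences plus
residual coordinates of each direction: `s_i` is projected onto the tangent
plane of the sphere at the base direction `s_i*`, expressed in the
orthonormal basis `Q = (b | c)` built from the standard basis vector least
aligned with `s_i*` (lowest index wins ties, for determinism). The chart
requires `s_i · s_i* > 0` (open hemisphere); a violation is an error at the
manifold level and is treated by the classifier as "this cluster cannot be
the answer". The construction makes the base map to the zero 7-vector, which
is the property the covariance estimator and the classifier rely on.
A literal reading of the construction in which `Q` is built from the data
point's own direction would make the projection identically zero, so the
base-point reading is the one implemented.

The tangent covariance is the outer-product sum over tangent vectors divided
by n − 1, taken at the Fréchet mean. The flat block is then exactly the
usual centred sample covariance; the sphere blocks are centred to first
order (the tangent mean of projected directions is not exactly zero), which
is deliberate: the estimator is defined at the Fréchet mean, not at the
tangent-space barycentre.

## 3. Training-side clustering on the torus

Each pucker-pair set is clustered separately:

1. **Average-linkage tree** (UPGMA) under the torus metric, computed with
   `stats::hclust` on the wrapped distance matrix.
2. **Adaptive cut.** A merge is severed when its height gap to its taller
   child exceeds `q ×` (total tree height) *and* at least one side of the
   split has at least κ members. The second condition stops a tight small
   cluster from being shattered from inside; the first detaches any group —
   including single stragglers — whose attachment height is far above its
   internal merge activity. Connected components of the unsevered merges are
   the preclusters; groups below κ become outliers. The fraction of outliers
   is compared against `d_max` and warned about, never enforced as an error.
   The severing rule is this package's own formulation of adaptive
   iterative cutting: it is documented here precisely because different
   formulations exist in the clustering literature.
3. **Mode hunting.** Each precluster is reduced to its dominant
   one-dimensional circular component: every angle is unwrapped into
   (−180°, 180°] about its circular mean (safe for concentrated clusters),
   and points are scored by projection onto the leading eigenvector of the
   unwrapped covariance. The scores are tested for bimodality with a
   likelihood ratio between a single Gaussian and a two-component
   equal-variance Gaussian mixture (EM, ten deterministic quantile-split
   restarts; equal variances avoid the unbounded-likelihood degeneracy of
   heteroscedastic one-dimensional mixtures). Significance comes from a
   parametric bootstrap. If the test rejects, the cluster is split at the
   mixture responsibilities and each part is re-projected and re-tested.

Two levels of the bimodality test exist deliberately:

* `mode_hunt_split()` — the standalone test on given scores — uses the
  conventional α = 0.05 with a 200-replicate one-dimensional bootstrap. Its
  calibration (type-I rate ≈ α) and power (two components 90° apart at
  σ = 10° are found essentially always) are what the test suite checks.
* Inside `mint_age()` the situation differs in two ways. First, the scores
  are projections onto a *data-chosen* direction, and a one-dimensional
  bootstrap that ignores this selection is anticonservative: the leading
  eigenvector of sample noise always looks more structured than a fixed
  direction. The refinement therefore uses a projection-aware bootstrap: each
  replicate re-draws a whole cluster from the fitted multivariate normal and
  is projected onto *its own* leading eigenvector before the statistic is
  computed. Second, the refinement takes many dependent, irreversible split
  decisions across preclusters and recursion levels, so its per-decision
  level defaults to 0.005 — the resolution floor of a 200-replicate bootstrap,
  i.e. a split requires the observed statistic to exceed every null
  replicate. Iterative splitting methods conventionally run their per-split
  tests far below 0.05 for exactly this reason. Genuinely bimodal clusters
  produce statistics orders of magnitude beyond the null range (two tight
  pairs at n = 4 are still split), so the strict level costs essentially no
  power while keeping well-separated unimodal clusters intact.

Per-pair defaults for the cut are q = 0.09/0.05/0.07/0.05 and κ = 3 for
P33/P32/P23/P22, with d_max 1.1%/0.34%/1.4%/0.7%. κ = 3 is small on purpose:
rare conformers form legitimate clusters of three or four members. Cluster
indices are assigned by decreasing size (ties by smallest member row), so
index 1 in P33 is the dominant helical class.

`mint_age()` seeds its bootstrap locally (default seed 1, caller's random
state restored), making a fit a deterministic function of its inputs.

## 4. The classifier

Training computes, per cluster, the Fréchet mean and tangent covariance of
the low-detail representatives, then regularizes every covariance towards
the reference `S1` of the single largest P33 cluster:
`RS_i = λ S_i + (1 − λ) S1`, λ = 0.5 by default (λ = 1 keeps each cluster's
own covariance, λ = 0 uses the reference alone; both endpoints are exact
identities in the tests). The largest P33 cluster is the natural reference
because it dwarfs every other cluster and its covariance spans the full
seven dimensions; small clusters whose spread is rank-deficient become
invertible through the blend. If training data contain no P33 cluster of at
least two members, the pooled covariance is used with a warning. Positive
definiteness is verified by Cholesky at train time; failure is an error
naming the cluster, never a silent pseudo-inverse.

Prediction gates a suite by the Pperp pair (2.9 Å boundary, the boundary
value on the C3′-endo side), evaluates
`log n_i − ½ log det RS_i − ½ Mahalanobis²` within that pair, and
normalizes. The formula is linear in log cluster size, so two otherwise
identical clusters with sizes 30 and 3 give exactly 10:1 posterior odds —
the prior is the cluster size, unnormalised. Normalization is performed on
the log scale with maximum subtraction (softmax); normalizing raw
likelihood values would overflow or underflow long before the posterior
ratios become extreme, and any reading that normalizes the *logarithms*
directly would not produce probabilities at all. Ties in the argmax go to
the lowest cluster index. Posteriors inherit the covariance regularization:
they are credibilities under the regularized model, not under the raw
per-cluster Gaussians.

Evaluation uses three categories: *pucker mismatch* when no answer conformer
belongs to the gated pucker-pair set (diagnosed from the model's
conformer-to-pair map when the manifest does not say), *prediction match*
when the predicted cluster's conformer set intersects the answer set (a
multi-conformer cluster matches any of its members, and any of several
answers counts), and *prediction mismatch* otherwise. Answers whose
conformer was never clustered are flagged; they can only ever be mismatches.

## 5. The synthetic generator

The generator emulates the structure of curated training data: concentrated
rotamer classes on the 7-torus, realised as wrapped Gaussians (sampled on
the line, wrapped into [0°, 360°)) around cluster centres, built into 3D
atoms by the standard internal-coordinate chain construction (each atom
placed from a bond length, bond angle and torsion relative to three
predecessors). The ribose is attached from a per-pucker template: ring
torsions follow the pseudorotation description with amplitude 38° at phase
18° (C3′-endo) or 162° (C2′-endo), and the two chirality-fixing torsion
offsets (−121° for O3′ relative to C2′ around C3′→C4′, and for N relative
to C2′ around O4′→C1′) were verified against an independently embedded
D-ribonucleoside so the generated sugars are genuinely D-ribose. With these
templates, δ ≈ 84° sugars read as C3′-endo and δ ≈ 147° sugars as C2′-endo
by both the ring-geometry route and the Pperp route (≈ 4.6 Å vs ≈ 1.9 Å on
noise-free geometry), which is the physical consistency the pucker gate
relies on.

Defaults define the simulated study conditions: four pucker pairs, four
clusters per pair, 40 training and 5 test suites per cluster, σ = 8° of
angular noise on every dihedral, random rigid motions on. The built-in
centres are rotamer-like settings of (ε, ζ, α, β, γ), mutually separated by
at least 60° in two or more coordinates — comfortably more than the 4σ
separation the recovery analyses assume — with δ values dictated by the
pucker pair. σ = 8° reflects the spread of real conformer classes; σ = 2°
is the near-noiseless regime. An auto-generated "random-separated" mode
enforces minimum pairwise torus separation of 4σ.

What the generator does *not* emulate: experimental-map artefacts,
modelling errors that move atoms off their true conformation,
non-standard bases, alternate conformations, chain breaks, or the extreme
class imbalance of real data (where the helical class outweighs everything
else by an order of magnitude). Passing tests on synthetic data therefore
demonstrate the correctness and internal consistency of the machinery —
geometry, manifold statistics, clustering, classification — not the
error-tolerance of the method on real crystallographic models.

## 6. Numerical and degenerate-input policy

* `arccos` arguments are clamped to [−1, 1]; sphere distances use the
  `atan2` form.
* Collinear dihedral quadruples, coincident glycosidic endpoints, parallel
  pseudo-bonds and planar riboses raise errors naming the condition.
* The Pperp boundary is closed on the C3′-endo side: exactly 2.9 Å is
  C3′-endo.
* Equal-variance EM puts a floor of 1e−4 × sd on the component standard
  deviation, so exact duplicates cannot produce infinite likelihoods.
* Alternate locations: per atom site, blank altloc is preferred, then "A",
  then highest occupancy; `drop_altloc = TRUE` removes suites touched by
  any alternate location. The O3′–P bondedness cutoff is 2.5 Å (covalent
  ≈ 1.6 Å; the slack tolerates poorly refined models). Residue numbers and
  insertion codes are taken verbatim from the file; only the first model of
  multi-model files is read.

## 7. Problem sizes used by the test suite

The default test run exercises: 300 random build/measure round trips; 1000
random triples for the metric axioms; 100 rigid motions for invariance; 50
random instances against each brute-force oracle (torsion, Pperp, torus
distance, UPGMA, tangent covariance, log-posterior); 20 seeds × (3 × 40 + 4)
points for exact cluster recovery; 20 + 20 replicates for the bimodality
test's level and power; and two full gold-standard pipelines (640 training,
80 test suites each) at σ = 8° and 2°. These sizes were chosen so each
property is tested at meaningful statistical resolution while the whole
suite stays fast enough to run on every change.

## 8. Known limitations

* The adaptive cut rule and the principal-circle reduction are documented
  interpretations, simpler than the stratified-sphere torus decomposition
  used in the original clustering line of work; they preserve the role of
  each stage (density-based precluster extraction; one-dimensional circular
  reduction feeding mode hunting) rather than the exact algorithms.
* Cluster indices are not comparable across retrainings; correspondence is
  by conformer-label content.
* The classifier cannot predict across pucker-pair sets by construction; a
  wrong Pperp gate (modelling error near the 2.9 Å boundary) is
  unrecoverable and is surfaced as the pucker-mismatch category.
* Conformers absent from training (or present below κ) can never be
  predicted; they are flagged in evaluation.
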