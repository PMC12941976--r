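---
title: "Benchmarking 3D explanations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 3D explanations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaibench3d)
```

## The problem

Classifiers of three-dimensional data — volumetric scans, binary occupancy
voxel grids, point clouds — are routinely explained with per-element
relevance maps, but explanation quality is rarely quantified, and almost
never comparably across modalities. `xaibench3d` implements one evaluation
protocol that treats every explanation the same way, whether it came from a
gradient method, a perturbation method, or a model's own attention: an
attribution map is a vector $a \in [0,1]^M$ aligned to the $M$ elements
(voxels or points) of one input $x$, and its quality is judged by how the
classifier's confidence responds when the elements $a$ ranks highly are
removed or retained, and by how concentrated $a$ is.

All methods and metrics reach the model through a single *adapter* contract
(`model_adapter()`): per-class confidences `score(x)`, raw class-score
gradients `gradient(x, class)`, named internal layers for class-activation
mapping, and optional attention masks. Anything satisfying the contract can
be benchmarked; the package ships tiny closed-form fixtures so the whole
protocol runs without external data.

A note on "confidence": metrics consume `score()`, which for the trained
fixtures is the softmax probability of the predicted class. Gradient-based
attribution differentiates the raw class score (the logit) — that is the
quantity for which the linear-model identities below hold exactly. The
linear oracle fixtures report their raw margin as their confidence so that
every metric on them is hand-computable.

## Attribution methods

* **Saliency** — $|\partial s_c / \partial x|$ per grid element, where $s_c$
  is the predicted class score; for point clouds, the L2 norm of the three
  coordinate gradients per point.
* **Integrated gradients** —
  $(x - b) \cdot \frac{1}{n}\sum_{k=1}^{n} \nabla s_c\!\left(b + \tfrac{k - 1/2}{n}(x - b)\right)$
  with baseline $b$ (zero by default) and $n = 50$ steps. The midpoint rule
  was chosen over a one-sided Riemann sum because it is exact for linear
  scores, so the completeness identity
  $\sum_i \mathrm{IG}_i = s_c(x) - s_c(b)$ holds exactly there and to
  quadrature accuracy ($\le 10^{-3}$ at 500 steps) on the nonlinear
  fixtures. Metrics rank the magnitude of the attribution (per-point L2 norm
  for clouds); the signed values stay available in the map's metadata,
  because the ranking population for negative evidence is a genuine
  convention choice and magnitude ranking is the one we adopt.
* **Occlusion** — slide a window (default: the modality default, $4^3$ for
  voxel grids, $\mathrm{dim}/8$ for volumetric) across the grid, replace the
  covered region with the baseline, and credit the confidence drop to every
  covered element. The default stride equals the window (a partition); when
  windows overlap, per-element drops are averaged. Point clouds have no
  lattice, so points are sorted by Morton (z-order) code and removed in
  consecutive clusters of 10 — deterministic and spatially coherent.
* **Grad-CAM** — channel weights are the global average of the layer
  gradients; the rectified weighted activation sum
  $\mathrm{ReLU}(\sum_c \alpha_c A_c)$ is upsampled trilinearly to input
  shape. ReLU precedes upsampling (the standard definition): negative
  channel evidence is discarded before interpolation can smear it. For point
  models, per-centroid values from the tapped set-abstraction layer are
  propagated to each point from its nearest centroid (exact Euclidean
  comparison; ties go to the lowest centroid index).
* **Intrinsic attention** — a named attention mask from the model's forward
  pass (the second stage, `"soft2"`, by default), trilinearly upsampled.
  Point adapters carry no dense attention masks, and the extraction refuses
  them explicitly rather than improvising one.

Every map is min–max normalized over its own elements to $[0,1]$. A
constant raw map normalizes to all zeros: if no element is distinguished,
no element is relevant, and the guard avoids dividing by zero.
Normalization is idempotent, and all methods are deterministic — identical
inputs give bit-identical maps.

## Perturbation metrics

Elements are ranked by attribution value, descending, with exact ties broken
by ascending flat index so rankings are reproducible. "Top fraction $f$"
means the first $\lceil f M \rceil$ elements of that ranking, counted
against the total element count $M$ (not the occupied count — the occupied
alternative is a documented ambiguity, and counting against $M$ keeps the
rule modality-uniform).

With schedule $f_k = k/K$ ($K = 10$ by default):

* **AOPC (correctness)** — remove the top $f_k$ at each step, record the
  confidence drop $d_k = s(x) - s(x^{(k)})$, and integrate the
  drop-versus-fraction curve by the trapezoidal rule with an implicit
  origin $(0, 0)$ (no removal, no drop).
* **AUPC (completeness)** — keep only the top $f_k$, record the confidence,
  prepend the empty-input point $(0, 0)$, and integrate the same way.

Removal and preservation are exact complements: at every fraction the
preserved set equals the removed set. Point "removal" replaces the selected
points' coordinates with the baseline constant instead of deleting rows, so
tensor shapes stay fixed and adapters need no variable-size support.

Baselines are modality-specific neutral states: zero for occupancy grids
and point coordinates (absence of structure), the sample's own mean
intensity for volumetric data (a gray scan rather than an unnaturally black
one). A Gaussian-blurred baseline is available for volumetric data
(`baseline_spec("blurred")`, $\sigma$ in voxels).

* **Compactness** — at a fixed threshold $t$, the ratio
  $\#\{a_i \ge t\} / \#\{x_i \ne 0\}$ (defaults $t \in \{0.5, 0.7, 0.9\}$);
  in the adaptive variant, the threshold is the value at descending rank
  $\lceil 0.1\,M \rceil$ (the empirical 90% quantile with ceiling
  cardinality). Every point counts as "non-zero" for clouds, where
  occupancy is meaningless. The ratio deliberately may exceed 1 on sparse
  grids — diffuse attribution over few occupied voxels is exactly the
  pathology the metric should expose. The adaptive quantile is taken over
  *all* elements; taking it over non-zero elements only is the plausible
  alternative, and the all-elements choice is what produces the >1 ratios
  on sparse inputs that make the variant informative.

## Statistical comparison

Per metric, each method's scores first pass an interquartile-range filter:
values outside $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ are
removed, with quartiles from linear-interpolation quantiles (type 7) —
adaptive compactness in particular produces extreme spikes on sparse
inputs. Fewer than four values skip the filter with a warning rather than
estimating quartiles from almost nothing.

Methods are then compared by Kruskal–Wallis (midrank tie correction,
chi-square p on $k-1$ df) with the effect size
$\eta^2 = (H - k + 1)/(n - k)$; small samples can push the estimator
negative, which is clamped to zero and flagged. Pairwise differences use
the Mann–Whitney U test. For small groups the p-value comes from full
enumeration of all $\binom{n_1 + n_2}{n_1}$ assignments — the exact
permutation distribution, which controls the type-I error by construction.
The automatic rule switches to the tie-corrected normal approximation (with
0.5 continuity correction) when the pooled size exceeds 12 or ties are
present; the approximation's Z-score is always retained because Cohen's
$r = |Z|/\sqrt{n}$ is derived from it (bands 0.1/0.3/0.5 for
small/medium/large; $\eta^2$ bands 0.01/0.06/0.14).

Pairwise p-values are Bonferroni-corrected within one dataset–metric
family, $m$ = the number of method pairs (five methods give $m = 10$ and an
effective cut of 0.005 at $\alpha = 0.05$). The pairwise stage is gated on
Kruskal–Wallis significance at $\alpha = 0.05$, but the pairwise table is
emitted either way with an `exploratory` flag — silently dropping
non-significant comparisons hides information a reader may need.

## The pipeline

`run_benchmark()` selects up to `samples_per_class` samples per class
(default 5), balanced between correctly and incorrectly classified
instances: the correct stratum gets the ceiling of the split, samples are
ordered by id before slicing, and a short stratum is back-filled from the
other. It then generates every configured attribution, scores all metrics,
runs the statistics stage, and writes the artifact set: per-record CSV
metrics, filtered summaries, the statistics table, perturbation curves and
attribution containers as NumPy arrays, and a JSON provenance block. Every
reported number is recomputable from the persisted per-record table, and a
fixed seed makes reruns bit-identical. Failures in individual
(sample, method) cells are recorded and skipped, not fatal.

Attribution maps are evaluated at the native sample resolution.
`resample_volume()` (trilinear, cell-center convention) exists for
cross-dataset aggregation at a unified resolution — applied to attribution
maps only, when requested — since resampling the *inputs* would change the
very predictions under explanation.

Array persistence uses one container directory per (sample, method) with
named members `values.npy`, `data.npy` (NumPy format, C element order,
float64, bit-exact round trips) and a `meta.json` sidecar carrying ids,
labels, and the method configuration.

## Synthetic fixtures: what they do and do not show

The generators emulate the three modalities at desk scale with known
class-relevant structure:

* `gen_blob_volumes()` — a truncated Gaussian intensity blob (peak 1, cut
  at half maximum) at a class-specific site on a zero background with
  Gaussian noise ($\sigma = 0.1$ by default, a signal-to-noise ratio at
  which a class-mean matched filter exceeds 90% accuracy); the mask is the
  blob support.
* `gen_voxel_objects()` — binary cube / spherical shell / cross primitives
  with jittered pose.
* `gen_point_clusters()` — class-specific numbers of Gaussian clusters plus
  uniform clutter, normalized into the unit sphere; the mask marks cluster
  membership.

Grids default to $16^3$ and clouds to 128 points, small enough that the
complete protocol — including occlusion's full window sweep — runs in
minutes on one CPU; realistic resolutions remain configurable. The model
fixtures are deliberately tiny: a frozen bank of seeded random 3D
convolution channels pooled over octants (global pooling would discard the
location information that separates the blob classes) with a trained
multinomial softmax head; a set-abstraction-style point model with fixed
anchor centroids and Gaussian soft assignment; an attention variant
exposing two sigmoid mask stages. Training touches only the head
(`fit_adapter()`, via `nnet::multinom`), so fitting is fast and exactly
reproducible; after fitting, the head is centered across classes, which
leaves softmax probabilities unchanged while avoiding the reference class's
degenerate constant-zero logit. All adapters expose analytic gradients and
pass central finite-difference checks at $10^{-4}$.

What passing on these fixtures does *not* show: real CT texture,
anisotropic spacing, class-relevant regions with complex topology,
cluttered scans with thousands of points, or deep-network gradient
pathologies (saturation, shattered gradients). The fixtures validate that
the metrics, statistics, and protocol are computed correctly — not that any
particular explanation method is good on real data.

## Numerical conventions, collected

* Ranking ties: ascending flat index (column-major for grids).
* Removal cardinality: $\lceil f M \rceil$ against all $M$ elements.
* Integration: trapezoid over the fraction axis; AOPC origin $(0,0)$
  implicit, AUPC origin mandated by the empty-input definition.
* IG quadrature: midpoint rule, $a_k = (k - 1/2)/n$.
* Trilinear resampling: cell-center alignment, edge clamping; constants are
  preserved and the operator commutes with affine intensity maps.
* Adaptive compactness threshold: value at descending rank
  $\lceil a M \rceil$; degenerate all-equal maps count every element.
* Quantiles (IQR filter): linear interpolation between order statistics.
* Exact/approximate Mann–Whitney switch: pooled $n \le 12$ and tie-free.
* Nearest-centroid ties: exact comparison, lowest index wins.
* Degenerate guards: constant maps normalize to zero; all-identical groups
  give $H = 0, p = 1$; all-zero samples make compactness undefined (error);
  negative $\eta^2$ clamps to 0.

## Problem sizes used by the test suite

The suite exercises the protocol at $16^3$ grids ($8^3$ for the heaviest
closed-form checks), 128-point clouds, 20 random fixtures per modality for
the metric-oracle equivalences, 2,000 null simulations for the exact test's
type-I error, 50 seeded repetitions of the mask-versus-random faithfulness
comparison, and one full five-method protocol run executed twice to verify
bit-identical artifacts. These sizes are the package's chosen desk-scale
defaults; everything scales up by configuration.

## Known limitations

* Occlusion cost grows with the window count; there is no GPU path — the
  package targets method evaluation, not production inference.
* The blurred baseline is the only smoothing-based perturbation; no
  region-growing or superpixel-style perturbation.
* Bonferroni is the only built-in correction (the family is explicit, so
  applying another correction to the emitted raw p-values is trivial).
* Intrinsic extraction requires dense grid attention; point-model attention
  would need an architecture the adapter contract does not presume.
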