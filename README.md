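# xaibench3d

Quantitative, cross-modality benchmarking of explanations for 3D
classifiers. Deep models on volumetric scans, voxel occupancy grids, and
point clouds are routinely "explained" with per-element relevance maps, but
those maps are rarely evaluated beyond visual inspection. `xaibench3d`
scores them: it generates post hoc attributions (Grad-CAM, input-gradient
saliency, integrated gradients, occlusion sensitivity) and intrinsic
attention maps behind one model-adapter contract, evaluates every map with
perturbation-based faithfulness and compactness metrics, and compares
methods with a nonparametric statistical protocol — identically across all
three modalities. It is aimed at researchers who need to decide *which*
explanation method to trust for a given 3D task, and at method developers
who need a reproducible harness.

## The metrics

For an attribution map $a \in [0,1]^M$ over the $M$ voxels or points of an
input $x$, with elements ranked by $a$ and perturbed at fractions
$f_k = k/K$ toward a modality-appropriate neutral baseline (zero for
geometric data, mean intensity for volumetric data):

- **Correctness — AOPC** (area over the perturbation curve): trapezoidal
  area of the confidence-drop curve $d_k = s(x) - s(x_{\text{top-}f_k\
  \text{removed}})$, with implicit origin $(0,0)$. High AOPC ⇒ the map
  points at elements the prediction causally depends on.
- **Completeness — AUPC** (area under the preservation curve): trapezoidal
  area of the confidence curve when *only* the top $f_k$ elements are kept,
  starting from the empty-input point $(0, 0)$. High AUPC ⇒ the highlighted
  region alone sustains the prediction.
- **Compactness**: $\#\{a_i \ge t\} / \#\{x_i \ne 0\}$ at fixed thresholds
  $t \in \{0.5, 0.7, 0.9\}$, and adaptively at the top-10% quantile
  threshold. Ratios above 1 flag diffuse attribution over sparse inputs.

Method differences are tested per metric with Kruskal–Wallis
($\eta^2 = (H-k+1)/(n-k)$ effect size) followed by pairwise Mann–Whitney U
tests — exact permutation p-values by full enumeration at small n —
Bonferroni-corrected over the method pairs of each dataset–metric family,
with Cohen's $r = |Z|/\sqrt{n}$ effect sizes, after interquartile-range
outlier filtering per method and metric.

Everything runs on shipped synthetic fixtures (blob volumes, voxel
primitives, clustered point clouds, each with known class-relevant masks)
and tiny deterministic model adapters with analytic gradients, so the full
protocol needs no datasets, no GPU, and no network access. See the methods
vignette (`vignettes/benchmarking-3d-explanations.Rmd`) for every
convention and design choice.

## Worked example

Train the tiny attention-equipped grid classifier on synthetic blob
volumes, then benchmark all five explanation methods on a fresh pool:

```r
library(xaibench3d)

train   <- gen_blob_volumes(n_classes = 3, samples_per_class = 15, seed = 11)
adapter <- fit_adapter(tiny_attention_adapter(seed = 5), train$samples)
pool    <- gen_blob_volumes(n_classes = 3, samples_per_class = 6, seed = 77)

cfg <- benchmark_config(
  dataset = "synthetic-blobs", modality = "volumetric",
  methods = c("gradcam", "saliency", "integrated_gradients",
              "occlusion", "intrinsic"),
  samples_per_class = 5, k_steps = 10, seed = 99)

bench <- run_benchmark(cfg, adapter, pool$samples)
summary(bench)
```

```
<xai_benchmark> synthetic-blobs (volumetric): 15 samples x 5 methods, 75 records, 0 failures

Per-method means after IQR filtering:
               method    aopc   aupc compactness_t0.5 compactness_t0.7
              gradcam 0.34283 0.7384         0.011686         0.004639
 integrated_gradients 0.53018 0.8528         0.007178         0.002808
            intrinsic 0.06952 0.4431         0.789232         0.058331
            occlusion 0.56389 0.8742         0.010026         0.005208
             saliency 0.51060 0.8532         0.019401         0.009375
 ...
42 significant pairwise differences at corrected alpha = 0.05:
               metric                        comparison p_corrected effect_size
                 aopc   gradcam vs integrated_gradients    7.80e-03       0.613
                 aopc              gradcam vs intrinsic    3.39e-05       0.848
 ...
```

Reading the table: occlusion and integrated gradients identify the most
causally relevant voxels on this fixture (highest AOPC ≈ 0.56/0.53 — the
model's confidence collapses quickly when their top voxels are removed, and
is sustained when only those voxels are kept, AUPC ≈ 0.87/0.85). The
intrinsic attention mask is by far the most *compact* (fixed-threshold
ratio 0.79 versus ≈0.01 for the gradient methods) but the least faithful
(AOPC ≈ 0.07): sharply localized attention that does not coincide with the
causally decisive region — the faithfulness/compactness trade-off the
statistics table quantifies pair by pair.

Each record, curve, and attribution map is also written to the output
directory (CSV + NumPy containers + JSON provenance) when
`output_dir` is set, and `plot(bench, metric = "aopc")` draws the
per-method boxplot. A thin CLI over the same functions lives in
`inst/cli/xaibench.R` (`generate`, `run-all`).

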