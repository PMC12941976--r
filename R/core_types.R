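#' Construct a 3D sample
#'
#' One input instance for the benchmark, in any of the three supported
#' modalities: a `volumetric` scalar grid (finite reals, dim `(D,H,W)`), a
#' binary `voxel` occupancy grid (values in \{0,1\}, dim `(D,H,W)`), or a
#' `pointcloud` (an `N x 3` matrix of finite xyz coordinates). Class labels
#' are 1-based indices; `correct` is derived from the two labels.
#'
#' @param sample_id character identifier, unique within a pool.
#' @param modality one of `"volumetric"`, `"voxel"`, `"pointcloud"`.
#' @param data 3D array or `N x 3` matrix, depending on modality.
#' @param true_label,predicted_label 1-based class indices; `predicted_label`
#'   may be `NA` for unscored samples.
#' @return object of class `sample3d`.
#' @export
sample3d <- function(sample_id, modality, data, true_label,
                     predicted_label = NA_integer_) {
  modality <- match.arg(modality, c("volumetric", "voxel", "pointcloud"))
  if (modality == "pointcloud") {
    if (!is.matrix(data) || ncol(data) != 3L) {
      stop_validation("pointcloud data must be an N x 3 coordinate matrix")
    }
    assert_finite(data, "point coordinates")
  } else {
    if (!(is.array(data) && length(dim(data)) == 3L)) {
      stop_validation(modality, " data must be a 3D array (D,H,W)")
    }
    assert_finite(data, "grid values")
    if (modality == "voxel" && !all(data %in% c(0, 1))) {
      stop_validation("voxel occupancy values must all be 0 or 1")
    }
  }
  structure(list(
    sample_id = as.character(sample_id),
    modality = modality,
    data = data,
    true_label = as.integer(true_label),
    predicted_label = as.integer(predicted_label),
    correct = !is.na(predicted_label) && as.integer(true_label) == as.integer(predicted_label)
  ), class = "sample3d")
}

#' @export
print.sample3d <- function(x, ...) {
  shape <- dim(x$data) %||% length(x$data)
  cat(sprintf("<sample3d '%s'> %s [%s], true=%d pred=%s (%s)\n",
              x$sample_id, x$modality, paste(shape, collapse = "x"),
              x$true_label,
              ifelse(is.na(x$predicted_label), "NA", x$predicted_label),
              if (isTRUE(x$correct)) "correct" else "incorrect"))
  invisible(x)
}

#' Number of attributable elements of a sample
#'
#' Grid modalities count voxels; point clouds count points (one relevance
#' value per point, not per coordinate).
#' @param sample a [sample3d()].
#' @return integer element count.
#' @export
n_elements <- function(sample) {
  if (sample$modality == "pointcloud") nrow(sample$data) else length(sample$data)
}

#' Construct an attribution map
#'
#' Per-element relevance values aligned to a sample: one value per voxel for
#' grid modalities (same `(D,H,W)` shape) or one per point (length-`N`
#' vector) for point clouds.
#'
#' @param values numeric array (grids) or vector (point clouds).
#' @param method one of `"gradcam"`, `"saliency"`, `"integrated_gradients"`,
#'   `"occlusion"`, `"intrinsic"`, or `"reference"` for externally supplied
#'   maps (e.g. ground-truth masks or random baselines under test).
#' @param sample the paired [sample3d()]; used to validate the shape.
#' @param normalized logical; `TRUE` when `values` are min-max scaled to
#'   `[0,1]`.
#' @param metadata optional list carried along (e.g. signed raw attributions).
#' @param config optional method configuration echoed into saved containers.
#' @return object of class `attribution_map`.
#' @export
attribution_map <- function(values, method, sample, normalized = FALSE,
                            metadata = list(), config = NULL) {
  method <- match.arg(method, c("gradcam", "saliency", "integrated_gradients",
                                "occlusion", "intrinsic", "reference"))
  assert_finite(values, "attribution values")
  map <- structure(list(values = values, method = method,
                        normalized = isTRUE(normalized),
                        sample_id = sample$sample_id, modality = sample$modality,
                        metadata = metadata, config = config),
                   class = "attribution_map")
  check_map_matches_sample(map, sample)
  if (map$normalized && length(values) &&
      (min(values) < 0 || max(values) > 1)) {
    stop_validation("normalized attribution values must lie in [0,1]")
  }
  map
}

#' @export
print.attribution_map <- function(x, ...) {
  shape <- dim(x$values) %||% length(x$values)
  cat(sprintf("<attribution_map %s> for '%s' (%s), [%s], %s\n", x$method,
              x$sample_id, x$modality, paste(shape, collapse = "x"),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @keywords internal
check_map_matches_sample <- function(map, sample) {
  if (sample$modality == "pointcloud") {
    ok <- is.null(dim(map$values)) && length(map$values) == nrow(sample$data)
  } else {
    ok <- identical(dim(map$values), dim(sample$data))
  }
  if (!ok) stop_validation("attribution shape does not match the paired sample")
  invisible(TRUE)
}

#' Min-max normalize raw attribution values to [0, 1]
#'
#' Applies `(x - min) / (max - min)` over all elements of one map. A constant
#' map has no distinguished element and normalizes to all zeros rather than
#' dividing by zero. Idempotent on already-normalized maps.
#'
#' @param raw numeric array or vector of finite values.
#' @return numeric object of the same shape with range within `[0,1]`.
#' @export
normalize_attribution <- function(raw) {
  if (!length(raw)) stop_validation("cannot normalize an empty attribution map")
  assert_finite(raw, "attribution values")
  lo <- min(raw)
  hi <- max(raw)
  if (hi == lo) {
    out <- raw
    out[] <- 0
    return(out)
  }
  (raw - lo) / (hi - lo)
}

#' Baseline (neutral value) specification for perturbation
#'
#' The replacement value used when elements are "removed": `zero` is the
#' constant 0 (default for occupancy grids and point coordinates, i.e. total
#' absence of structure), `mean` is the scalar mean of the sample's own data
#' (default for volumetric intensities), and `blurred` replaces elements by a
#' Gaussian-smoothed copy of the grid.
#'
#' @param kind `"zero"`, `"mean"`, or `"blurred"`.
#' @param sigma smoothing radius (voxels) for `kind = "blurred"`.
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("zero", "mean", "blurred"), sigma = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, sigma = sigma), class = "baseline_spec")
}

#' Default baseline for a modality
#' @param modality one of the three modality names.
#' @return a [baseline_spec()]: `mean` for volumetric data, `zero` otherwise.
#' @export
default_baseline <- function(modality) {
  if (modality == "volumetric") baseline_spec("mean") else baseline_spec("zero")
}

# Materialise the baseline as an object shaped like the sample data (grids)
# or a scalar coordinate value (point clouds).
baseline_field <- function(spec, sample) {
  if (!inherits(spec, "baseline_spec")) stop_validation("baseline must be a baseline_spec")
  if (sample$modality == "pointcloud") {
    if (spec$kind == "blurred") {
      stop_validation("blurred baseline is not defined for point clouds")
    }
    return(if (spec$kind == "zero") 0 else mean(sample$data))
  }
  switch(spec$kind,
    zero = array(0, dim(sample$data)),
    mean = array(mean(sample$data), dim(sample$data)),
    blurred = gaussian_blur3d(sample$data, spec$sigma)
  )
}

# Separable 3D Gaussian smoothing with reflected edges.
gaussian_blur3d <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    idx <- function(i) pmin(pmax(i, 1L), d[axis])  # clamp (replicate edges)
    out <- array(0, d)
    for (o in seq(-r, r)) {
      w <- k[o + r + 1L]
      sl <- idx(seq_len(d[axis]) + o)
      out <- out + w * switch(axis, a[sl, , , drop = FALSE],
                              a[, sl, , drop = FALSE], a[, , sl, drop = FALSE])
    }
    out
  }
  smooth_axis(smooth_axis(smooth_axis(x, 1L), 2L), 3L)
}

#' Trilinear resampling of a 3D grid
#'
#' Interpolates a scalar grid onto a new lattice using trilinear
#' interpolation on cell-center coordinates, the convention used to bring
#' attribution maps of different native resolutions to a unified shape
#' (e.g. 112 x 112 x 112 for cross-dataset aggregation) and to upsample
#' coarse class-activation or attention maps to input resolution. Constant
#' grids resample to the same constant, and the operation commutes with
#' affine intensity changes.
#'
#' @param grid 3D numeric array.
#' @param target_shape integer vector of length 3, all entries >= 1.
#' @return 3D array with dimensions `target_shape`.
#' @export
resample_volume <- function(grid, target_shape) {
  if (!(is.array(grid) && length(dim(grid)) == 3L) || !length(grid)) {
    stop_validation("resample_volume() needs a non-empty 3D array")
  }
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop_validation("target shape must be 3 integers >= 1")
  }
  d <- dim(grid)
  if (identical(d, target_shape)) return(grid)
  # cell-center mapping: target index t (0-based) sits at source coordinate
  # (t + 0.5) * d/n - 0.5, clamped to the source domain
  ax <- lapply(1:3, function(a) {
    s <- (seq_len(target_shape[a]) - 0.5) * d[a] / target_shape[a] - 0.5
    s <- pmin(pmax(s, 0), d[a] - 1L)
    lo <- pmin(floor(s), d[a] - 1L)
    list(lo = as.integer(lo) + 1L, hi = as.integer(pmin(lo + 1, d[a] - 1L)) + 1L,
         f = s - lo)
  })
  out <- array(0, target_shape)
  g1 <- expand.grid(z = seq_len(target_shape[1L]), y = seq_len(target_shape[2L]),
                    x = seq_len(target_shape[3L]))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wz <- if (cz == 0) 1 - ax[[1L]]$f else ax[[1L]]$f
    wy <- if (cy == 0) 1 - ax[[2L]]$f else ax[[2L]]$f
    wx <- if (cx == 0) 1 - ax[[3L]]$f else ax[[3L]]$f
    iz <- if (cz == 0) ax[[1L]]$lo else ax[[1L]]$hi
    iy <- if (cy == 0) ax[[2L]]$lo else ax[[2L]]$hi
    ix <- if (cx == 0) ax[[3L]]$lo else ax[[3L]]$hi
    w <- wz[g1$z] * wy[g1$y] * wx[g1$x]
    out <- out + array(w * grid[cbind(iz[g1$z], iy[g1$y], ix[g1$x])], target_shape)
  }
  out
}

#' Define a model adapter
#'
#' The contract through which every attribution method and metric queries a
#' classifier, keeping the benchmark architecture-agnostic. `score` returns
#' the per-class confidence vector used by the perturbation metrics (for
#' trained models, softmax probabilities); `gradient` differentiates the raw
#' class score (logit) with respect to the input, which is what gradient
#' attribution consumes.
#'
#' @param n_classes number of classes; `score` output length.
#' @param score `function(data) -> numeric(n_classes)` of finite confidences.
#' @param gradient `function(data, class) -> same shape as data`, or `NULL`
#'   for models without input gradients.
#' @param layer_forward_backward optional
#'   `function(data, class, layer_name) -> list(activations, gradients[, centroids])`
#'   exposing a named internal layer. Grid layers return 4-D arrays
#'   `(d,h,w,channels)`; point set-abstraction layers return
#'   `M x channels` matrices plus `M x 3` centroid coordinates.
#' @param attention_masks optional `function(data) -> named list` of spatial
#'   attention masks (3D arrays), or `NULL` for architectures without them.
#' @param layers character vector naming the layers
#'   `layer_forward_backward` accepts.
#' @param modality `"grid"` (volumetric/voxel) or `"pointcloud"`.
#' @param label short description used for printing.
#' @param logits optional `function(data) -> numeric(n_classes)` returning
#'   the raw class scores `gradient` differentiates; defaults to `score`
#'   (appropriate when confidences are the raw scores, as for the linear
#'   fixtures).
#' @return object of class `model_adapter`.
#' @export
model_adapter <- function(n_classes, score, gradient = NULL,
                          layer_forward_backward = NULL, attention_masks = NULL,
                          layers = character(), modality = "grid",
                          label = "model", logits = NULL) {
  stopifnot(is.function(score))
  structure(list(n_classes = as.integer(n_classes), score = score,
                 logits = logits %||% score, gradient = gradient,
                 layer_forward_backward = layer_forward_backward,
                 attention_masks = attention_masks, layers = layers,
                 modality = modality, label = label),
            class = "model_adapter")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter '%s'> %d classes, %s input%s%s\n", x$label,
              x$n_classes, x$modality,
              if (length(x$layers)) paste0(", layers: ", paste(x$layers, collapse = ", ")) else "",
              if (is.null(x$attention_masks)) "" else ", attention"))
  invisible(x)
}

# Confidence of the predicted class on (possibly perturbed) data.
predicted_confidence <- function(adapter, sample, data = sample$data) {
  s <- adapter$score(data)
  if (length(s) != adapter$n_classes || any(!is.finite(s))) {
    stop_validation("adapter score() must return ", adapter$n_classes,
                    " finite confidences")
  }
  s[[sample$predicted_label]]
}

#' Fill predicted labels of a sample pool using an adapter
#'
#' Scores every sample and stores the argmax class as its prediction,
#' recomputing the `correct` flag.
#'
#' @param adapter a [model_adapter()].
#' @param pool list of [sample3d()] objects.
#' @return the pool with `predicted_label`/`correct` populated.
#' @export
predict_pool <- function(adapter, pool) {
  lapply(pool, function(s) {
    pred <- which.max(adapter$score(s$data))
    sample3d(s$sample_id, s$modality, s$data, s$true_label, pred)
  })
}
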