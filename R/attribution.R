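#' Grad-CAM configuration
#'
#' @param layer_name internal layer to tap: the last 3D convolutional layer
#'   for grid models, the second set-abstraction level for point models.
#' @param upsample how coarse layer maps reach input resolution:
#'   `"trilinear"` for grids, `"nearest_neighbor_points"` for point clouds.
#' @return object of class `gradcam_config`.
#' @export
gradcam_config <- function(layer_name, upsample = c("trilinear", "nearest_neighbor_points")) {
  structure(list(layer_name = layer_name, upsample = match.arg(upsample)),
            class = "gradcam_config")
}

#' Integrated-gradients configuration
#' @param baseline a [baseline_spec()]; the path start point (default zero).
#' @param n_steps number of quadrature steps along the path (default 50).
#' @return object of class `ig_config`.
#' @export
ig_config <- function(baseline = baseline_spec("zero"), n_steps = 50L) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop_validation("integrated gradients needs n_steps >= 1")
  structure(list(baseline = baseline, n_steps = n_steps), class = "ig_config")
}

#' Occlusion configuration
#'
#' @param window integer triple: occlusion patch size for grid modalities.
#'   Defaults: `(4,4,4)` for voxel grids, `dim/8` per axis for volumetric.
#' @param stride integer triple; defaults to `window` (non-overlapping).
#' @param cluster_size number of points removed together for point clouds
#'   (default 10).
#' @param baseline a [baseline_spec()] or `NULL` for the modality default.
#' @return object of class `occlusion_config`.
#' @export
occlusion_config <- function(window = NULL, stride = NULL, cluster_size = 10L,
                             baseline = NULL) {
  structure(list(window = window, stride = stride,
                 cluster_size = as.integer(cluster_size), baseline = baseline),
            class = "occlusion_config")
}

finish_map <- function(raw, method, sample, metadata = list(), config = NULL) {
  attribution_map(normalize_attribution(raw), method = method, sample = sample,
                  normalized = TRUE, metadata = metadata, config = config)
}

#' Input-gradient saliency map
#'
#' Differentiates the predicted-class score with respect to the input and
#' takes magnitudes: per-voxel absolute gradient for grid modalities, and the
#' per-point L2 norm over the three coordinate channels for point clouds.
#' The result is min-max normalized.
#'
#' @param adapter a [model_adapter()] providing `gradient`.
#' @param sample a [sample3d()] with a populated `predicted_label`.
#' @return normalized [attribution_map()].
#' @export
saliency <- function(adapter, sample) {
  if (is.null(adapter$gradient)) stop_validation("adapter exposes no input gradient")
  g <- adapter$gradient(sample$data, sample$predicted_label)
  assert_finite(g, "input gradients")
  raw <- if (sample$modality == "pointcloud") sqrt(rowSums(g^2)) else abs(g)
  if (all(raw == 0)) warning("saliency gradient is identically zero; returning an all-zero map")
  finish_map(raw, "saliency", sample)
}

#' Integrated gradients
#'
#' Accumulates input gradients along the straight path from a baseline input
#' to the sample, approximating the path integral by a midpoint Riemann sum
#' over `n_steps` steps: attribution = (x - b) * mean_k grad(b + a_k (x - b))
#' with a_k = (k - 1/2)/n_steps. The midpoint rule is exact for linear
#' scores, so the completeness identity sum(attr) = f(x) - f(b) holds exactly
#' there and to quadrature accuracy otherwise. Rankings and metrics consume
#' attribution magnitudes (point clouds: per-point L2 norm over coordinate
#' channels); the signed raw attributions are kept in `metadata$raw_signed`.
#'
#' @param adapter a [model_adapter()] providing `gradient`.
#' @param sample a [sample3d()].
#' @param cfg an [ig_config()].
#' @return normalized [attribution_map()] with signed raw values in metadata.
#' @export
integrated_gradients <- function(adapter, sample, cfg = ig_config()) {
  if (is.null(adapter$gradient)) stop_validation("adapter exposes no input gradient")
  x <- sample$data
  b <- baseline_field(cfg$baseline, sample)
  if (sample$modality == "pointcloud" && length(b) == 1L) {
    b <- matrix(b, nrow(x), ncol(x))
  }
  diff <- x - b
  acc <- x * 0
  for (k in seq_len(cfg$n_steps)) {
    alpha <- (k - 0.5) / cfg$n_steps
    g <- adapter$gradient(b + alpha * diff, sample$predicted_label)
    if (any(!is.finite(g))) {
      stop_validation("non-finite gradient at integration step ", k)
    }
    acc <- acc + g
  }
  signed <- diff * (acc / cfg$n_steps)
  raw <- if (sample$modality == "pointcloud") sqrt(rowSums(signed^2)) else abs(signed)
  finish_map(raw, "integrated_gradients", sample,
             metadata = list(raw_signed = signed),
             config = list(baseline = cfg$baseline$kind, n_steps = cfg$n_steps))
}

# Window origin positions covering an axis of length d with window w, stride s.
occlusion_positions <- function(d, w, s) {
  p <- seq.int(1L, d - w + 1L, by = s)
  if (p[length(p)] != d - w + 1L) p <- c(p, d - w + 1L)  # cover trailing edge
  p
}

#' Occlusion sensitivity map
#'
#' Slides a fixed-size 3D window across grid inputs (or removes contiguous
#' spatial clusters of points), replaces the covered region by the baseline,
#' and records the confidence drop of the predicted class. Each covered
#' element is credited with the drop; where windows overlap, drops are
#' averaged per element. Point clouds are partitioned deterministically by
#' Morton (z-order) spatial sorting into consecutive clusters of
#' `cluster_size`.
#'
#' @param adapter a [model_adapter()].
#' @param sample a [sample3d()].
#' @param cfg an [occlusion_config()].
#' @return normalized [attribution_map()].
#' @export
occlusion <- function(adapter, sample, cfg = occlusion_config()) {
  baseline <- cfg$baseline %||% default_baseline(sample$modality)
  conf0 <- predicted_confidence(adapter, sample)
  if (sample$modality == "pointcloud") {
    n <- nrow(sample$data)
    cs <- cfg$cluster_size
    if (cs < 1L || cs > n) stop_validation("cluster_size must be in [1, N]")
    ord <- morton_order(sample$data)
    bval <- baseline_field(baseline, sample)
    raw <- numeric(n)
    starts <- seq.int(1L, n, by = cs)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + cs - 1L, n)]
      pert <- sample$data
      pert[idx, ] <- bval
      raw[idx] <- conf0 - predicted_confidence(adapter, sample, pert)
    }
    return(finish_map(raw, "occlusion", sample,
                      config = list(cluster_size = cs, baseline = baseline$kind)))
  }
  d <- dim(sample$data)
  w <- as.integer(cfg$window %||% (if (sample$modality == "voxel") c(4L, 4L, 4L)
                                   else pmax(1L, d %/% 8L)))
  if (any(w < 1L) || any(w > d)) stop_validation("occlusion window must fit inside the grid")
  s <- as.integer(cfg$stride %||% w)
  if (any(s < 1L)) stop_validation("occlusion stride must be >= 1")
  bfield <- baseline_field(baseline, sample)
  drops <- array(0, d)
  cover <- array(0, d)
  for (pz in occlusion_positions(d[1L], w[1L], s[1L])) {
    for (py in occlusion_positions(d[2L], w[2L], s[2L])) {
      for (px in occlusion_positions(d[3L], w[3L], s[3L])) {
        iz <- pz:(pz + w[1L] - 1L); iy <- py:(py + w[2L] - 1L); ix <- px:(px + w[3L] - 1L)
        pert <- sample$data
        pert[iz, iy, ix] <- bfield[iz, iy, ix]
        drop <- conf0 - predicted_confidence(adapter, sample, pert)
        drops[iz, iy, ix] <- drops[iz, iy, ix] + drop
        cover[iz, iy, ix] <- cover[iz, iy, ix] + 1
      }
    }
  }
  finish_map(drops / cover, "occlusion", sample,
             config = list(window = w, stride = s, baseline = baseline$kind))
}

gradcam_from_layer <- function(activations, gradients) {
  # channel weights: global average of the layer gradients per channel
  nd <- length(dim(activations))
  weights <- apply(gradients, nd, mean)
  flat <- matrix(activations, ncol = dim(activations)[nd])
  pmax(drop(flat %*% weights), 0)  # ReLU: keep positively contributing evidence
}

#' Grad-CAM for grid and point-cloud inputs
#'
#' Weights the feature maps of a target internal layer by the
#' global-average-pooled gradients of the predicted class score, rectifies
#' the weighted sum (ReLU), and projects it back to input resolution:
#' trilinear upsampling for volumetric/voxel grids, nearest-centroid
#' assignment (Euclidean distance, ties to the lowest centroid index) for
#' point clouds whose tapped set-abstraction layer exposes centroid
#' coordinates.
#'
#' @param adapter a [model_adapter()] exposing `layer_forward_backward`.
#' @param sample a [sample3d()].
#' @param cfg a [gradcam_config()].
#' @return normalized [attribution_map()].
#' @export
grad_cam <- function(adapter, sample, cfg) {
  if (is.null(adapter$layer_forward_backward)) {
    stop_validation("adapter exposes no named internal layers")
  }
  if (!cfg$layer_name %in% adapter$layers) {
    stop_validation("layer '", cfg$layer_name, "' not provided by this adapter (has: ",
                    paste(adapter$layers, collapse = ", "), ")")
  }
  lf <- adapter$layer_forward_backward(sample$data, sample$predicted_label,
                                       cfg$layer_name)
  if (sample$modality == "pointcloud") {
    centroids <- lf$centroids
    if (is.null(centroids) || nrow(centroids) == 0L) {
      stop_validation("point Grad-CAM needs a layer exposing centroid coordinates")
    }
    cam <- gradcam_from_layer(lf$activations, lf$gradients)
    # nearest centroid per original point; which.min breaks exact ties low
    d2 <- outer(rowSums(sample$data^2), rowSums(centroids^2), "+") -
      2 * sample$data %*% t(centroids)
    nearest <- apply(d2, 1L, which.min)
    raw <- cam[nearest]
  } else {
    cam_flat <- gradcam_from_layer(lf$activations, lf$gradients)
    cam <- array(cam_flat, dim(lf$activations)[1:3])
    raw <- resample_volume(cam, dim(sample$data))
  }
  finish_map(raw, "gradcam", sample,
             config = list(layer = cfg$layer_name, upsample = cfg$upsample))
}

#' Extract an intrinsic attention map
#'
#' Reads a named spatial attention mask from the adapter's forward pass
#' (by default the second-stage `"soft2"` mask), upsamples it trilinearly to
#' input resolution, and normalizes it. Adapters without attention (in
#' particular point-cloud models, whose set-abstraction layers carry no
#' dense attention masks) raise an unsupported-method error.
#'
#' @param adapter a [model_adapter()].
#' @param sample a [sample3d()] with grid modality.
#' @param mask_name which attention mask to extract.
#' @return normalized [attribution_map()].
#' @export
intrinsic_attention <- function(adapter, sample, mask_name = "soft2") {
  if (is.null(adapter$attention_masks)) {
    stop_validation("intrinsic attention is unsupported for this adapter (no attention masks)")
  }
  masks <- adapter$attention_masks(sample$data)
  if (!mask_name %in% names(masks)) {
    stop_validation("adapter has no attention mask named '", mask_name, "'")
  }
  raw <- resample_volume(masks[[mask_name]], dim(sample$data))
  finish_map(raw, "intrinsic", sample, config = list(mask = mask_name))
}

#' Run one attribution method by name
#'
#' Convenience dispatcher used by the benchmark pipeline.
#'
#' @param method one of `"gradcam"`, `"saliency"`, `"integrated_gradients"`,
#'   `"occlusion"`, `"intrinsic"`.
#' @param adapter a [model_adapter()].
#' @param sample a [sample3d()].
#' @param config optional method-specific configuration object.
#' @return normalized [attribution_map()].
#' @export
run_attribution <- function(method, adapter, sample, config = NULL) {
  switch(method,
    saliency = saliency(adapter, sample),
    integrated_gradients = integrated_gradients(adapter, sample, config %||% ig_config()),
    occlusion = occlusion(adapter, sample, config %||% occlusion_config()),
    gradcam = grad_cam(adapter, sample,
                       config %||% gradcam_config(utils::tail(adapter$layers, 1L),
                         if (sample$modality == "pointcloud")
                           "nearest_neighbor_points" else "trilinear")),
    intrinsic = intrinsic_attention(adapter, sample),
    stop_validation("unknown attribution method '", method, "'")
  )
}
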