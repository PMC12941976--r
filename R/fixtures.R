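# Synthetic data generators and tiny deterministic model adapters. These
# stand in, at desk scale, for the real 3D datasets and networks a full
# deployment would use: blob volumes for volumetric scans, occupancy
# primitives for voxelized shapes, clustered point sets for scanned point
# clouds. Every generator carries a per-sample ground-truth mask of the
# class-determining region so faithfulness properties are testable, and all
# randomness is driven by an explicit seed.

blob_centers <- rbind(
  c(0.30, 0.30, 0.30), c(0.70, 0.70, 0.70), c(0.30, 0.70, 0.70),
  c(0.70, 0.30, 0.30), c(0.30, 0.30, 0.70), c(0.70, 0.70, 0.30),
  c(0.30, 0.70, 0.30), c(0.70, 0.30, 0.70))

#' Generate synthetic blob volumes
#'
#' Volumetric samples in which each class is a truncated Gaussian intensity
#' blob at a class-specific location on a noisy zero background. The blob is
#' cut at half its peak amplitude, so with `noise_sd = 0` every voxel
#' outside the blob equals the background exactly and the ground-truth mask
#' (blob support above half-maximum) coincides with the non-background
#' region. Blob centers jitter by up to one voxel per sample.
#'
#' @param n_classes number of classes (at most 8 distinct blob sites).
#' @param samples_per_class samples generated per class.
#' @param shape grid dimensions (default 16^3; kept small so a full
#'   benchmark runs in minutes on one CPU).
#' @param noise_sd Gaussian background noise level (default 0.1; blob peak
#'   amplitude is 1).
#' @param seed RNG seed; generation is bit-deterministic given it.
#' @return list with `samples` (list of [sample3d()]) and `masks` (list of
#'   logical arrays marking the class-relevant region).
#' @export
gen_blob_volumes <- function(n_classes = 3L, samples_per_class = 10L,
                             shape = c(16L, 16L, 16L), noise_sd = 0.1,
                             seed = 1L) {
  if (n_classes > nrow(blob_centers)) stop_validation("at most 8 blob classes supported")
  shape <- as.integer(shape)
  width <- min(shape) / 6
  if (2 * width > min(shape)) stop_validation("blob larger than the grid")
  set.seed(seed)
  grid <- expand.grid(z = seq_len(shape[1L]), y = seq_len(shape[2L]),
                      x = seq_len(shape[3L]))
  samples <- list(); masks <- list()
  for (cls in seq_len(n_classes)) {
    for (s in seq_len(samples_per_class)) {
      center <- blob_centers[cls, ] * shape + stats::runif(3, -1, 1)
      r2 <- (grid$z - center[1L])^2 + (grid$y - center[2L])^2 + (grid$x - center[3L])^2
      blob <- exp(-r2 / (2 * width^2))
      blob[blob < 0.5] <- 0  # truncate at half maximum
      blob <- array(blob, shape)
      noise <- if (noise_sd > 0) array(stats::rnorm(prod(shape), 0, noise_sd), shape) else 0
      id <- sprintf("blob_c%d_s%03d", cls, s)
      samples[[id]] <- sample3d(id, "volumetric", blob + noise, cls)
      masks[[id]] <- blob > 0
    }
  }
  list(samples = samples, masks = masks)
}

#' Generate synthetic voxel occupancy objects
#'
#' Binary occupancy grids of simple primitives with jittered pose: class 1 a
#' filled cube, class 2 a spherical shell, class 3 a three-bar cross. The
#' ground-truth mask equals the occupied voxels.
#'
#' @param n_classes up to 3 primitive classes.
#' @param samples_per_class samples per class.
#' @param shape grid dimensions (default 16^3).
#' @param seed RNG seed.
#' @return list with `samples` and `masks` as in [gen_blob_volumes()].
#' @export
gen_voxel_objects <- function(n_classes = 3L, samples_per_class = 10L,
                              shape = c(16L, 16L, 16L), seed = 1L) {
  if (n_classes > 3L) stop_validation("at most 3 voxel primitive classes supported")
  shape <- as.integer(shape)
  set.seed(seed)
  grid <- expand.grid(z = seq_len(shape[1L]), y = seq_len(shape[2L]),
                      x = seq_len(shape[3L]))
  half <- min(shape) / 4
  samples <- list(); masks <- list()
  for (cls in seq_len(n_classes)) {
    for (s in seq_len(samples_per_class)) {
      center <- shape / 2 + stats::runif(3, -2, 2)
      dz <- abs(grid$z - center[1L]); dy <- abs(grid$y - center[2L]); dx <- abs(grid$x - center[3L])
      occ <- switch(cls,
        dz <= half & dy <= half & dx <= half,                       # cube
        { r <- sqrt(dz^2 + dy^2 + dx^2); r <= half & r >= half - 1.5 },  # shell
        (dz <= 1 & dy <= 1 & dx <= half) | (dz <= 1 & dx <= 1 & dy <= half) |
          (dy <= 1 & dx <= 1 & dz <= half)                          # cross
      )
      occ <- array(as.numeric(occ), shape)
      id <- sprintf("vox_c%d_s%03d", cls, s)
      samples[[id]] <- sample3d(id, "voxel", occ, cls)
      masks[[id]] <- occ > 0
    }
  }
  list(samples = samples, masks = masks)
}

#' Generate synthetic clustered point clouds
#'
#' Point sets in which class `c` consists of `c + 1` Gaussian clusters at
#' fixed directions plus uniform clutter points, all normalized into the
#' unit sphere. The mask marks cluster membership (the class-relevant
#' points).
#'
#' @param n_classes up to 5 classes.
#' @param samples_per_class samples per class.
#' @param n_points points per cloud (default 128).
#' @param cluster_frac fraction of points placed in clusters (default 0.75).
#' @param jitter_sd within-cluster spread before normalization (default
#'   0.05; 0 collapses clusters onto their centers).
#' @param seed RNG seed.
#' @return list with `samples` (pointcloud [sample3d()]) and `masks`
#'   (logical vectors of length `n_points`).
#' @export
gen_point_clusters <- function(n_classes = 3L, samples_per_class = 10L,
                               n_points = 128L, cluster_frac = 0.75,
                               jitter_sd = 0.05, seed = 1L) {
  if (n_classes > 5L) stop_validation("at most 5 point-cluster classes supported")
  set.seed(seed)
  dirs <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0),
                c(0, 0, 1), c(0, 0, -1), c(0.577, 0.577, 0.577))
  samples <- list(); masks <- list()
  for (cls in seq_len(n_classes)) {
    centers <- dirs[seq_len(cls + 1L), , drop = FALSE] * 0.7
    for (s in seq_len(samples_per_class)) {
      n_clu <- round(cluster_frac * n_points)
      assign_to <- rep(seq_len(nrow(centers)), length.out = n_clu)
      clu <- centers[assign_to, , drop = FALSE] +
        matrix(stats::rnorm(3 * n_clu, 0, jitter_sd), ncol = 3)
      n_noise <- n_points - n_clu
      clutter <- matrix(stats::runif(3 * n_noise, -1, 1), ncol = 3)
      pts <- rbind(clu, clutter)
      pts <- pts / max(sqrt(rowSums(pts^2)), 1)  # normalize into the unit sphere
      id <- sprintf("pts_c%d_s%03d", cls, s)
      samples[[id]] <- sample3d(id, "pointcloud", pts, cls)
      masks[[id]] <- c(rep(TRUE, n_clu), rep(FALSE, n_noise))
    }
  }
  list(samples = samples, masks = masks)
}

#' Linear model adapter (closed-form oracle fixture)
#'
#' A two-class linear score `f(x) = sum(w * x) + intercept`, reported as the
#' confidence vector `(f, -f)` without any squashing: this fixture's
#' confidence IS its raw margin, which makes saliency, integrated gradients,
#' occlusion, and the perturbation metrics exactly computable by hand
#' (gradient of class 1 equals `w` everywhere).
#'
#' @param weights numeric array/matrix with the shape of the inputs it will
#'   score (grid array, or `N x 3` for point clouds).
#' @param intercept scalar added to the class-1 score.
#' @return a [model_adapter()] with 2 classes.
#' @export
linear_adapter <- function(weights, intercept = 0) {
  force(weights); force(intercept)
  model_adapter(
    n_classes = 2L,
    score = function(x) { f <- sum(weights * x) + intercept; c(f, -f) },
    gradient = function(x, class) if (class == 1L) weights + 0 else -weights,
    modality = if (is.matrix(weights) && ncol(weights) == 3L) "pointcloud" else "grid",
    label = "linear"
  )
}

#' Matched-filter adapter: one linear template per class
#'
#' Multi-class linear fixture: class scores are inner products with fixed
#' templates, confidences are softmax probabilities, and the class-score
#' gradient equals the class template everywhere. With class-mean templates
#' this is the matched filter for the blob-volume generator.
#'
#' @param templates list of arrays (one per class, input-shaped).
#' @return a [model_adapter()].
#' @export
matched_filter_adapter <- function(templates) {
  force(templates)
  logits <- function(x) vapply(templates, function(tp) sum(tp * x), numeric(1))
  model_adapter(
    n_classes = length(templates),
    score = function(x) softmax(logits(x)),
    gradient = function(x, class) templates[[class]] + 0,
    label = "matched_filter", logits = logits
  )
}

random_kernel <- function(k = 3L) array(stats::rnorm(k^3, 0, 1 / sqrt(k^3)), c(k, k, k))

# Features: per conv channel, mean activation over each of the 8 octants of
# the layer grid (coarse region pooling keeps location information that a
# single global average would destroy). Length 8 * n_channels, octants
# fastest within each channel.
conv_features <- function(params, x) {
  xp <- avgpool3d(x, params$pool)
  f <- dim(xp)[1L] %/% 2L
  unlist(lapply(params$kernels, function(K) {
    as.vector(avgpool3d(pmax(conv3d_same(xp, K), 0), f))
  }), use.names = FALSE)
}

build_conv_adapter <- function(params, label = "tiny_conv") {
  force(params)
  logits <- function(x) drop(params$V %*% conv_features(params, x)) + params$b
  score <- function(x) softmax(logits(x))
  # d logit / d activation for channel ci: the octant head weight divided by
  # the octant cell count, spread back over the layer grid
  act_grad <- function(class, ci, dl) {
    w8 <- array(params$V[class, ((ci - 1L) * 8L + 1L):(ci * 8L)], c(2L, 2L, 2L))
    avgpool3d_backward(w8, dl[1L] %/% 2L)
  }
  logits_grad <- function(x, class) {
    xp <- avgpool3d(x, params$pool)
    g_xp <- array(0, dim(xp))
    for (ci in seq_along(params$kernels)) {
      z <- conv3d_same(xp, params$kernels[[ci]])
      gz <- act_grad(class, ci, dim(xp)) * (z > 0)
      g_xp <- g_xp + conv3d_same_backward(gz, params$kernels[[ci]])
    }
    avgpool3d_backward(g_xp, params$pool)
  }
  layer_fb <- function(x, class, layer_name) {
    if (layer_name != "conv1") stop_validation("unknown layer '", layer_name, "'")
    xp <- avgpool3d(x, params$pool)
    dl <- dim(xp)
    C <- length(params$kernels)
    act <- array(0, c(dl, C)); grd <- array(0, c(dl, C))
    for (ci in seq_len(C)) {
      act[, , , ci] <- pmax(conv3d_same(xp, params$kernels[[ci]]), 0)
      grd[, , , ci] <- act_grad(class, ci, dl)
    }
    list(activations = act, gradients = grd)
  }
  att <- if (is.null(params$att_kernels)) NULL else function(x) {
    out <- list()
    for (nm in names(params$att_kernels)) {
      a <- params$att_kernels[[nm]]
      out[[nm]] <- 1 / (1 + exp(-conv3d_same(avgpool3d(x, a$pool), a$kernel)))
    }
    out
  }
  model_adapter(n_classes = nrow(params$V), score = score, gradient = logits_grad,
                layer_forward_backward = layer_fb, attention_masks = att,
                layers = "conv1", modality = "grid", label = label, logits = logits)
}

#' Tiny 3D convolutional adapter
#'
#' A minimal grid classifier fixture: 2x average pooling, a bank of seeded
#' random 3x3x3 convolution channels with ReLU, global average pooling, and
#' a linear softmax head. Exposes exact analytic input gradients, the named
#' layer `"conv1"` for Grad-CAM, and (optionally, via
#' [tiny_attention_adapter()]) attention masks. The random feature bank is
#' fixed; only the head is trained by [fit_adapter()].
#'
#' @param seed RNG seed for kernels and head.
#' @param n_classes number of classes.
#' @param n_channels convolution channels (default 4).
#' @param pool average-pooling factor before the conv layer (default 2; grid
#'   dims must be divisible by it).
#' @return a [model_adapter()] with `$params` attached.
#' @export
tiny_conv_adapter <- function(seed = 1L, n_classes = 3L, n_channels = 4L, pool = 2L) {
  set.seed(seed)
  params <- list(
    kernels = replicate(n_channels, random_kernel(), simplify = FALSE),
    V = matrix(stats::rnorm(n_classes * 8L * n_channels), n_classes, 8L * n_channels),
    b = stats::rnorm(n_classes), pool = as.integer(pool), att_kernels = NULL
  )
  ad <- build_conv_adapter(params)
  ad$params <- params
  ad
}

#' Tiny attention adapter
#'
#' The [tiny_conv_adapter()] architecture augmented with two named spatial
#' attention stages, `"soft1"` (half resolution) and `"soft2"` (quarter
#' resolution): sigmoid-activated seeded random convolutions of the pooled
#' input, so masks always lie in (0, 1). `"soft2"` is the stage the
#' intrinsic extraction reads by default.
#'
#' @inheritParams tiny_conv_adapter
#' @return a [model_adapter()] whose `attention_masks()` returns both masks.
#' @export
tiny_attention_adapter <- function(seed = 1L, n_classes = 3L, n_channels = 4L, pool = 2L) {
  set.seed(seed)
  params <- list(
    kernels = replicate(n_channels, random_kernel(), simplify = FALSE),
    V = matrix(stats::rnorm(n_classes * 8L * n_channels), n_classes, 8L * n_channels),
    b = stats::rnorm(n_classes), pool = as.integer(pool),
    att_kernels = list(soft1 = list(kernel = random_kernel(), pool = 2L),
                       soft2 = list(kernel = random_kernel(), pool = 4L))
  )
  ad <- build_conv_adapter(params, label = "tiny_attention")
  ad$params <- params
  ad
}

point_forward <- function(params, P) {
  d2 <- outer(rowSums(P^2), rowSums(params$centroids^2), "+") -
    2 * P %*% t(params$centroids)
  k <- exp(-d2 / (2 * params$s^2))                       # N x M soft assignment
  G <- P %*% params$u + matrix(params$bc, nrow(P), length(params$bc), byrow = TRUE)
  A <- t(k) %*% G                                        # M x C centroid activations
  list(k = k, G = G, A = A, features = colMeans(A))
}

build_point_adapter <- function(params, label = "tiny_point") {
  force(params)
  logits <- function(x) drop(params$V %*% point_forward(params, x)$features) + params$b
  score <- function(x) softmax(logits(x))
  gradient <- function(x, class) {
    fw <- point_forward(params, x)
    M <- nrow(params$centroids)
    w <- params$V[class, ] / M                           # d logit / d A_mc
    uw <- drop(params$u %*% w)                           # 3-vector
    gw <- drop(fw$G %*% w)                               # N
    ksum <- rowSums(fw$k)                                # N
    kmu <- fw$k %*% params$centroids                     # N x 3
    ksum %o% uw + gw / params$s^2 * (kmu - ksum * x)
  }
  layer_fb <- function(x, class, layer_name) {
    if (layer_name != "sa2") stop_validation("unknown layer '", layer_name, "'")
    fw <- point_forward(params, x)
    M <- nrow(params$centroids)
    list(activations = fw$A,
         gradients = matrix(params$V[class, ] / M, M, ncol(fw$A), byrow = TRUE),
         centroids = params$centroids)
  }
  model_adapter(n_classes = nrow(params$V), score = score, gradient = gradient,
                layer_forward_backward = layer_fb, attention_masks = NULL,
                layers = "sa2", modality = "pointcloud", label = label, logits = logits)
}

#' Tiny point-cloud adapter
#'
#' A set-abstraction-style fixture for point clouds: fixed seeded anchor
#' centroids with Gaussian soft assignment pool linear per-point features
#' into per-centroid activations, which feed a linear softmax head. Exposes
#' exact analytic coordinate gradients and the named layer `"sa2"`
#' (activations, gradients, and centroid coordinates) for point Grad-CAM.
#' It has no dense attention masks, so intrinsic extraction is rejected, as
#' it is for point architectures generally.
#'
#' @param seed RNG seed.
#' @param n_classes number of classes.
#' @param n_centroids anchor centroids (default 8).
#' @param n_channels feature channels (default 4).
#' @param s Gaussian assignment bandwidth (default 0.5, unit-sphere scale).
#' @return a [model_adapter()] with `$params` attached.
#' @export
tiny_point_adapter <- function(seed = 1L, n_classes = 3L, n_centroids = 8L,
                               n_channels = 4L, s = 0.5) {
  set.seed(seed)
  cen <- matrix(stats::rnorm(3 * n_centroids), ncol = 3)
  cen <- cen / pmax(sqrt(rowSums(cen^2)), 1) * 0.8
  params <- list(
    centroids = cen, s = s,
    u = matrix(stats::rnorm(3 * n_channels), 3, n_channels),
    bc = stats::rnorm(n_channels, 0, 0.1),
    V = matrix(stats::rnorm(n_classes * n_channels), n_classes, n_channels),
    b = stats::rnorm(n_classes)
  )
  ad <- build_point_adapter(params)
  ad$params <- params
  ad
}

#' Fit an adapter's softmax head on labelled samples
#'
#' The deterministic fitting helper for the tiny fixtures: the random
#' feature extractor (conv bank or centroid pooling) stays frozen and only
#' the linear softmax head is re-estimated by multinomial logistic
#' regression ([nnet::multinom()]) on the pooled features. Given the same
#' samples, the refit is reproducible.
#'
#' @param adapter a [tiny_conv_adapter()], [tiny_attention_adapter()], or
#'   [tiny_point_adapter()].
#' @param samples list of [sample3d()] with true labels covering every class.
#' @return a new adapter of the same architecture with the trained head.
#' @export
fit_adapter <- function(adapter, samples) {
  params <- adapter$params
  if (is.null(params)) stop_validation("fit_adapter() only supports the tiny fixture adapters")
  is_point <- adapter$modality == "pointcloud"
  feat_fun <- if (is_point) function(s) point_forward(params, s$data)$features else
    function(s) conv_features(params, s$data)
  n_feat <- length(feat_fun(samples[[1L]]))
  feats <- t(vapply(samples, feat_fun, numeric(n_feat)))
  labels <- factor(vapply(samples, `[[`, integer(1), "true_label"),
                   levels = seq_len(adapter$n_classes))
  df <- data.frame(y = labels, feats)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300, decay = 0.01)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)   # 2-class case
  V <- rbind(0, co[, -1L, drop = FALSE])             # reference class 1 at zero
  b <- c(0, co[, 1L])
  # center across classes: softmax probabilities are unchanged but no class
  # keeps the degenerate constant-zero logit of the reference coding
  V <- sweep(V, 2L, colMeans(V))
  b <- b - mean(b)
  params$V <- unname(V)
  params$b <- unname(b)
  ad <- if (is_point) build_point_adapter(params, label = paste0(adapter$label, "_fit"))
        else build_conv_adapter(params, label = paste0(adapter$label, "_fit"))
  ad$params <- params
  ad
}

#' Finite-difference gradient self-check
#'
#' Central-difference verification of an adapter's analytic gradient at a
#' random subset of input elements; the fixture contract requires agreement
#' within `tol`.
#'
#' @param adapter a [model_adapter()] with a gradient.
#' @param data one input (grid array or point matrix).
#' @param class class index to differentiate.
#' @param n_probe number of elements probed.
#' @param h step size.
#' @param tol maximum tolerated absolute discrepancy (default 1e-4).
#' @param seed seed for probe selection.
#' @return largest absolute discrepancy observed, invisibly; errors if it
#'   exceeds `tol`.
#' @export
gradient_check <- function(adapter, data, class, n_probe = 20L, h = 1e-5,
                           tol = 1e-4, seed = 1L) {
  logits <- adapter$logits %||% adapter$score
  g <- adapter$gradient(data, class)
  set.seed(seed)
  idx <- sample.int(length(data), min(n_probe, length(data)))
  worst <- 0
  for (i in idx) {
    xp <- data; xm <- data
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    fd <- (logits(xp)[class] - logits(xm)[class]) / (2 * h)
    worst <- max(worst, abs(fd - g[i]))
  }
  if (worst > tol) {
    stop("fixture gradient self-test failed: finite-difference mismatch ",
         format(worst), " exceeds ", format(tol))
  }
  invisible(worst)
}

#' Wrap a ground-truth mask or external values as an attribution map
#'
#' Used to score reference explanations (planted masks, random baselines)
#' with the same metric machinery as the real methods.
#'
#' @param sample a [sample3d()].
#' @param values logical/numeric mask or values shaped like the sample's
#'   elements.
#' @return a normalized [attribution_map()] with method `"reference"`.
#' @export
reference_attribution <- function(sample, values) {
  v <- if (sample$modality == "pointcloud") as.numeric(values) else {
    a <- array(as.numeric(values), dim(sample$data)); a
  }
  attribution_map(normalize_attribution(v), method = "reference", sample = sample,
                  normalized = TRUE)
}
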