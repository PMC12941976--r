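test_that("saliency of a linear model is the normalized |weight| pattern", {
  fx <- linear_grid_fixture(c(2, -1), c(3, 4))
  m <- saliency(fx$adapter, fx$sample)
  expect_equal(as.vector(m$values), c(1, 0))  # |2|,|1| min-max normalized
  expect_true(m$normalized)
})

test_that("point saliency takes the per-point L2 norm over coordinate channels", {
  w <- rbind(c(3, 4, 0), c(0, 0, 1))
  adapter <- linear_adapter(w)
  s <- sample3d("p", "pointcloud", matrix(0.5, 2, 3), 1L, 1L)
  m <- saliency(adapter, s)
  # raw per-point values 5 and 1 -> normalized 1, 0
  expect_equal(as.vector(m$values), c(1, 0))
})

test_that("zero gradients yield a warned all-zero saliency map", {
  adapter <- model_adapter(2L, score = function(x) c(1, 0),
                           gradient = function(x, class) x * 0)
  s <- sample3d("z", "volumetric", array(1, c(2, 2, 2)), 1L, 1L)
  expect_warning(m <- saliency(adapter, s), "zero")
  expect_true(all(m$values == 0))
})

test_that("integrated gradients are exact for linear scores", {
  fx <- linear_grid_fixture(c(2, -1), c(3, 4))
  m <- integrated_gradients(fx$adapter, fx$sample, ig_config(n_steps = 7))
  expect_equal(as.vector(m$metadata$raw_signed), c(6, -4))
  expect_equal(sum(m$metadata$raw_signed), fx$adapter$score(fx$sample$data)[1])
  # magnitudes are ranked: |6| > |-4|
  expect_equal(as.vector(m$values), c(1, 0))
})

test_that("integrated gradients vanish when the input equals the baseline", {
  fx <- linear_grid_fixture(c(2, -1), c(0, 0))
  m <- integrated_gradients(fx$adapter, fx$sample, ig_config())
  expect_true(all(m$metadata$raw_signed == 0))
  expect_true(all(m$values == 0))
})

test_that("integrated gradients satisfy completeness on nonlinear fixtures", {
  ad <- tiny_conv_adapter(seed = 2)
  set.seed(9)
  x <- array(rnorm(8^3), c(8, 8, 8))
  s <- sample3d("nl", "volumetric", x, 1L, which.max(ad$score(x)))
  m <- integrated_gradients(ad, s, ig_config(n_steps = 500))
  gap <- ad$logits(x)[s$predicted_label] -
    ad$logits(array(0, dim(x)))[s$predicted_label]
  expect_lt(abs(sum(m$metadata$raw_signed) - gap), 1e-3)
})

test_that("occlusion reproduces hand-computed window drops on a linear model", {
  fx <- linear_grid_fixture(c(4, 3, 2, 1), c(1, 1, 1, 1))
  m <- occlusion(fx$adapter, fx$sample,
                 occlusion_config(window = c(2, 1, 1), stride = c(2, 1, 1),
                                  baseline = baseline_spec("zero")))
  # drops 7 and 3 assigned to their windows -> normalized [1,1,0,0]
  expect_equal(as.vector(m$values), c(1, 1, 0, 0))
})

test_that("single-element occlusion of a linear model equals per-feature ablation", {
  set.seed(4)
  w <- rnorm(6); x <- rnorm(6)
  fx <- linear_grid_fixture(w, x)
  m <- occlusion(fx$adapter, fx$sample,
                 occlusion_config(window = c(1, 1, 1), stride = c(1, 1, 1),
                                  baseline = baseline_spec("zero")))
  expect_equal(as.vector(m$values), as.vector(normalize_attribution(w * x)),
               tolerance = 1e-12)
})

test_that("occluding with a baseline equal to the sample changes nothing", {
  s <- sample3d("c", "volumetric", array(0, c(4, 4, 4)), 1L, 1L)
  ad <- linear_adapter(array(rnorm(64), c(4, 4, 4)))
  m <- occlusion(ad, s, occlusion_config(window = c(2, 2, 2), baseline = baseline_spec("zero")))
  expect_true(all(m$values == 0))  # zero baseline == zero sample: all drops 0
  expect_error(occlusion(ad, s, occlusion_config(window = c(8, 2, 2))), "window")
})

test_that("grid Grad-CAM matches the hand chain rule on a two-layer fixture", {
  set.seed(11)
  act <- pmax(array(rnorm(4^3), c(4, 4, 4)), 0)  # post-ReLU conv activations
  make_ad <- function(v) {
    model_adapter(2L, score = function(x) c(1, 0),
                  layer_forward_backward = function(x, class, layer) {
                    list(activations = array(act, c(4, 4, 4, 1)),
                         gradients = array(v / length(act), c(4, 4, 4, 1)))
                  }, layers = "conv1")
  }
  s <- sample3d("g", "volumetric", array(0, c(4, 4, 4)), 1L, 1L)
  m <- grad_cam(make_ad(1), s, gradcam_config("conv1"))
  expect_equal(m$values, normalize_attribution(pmax(act, 0)), tolerance = 1e-12)
  # a negative head weight flips the weighted sum below zero: ReLU erases it
  m_neg <- grad_cam(make_ad(-1), s, gradcam_config("conv1"))
  expect_true(all(m_neg$values == 0))
})

test_that("Grad-CAM upsamples coarse layers to the input shape", {
  ad <- tiny_conv_adapter(seed = 6)
  x <- array(rnorm(16^3), c(16, 16, 16))
  s <- sample3d("u", "volumetric", x, 1L, which.max(ad$score(x)))
  m <- grad_cam(ad, s, gradcam_config("conv1"))
  expect_identical(dim(m$values), dim(x))
  expect_error(grad_cam(ad, s, gradcam_config("nope")), "not provided")
})

test_that("point Grad-CAM assigns nearest-centroid values with low-index ties", {
  cen <- rbind(c(0, 0, 0), c(10, 0, 0))
  stub <- model_adapter(2L, score = function(x) c(1, 0),
    layer_forward_backward = function(x, class, layer) {
      list(activations = matrix(c(1, 0), 2, 1), gradients = matrix(1, 2, 1),
           centroids = cen)
    }, layers = "sa2", modality = "pointcloud")
  pts <- rbind(c(1, 0, 0), c(9, 0, 0), c(5, 0, 0), c(4, 1, 0))
  s <- sample3d("pc", "pointcloud", pts, 1L, 1L)
  m <- grad_cam(stub, s, gradcam_config("sa2", "nearest_neighbor_points"))
  # x<5 half-space takes centroid 1's value, x>5 takes centroid 2's;
  # the exactly equidistant point at x=5 resolves to the lower index
  expect_equal(as.vector(m$values), c(1, 0, 1, 1))
})

test_that("a single-centroid point Grad-CAM collapses to the all-zero map", {
  stub <- model_adapter(2L, score = function(x) c(1, 0),
    layer_forward_backward = function(x, class, layer) {
      list(activations = matrix(0.8, 1, 1), gradients = matrix(1, 1, 1),
           centroids = matrix(0, 1, 3))
    }, layers = "sa2", modality = "pointcloud")
  s <- sample3d("pc", "pointcloud", matrix(rnorm(9), 3), 1L, 1L)
  m <- grad_cam(stub, s, gradcam_config("sa2", "nearest_neighbor_points"))
  expect_true(all(m$values == 0))  # constant raw map normalizes to zeros
})

test_that("intrinsic attention upsampling agrees with the resampling oracle", {
  mask <- array(runif(8), c(2, 2, 2))
  stub <- model_adapter(2L, score = function(x) c(1, 0),
                        attention_masks = function(x) list(soft1 = mask * 0.5,
                                                           soft2 = mask))
  s <- sample3d("a", "volumetric", array(0, c(8, 8, 8)), 1L, 1L)
  m <- intrinsic_attention(stub, s)
  expect_equal(m$values, normalize_attribution(resample_volume(mask, c(8, 8, 8))),
               tolerance = 1e-12)
  # a mask already at input resolution passes through up to normalization
  mask_full <- array(runif(8^3), c(8, 8, 8))
  stub2 <- model_adapter(2L, score = function(x) c(1, 0),
                         attention_masks = function(x) list(soft2 = mask_full))
  expect_equal(intrinsic_attention(stub2, s)$values,
               normalize_attribution(mask_full), tolerance = 1e-12)
  expect_error(intrinsic_attention(stub, s, "soft9"), "no attention mask named")
})

test_that("intrinsic attention is rejected for point-cloud adapters", {
  pa <- tiny_point_adapter(seed = 1)
  s <- sample3d("p", "pointcloud", matrix(rnorm(30), 10), 1L, 1L)
  expect_error(intrinsic_attention(pa, s), "unsupported")
})

test_that("all methods return normalized, shape-matched, deterministic maps", {
  ad <- tiny_attention_adapter(seed = 8)
  set.seed(12)
  x <- array(rnorm(16^3), c(16, 16, 16))
  s <- sample3d("d", "volumetric", x, 1L, which.max(ad$score(x)))
  for (method in c("saliency", "integrated_gradients", "occlusion", "gradcam", "intrinsic")) {
    m1 <- run_attribution(method, ad, s)
    m2 <- run_attribution(method, ad, s)
    expect_identical(m1$values, m2$values)
    expect_identical(dim(m1$values), dim(x))
    expect_true(all(m1$values >= 0 & m1$values <= 1))
  }
})
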