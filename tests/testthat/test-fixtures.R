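test_that("all generators are bit-deterministic under a fixed seed", {
  expect_identical(gen_blob_volumes(2, 3, seed = 42), gen_blob_volumes(2, 3, seed = 42))
  expect_identical(gen_voxel_objects(3, 2, seed = 42), gen_voxel_objects(3, 2, seed = 42))
  expect_identical(gen_point_clusters(2, 2, seed = 42), gen_point_clusters(2, 2, seed = 42))
  # and actually differ across seeds
  expect_false(identical(gen_blob_volumes(2, 3, seed = 1)$samples[[1]]$data,
                         gen_blob_volumes(2, 3, seed = 2)$samples[[1]]$data))
})

test_that("noise-free blob volumes are exactly background outside the mask", {
  gen <- gen_blob_volumes(3, 2, noise_sd = 0, seed = 9)
  for (id in names(gen$samples)) {
    s <- gen$samples[[id]]
    expect_true(all(s$data[!gen$masks[[id]]] == 0))
    expect_true(any(gen$masks[[id]]))
    expect_identical(dim(gen$masks[[id]]), dim(s$data))
  }
})

test_that("a class-mean matched filter separates blob volumes at noise 0.1", {
  train <- gen_blob_volumes(3, 10, noise_sd = 0.1, seed = 21)
  templates <- lapply(1:3, function(cl) {
    idx <- grep(sprintf("^blob_c%d_", cl), names(train$samples))
    Reduce(`+`, lapply(train$samples[idx], `[[`, "data")) / length(idx)
  })
  mf <- matched_filter_adapter(templates)
  test_set <- gen_blob_volumes(3, 67, noise_sd = 0.1, seed = 22)  # ~200 samples
  pool <- predict_pool(mf, test_set$samples)
  expect_gt(mean(vapply(pool, `[[`, logical(1), "correct")), 0.9)
})

test_that("voxel primitives are binary with shell sparser than cube", {
  gen <- gen_voxel_objects(3, 4, seed = 3)
  fills <- vapply(gen$samples, function(s) {
    expect_true(all(s$data %in% c(0, 1)))
    mean(s$data)
  }, numeric(1))
  cube_fill <- mean(fills[grep("^vox_c1_", names(fills))])
  shell_fill <- mean(fills[grep("^vox_c2_", names(fills))])
  expect_lt(shell_fill, cube_fill)  # a shell occupies less of its bounding box
  # occupancy and mask coincide
  for (id in names(gen$samples)) {
    expect_identical(gen$samples[[id]]$data > 0, gen$masks[[id]])
  }
})

test_that("point clouds are unit-sphere normalized with the stated cluster fraction", {
  gen <- gen_point_clusters(3, 3, n_points = 128, seed = 4)
  for (id in names(gen$samples)) {
    pts <- gen$samples[[id]]$data
    expect_lte(max(sqrt(rowSums(pts^2))), 1 + 1e-12)
    expect_lte(abs(sum(gen$masks[[id]]) - round(0.75 * 128)), 1)
  }
})

test_that("zero-jitter clusters land exactly on centers, reproducing the mask", {
  gen <- gen_point_clusters(2, 2, n_points = 64, jitter_sd = 0, seed = 6)
  for (id in names(gen$samples)) {
    pts <- gen$samples[[id]]$data
    mask <- gen$masks[[id]]
    centers <- unique(pts[mask, , drop = FALSE])
    d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") - 2 * pts %*% t(centers)
    on_center <- apply(d2, 1, min) < 1e-12  # squared distance, fp noise ~1e-16
    expect_identical(on_center, mask)
  }
})

test_that("linear adapter gradients equal its weights for any input", {
  w <- array(rnorm(27), c(3, 3, 3))
  ad <- linear_adapter(w)
  x <- array(rnorm(27), c(3, 3, 3))
  expect_identical(ad$gradient(x, 1L), w)
  expect_identical(ad$gradient(x, 2L), -w)
  expect_equal(ad$score(x)[1], sum(w * x))
})

test_that("every fixture adapter passes central finite-difference gradient checks", {
  set.seed(31)
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_lt(gradient_check(tiny_conv_adapter(seed = 3), x, 2L), 1e-4)
  expect_lt(gradient_check(tiny_attention_adapter(seed = 5), x, 1L), 1e-4)
  expect_lt(gradient_check(linear_adapter(array(rnorm(16^3), c(16, 16, 16))), x, 1L), 1e-4)
  P <- matrix(rnorm(90, 0, 0.5), ncol = 3)
  expect_lt(gradient_check(tiny_point_adapter(seed = 7), P, 1L), 1e-4)
  tm <- lapply(1:3, function(i) array(rnorm(16^3), c(16, 16, 16)))
  expect_lt(gradient_check(matched_filter_adapter(tm), x, 3L), 1e-4)
})

test_that("the attention fixture exposes a soft2 mask bounded in (0,1)", {
  ad <- tiny_attention_adapter(seed = 5)
  masks <- ad$attention_masks(array(rnorm(16^3), c(16, 16, 16)))
  expect_true(all(c("soft1", "soft2") %in% names(masks)))
  expect_true(all(masks$soft2 > 0 & masks$soft2 < 1))
})

test_that("head fitting is deterministic and lifts accuracy well above chance", {
  train <- gen_blob_volumes(3, 15, seed = 11)
  ad1 <- fit_adapter(tiny_conv_adapter(seed = 3), train$samples)
  ad2 <- fit_adapter(tiny_conv_adapter(seed = 3), train$samples)
  expect_identical(ad1$params$V, ad2$params$V)
  test_set <- gen_blob_volumes(3, 10, seed = 12)
  acc <- mean(vapply(predict_pool(ad1, test_set$samples), `[[`, logical(1), "correct"))
  expect_gt(acc, 0.8)  # chance is 1/3
})

test_that("point-adapter head fitting separates cluster-count classes", {
  train <- gen_point_clusters(3, 15, seed = 13)
  ad <- fit_adapter(tiny_point_adapter(seed = 7), train$samples)
  test_set <- gen_point_clusters(3, 10, seed = 14)
  acc <- mean(vapply(predict_pool(ad, test_set$samples), `[[`, logical(1), "correct"))
  expect_gt(acc, 0.6)
})
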