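make_map <- function(values, sample) {
  attribution_map(normalize_attribution(values), "reference", sample,
                  normalized = TRUE)
}

test_that("ranking is descending with ascending-index tie breaks", {
  s <- sample3d("r", "volumetric", array(0, c(3, 1, 1)), 1L, 1L)
  m <- attribution_map(array(c(0.2, 0.9, 0.9), c(3, 1, 1)), "reference", s,
                       normalized = TRUE)
  expect_identical(rank_elements(m), c(2L, 3L, 1L))
  s4 <- sample3d("r4", "volumetric", array(0, c(4, 1, 1)), 1L, 1L)
  m4 <- attribution_map(array(c(1, 0.8, 0.5, 0.2), c(4, 1, 1)), "reference", s4,
                        normalized = TRUE)
  expect_identical(rank_elements(m4), 1:4)
  # agreement with a brute-force stable sort oracle on a larger map
  set.seed(3)
  v <- round(runif(100), 1)  # coarse values force many ties
  s100 <- sample3d("r100", "volumetric", array(0, c(100, 1, 1)), 1L, 1L)
  m100 <- attribution_map(array(v, c(100, 1, 1)), "reference", s100, normalized = TRUE)
  expect_identical(rank_elements(m100), order(-v, seq_along(v)))
})

test_that("removal counts follow ceil(fraction * M) and full removal zeroes everything", {
  s <- sample3d("c", "volumetric", array(runif(10), c(10, 1, 1)), 1L, 1L)
  m <- make_map(array(seq(1, 0.1, length.out = 10), c(10, 1, 1)), s)
  ord <- rank_elements(m)
  zero <- baseline_spec("zero")
  expect_equal(sum(apply_removal(s, ord, 0.25, zero) == 0), 3)  # ceil(2.5)
  expect_true(all(apply_removal(s, ord, 1, zero) == 0))
  s4 <- sample3d("c4", "volumetric", array(runif(4) + 1, c(4, 1, 1)), 1L, 1L)
  m4 <- make_map(array(runif(4), c(4, 1, 1)), s4)
  expect_equal(sum(apply_removal(s4, rank_elements(m4), 0.25, zero) == 0), 1)
  expect_error(apply_removal(s, ord, 0, zero), "fraction")
  expect_error(apply_removal(s, ord, 1.2, zero), "fraction")
})

test_that("removal and preservation are exact complements at every fraction", {
  set.seed(5)
  s <- sample3d("d", "volumetric", array(rnorm(24) + 10, c(4, 3, 2)), 1L, 1L)
  m <- make_map(array(runif(24), c(4, 3, 2)), s)
  ord <- rank_elements(m)
  zero <- baseline_spec("zero")
  for (f in c(0.1, 0.25, 0.5, 0.9, 1)) {
    removed_idx <- which(apply_removal(s, ord, f, zero) == 0)
    kept_idx <- which(apply_preservation(s, ord, f, zero) != 0)
    expect_identical(kept_idx, removed_idx)  # same top set
    expect_length(union(kept_idx, setdiff(seq_len(24), kept_idx)), 24)
  }
  expect_identical(apply_preservation(s, ord, 1, zero), s$data)
})

test_that("point removal collapses selected coordinates to the baseline constant", {
  pts <- matrix(rnorm(30) + 5, 10, 3)
  s <- sample3d("p", "pointcloud", pts, 1L, 1L)
  m <- make_map(seq(1, 0.1, length.out = 10), s)
  out <- apply_removal(s, rank_elements(m), 0.3, baseline_spec("zero"))
  expect_equal(sum(rowSums(out == 0) == 3), 3)
  expect_identical(dim(out), dim(pts))
})

test_that("AOPC reproduces the hand trapezoid on the linear ramp fixture", {
  fx <- linear_grid_fixture(c(4, 3, 2, 1), c(1, 1, 1, 1))
  m <- make_map(array(c(4, 3, 2, 1), c(4, 1, 1)), fx$sample)
  res <- compute_aopc(fx$adapter, fx$sample, m, perturbation_schedule(4),
                      baseline_spec("zero"))
  expect_equal(res$drop_curve, c(4, 7, 9, 10))
  expect_equal(res$aopc, 6.25)
  expect_equal(res$conf_init, 10)
})

test_that("a constant model has zero AOPC and a flat preservation curve", {
  ad <- model_adapter(2L, score = function(x) c(0.8, 0.2))
  s <- sample3d("k", "volumetric", array(runif(8), c(2, 2, 2)), 1L, 1L)
  m <- make_map(array(runif(8), c(2, 2, 2)), s)
  ao <- compute_aopc(ad, s, m, perturbation_schedule(4), baseline_spec("zero"))
  expect_equal(ao$drop_curve, rep(0, 4))
  expect_equal(ao$aopc, 0)
  au <- compute_aupc(ad, s, m, perturbation_schedule(4), baseline_spec("zero"))
  expect_equal(au$preservation_curve, c(0, rep(0.8, 4)))
  expect_equal(au$aupc, 0.7)  # trapezoid of the 0 -> 0.8 plateau
})

test_that("linearity ties preservation and removal confidences together", {
  set.seed(8)
  fx <- linear_grid_fixture(rnorm(12), rnorm(12))
  m <- make_map(array(runif(12), c(12, 1, 1)), fx$sample)
  ord <- rank_elements(m)
  zero <- baseline_spec("zero")
  conf <- function(d) fx$adapter$score(d)[1]
  for (f in c(0.25, 0.5, 0.75)) {
    lhs <- conf(apply_preservation(fx$sample, ord, f, zero)) +
      conf(apply_removal(fx$sample, ord, f, zero))
    expect_equal(lhs - conf(fx$sample$data * 0), conf(fx$sample$data),
                 tolerance = 1e-12)
  }
})

test_that("drop curves are non-decreasing for positive-mass linear fixtures", {
  set.seed(13)
  for (i in 1:5) {
    fx <- linear_grid_fixture(runif(10), runif(10))
    m <- make_map(array(runif(10), c(10, 1, 1)), fx$sample)
    res <- compute_aopc(fx$adapter, fx$sample, m, perturbation_schedule(10),
                        baseline_spec("zero"))
    expect_true(all(diff(res$drop_curve) >= -1e-12))
  }
})

test_that("fixed compactness counts thresholded elements against occupancy", {
  s <- sample3d("f", "volumetric", array(c(1, 1, 1, 0), c(4, 1, 1)), 1L, 1L)
  m <- attribution_map(array(c(0.9, 0.6, 0.4, 0.1), c(4, 1, 1)), "reference", s,
                       normalized = TRUE)
  r <- compute_compactness_fixed(m, s, 0.5)
  expect_equal(unname(r), 2 / 3)
  # all above threshold over a fully occupied grid gives exactly 1
  s2 <- sample3d("f2", "volumetric", array(1, c(4, 1, 1)), 1L, 1L)
  m2 <- attribution_map(array(c(0.9, 0.8, 0.7, 1), c(4, 1, 1)), "reference", s2,
                        normalized = TRUE)
  expect_equal(unname(compute_compactness_fixed(m2, s2, 0.5)), 1)
  z <- sample3d("z", "voxel", array(0, c(2, 2, 2)), 1L, 1L)
  mz <- attribution_map(array(0.5, c(2, 2, 2)), "reference", z, normalized = TRUE)
  expect_error(compute_compactness_fixed(mz, z, 0.5), "all-zero")
})

test_that("fixed compactness is non-increasing in the threshold", {
  set.seed(21)
  for (i in 1:10) {
    s <- sample3d("m", "volumetric", array(runif(27) + 0.1, c(3, 3, 3)), 1L, 1L)
    m <- make_map(array(runif(27), c(3, 3, 3)), s)
    r <- compute_compactness_fixed(m, s, seq(0.1, 0.9, by = 0.1))
    expect_true(all(diff(r) <= 0))
  }
})

test_that("adaptive compactness uses the descending-rank quantile and exceeds 1 on sparse grids", {
  vals <- array(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1), c(8, 1, 1))
  x <- array(c(1, 1, 0, 0, 0, 0, 0, 0), c(8, 1, 1))
  s <- sample3d("a", "volumetric", x, 1L, 1L)
  m <- attribution_map(vals, "reference", s, normalized = TRUE)
  expect_equal(compute_compactness_adaptive(m, s, 0.1), 0.5)  # top-1 of 8 / 2 occupied
  # degenerate equal map: every element clears the threshold
  me <- attribution_map(array(0, c(8, 1, 1)), "reference", s, normalized = TRUE)
  expect_equal(compute_compactness_adaptive(me, s, 0.1), 8 / 2)
  # sparse voxel grid with dense attribution: ratio far above 1
  occ <- array(0, c(4, 4, 4)); occ[1, 1, 1] <- 1; occ[2, 2, 2] <- 1
  sv <- sample3d("sv", "voxel", occ, 1L, 1L)
  mv <- make_map(array(seq(0, 1, length.out = 64), c(4, 4, 4)), sv)
  expect_gt(compute_compactness_adaptive(mv, sv, 0.1), 1)
})

test_that("evaluate_sample bundles every metric consistently", {
  fx <- linear_grid_fixture(c(4, 3, 2, 1), c(1, 1, 1, 1))
  m <- make_map(array(c(4, 3, 2, 1), c(4, 1, 1)), fx$sample)
  rec <- evaluate_sample(fx$adapter, fx$sample, m, perturbation_schedule(4),
                         baseline_spec("zero"))
  expect_s3_class(rec, "metric_record")
  expect_equal(rec$aopc, 6.25)
  expect_length(rec$drop_curve, 4)
  expect_equal(rec$preservation_curve[1], 0)
  expect_named(rec$compactness_fixed, c("t0.5", "t0.7", "t0.9"))
})
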