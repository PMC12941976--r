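# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities from first principles (explicit
# loops, direct counting, full enumeration) rather than calling the package
# internals they check.

# Brute-force AOPC: direct adapter calls, explicit ranking, replacement, and
# trapezoid sum.
oracle_aopc <- function(adapter, sample, values, K, baseline_value) {
  v <- as.vector(values)
  ord <- order(-v, seq_along(v))
  M <- if (sample$modality == "pointcloud") nrow(sample$data) else length(sample$data)
  pred <- sample$predicted_label
  conf0 <- adapter$score(sample$data)[pred]
  drops <- numeric(K)
  for (k in 1:K) {
    n <- ceiling(k / K * M)
    pert <- sample$data
    if (sample$modality == "pointcloud") {
      pert[ord[1:n], ] <- baseline_value
    } else {
      pert[ord[1:n]] <- baseline_value
    }
    drops[k] <- conf0 - adapter$score(pert)[pred]
  }
  area <- 0
  prev <- 0
  for (k in 1:K) {
    area <- area + (prev + drops[k]) / 2 * (1 / K)
    prev <- drops[k]
  }
  area
}

# Brute-force AUPC with the mandatory (0, 0) origin.
oracle_aupc <- function(adapter, sample, values, K, baseline_value) {
  v <- as.vector(values)
  ord <- order(-v, seq_along(v))
  M <- if (sample$modality == "pointcloud") nrow(sample$data) else length(sample$data)
  pred <- sample$predicted_label
  confs <- numeric(K)
  for (k in 1:K) {
    n <- ceiling(k / K * M)
    keep <- ord[1:n]
    pert <- sample$data
    if (sample$modality == "pointcloud") {
      pert[setdiff(seq_len(M), keep), ] <- baseline_value
    } else {
      pert[setdiff(seq_len(M), keep)] <- baseline_value
    }
    confs[k] <- adapter$score(pert)[pred]
  }
  curve <- c(0, confs)
  area <- 0
  for (k in 1:K) area <- area + (curve[k] + curve[k + 1]) / 2 * (1 / K)
  area
}

# Independent exact two-sided Mann-Whitney p by full enumeration, computing
# U directly as the count of (a_i, b_j) pairs with a_i > b_j (+ 1/2 per tie).
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  u_of <- function(ia) {
    av <- pooled[ia]
    bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  mu <- n1 * (N - n1) / 2
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# One random (adapter, sample, attribution) fixture per modality, for the
# metric oracle-equivalence checks.
random_metric_fixture <- function(modality, seed) {
  set.seed(seed)
  if (modality == "pointcloud") {
    n <- 40L
    data <- matrix(rnorm(n * 3), ncol = 3)
    adapter <- linear_adapter(matrix(rnorm(n * 3), ncol = 3))
    sample <- sample3d(paste0("rf", seed), modality, data, 1L,
                       which.max(adapter$score(data)))
    values <- runif(n)
  } else {
    d <- c(6L, 5L, 4L)
    data <- if (modality == "voxel") {
      array(rbinom(prod(d), 1, 0.5), d)
    } else {
      array(rnorm(prod(d)), d)
    }
    templates <- lapply(1:3, function(i) array(rnorm(prod(d)), d))
    adapter <- matched_filter_adapter(templates)
    sample <- sample3d(paste0("rf", seed), modality, data, 1L,
                       which.max(adapter$score(data)))
    values <- array(runif(prod(d)), d)
  }
  map <- attribution_map(normalize_attribution(values), "reference", sample,
                         normalized = TRUE)
  list(adapter = adapter, sample = sample, map = map)
}

# A tiny volumetric sample around a weight array, for linear-model checks.
linear_grid_fixture <- function(w, x) {
  stopifnot(length(w) == length(x))
  d <- c(length(w), 1L, 1L)
  adapter <- linear_adapter(array(w, d))
  sample <- sample3d("lin", "volumetric", array(x, d), 1L, 1L)
  list(adapter = adapter, sample = sample)
}

# Mask-vs-random faithfulness trial on blob volumes with a trained conv
# adapter: returns the one-sided exact Mann-Whitney p-value that mask-guided
# removal hurts confidence more than random removal.
faithfulness_trial <- function(adapter, rep_seed, n_eval = 8L, K = 10L) {
  gen <- gen_blob_volumes(n_classes = 3L, samples_per_class = ceiling(n_eval / 3),
                          seed = 10000L + rep_seed)
  pool <- predict_pool(adapter, gen$samples)[seq_len(n_eval)]
  set.seed(20000L + rep_seed)
  aopc_mask <- aopc_rand <- numeric(n_eval)
  for (i in seq_len(n_eval)) {
    s <- pool[[i]]
    mask_map <- reference_attribution(s, gen$masks[[s$sample_id]])
    rand_map <- reference_attribution(s, array(runif(length(s$data)), dim(s$data)))
    sched <- perturbation_schedule(K)
    aopc_mask[i] <- compute_aopc(adapter, s, mask_map, sched)$aopc
    aopc_rand[i] <- compute_aopc(adapter, s, rand_map, sched)$aopc
  }
  mann_whitney(aopc_mask, aopc_rand, mode = "exact", alternative = "greater")$p_raw
}

trained_blob_conv_adapter <- function() {
  train <- gen_blob_volumes(n_classes = 3L, samples_per_class = 15L, seed = 11L)
  fit_adapter(tiny_conv_adapter(seed = 3L), train$samples)
}
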