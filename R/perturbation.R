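#' Perturbation schedule
#'
#' The sequence of removal/preservation fractions k/K for k = 1..K
#' (default K = 10: 0.1, 0.2, ..., 1.0).
#'
#' @param K integer number of steps.
#' @return object of class `perturbation_schedule` with fields `K` and
#'   `fractions` (strictly increasing, ending at 1).
#' @export
perturbation_schedule <- function(K = 10L) {
  K <- as.integer(K)
  if (K < 1L) stop_validation("schedule needs K >= 1")
  structure(list(K = K, fractions = seq_len(K) / K), class = "perturbation_schedule")
}

#' Rank attribution elements by importance
#'
#' Descending by attribution value; exact ties break by ascending flat index
#' (column-major for grids, row/point index for clouds), making the ranking
#' fully deterministic.
#'
#' @param map an [attribution_map()] (normalized).
#' @return integer vector of 1-based element indices, most important first.
#' @export
rank_elements <- function(map) {
  v <- as.vector(map$values)
  order(-v)  # order() is stable: ties stay in ascending index order
}

removal_count <- function(fraction, M) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop_validation("fraction must lie in (0, 1]")
  }
  as.integer(ceiling(fraction * M))
}

perturb_elements <- function(sample, idx, baseline) {
  data <- sample$data
  if (sample$modality == "pointcloud") {
    data[idx, ] <- baseline_field(baseline, sample)  # coordinates collapse to the neutral value
  } else {
    bfield <- baseline_field(baseline, sample)
    data[idx] <- bfield[idx]
  }
  data
}

#' Remove the top-attributed fraction of a sample
#'
#' Sets the first `ceiling(fraction * M)` elements of the importance order
#' (M = total element count) to the baseline value; grid voxels take the
#' baseline field value at their position, selected points have their
#' coordinates replaced by the baseline constant (tensor shape is kept).
#'
#' @param sample a [sample3d()].
#' @param order importance ranking from [rank_elements()].
#' @param fraction in (0, 1].
#' @param baseline a [baseline_spec()].
#' @return perturbed data object (same shape as `sample$data`).
#' @export
apply_removal <- function(sample, order, fraction, baseline = default_baseline(sample$modality)) {
  n <- removal_count(fraction, n_elements(sample))
  perturb_elements(sample, order[seq_len(n)], baseline)
}

#' Keep only the top-attributed fraction of a sample
#'
#' Exact complement of [apply_removal()]: the kept set at a given fraction
#' equals removal's replaced set, and everything else goes to baseline.
#'
#' @inheritParams apply_removal
#' @return perturbed data object.
#' @export
apply_preservation <- function(sample, order, fraction, baseline = default_baseline(sample$modality)) {
  n <- removal_count(fraction, n_elements(sample))
  keep <- order[seq_len(n)]
  drop_idx <- setdiff(seq_len(n_elements(sample)), keep)
  perturb_elements(sample, drop_idx, baseline)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)

#' Correctness: area over the perturbation curve (AOPC)
#'
#' Iteratively removes the top k/K attributed elements, records the
#' predicted-class confidence drop, and integrates the drop-versus-fraction
#' curve by the trapezoidal rule with an implicit origin (0, 0). Higher AOPC
#' means the explanation points at elements the prediction causally depends
#' on.
#'
#' @param adapter a [model_adapter()].
#' @param sample a [sample3d()].
#' @param map the paired normalized [attribution_map()].
#' @param schedule a [perturbation_schedule()].
#' @param baseline a [baseline_spec()].
#' @return list with `aopc`, `drop_curve` (length K), `conf_init`.
#' @export
compute_aopc <- function(adapter, sample, map, schedule = perturbation_schedule(),
                         baseline = default_baseline(sample$modality)) {
  check_map_matches_sample(map, sample)
  ord <- rank_elements(map)
  conf_init <- predicted_confidence(adapter, sample)
  drops <- vapply(seq_len(schedule$K), function(k) {
    pert <- apply_removal(sample, ord, schedule$fractions[k], baseline)
    conf_init - predicted_confidence(adapter, sample, pert)
  }, numeric(1))
  list(aopc = trapezoid(c(0, schedule$fractions), c(0, drops)),
       drop_curve = drops, conf_init = conf_init)
}

#' Completeness: area under the preservation curve (AUPC)
#'
#' Keeps only the top k/K attributed elements, records the predicted-class
#' confidence, prepends the empty-input point (fraction 0, confidence 0),
#' and integrates by the trapezoidal rule. Higher AUPC means the highlighted
#' region alone sustains the prediction.
#'
#' @inheritParams compute_aopc
#' @return list with `aupc` and `preservation_curve` (length K + 1,
#'   starting at 0).
#' @export
compute_aupc <- function(adapter, sample, map, schedule = perturbation_schedule(),
                         baseline = default_baseline(sample$modality)) {
  check_map_matches_sample(map, sample)
  ord <- rank_elements(map)
  confs <- vapply(seq_len(schedule$K), function(k) {
    pert <- apply_preservation(sample, ord, schedule$fractions[k], baseline)
    predicted_confidence(adapter, sample, pert)
  }, numeric(1))
  curve <- c(0, confs)
  list(aupc = trapezoid(c(0, schedule$fractions), curve),
       preservation_curve = curve)
}

#' Compactness configuration
#' @param fixed_thresholds absolute thresholds in (0, 1] (default 0.5, 0.7, 0.9).
#' @param adaptive_fraction top fraction for the adaptive variant (default 0.1).
#' @return object of class `compactness_config`.
#' @export
compactness_config <- function(fixed_thresholds = c(0.5, 0.7, 0.9),
                               adaptive_fraction = 0.1) {
  if (any(fixed_thresholds <= 0 | fixed_thresholds > 1)) {
    stop_validation("fixed thresholds must lie in (0, 1]")
  }
  if (adaptive_fraction <= 0 || adaptive_fraction >= 1) {
    stop_validation("adaptive fraction must lie in (0, 1)")
  }
  structure(list(fixed_thresholds = fixed_thresholds,
                 adaptive_fraction = adaptive_fraction),
            class = "compactness_config")
}

compactness_denominator <- function(sample) {
  n <- if (sample$modality == "pointcloud") nrow(sample$data) else sum(sample$data != 0)
  if (n == 0L) stop_validation("compactness is undefined for an all-zero sample")
  n
}

#' Fixed-threshold compactness
#'
#' For each absolute threshold t, the ratio of elements with attribution
#' >= t to the number of non-zero input elements (all N points count as
#' non-zero for point clouds, where occupancy is meaningless). On sparse
#' grids the ratio can exceed 1 when attributed elements outnumber occupied
#' voxels.
#'
#' @param map a normalized [attribution_map()].
#' @param sample the paired [sample3d()] with at least one non-zero element.
#' @param thresholds numeric thresholds in (0, 1].
#' @return named numeric vector, one ratio per threshold.
#' @export
compute_compactness_fixed <- function(map, sample, thresholds = c(0.5, 0.7, 0.9)) {
  check_map_matches_sample(map, sample)
  denom <- compactness_denominator(sample)
  out <- vapply(thresholds, function(t) sum(map$values >= t) / denom, numeric(1))
  names(out) <- paste0("t", thresholds)
  out
}

#' Adaptive (top-fraction) compactness
#'
#' Thresholds at the empirical (1 - a) quantile of the attribution values,
#' taken as the value at descending rank `ceiling(a * M)`, and reports the
#' count of elements at or above it relative to the non-zero input count.
#' Concentrated attributions on sparse inputs give ratios above 1.
#'
#' @param map a normalized [attribution_map()].
#' @param sample the paired [sample3d()].
#' @param fraction top fraction a in (0, 1) (default 0.1).
#' @return single ratio.
#' @export
compute_compactness_adaptive <- function(map, sample, fraction = 0.1) {
  check_map_matches_sample(map, sample)
  if (fraction <= 0 || fraction >= 1) stop_validation("fraction must lie in (0, 1)")
  denom <- compactness_denominator(sample)
  v <- as.vector(map$values)
  thr <- sort(v, decreasing = TRUE)[ceiling(fraction * length(v))]
  sum(v >= thr) / denom
}

#' Score one (sample, attribution) pair on all metrics
#'
#' Bundles AOPC, AUPC, and both compactness variants into one record, the
#' unit the benchmark pipeline aggregates and tests over.
#'
#' @inheritParams compute_aopc
#' @param compactness a [compactness_config()].
#' @return object of class `metric_record`: a list with `sample_id`,
#'   `method`, `aopc`, `aupc`, `compactness_fixed`, `compactness_adaptive`,
#'   `drop_curve`, `preservation_curve`, `conf_init`.
#' @export
evaluate_sample <- function(adapter, sample, map,
                            schedule = perturbation_schedule(),
                            baseline = default_baseline(sample$modality),
                            compactness = compactness_config()) {
  ao <- compute_aopc(adapter, sample, map, schedule, baseline)
  au <- compute_aupc(adapter, sample, map, schedule, baseline)
  structure(list(
    sample_id = sample$sample_id,
    method = map$method,
    aopc = ao$aopc,
    aupc = au$aupc,
    compactness_fixed = compute_compactness_fixed(map, sample, compactness$fixed_thresholds),
    compactness_adaptive = compute_compactness_adaptive(map, sample, compactness$adaptive_fraction),
    drop_curve = ao$drop_curve,
    preservation_curve = au$preservation_curve,
    conf_init = ao$conf_init
  ), class = "metric_record")
}

#' @export
print.metric_record <- function(x, ...) {
  cat(sprintf("<metric_record> '%s' x %s: AOPC=%.4f AUPC=%.4f compact(a)=%.4f\n",
              x$sample_id, x$method, x$aopc, x$aupc, x$compactness_adaptive))
  invisible(x)
}
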