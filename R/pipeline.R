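#' Benchmark configuration
#'
#' Governs one end-to-end benchmark run: which attribution methods to score,
#' how many samples per class to select (balanced between correctly and
#' incorrectly classified instances), the perturbation schedule, and the
#' output location.
#'
#' @param dataset short dataset name used in reports.
#' @param modality `"volumetric"`, `"voxel"`, or `"pointcloud"`.
#' @param methods character vector of attribution method names; `"intrinsic"`
#'   is rejected for point clouds.
#' @param samples_per_class samples drawn per class (default 5).
#' @param k_steps perturbation steps K (default 10).
#' @param compactness a [compactness_config()].
#' @param baseline optional [baseline_spec()] overriding the modality default.
#' @param seed integer seed governing the run.
#' @param output_dir directory for artifacts, or `NULL` to keep everything
#'   in memory.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(dataset = "synthetic", modality, methods,
                             samples_per_class = 5L, k_steps = 10L,
                             compactness = compactness_config(),
                             baseline = NULL, seed = 1L, output_dir = NULL) {
  modality <- match.arg(modality, c("volumetric", "voxel", "pointcloud"))
  known <- c("gradcam", "saliency", "integrated_gradients", "occlusion", "intrinsic")
  bad <- setdiff(methods, known)
  if (length(bad)) stop_validation("unknown method(s): ", paste(bad, collapse = ", "))
  if (modality == "pointcloud" && "intrinsic" %in% methods) {
    stop_validation("intrinsic attention is not supported for point clouds")
  }
  if (samples_per_class < 1L) stop_validation("samples_per_class must be >= 1")
  structure(list(dataset = dataset, modality = modality, methods = methods,
                 samples_per_class = as.integer(samples_per_class),
                 k_steps = as.integer(k_steps), compactness = compactness,
                 baseline = baseline, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "benchmark_config")
}

#' Select a class-balanced evaluation subset
#'
#' Per class (by true label), takes `ceiling(s/2)` correctly and
#' `floor(s/2)` incorrectly classified samples, ordered by `sample_id`
#' before slicing; a shortfall in one stratum is back-filled from the other.
#' Classes absent from the pool are skipped with a warning. The selection is
#' fully deterministic for a given pool.
#'
#' @param pool list of [sample3d()] with predictions populated (see
#'   [predict_pool()]).
#' @param samples_per_class target count s per class.
#' @return list of selected [sample3d()].
#' @export
select_samples <- function(pool, samples_per_class = 5L) {
  if (!length(pool)) stop_validation("sample pool is empty")
  if (any(vapply(pool, function(s) is.na(s$predicted_label), logical(1)))) {
    stop_validation("pool has samples without predictions; run predict_pool() first")
  }
  labs <- vapply(pool, `[[`, integer(1), "true_label")
  ids <- vapply(pool, `[[`, character(1), "sample_id")
  pool <- pool[order(ids)]
  labs <- labs[order(ids)]
  out <- list()
  for (cls in sort(unique(labs))) {
    members <- pool[labs == cls]
    if (!length(members)) {
      warning("class ", cls, " absent from pool; skipped")
      next
    }
    corr <- Filter(function(s) s$correct, members)
    inc <- Filter(function(s) !s$correct, members)
    n_c <- ceiling(samples_per_class / 2)
    n_i <- floor(samples_per_class / 2)
    take_c <- utils::head(corr, n_c)
    take_i <- utils::head(inc, n_i)
    short <- samples_per_class - length(take_c) - length(take_i)
    if (short > 0) {  # back-fill from whichever stratum has spares
      spare <- c(utils::tail(corr, -length(take_c)), utils::tail(inc, -length(take_i)))
      take_c <- c(take_c, utils::head(spare, short))
    }
    out <- c(out, take_c, take_i)
  }
  out
}

record_row <- function(rec) {
  row <- data.frame(sample_id = rec$sample_id, method = rec$method,
                    aopc = rec$aopc, aupc = rec$aupc,
                    compactness_adaptive = rec$compactness_adaptive,
                    conf_init = rec$conf_init, stringsAsFactors = FALSE)
  for (nm in names(rec$compactness_fixed)) {
    row[[paste0("compactness_", nm)]] <- rec$compactness_fixed[[nm]]
  }
  row
}

#' Flatten metric records to a table
#' @param records list of `metric_record` objects.
#' @return data.frame, one row per (sample, method).
#' @export
records_table <- function(records) {
  if (!length(records)) return(data.frame())
  do.call(rbind, lapply(records, record_row))
}

benchmark_metrics <- function(tbl) {
  fixed <- grep("^compactness_t", names(tbl), value = TRUE)
  c("aopc", "aupc", fixed, "compactness_adaptive")
}

# Statistics stage: per metric, IQR-filter each method's values, test method
# differences by Kruskal-Wallis, and (gated at alpha = 0.05, but always
# reported, flagged exploratory when the gate fails) run Bonferroni-corrected
# pairwise Mann-Whitney tests with the family = all method pairs of this
# dataset-metric combination.
analyze_records <- function(tbl, alpha = 0.05) {
  metrics <- benchmark_metrics(tbl)
  methods <- sort(unique(tbl$method))
  summary_rows <- list(); stat_rows <- list()
  for (metric in metrics) {
    groups <- list()
    for (m in methods) {
      vals <- tbl[[metric]][tbl$method == m]
      filt <- withCallingHandlers(iqr_filter(vals),
                                  warning = function(w) invokeRestart("muffleWarning"))
      groups[[m]] <- filt$kept
      q <- stats::quantile(filt$kept, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        metric = metric, method = m, n_total = length(vals),
        n_kept = length(filt$kept), n_removed = length(filt$removed),
        mean = mean(filt$kept), q1 = q[1L], median = q[2L], q3 = q[3L],
        stringsAsFactors = FALSE)
    }
    kw <- kruskal_wallis(groups)
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      metric = metric, comparison = "all methods", test = "kruskal_wallis",
      statistic = kw$statistic, z_score = NA_real_, p_raw = kw$p_raw,
      p_corrected = kw$p_raw, effect_size = kw$effect_size,
      effect_label = kw$effect_label, exploratory = FALSE,
      stringsAsFactors = FALSE)
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    m_family <- length(pairs)
    exploratory <- kw$p_raw >= alpha
    for (pr in pairs) {
      mw <- mann_whitney(groups[[pr[1L]]], groups[[pr[2L]]], mode = "auto")
      stat_rows[[length(stat_rows) + 1L]] <- data.frame(
        metric = metric, comparison = paste(pr, collapse = " vs "),
        test = "mann_whitney", statistic = mw$statistic, z_score = mw$z_score,
        p_raw = mw$p_raw, p_corrected = bonferroni(mw$p_raw, m_family),
        effect_size = mw$effect_size, effect_label = mw$effect_label,
        exploratory = exploratory, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary_rows), stats = do.call(rbind, stat_rows))
}

#' Run the full benchmark protocol
#'
#' Orchestrates the end-to-end protocol on a scored sample pool: balanced
#' per-class sample selection, attribution map generation for every
#' configured method, metric evaluation (AOPC, AUPC, compactness),
#' per-method-and-metric IQR outlier filtering, Kruskal-Wallis across
#' methods per metric followed by Bonferroni-corrected pairwise
#' Mann-Whitney tests, and artifact emission. Failures in any (sample,
#' method) cell are recorded and the run continues. Given a fixed seed and
#' pool the run is bit-deterministic.
#'
#' @param cfg a [benchmark_config()].
#' @param adapter the [model_adapter()] under explanation.
#' @param pool list of [sample3d()]; predictions are filled in via the
#'   adapter if absent.
#' @return object of class `xai_benchmark`.
#' @export
run_benchmark <- function(cfg, adapter, pool) {
  set.seed(cfg$seed)
  if (any(vapply(pool, function(s) is.na(s$predicted_label), logical(1)))) {
    pool <- predict_pool(adapter, pool)
  }
  selected <- select_samples(pool, cfg$samples_per_class)
  schedule <- perturbation_schedule(cfg$k_steps)
  baseline <- cfg$baseline %||% default_baseline(cfg$modality)
  records <- list(); maps <- list(); failures <- list()
  for (s in selected) {
    for (method in cfg$methods) {
      key <- paste(s$sample_id, method, sep = "_")
      res <- tryCatch({
        map <- run_attribution(method, adapter, s)
        rec <- evaluate_sample(adapter, s, map, schedule, baseline, cfg$compactness)
        list(map = map, rec = rec)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        records[[key]] <- res$rec
        maps[[key]] <- res$map
      }
    }
  }
  tbl <- records_table(records)
  analysis <- if (nrow(tbl) && length(unique(tbl$method)) >= 2L) {
    analyze_records(tbl)
  } else {
    list(summary = data.frame(), stats = data.frame())
  }
  result <- structure(list(config = cfg, records = records, table = tbl,
                           summary = analysis$summary, stats = analysis$stats,
                           maps = maps, failures = failures,
                           selected_ids = vapply(selected, `[[`, character(1), "sample_id"),
                           samples = stats::setNames(selected,
                             vapply(selected, `[[`, character(1), "sample_id"))),
                      class = "xai_benchmark")
  if (!is.null(cfg$output_dir)) emit_report(result, cfg$output_dir)
  result
}

#' Write benchmark artifacts to disk
#'
#' Emits the CSV metric table, the filtered summary and statistics tables,
#' the per-record perturbation curves (NumPy arrays), one attribution
#' container per (sample, method), a JSON provenance block echoing the
#' configuration and seed, and optionally one boxplot image per metric.
#' An empty run writes an explicit no-records marker instead of tables.
#'
#' @param result an `xai_benchmark` object.
#' @param dir output directory (created if needed).
#' @param boxplots logical; also render per-metric PNG boxplots.
#' @return `dir`, invisibly.
#' @export
emit_report <- function(result, dir, boxplots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  cfg <- result$config
  prov <- list(dataset = cfg$dataset, modality = cfg$modality,
               methods = cfg$methods, samples_per_class = cfg$samples_per_class,
               k_steps = cfg$k_steps,
               compactness = list(fixed_thresholds = cfg$compactness$fixed_thresholds,
                                  adaptive_fraction = cfg$compactness$adaptive_fraction),
               baseline = (cfg$baseline %||% default_baseline(cfg$modality))$kind,
               seed = cfg$seed, selected = result$selected_ids,
               n_failures = length(result$failures),
               package_version = as.character(utils::packageVersion("xaibench3d")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!nrow(result$table)) {
    writeLines("no records", file.path(dir, "NO_RECORDS"))
    return(invisible(dir))
  }
  utils::write.csv(result$table, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(result$stats, file.path(dir, "stats.csv"), row.names = FALSE)
  curve_dir <- file.path(dir, "curves")
  dir.create(curve_dir, showWarnings = FALSE)
  for (key in names(result$records)) {
    rec <- result$records[[key]]
    write_npy(rec$drop_curve, file.path(curve_dir, paste0(key, "_drop.npy")))
    write_npy(rec$preservation_curve, file.path(curve_dir, paste0(key, "_preservation.npy")))
  }
  attr_dir <- file.path(dir, "attributions")
  for (key in names(result$maps)) {
    rec <- result$records[[key]]
    save_attribution(result$maps[[key]], result$samples[[rec$sample_id]],
                     file.path(attr_dir, key))
  }
  if (boxplots) {
    for (metric in benchmark_metrics(result$table)) {
      grDevices::png(file.path(dir, paste0("boxplot_", metric, ".png")),
                     width = 640, height = 480)
      plot(result, metric = metric)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}

#' @export
print.xai_benchmark <- function(x, ...) {
  cat(sprintf("<xai_benchmark> %s (%s): %d samples x %d methods, %d records, %d failures\n",
              x$config$dataset, x$config$modality, length(x$selected_ids),
              length(x$config$methods), nrow(x$table), length(x$failures)))
  invisible(x)
}

#' @export
summary.xai_benchmark <- function(object, alpha = 0.05, ...) {
  print(object)
  if (!nrow(object$summary)) {
    cat("no records\n")
    return(invisible(object))
  }
  cat("\nPer-method means after IQR filtering:\n")
  means <- stats::reshape(object$summary[, c("metric", "method", "mean")],
                          direction = "wide", idvar = "method", timevar = "metric")
  names(means) <- sub("^mean\\.", "", names(means))
  print(means, row.names = FALSE, digits = 4)
  sig <- object$stats[object$stats$test == "mann_whitney" &
                        object$stats$p_corrected < alpha &
                        !object$stats$exploratory, , drop = FALSE]
  cat(sprintf("\n%d significant pairwise differences at corrected alpha = %.3g:\n",
              nrow(sig), alpha))
  if (nrow(sig)) {
    print(sig[, c("metric", "comparison", "p_corrected", "effect_size", "effect_label")],
          row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Boxplot of one benchmark metric across methods
#' @param x an `xai_benchmark` object.
#' @param metric column of the metric table to plot (default `"aopc"`).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.xai_benchmark <- function(x, metric = "aopc", ...) {
  if (!metric %in% names(x$table)) stop_validation("unknown metric '", metric, "'")
  graphics::boxplot(stats::as.formula(paste(metric, "~ method")), data = x$table,
                    main = paste(x$config$dataset, "-", metric),
                    xlab = "method", ylab = metric, ...)
  invisible(x)
}
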