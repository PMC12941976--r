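effect_label_r <- function(r) {
  if (r >= 0.5) "Large" else if (r >= 0.3) "Medium" else if (r >= 0.1) "Small" else "Negligible"
}

effect_label_eta <- function(e) {
  if (e >= 0.14) "Large" else if (e >= 0.06) "Medium" else if (e >= 0.01) "Small" else "Negligible"
}

stat_result <- function(test, statistic, p_raw, effect_size, effect_label,
                        z_score = NA_real_, p_corrected = NA_real_,
                        group_labels = NULL, n_per_group = NULL, note = NULL) {
  structure(list(test = test, statistic = statistic, z_score = z_score,
                 p_raw = p_raw, p_corrected = p_corrected,
                 effect_size = effect_size, effect_label = effect_label,
                 group_labels = group_labels, n_per_group = n_per_group,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, p=%.4g%s, effect=%.3f (%s)\n", x$test,
              x$statistic, x$p_raw,
              if (is.na(x$p_corrected)) "" else sprintf(" (corrected %.4g)", x$p_corrected),
              x$effect_size, x$effect_label))
  invisible(x)
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based k-group comparison: H with midrank tie correction and a
#' chi-square p-value on k - 1 degrees of freedom (via
#' [stats::kruskal.test()]), plus the eta-squared estimator
#' `(H - k + 1) / (n - k)`. Negative estimates (possible when H < k - 1 in
#' small samples) are clamped to 0 and noted. Identical values across all
#' groups give the degenerate H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each non-empty.
#' @return a `stat_result` with `test = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || any(lengths(groups) < 1L)) {
    stop_validation("kruskal_wallis() needs >= 2 non-empty groups")
  }
  k <- length(groups)
  n <- sum(lengths(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(stat_result("kruskal_wallis", statistic = 0, p_raw = 1,
                       effect_size = 0, effect_label = "Negligible",
                       group_labels = names(groups), n_per_group = lengths(groups),
                       note = "degenerate: all values identical"))
  }
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  eta <- (H - k + 1) / (n - k)
  note <- NULL
  if (eta < 0) {
    eta <- 0
    note <- "eta-squared clamped to 0 (H < k - 1)"
  }
  stat_result("kruskal_wallis", statistic = H, p_raw = unname(kt$p.value),
              effect_size = eta, effect_label = effect_label_eta(eta),
              group_labels = names(groups), n_per_group = lengths(groups),
              note = note)
}

mwu_u1 <- function(ranks_a, n1, n2) sum(ranks_a) - n1 * (n1 + 1) / 2

#' Mann-Whitney U test with exact permutation p-values
#'
#' Two-group rank test reporting `U = min(U1, U2)`. In `exact` mode the
#' two-sided p-value is computed by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments (the permutation distribution of
#' U), which controls the type-I error exactly at small n. `auto` uses the
#' exact test when the pooled size is at most 12 and the data are tie-free,
#' otherwise the tie-corrected normal approximation with a 0.5 continuity
#' correction. The normal-approximation Z-score is always retained so
#' Cohen's r can be derived from it.
#'
#' @param a,b non-empty numeric vectors.
#' @param mode `"exact"`, `"approx"`, or `"auto"`.
#' @param alternative `"two.sided"` (default) or `"greater"` (a tends larger).
#' @return a `stat_result` with `test = "mann_whitney"`, the `z_score`, and
#'   Cohen's r as the effect size.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx"),
                         alternative = c("two.sided", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop_validation("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- any(duplicated(pooled))
  U1 <- mwu_u1(r[seq_len(n1)], n1, n2)
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  cc <- if (abs(U1 - mu) > 0.5) sign(U1 - mu) * 0.5 else U1 - mu
  z <- if (sigma > 0) (U1 - mu - cc) / sigma else 0
  if (mode == "auto") mode <- if (N <= 12L && !ties) "exact" else "approx"
  eps <- 1e-9
  if (mode == "exact") {
    sets <- utils::combn(N, n1)
    u_perm <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (alternative == "two.sided") {
      mean(abs(u_perm - mu) >= abs(U1 - mu) - eps)
    } else {
      mean(u_perm >= U1 - eps)
    }
  } else {
    p <- if (sigma == 0) 1 else if (alternative == "two.sided") {
      min(1, 2 * stats::pnorm(-abs(z)))
    } else {
      stats::pnorm(-(U1 - mu - 0.5) / sigma)
    }
  }
  r_eff <- cohen_r(z, N)
  stat_result("mann_whitney", statistic = min(U1, U2), p_raw = p,
              effect_size = r_eff, effect_label = effect_label_r(r_eff),
              z_score = z, n_per_group = c(n1, n2),
              note = paste0("mode=", mode,
                            if (alternative != "two.sided") paste0(", alternative=", alternative) else ""))
}

#' Cohen's r effect size from a Z-score
#'
#' `r = |Z| / sqrt(n_total)`, with the conventional interpretation bands
#' 0.1 (small), 0.3 (medium), 0.5 (large).
#'
#' @param z_score normal-approximation Z of a rank test.
#' @param n_total total number of observations (>= 2).
#' @return numeric effect size; its band label is in
#'   `attr(, "label")`.
#' @export
cohen_r <- function(z_score, n_total) {
  if (n_total < 2) stop_validation("cohen_r() needs n_total >= 2")
  r <- abs(z_score) / sqrt(n_total)
  attr(r, "label") <- effect_label_r(r)
  r
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons in its family and
#' caps at 1. For the pairwise stage of the benchmark the family is the set
#' of method pairs within one dataset-metric combination (5 methods give
#' m = 10 and an alpha = 0.05 significance cut of 0.005).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)` and must be at least
#'   that.
#' @return corrected p-values, never smaller than the input, never above 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) {
    stop_validation("family size m must be >= the number of p-values")
  }
  pmin(p_values * m, 1)
}

#' Interquartile-range outlier filter
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' from linear-interpolation quantiles ([stats::quantile()] type 7). The
#' order of kept values is preserved. With fewer than 4 values the filter is
#' skipped with a warning and everything is kept.
#'
#' @param values numeric vector.
#' @return list with `kept` (filtered values), `bounds` (an
#'   `outlier_bounds` list: `q1`, `q3`, `iqr`, `lower`, `upper`, or `NULL`
#'   when skipped), and `removed` (indices into the input).
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; IQR filter skipped")
    return(list(kept = values, bounds = NULL, removed = integer()))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  bounds <- structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr,
                           lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr),
                      class = "outlier_bounds")
  removed <- which(values < bounds$lower | values > bounds$upper)
  kept <- if (length(removed)) values[-removed] else values
  list(kept = kept, bounds = bounds, removed = removed)
}
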