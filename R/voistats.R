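# VOI statistics: per-subject VOI means of parameter maps, pooled-variance
# two-sample t-tests and Pearson correlations, and the cohort-level report
# (group comparisons and all pairwise correlations among the five myelin
# measures and the five g-ratio variants).

#' VOI-mean values of parameter maps
#'
#' Means over valid (finite) voxels, one row per VOI and metric; with
#' `per_lesion = TRUE` each connected lesion component (6-connectivity)
#' additionally gets its own row (`lesion_01`, ...).
#'
#' @param maps named list of [volume_map]s (or 3D arrays) sharing one grid.
#' @param vois named list of logical masks (entries that are not logical
#'   3D masks, e.g. probability maps, are ignored).
#' @param per_lesion add per-lesion-component rows (needs a `lesion` mask).
#' @return data.frame with columns `voi`, `metric`, `mean`, `n_voxels`.
#'   Empty VOIs yield `NA` means with `n_voxels = 0`.
#' @export
extract_voi_means <- function(maps, vois, per_lesion = FALSE) {
  arrs <- lapply(maps, vol_values)
  masks <- Filter(function(m) is.logical(m) && length(dim(m)) == 3L,
                  lapply(vois, function(v)
                    if (is.logical(v)) v else NULL))
  do.call(check_same_grid, c(arrs, masks))
  if (per_lesion && !is.null(masks$lesion)) {
    lab <- label_components(masks$lesion)
    for (k in seq_len(max(lab)))
      masks[[sprintf("lesion_%02d", k)]] <- lab == k
  }
  rows <- list()
  for (vn in names(masks)) {
    idx <- which(masks[[vn]])
    for (mn in names(arrs)) {
      vals <- arrs[[mn]][idx]
      vals <- vals[is.finite(vals)]
      rows[[length(rows) + 1L]] <-
        data.frame(voi = vn, metric = mn,
                   mean = if (length(vals)) mean(vals) else NA_real_,
                   n_voxels = length(vals))
    }
  }
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t-test
#'
#' Equal-variance two-sided t-test with `df = n_a + n_b - 2` (the classic
#' `ttest2` convention). Zero pooled variance with equal means gives
#' `t = 0, p = 1`; with unequal means it gives an infinite statistic,
#' `p = 0`, and `degenerate = TRUE`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `n_a`, `n_b`, `degenerate`.
#' @export
two_sample_ttest <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = df, n_a = na, n_b = nb,
                  degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df,
                n_a = na, n_b = nb, degenerate = TRUE))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, n_a = na, n_b = nb,
       degenerate = FALSE)
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson R with the p value from the t-transform at `df = n - 2`.
#' Zero variance in either input gives an NA result with
#' `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors, >= 3 complete pairs.
#' @return list with `r`, `p`, `n`, `degenerate`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, degenerate = FALSE))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n, degenerate = FALSE)
}

#' Cohort-level statistics report
#'
#' Assembles the per-subject VOI-mean tables and computes (i) group t-tests
#' -- healthy WM vs patient NAWM per metric, and NAWM vs lesion / NAWM vs
#' perilesion within patients -- and (ii) all pairwise Pearson correlations
#' of subject-mean values among the supplied metrics, separately per tissue
#' class (healthy WM, NAWM, lesions). No multiple-testing correction is
#' applied; the number of tests is recorded instead.
#'
#' @param subject_tables named list of per-subject VOI-mean tables from
#'   [extract_voi_means()].
#' @param groups character vector (`"healthy"`/`"patient"`) parallel to
#'   `subject_tables`.
#' @param metrics metrics to test/correlate; default: all shared metrics.
#' @return A `cohort_stats` list: `voi_means` (long table with subject and
#'   group columns), `ttests`, `correlations`, `n_tests`.
#' @export
build_cohort_report <- function(subject_tables, groups, metrics = NULL) {
  stopifnot(length(subject_tables) == length(groups))
  ids <- names(subject_tables) %||% sprintf("sub%02d",
                                            seq_along(subject_tables))
  long <- do.call(rbind, Map(function(tab, id, gr)
    cbind(subject = id, group = gr, tab), subject_tables, ids, groups))
  rownames(long) <- NULL
  if (is.null(metrics)) metrics <- unique(long$metric)
  pick <- function(voi, metric, group = NULL) {
    sel <- long$voi == voi & long$metric == metric
    if (!is.null(group)) sel <- sel & long$group == group
    long$mean[sel]
  }
  ttests <- list()
  add_test <- function(label, metric, a, b) {
    if (length(a[is.finite(a)]) < 2 || length(b[is.finite(b)]) < 2) {
      message("skipping comparison ", label, " for ", metric,
              ": group too small")
      return(invisible(NULL))
    }
    tt <- two_sample_ttest(a, b)
    ttests[[length(ttests) + 1L]] <<-
      data.frame(comparison = label, metric = metric, t = tt$t, p = tt$p,
                 df = tt$df, n_a = tt$n_a, n_b = tt$n_b,
                 degenerate = tt$degenerate)
  }
  for (m in metrics) {
    add_test("healthyWM_vs_NAWM", m, pick("WM", m, "healthy"),
             pick("WM", m, "patient"))
    add_test("NAWM_vs_lesion", m, pick("WM", m, "patient"),
             pick("lesion", m, "patient"))
    add_test("NAWM_vs_perilesion", m, pick("WM", m, "patient"),
             pick("perilesion", m, "patient"))
  }
  ttests <- if (length(ttests)) do.call(rbind, ttests) else NULL

  cors <- list()
  classes <- list(healthyWM = list(voi = "WM", group = "healthy"),
                  NAWM = list(voi = "WM", group = "patient"),
                  lesion = list(voi = "lesion", group = "patient"))
  pairs <- if (length(metrics) >= 2) utils::combn(metrics, 2) else NULL
  if (!is.null(pairs)) {
    for (cl in names(classes)) {
      for (k in seq_len(ncol(pairs))) {
        m1 <- pairs[1, k]; m2 <- pairs[2, k]
        x <- pick(classes[[cl]]$voi, m1, classes[[cl]]$group)
        y <- pick(classes[[cl]]$voi, m2, classes[[cl]]$group)
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3) next
        pc <- suppressWarnings(pearson_corr(x[ok], y[ok]))
        cors[[length(cors) + 1L]] <-
          data.frame(tissue = cl, metric_a = m1, metric_b = m2, r = pc$r,
                     p = pc$p, n = pc$n,
                     significant = is.finite(pc$p) && pc$p < 0.05)
      }
    }
  }
  cors <- if (length(cors)) do.call(rbind, cors) else NULL
  n_tests <- (if (!is.null(ttests)) nrow(ttests) else 0L) +
    (if (!is.null(cors)) nrow(cors) else 0L)
  structure(list(voi_means = long, ttests = ttests, correlations = cors,
                 n_tests = n_tests),
            class = "cohort_stats")
}
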