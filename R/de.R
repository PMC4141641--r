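#' @name de
#' @title Two-condition expression-array differential expression
#'
#' @description
#' Detection-p-value filtering, quantile normalization, per-timepoint
#' Welch t-testing and signed fold-change list assembly for duplicate
#' two-condition expression arrays.
NULL

#' Remove probes not reliably detected on the array
#'
#' Keeps probes whose platform detection p-value falls below `alpha` in
#' at least `min_samples` samples; the rest carry signal too low to be
#' reliably measured.
#'
#' @param es An [expression_set()].
#' @param alpha Detection cutoff in (0, 1); default 0.05.
#' @param min_samples Minimum number of samples meeting the cutoff.
#' @return The filtered `expression_set` (possibly with zero probes).
#' @export
detection_filter <- function(es, alpha = 0.05, min_samples = 1L) {
  stopifnot(inherits(es, "expression_set"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must lie in (0, 1)")
  keep <- rowSums(es$detection_p < alpha) >= min_samples
  subset_probes(es, keep)
}

#' Quantile normalization (rank-mean)
#'
#' Forces every sample to share one empirical intensity distribution:
#' each column is sorted, values are averaged across columns at each
#' rank to form the reference distribution, and each column's values are
#' replaced by the reference value at their original rank. Ties within a
#' column receive the mean of their rank-group's reference values, so
#' the map is well defined and the operation idempotent.
#'
#' @param x Numeric matrix (features x samples) with >= 2 columns, or an
#'   [expression_set()] whose intensities are normalized in place.
#' @return Same type as `x`, quantile normalized.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expression_set")) {
    x$intensity <- quantile_normalize(x$intensity)
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("quantile normalization needs >= 2 samples")
  if (nrow(x) == 0L) return(x)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- x[o, j]
    grp <- cumsum(c(TRUE, v[-1L] != v[-length(v)]))  # runs of tied values
    out[o, j] <- stats::ave(ref, grp)                # rank-group mean of ref
  }
  out
}

#' Welch two-sample t-test
#'
#' The unequal-variance t statistic `(mean(x) - mean(y)) /
#' sqrt(s2x/nx + s2y/ny)` with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and
#' equal means the comparison is vacuous and `p = 1` by convention.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' welch_test(c(10, 12), c(20, 24))
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs at least 2 finite values")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2, p = if (d == 0) 1 else 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1L) + vy^2 / (length(y) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Signed linear fold change
#'
#' The expression ratio `r = mean_b / mean_a` reported in the signed
#' convention common for array lists: `+r` for increases (`r >= 1`) and
#' `-1/r` for decreases, so a 5-fold drop reads -5.
#'
#' @param mean_a Reference (control) mean, > 0.
#' @param mean_b Treatment mean, > 0.
#' @return Signed fold change (never in (-1, 1)).
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0))
    stopf("fold change requires positive means")
  r <- mean_b / mean_a
  ifelse(r >= 1, r, -1 / r)
}

#' Select differentially expressed probes
#'
#' Keeps probes with `|signed fold change| > fc_threshold` (strict) and
#' `p <= p_threshold`, partitioned by direction and ordered by absolute
#' fold change, descending (ties by probe id).
#'
#' @param detable A data frame with `probe_id`, `fold_change`, `p_value`
#'   (as built by [run_de_pipeline()]).
#' @param fc_threshold Linear fold-change cutoff (> 0), exceeded
#'   strictly.
#' @param p_threshold p-value cutoff, met inclusively.
#' @return A list with data frames `up` and `down`.
#' @export
select_de <- function(detable, fc_threshold = 5, p_threshold = 0.05) {
  check_positive(fc_threshold, "fc_threshold")
  check_positive(p_threshold, "p_threshold")
  pass <- abs(detable$fold_change) > fc_threshold & detable$p_value <= p_threshold
  sel <- detable[pass & !is.na(pass), , drop = FALSE]
  sel <- sel[order(-abs(sel$fold_change), sel$probe_id), , drop = FALSE]
  list(up = sel[sel$fold_change > 0, , drop = FALSE],
       down = sel[sel$fold_change < 0, , drop = FALSE])
}

#' Volcano-plot coordinates
#'
#' Adds the two derived columns a volcano plot uses: the signed log2
#' fold change (`sign(fc) * log2(|fc|)`) and `-log10(p)`. No filtering.
#'
#' @param detable A data frame with `fold_change` and `p_value`.
#' @return The table with `log2_fc` and `neg_log10_p` appended.
#' @export
build_volcano_table <- function(detable) {
  detable$log2_fc <- sign(detable$fold_change) * log2(abs(detable$fold_change))
  detable$neg_log10_p <- -log10(detable$p_value)
  detable
}

#' Run the expression-array differential-expression pipeline
#'
#' Applies the detection filter, quantile normalizes all arrays of the
#' experiment jointly, then per timepoint computes condition means on
#' the normalized linear scale, the signed fold change, and a Welch
#' t-test across the biological replicates. Gene lists are assembled at
#' the 3x and 5x fold cutoffs (both at `p <= p_threshold`).
#'
#' @param es An [expression_set()] with conditions `ref_condition` and
#'   one treatment condition at each requested timepoint.
#' @param timepoints Timepoints to analyse (default: all in the sample
#'   sheet).
#' @param ref_condition Control condition, the fold-change denominator
#'   (default `"GFP"`).
#' @param alpha,min_samples Detection-filter parameters.
#' @param fc_thresholds Fold cutoffs for list assembly (default
#'   `c(3, 5)`).
#' @param p_threshold p cutoff (default 0.05).
#' @param pool_timepoints If `TRUE`, replicates from all timepoints enter
#'   one Welch test per probe (n = replicates x timepoints per group)
#'   and a single table is returned under timepoint `"pooled"`;
#'   otherwise each timepoint is tested separately on its own
#'   replicates.
#' @return An object of class `de_result`: `tables` (one DE data frame
#'   per timepoint: means, fold change, t, df, p, direction, volcano
#'   columns), `lists` (per timepoint and fold cutoff: up/down frames),
#'   `stage_report`, and `normalized` (the filtered, normalized
#'   `expression_set`).
#' @examples
#' sim <- simulate_expression(array_sim_config(n_probes = 300, seed = 9))
#' res <- run_de_pipeline(sim$expr)
#' res$stage_report
#' @export
run_de_pipeline <- function(es, timepoints = NULL, ref_condition = "GFP",
                            alpha = 0.05, min_samples = 1L,
                            fc_thresholds = c(3, 5), p_threshold = 0.05,
                            pool_timepoints = FALSE) {
  stopifnot(inherits(es, "expression_set"))
  conds <- unique(es$samples$condition)
  if (!ref_condition %in% conds)
    stopf("reference condition '%s' absent from sample sheet", ref_condition)
  trt <- setdiff(conds, ref_condition)
  if (length(trt) != 1L)
    stopf("expected exactly one non-reference condition, found: %s",
          paste(trt, collapse = ", "))
  if (is.null(timepoints)) timepoints <- sort(unique(es$samples$timepoint))

  n0 <- nrow(es$intensity)
  filtered <- detection_filter(es, alpha = alpha, min_samples = min_samples)
  n1 <- nrow(filtered$intensity)
  stage_report <- data.frame(
    stage = c("probes_total", "probes_detected"),
    retained = c(n0, n1), stringsAsFactors = FALSE)
  if (n1 == 0L) {
    return(structure(list(tables = list(), lists = list(),
                          stage_report = stage_report, normalized = filtered),
                     class = "de_result"))
  }
  normalized <- quantile_normalize(filtered)

  de_one <- function(tp_label, tp_set) {
    sm <- normalized$samples
    in_tp <- sm$timepoint %in% tp_set
    ref_cols <- sm$sample[in_tp & sm$condition == ref_condition]
    trt_cols <- sm$sample[in_tp & sm$condition == trt]
    if (length(ref_cols) < 2L || length(trt_cols) < 2L)
      stopf("timepoint %s needs >= 2 replicates per condition", tp_label)
    X <- normalized$intensity
    mean_ref <- rowMeans(X[, ref_cols, drop = FALSE])
    mean_trt <- rowMeans(X[, trt_cols, drop = FALSE])
    wt <- lapply(seq_len(nrow(X)), function(i)
      welch_test(X[i, trt_cols], X[i, ref_cols]))
    tab <- data.frame(
      probe_id = normalized$probes$probe_id,
      gene_symbol = normalized$probes$gene_symbol,
      timepoint = tp_label,
      mean_ref = mean_ref, mean_trt = mean_trt,
      fold_change = fold_change(mean_ref, mean_trt),
      t_stat = vapply(wt, `[[`, 0, "t"),
      df = vapply(wt, `[[`, 0, "df"),
      p_value = vapply(wt, `[[`, 0, "p"),
      stringsAsFactors = FALSE)
    tab$direction <- ifelse(tab$fold_change >= 1, "up", "down")
    build_volcano_table(tab)
  }

  if (pool_timepoints) {
    tables <- list(pooled = de_one("pooled", timepoints))
  } else {
    tables <- lapply(timepoints, function(tp) de_one(as.character(tp), tp))
    names(tables) <- as.character(timepoints)
  }
  lists <- lapply(tables, function(tab) {
    out <- lapply(fc_thresholds, select_de, detable = tab,
                  p_threshold = p_threshold)
    names(out) <- paste0("fc", fc_thresholds)
    out
  })
  for (tp in names(tables)) {
    for (fc in names(lists[[tp]])) {
      sel <- lists[[tp]][[fc]]
      stage_report <- rbind(stage_report, data.frame(
        stage = sprintf("de_%s_%s", tp, fc),
        retained = nrow(sel$up) + nrow(sel$down), stringsAsFactors = FALSE))
    }
  }
  structure(list(tables = tables, lists = lists, stage_report = stage_report,
                 normalized = normalized),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("Expression-array differential expression\n")
  with(x$stage_report,
       cat(paste(sprintf("  %-20s %d", stage, retained), collapse = "\n"), "\n"))
  for (tp in names(x$lists)) {
    for (fc in names(x$lists[[tp]])) {
      sel <- x$lists[[tp]][[fc]]
      cat(sprintf("  timepoint %s, %s: %d up / %d down\n",
                  tp, fc, nrow(sel$up), nrow(sel$down)))
    }
  }
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  print(object)
  for (tp in names(object$tables)) {
    tab <- object$tables[[tp]]
    top <- tab[order(-abs(tab$fold_change)), , drop = FALSE]
    cat(sprintf("Top probes at timepoint %s:\n", tp))
    print(utils::head(top[, c("probe_id", "gene_symbol", "fold_change",
                              "t_stat", "p_value")], 5L), row.names = FALSE)
  }
  invisible(object)
}
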