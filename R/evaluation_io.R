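# Batch evaluation: condition summaries in the style of the six-metric
# performance table, percent-change / effect-size consistency arithmetic on
# printed values, and normality-gated paired comparisons on simulated
# cohorts.

#' Percent change with a stated metric direction
#'
#' For higher-is-better metrics, `100 (t - b) / b`; for lower-is-better
#' metrics (spatial error, workload), `100 (b - t) / b`, so improvements
#' are positive either way.
#'
#' @param baseline,treatment condition means.
#' @param direction `"higher"` or `"lower"` (which direction is better).
#' @param digits rounding for table display (1 decimal); `NULL` for none.
#' @export
percent_change <- function(baseline, treatment,
                           direction = c("higher", "lower"), digits = 1) {
  direction <- match.arg(direction)
  if (any(baseline == 0)) stop("zero baseline")
  pc <- if (direction == "higher") {
    100 * (treatment - baseline) / baseline
  } else {
    100 * (baseline - treatment) / baseline
  }
  if (is.null(digits)) pc else round(pc, digits)
}

#' Cohen's d from a paired t statistic
#'
#' Paired-design convention: `d = t / sqrt(n)` with `n` the number of
#' pairs.
#'
#' @param t_value paired t statistic.
#' @param n number of pairs (>= 2).
#' @export
cohens_d_from_t <- function(t_value, n) {
  stopifnot(n >= 2)
  t_value / sqrt(n)
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences selects a paired t test (with
#' Cohen's d = mean(diff)/sd(diff)) or a Wilcoxon signed-rank test (with
#' the rank-biserial correlation). Zero-variance differences are handled as
#' a degenerate case. The Bonferroni-adjusted alpha for the six planned
#' metrics (0.05/6) is reported alongside.
#'
#' @param a,b paired, equal-length samples (condition A and B).
#' @param alpha unadjusted significance level.
#' @param n_comparisons planned comparisons for the Bonferroni adjustment.
#' @return list: `method`, `statistic`, `p_value`, `effect`, `effect_type`,
#'   `alpha_adjusted`, `significant`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, n_comparisons = 6) {
  if (length(a) != length(b)) stop("samples must be paired and equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  d <- b - a
  alpha_adj <- alpha / n_comparisons
  if (stats::sd(d) == 0) {
    return(list(
      method = "degenerate", statistic = 0,
      p_value = if (all(d == 0)) 1 else NA_real_,
      effect = if (all(d == 0)) 0 else sign(d[1]) * Inf,
      effect_type = "d", alpha_adjusted = alpha_adj, significant = FALSE
    ))
  }
  normal <- stats::shapiro.test(d)$p.value >= 0.05
  if (normal) {
    tt <- stats::t.test(b, a, paired = TRUE)
    eff <- mean(d) / stats::sd(d)
    res <- list(method = "paired t", statistic = unname(tt$statistic),
                p_value = tt$p.value, effect = eff, effect_type = "d")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))
    rk <- rank(abs(d[d != 0]))
    sg <- sign(d[d != 0])
    rb <- sum(rk * sg) / sum(rk) # rank-biserial correlation
    res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value, effect = rb, effect_type = "rank-biserial")
  }
  res$alpha_adjusted <- alpha_adj
  res$significant <- res$p_value < alpha_adj
  res
}

# metric direction conventions for the six-metric table
metric_directions <- c(
  tasks_completed = "higher", spatial_error_mm = "lower",
  efficiency = "higher", nasa_tlx = "lower",
  success_rate = "higher", precision = "higher"
)

#' Summarise per-condition trial results into a metrics table
#'
#' @param results data.frame with a `condition` column (two levels:
#'   baseline first by factor order) and one column per metric.
#' @param directions named character vector mapping metric columns to
#'   `"higher"`/`"lower"`; defaults cover the six standard metrics.
#' @param paired run [paired_compare()] per metric (requires equal trial
#'   counts per condition, matched by order).
#' @return data.frame of class `metrics_table`: per-condition mean/SD,
#'   improvement %, and test statistics.
#' @export
summarize_metrics <- function(results, directions = metric_directions,
                              paired = TRUE) {
  if (nrow(results) == 0) stop("empty results")
  conds <- unique(results$condition)
  if (length(conds) != 2) stop("exactly two conditions required")
  metrics <- setdiff(names(results), c("condition", "trial"))
  rows <- lapply(metrics, function(m) {
    a <- results[[m]][results$condition == conds[1]]
    b <- results[[m]][results$condition == conds[2]]
    dir <- directions[[m]] %||% "higher"
    row <- data.frame(
      metric = m,
      baseline_mean = mean(a), baseline_sd = if (length(a) > 1) stats::sd(a) else NA_real_,
      treatment_mean = mean(b), treatment_sd = if (length(b) > 1) stats::sd(b) else NA_real_,
      improvement_pct = percent_change(mean(a), mean(b), dir)
    )
    if (paired && length(a) == length(b) && length(a) >= 3 && dir %in% c("higher", "lower")) {
      pc <- paired_compare(a, b)
      row$method <- pc$method
      row$statistic <- pc$statistic
      row$p_value <- pc$p_value
      row$effect <- pc$effect
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Read a tab-separated metrics fixture with column validation
#'
#' @param path TSV file path.
#' @param required character vector of required column names.
#' @export
read_metrics_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("malformed metrics table: missing column(s) ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Write an evaluation report
#'
#' TSV table plus a human-readable text rendering.
#'
#' @param table a [summarize_metrics()] table (or any data.frame).
#' @param path output path without extension; writes `<path>.tsv` and
#'   `<path>.txt`.
#' @export
write_report <- function(table, path) {
  write_tsv(as.data.frame(table), paste0(path, ".tsv"))
  txt <- utils::capture.output(print(as.data.frame(table), row.names = FALSE))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' Consistency check of a printed performance table
#'
#' Recomputes each improvement percentage from the printed condition means
#' (with the metric's stated direction) and each Cohen's d from the printed
#' t statistic and sample size, and compares with the printed values at
#' table precision.
#'
#' @param fixture data.frame with columns `metric`, `mean_baseline`,
#'   `mean_treatment`, `direction`, `improvement_pct`, and optionally
#'   `t_value`, `n`, `effect_d`.
#' @return the fixture with `improvement_recomputed`, `d_recomputed` and
#'   logical `*_match` columns.
#' @export
check_printed_table <- function(fixture) {
  fixture$improvement_recomputed <- mapply(
    function(b, t, dir) percent_change(b, t, dir),
    fixture$mean_baseline, fixture$mean_treatment, fixture$direction
  )
  fixture$improvement_match <-
    abs(fixture$improvement_recomputed - abs(fixture$improvement_pct)) < 0.05
  if (!is.null(fixture$t_value)) {
    has_t <- !is.na(fixture$t_value)
    fixture$d_recomputed <- NA_real_
    fixture$d_recomputed[has_t] <-
      round(cohens_d_from_t(fixture$t_value[has_t], fixture$n[has_t]), 2)
    fixture$d_match <- is.na(fixture$t_value) |
      abs(fixture$d_recomputed - fixture$effect_d) < 0.005
  }
  fixture
}
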