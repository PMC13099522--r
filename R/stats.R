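#' Standardized mean-difference effect size
#'
#' \eqn{E = (\mu_1 - \mu_2) / \sigma}, where \eqn{\sigma} is by default the
#' population standard deviation of the two groups concatenated; the
#' classical pooled within-group SD is available as an option (the two
#' coincide when group means are equal).
#'
#' @param group1,group2 numeric vectors.
#' @param sigma \code{"population"} (SD of the concatenation, divisor n) or
#'   \code{"pooled"} (pooled within-group SD, divisor n1 + n2 - 2).
#' @return Unitless effect size; \code{NA} when the spread is zero.
#' @export
effect_size <- function(group1, group2,
                        sigma = c("population", "pooled")) {
  sigma <- match.arg(sigma)
  if (!length(group1) || !length(group2))
    stop("effect_size: both groups must be non-empty")
  s <- if (sigma == "population") {
    all_v <- c(group1, group2)
    sqrt(mean((all_v - mean(all_v))^2))
  } else {
    n1 <- length(group1); n2 <- length(group2)
    sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
           (n1 + n2 - 2))
  }
  if (!is.finite(s) || s == 0) return(NA_real_)
  (mean(group1) - mean(group2)) / s
}

#' Compare two conditions or groups with Wilcoxon rank tests
#'
#' The harness enforces the unit-of-analysis convention: one value per unit
#' (fish or pair) per condition, averaged first if several records share a
#' unit/condition cell. Paired comparisons (e.g. no-shock vs shock within
#' fish) use the Wilcoxon signed-rank test; unpaired group comparisons (e.g.
#' WT vs TG) the Wilcoxon rank-sum test. Tests are two-sided; exact
#' small-sample p-values are used whenever the data permit.
#'
#' @param data data frame with columns \code{unit}, \code{condition},
#'   \code{value}; \code{condition} must take exactly two levels. Records
#'   with missing values are dropped (missingness propagates by exclusion,
#'   never as zeros).
#' @param paired logical: signed-rank on per-unit differences (TRUE) or
#'   rank-sum on the two groups (FALSE).
#' @param sigma passed to [effect_size()].
#' @return Object of class \code{"comparison_result"} with fields
#'   \code{test}, \code{p_value}, \code{effect_size}, \code{n1}, \code{n2},
#'   \code{mean1}, \code{mean2}, \code{sd1}, \code{sd2}, \code{conditions}.
#' @export
compare_conditions <- function(data, paired, sigma = "population") {
  need <- c("unit", "condition", "value")
  if (!all(need %in% names(data)))
    stop("compare_conditions: data must have columns unit, condition, value")
  data <- data[!is.na(data$value), , drop = FALSE]
  conds <- sort(unique(as.character(data$condition)))
  if (length(conds) != 2L)
    stop("compare_conditions: exactly two conditions required")
  agg <- stats::aggregate(value ~ unit + condition, data = data, FUN = mean)
  g1 <- agg$value[agg$condition == conds[1]]
  u1 <- agg$unit[agg$condition == conds[1]]
  g2 <- agg$value[agg$condition == conds[2]]
  u2 <- agg$unit[agg$condition == conds[2]]
  if (paired) {
    common <- intersect(u1, u2)
    if (length(common) < length(union(u1, u2)))
      stop("compare_conditions: paired mode requires both conditions per unit")
    if (length(common) < 3L)
      stop("compare_conditions: need at least 3 units")
    v1 <- g1[match(common, u1)]; v2 <- g2[match(common, u2)]
    diffs <- v1 - v2
    p <- if (all(diffs == 0)) 1  # degenerate: no signed differences to rank
         else suppressWarnings(stats::wilcox.test(v1, v2, paired = TRUE)$p.value)
    n1 <- n2 <- length(common)
    m1 <- mean(v1); m2 <- mean(v2); s1 <- stats::sd(v1); s2 <- stats::sd(v2)
    es <- effect_size(v1, v2, sigma)
    test <- "signed_rank"
  } else {
    if (length(g1) + length(g2) < 3L)
      stop("compare_conditions: need at least 3 units")
    p <- suppressWarnings(stats::wilcox.test(g1, g2)$p.value)
    n1 <- length(g1); n2 <- length(g2)
    m1 <- mean(g1); m2 <- mean(g2); s1 <- stats::sd(g1); s2 <- stats::sd(g2)
    es <- effect_size(g1, g2, sigma)
    test <- "rank_sum"
  }
  structure(list(test = test, p_value = p, effect_size = es,
                 n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, sd1 = s1,
                 sd2 = s2, conditions = conds),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Wilcoxon %s test: %s vs %s\n",
              sub("_", "-", x$test), x$conditions[1], x$conditions[2]))
  cat(sprintf("  n = %d/%d, mean %.4g vs %.4g\n", x$n1, x$n2, x$mean1, x$mean2))
  cat(sprintf("  p = %.5g, effect size = %.5g\n", x$p_value, x$effect_size))
  invisible(x)
}

#' Batch comparisons over a metrics table
#'
#' Runs [compare_conditions()] for every metric column of a per-unit metrics
#' table, mirroring the panel-by-panel comparison layout of the analysis.
#'
#' @param metrics data frame with columns \code{unit}, \code{condition} and
#'   one column per metric.
#' @param metric_cols character vector of metric column names (default: all
#'   numeric columns except unit/condition).
#' @param paired passed to [compare_conditions()].
#' @return Data frame: one row per metric with n, group means, p and effect
#'   size.
#' @export
compare_metrics <- function(metrics, metric_cols = NULL, paired = FALSE) {
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                           c("unit", "condition"))
  rows <- lapply(metric_cols, function(mc) {
    r <- compare_conditions(
      data.frame(unit = metrics$unit, condition = metrics$condition,
                 value = metrics[[mc]]),
      paired = paired)
    data.frame(metric = mc, test = r$test, n1 = r$n1, n2 = r$n2,
               mean1 = r$mean1, mean2 = r$mean2,
               p_value = r$p_value, effect_size = r$effect_size)
  })
  do.call(rbind, rows)
}
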