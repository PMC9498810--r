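#' Rank-based comparison of two groups
#'
#' Two-sided Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired)
#' test, with the exact small-sample p-value where feasible and the
#' normal approximation with tie correction otherwise (the default
#' behavior of [stats::wilcox.test()]). Fully degenerate inputs (all
#' values identical across both groups, or all paired differences zero)
#' are reported with p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors (>= 3 finite values each;
#'   equal lengths if `paired`).
#' @param paired Paired test?
#' @return One-row tibble: `test`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `median_a`, `median_b`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (paired) {
    if (length(values_a) != length(values_b))
      abort("paired comparison needs equal-length vectors")
    keep <- is.finite(values_a) & is.finite(values_b)
    a <- values_a[keep]; b <- values_b[keep]
  }
  if (length(a) < 3 || length(b) < 3)
    abort("compare_groups needs at least 3 values per group")
  test <- if (paired) "wilcoxon_paired" else "mann_whitney"
  degenerate <- if (paired) all(a == b) else
    length(unique(c(a, b))) == 1
  if (degenerate) {
    stat <- NA_real_; p <- 1
  } else {
    w <- suppressWarnings(wilcox.test(a, b, paired = paired,
                                      alternative = "two.sided"))
    stat <- unname(w$statistic); p <- w$p.value
  }
  tibble(test = test, n_a = length(a), n_b = length(b),
         statistic = stat, p_value = p,
         median_a = median(a), median_b = median(b))
}

#' Correlation between two measurements
#'
#' Spearman's rho or Pearson's r with a two-sided p-value, on pairwise-
#' complete observations. Zero variance in either variable gives an
#' undefined coefficient, flagged rather than errored.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row tibble: `method`, `n`, `estimate`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("correlate needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(method = method, n = length(x), estimate = NA_real_,
                  statistic = NA_real_, p_value = NA_real_,
                  degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  tibble(method = method, n = length(x), estimate = unname(ct$estimate),
         statistic = unname(ct$statistic), p_value = ct$p.value,
         degenerate = FALSE)
}

#' Summary statistics per speed class and condition
#'
#' Median, mean, standard deviation and n of a measurement, for every
#' class (and condition, if present), in deterministic order. Classes
#' emptied by QC keep a row with `n = 0`; single-observation cells report
#' `sd = 0` with `single_obs = TRUE`.
#'
#' @param data Tibble of per-gene measurements.
#' @param value Column name (string) of the measurement.
#' @param class_col Column name of the class labels.
#' @param condition_col Optional column name of the condition labels.
#' @return Tibble `measurement`, class, (condition), `n`, `mean`,
#'   `median`, `sd`, `single_obs`.
#' @export
summarize_by_class <- function(data, value, class_col = "speed_class",
                               condition_col = NULL) {
  if (!value %in% names(data)) abort(paste0("no column ", value))
  grp <- c(class_col, condition_col)
  out <- data |>
    filter(!is.na(.data[[value]])) |>
    group_by(across(all_of(grp)), .drop = FALSE) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      median = median(.data[[value]]),
      sd = sd(.data[[value]]),
      .groups = "drop"
    ) |>
    mutate(
      single_obs = .data$n == 1,
      sd = ifelse(.data$n <= 1, ifelse(.data$n == 1, 0, NA_real_), .data$sd),
      mean = ifelse(.data$n == 0, NA_real_, .data$mean),
      median = ifelse(.data$n == 0, NA_real_, .data$median)
    ) |>
    arrange(across(all_of(grp)))
  bind_cols(tibble(measurement = rep(value, nrow(out))), out)
}
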