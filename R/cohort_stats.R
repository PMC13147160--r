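# Group-level comparison of per-cell (or per-well) measurements: Welch's
# t-test with Satterthwaite degrees of freedom, the conventional
# significance-star labels, and fold changes of group means. Comparisons
# are two-sided throughout and summaries are reported as mean +/- SD.

#' Welch's two-sample t-test with cohort summaries
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) plus the descriptive summaries used in cohort tables: per-group
#' mean +/- SD, significance stars and the fold change of group means
#' (b over a, when both means are positive).
#'
#' @param a,b numeric vectors of per-cell/per-well measurements (each
#'   `n >= 2`, finite).
#' @return an object of class `welch_comparison`: list with `t_statistic`,
#'   `welch_df`, `p_value`, `stars`, `fold_change`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))$p_value
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs n >= 2 (got %d and %d)", length(a), length(b))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stopf("non-finite values in input")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      warnf("both groups constant and equal: reporting t = 0, p = 1")
      res <- list(statistic = 0, parameter = NA_real_, p.value = 1)
    } else {
      stopf("both groups have zero variance but different means")
    }
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter), p.value = tt$p.value)
  }
  fc <- if (mean(a) > 0 && mean(b) > 0) mean(b) / mean(a) else NA_real_
  structure(list(
    t_statistic = res$statistic, welch_df = res$parameter,
    p_value = res$p.value, stars = significance_stars(res$p.value),
    fold_change = fc,
    n = c(a = length(a), b = length(b)),
    mean = c(a = mean(a), b = mean(b)),
    sd = c(a = sd(a), b = sd(b))),
    class = "welch_comparison")
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.3g, p = %.4g (%s)\n",
              x$t_statistic, x$welch_df, x$p_value, x$stars))
  cat(sprintf("  a: %.4g +/- %.4g (n = %d); b: %.4g +/- %.4g (n = %d); fold b/a = %.4g\n",
              x$mean["a"], x$sd["a"], x$n["a"],
              x$mean["b"], x$sd["b"], x$n["b"], x$fold_change))
  invisible(x)
}

#' Significance star labels
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 and `****` for p < 0.0001 (strict inequalities; the most
#' extreme applicable label is returned). Vectorized.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of labels.
#' @export
#' @examples
#' significance_stars(c(0.03, 0.05, 5e-5))
significance_stars <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' Fold change of group means
#'
#' `mean(test) / mean(reference)`. The metrics compared here are
#' non-negative, so a non-positive reference mean makes the ratio
#' undefined and raises an error rather than returning an infinity.
#'
#' @param reference,test numeric vectors (or lists with a `values`
#'   element) of measurements.
#' @return the ratio of means.
#' @export
fold_change <- function(reference, test) {
  if (is.list(reference)) reference <- reference$values
  if (is.list(test)) test <- test$values
  mr <- mean(as.numeric(reference))
  if (!is.finite(mr) || mr <= 0)
    stopf("reference mean must be positive (got %g); fold change undefined", mr)
  mean(as.numeric(test)) / mr
}

#' Summarize paired condition groups across temperatures
#'
#' Reproduces the structure of a per-temperature bar panel: for every
#' temperature label, the reference and test groups (e.g. non-acclimated
#' vs cold-acclimated) are summarized as mean +/- SD and compared with
#' Welch's t-test, stars and fold change (test over reference). No
#' correction across temperature panels is applied; each panel is tested
#' on its own, and the resulting p-values are per-panel.
#'
#' @param data data.frame with columns `temperature` (or any panel label),
#'   `condition` and `value`.
#' @param reference,test the two condition labels to compare.
#' @param panel_col name of the panel/temperature column.
#' @return a data.frame with one row per panel label: group n/mean/sd, the
#'   Welch statistics, stars and fold change; comparison fields are `NA`
#'   when a panel lacks one of the two groups.
#' @export
summarize_conditions <- function(data, reference, test,
                                 panel_col = "temperature") {
  stopifnot(all(c(panel_col, "condition", "value") %in% names(data)))
  panels <- unique(data[[panel_col]])
  rows <- lapply(panels, function(tp) {
    sub <- data[data[[panel_col]] == tp, ]
    va <- sub$value[sub$condition == reference]
    vb <- sub$value[sub$condition == test]
    row <- data.frame(
      panel = tp,
      n_ref = length(va), mean_ref = mean(va), sd_ref = sd(va),
      n_test = length(vb), mean_test = mean(vb), sd_test = sd(vb),
      t_statistic = NA_real_, welch_df = NA_real_, p_value = NA_real_,
      stars = NA_character_, fold_change = NA_real_)
    if (length(va) >= 2L && length(vb) >= 2L) {
      w <- welch_t_test(va, vb)
      row$t_statistic <- w$t_statistic
      row$welch_df <- w$welch_df
      row$p_value <- w$p_value
      row$stars <- w$stars
      row$fold_change <- w$fold_change
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- panel_col
  out
}
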