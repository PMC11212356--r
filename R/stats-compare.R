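# Two-group comparison layer: paired t for within-subject vessel-type
# contrasts, normality-gated pooled t / Mann-Whitney for independent groups,
# and fold changes with Fieller confidence intervals.

stat_result <- function(variable, groups, test_used, statistic, df, p,
                        fold_change = NA_real_, fc_ci95 = c(NA_real_, NA_real_),
                        n = NA_integer_) {
  structure(list(variable = variable, groups = groups, test_used = test_used,
                 statistic = statistic, df = df, p_two_tailed = p,
                 fold_change = fold_change, fc_ci95 = fc_ci95, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$variable, ": ", paste(x$groups, collapse = " vs "),
      "\n  test = ", x$test_used, ", statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", round(x$df, 2)) else "",
      ", P (two-tailed) = ", format_p(x$p_two_tailed), "\n", sep = "")
  if (!is.na(x$fold_change))
    cat("  FC = ", format_fc(x$fold_change), " [",
        paste(format_fc(x$fc_ci95), collapse = ", "), "], n = ",
        paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Paired peri-arteriolar vs peri-venular comparison
#'
#' Paired two-tailed Student's t test on within-subject differences between
#' the two vessel-type counts.  If every within-subject difference is zero
#' the statistic is 0 and p = 1 by convention.
#'
#' @param periA_counts,periV_counts aligned per-subject count vectors.
#' @param variable label for the compared quantity.
#' @return a `stat_result` (statistic is t on the A - V differences).
#' @export
paired_vessel_comparison <- function(periA_counts, periV_counts,
                                     variable = "AP count") {
  ok <- !is.na(periA_counts) & !is.na(periV_counts)
  a <- periA_counts[ok]; v <- periV_counts[ok]
  n <- length(a)
  if (n < 3) stop("paired comparison requires n >= 3 complete pairs")
  d <- a - v
  if (stats::sd(d) == 0) {
    # degenerate spread: identical pairs give p = 1 by convention; an
    # exactly constant nonzero shift is the t -> Inf limit
    if (mean(d) == 0)
      return(stat_result(variable, c("peri-arteriolar", "peri-venular"),
                         "paired_t", 0, n - 1, 1, n = n))
    return(stat_result(variable, c("peri-arteriolar", "peri-venular"),
                       "paired_t", sign(mean(d)) * Inf, n - 1,
                       .Machine$double.xmin, n = n))
  }
  tt <- stats::t.test(a, v, paired = TRUE)
  stat_result(variable, c("peri-arteriolar", "peri-venular"), "paired_t",
              unname(tt$statistic), unname(tt$parameter), tt$p.value, n = n)
}

#' Fold change with Fieller 95% confidence interval
#'
#' FC = mean_cmp / mean_ref.  The CI is Fieller's interval for the ratio of
#' two independent means, using the t quantile at `n_ref + n_cmp - 2` df;
#' when the reference mean is indistinguishable from zero at that level
#' (g >= 1) the interval is unbounded and returned as NA with a flag.
#'
#' @param mean_ref,sd_ref,n_ref reference (denominator) group summary.
#' @param mean_cmp,sd_cmp,n_cmp comparison (numerator) group summary.
#' @param conf confidence level.
#' @return list `fc`, `ci` (length 2), `unbounded` flag.
#' @export
fold_change <- function(mean_ref, sd_ref, n_ref, mean_cmp, sd_cmp, n_cmp,
                        conf = 0.95) {
  if (mean_ref <= 0) {
    warning("reference mean <= 0: fold change undefined")
    return(list(fc = NA_real_, ci = c(NA_real_, NA_real_), unbounded = TRUE))
  }
  fc <- mean_cmp / mean_ref
  se_r2 <- sd_ref^2 / n_ref
  se_c2 <- sd_cmp^2 / n_cmp
  tq <- stats::qt(1 - (1 - conf) / 2, df = n_ref + n_cmp - 2)
  g <- tq^2 * se_r2 / mean_ref^2
  if (g >= 1)
    return(list(fc = fc, ci = c(NA_real_, NA_real_), unbounded = TRUE))
  disc <- sqrt(se_c2 + fc^2 * se_r2 - g * se_c2)
  lo <- (fc - tq / mean_ref * disc) / (1 - g)
  hi <- (fc + tq / mean_ref * disc) / (1 - g)
  list(fc = fc, ci = c(lo, hi), unbounded = FALSE)
}

#' Normality-gated two-group comparison
#'
#' If both samples pass the Gaussian gate the comparison is a
#' pooled-variance unpaired two-tailed Student's t test; otherwise a
#' two-tailed Mann-Whitney test.  A fold change (mean of `sample_y` over
#' mean of `sample_x`) with Fieller CI is attached either way.
#'
#' @param sample_x reference group (e.g. NC), n >= 3.
#' @param sample_y comparison group (e.g. IC), n >= 3.
#' @param variable label.
#' @param groups length-2 labels for x and y.
#' @param force_gate override the gate with `"gaussian"` or
#'   `"non_gaussian"` (used for closed-form cross-checks).
#' @param gate_alpha gate level.
#' @return a `stat_result`.
#' @export
group_comparison <- function(sample_x, sample_y, variable = "value",
                             groups = c("x", "y"), force_gate = NULL,
                             gate_alpha = 0.05) {
  x <- sample_x[!is.na(sample_x)]; y <- sample_y[!is.na(sample_y)]
  if (length(x) < 3 || length(y) < 3)
    stop("group_comparison requires n >= 3 in both groups")
  gate <- if (!is.null(force_gate))
    match.arg(force_gate, c("gaussian", "non_gaussian"))
  else if (gaussian_gate(x, gate_alpha) == "gaussian" &&
           gaussian_gate(y, gate_alpha) == "gaussian") "gaussian"
  else "non_gaussian"
  fcres <- if (mean(x) > 0)
    fold_change(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y))
  else list(fc = NA_real_, ci = c(NA_real_, NA_real_))
  if (gate == "gaussian") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      res <- stat_result(variable, groups, "unpaired_t", 0,
                         length(x) + length(y) - 2, 1,
                         fcres$fc, fcres$ci, c(length(x), length(y)))
      return(res)
    }
    tt <- stats::t.test(y, x, var.equal = TRUE)
    stat_result(variable, groups, "unpaired_t", unname(tt$statistic),
                unname(tt$parameter), tt$p.value, fcres$fc, fcres$ci,
                c(length(x), length(y)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(y, x, exact = NULL))
    stat_result(variable, groups, "mann_whitney", unname(wt$statistic),
                NA_real_, wt$p.value, fcres$fc, fcres$ci,
                c(length(x), length(y)))
  }
}

#' Two-group comparison from printed summary statistics
#'
#' Pooled-variance unpaired two-tailed Student's t computed directly from
#' (mean, SD, n) pairs, with fold change and Fieller CI — lets printed
#' table cells be recomputed without raw data.
#'
#' @param mean_x,sd_x,n_x reference group summary.
#' @param mean_y,sd_y,n_y comparison group summary.
#' @param variable label.
#' @param groups length-2 labels.
#' @return a `stat_result` with `test_used = "unpaired_t"`.
#' @export
group_comparison_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                                     variable = "value", groups = c("x", "y")) {
  df <- n_x + n_y - 2
  sp <- sqrt(((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df)
  t <- (mean_y - mean_x) / (sp * sqrt(1 / n_x + 1 / n_y))
  p <- 2 * stats::pt(-abs(t), df)
  fcres <- fold_change(mean_x, sd_x, n_x, mean_y, sd_y, n_y)
  stat_result(variable, groups, "unpaired_t", t, df, p,
              fcres$fc, fcres$ci, c(n_x, n_y))
}

# report-display rounding: FC to 1 decimal, r to 2, p to 2 significant figures
format_fc <- function(fc) ifelse(is.na(fc), NA, sprintf("%.1f", fc))
format_r <- function(r) ifelse(is.na(r), NA, sprintf("%.2f", r))
format_p <- function(p) ifelse(is.na(p), NA, signif(p, 2))
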