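# One-way ANOVA across ordinal severity strata (CDR levels here) with
# Tukey's HSD correcting the pairwise comparisons.

#' One-way ANOVA with Tukey HSD post-hoc pairs
#'
#' @param values numeric response vector.
#' @param groups grouping vector (e.g. CDR level), coerced to factor.
#' @return list with `F`, `df` (c(between, within)), `p` (omnibus), and
#'   `pairs`, a data.frame of pairwise mean differences with Tukey-adjusted
#'   p-values.  Levels with fewer than 2 observations are dropped with a
#'   warning; at least 3 usable levels are required.
#' @export
anova_tukey <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  sizes <- table(groups)
  thin <- names(sizes)[sizes < 2]
  if (length(thin)) {
    warning("dropping levels with n < 2: ", paste(thin, collapse = ", "))
    keep <- !groups %in% thin
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 3)
    stop("anova_tukey requires >= 3 usable levels (got ", nlevels(groups), ")")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1], pairs = pairs, n = as.vector(table(groups)),
       levels = levels(groups))
}
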