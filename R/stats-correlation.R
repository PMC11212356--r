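# Pearson correlation grid between vascular count categories and clinical /
# volumetric variables, with Holm-Bonferroni significance flags applied
# within configurable multiple-testing families.

#' Correlation table between count categories and clinical variables
#'
#' For every (count column, clinical column) pair: Pearson's r on
#' pairwise-complete observations, the unadjusted two-tailed p, and the n
#' remaining after pairwise deletion.  Holm-Bonferroni flags are set within
#' each family: by default one clinical variable's column across all
#' vascular categories (`family = "column"`); `family = "global"` treats
#' the whole grid as one family.
#'
#' @param count_matrix data.frame of per-subject counts (one column per
#'   vascular category), rows aligned with `clinical_matrix`.
#' @param clinical_matrix data.frame of clinical variables.
#' @param family `"column"` or `"global"`.
#' @param alpha significance level for the Holm flag.
#' @return data.frame with `category`, `clinical`, `r`, `p`, `n`,
#'   `holm_significant`, `note` (`"low_n"`/`"zero_variance"` when a cell is
#'   undefined).
#' @export
correlation_table <- function(count_matrix, clinical_matrix,
                              family = c("column", "global"), alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(nrow(count_matrix) == nrow(clinical_matrix))
  grid <- expand.grid(category = names(count_matrix),
                      clinical = names(clinical_matrix),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- count_matrix[[grid$category[i]]]
    y <- clinical_matrix[[grid$clinical[i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(r = NA_real_, p = NA_real_, n = n, note = "low_n"))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(r = NA_real_, p = NA_real_, n = n,
                        note = "zero_variance"))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = n, note = "")
  })
  out <- cbind(grid, do.call(rbind, res))
  out$holm_significant <- FALSE
  fams <- if (family == "column") split(seq_len(nrow(out)), out$clinical)
          else list(seq_len(nrow(out)))
  for (idx in fams) {
    usable <- idx[!is.na(out$p[idx])]
    if (length(usable))
      out$holm_significant[usable] <- holm_bonferroni(out$p[usable], alpha)
  }
  out
}

#' Holm-Bonferroni step-down rejections
#'
#' Orders the m p-values ascending and rejects while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure.
#'
#' @param p numeric vector of unadjusted p-values.
#' @param alpha family-wise error level.
#' @return logical rejection vector aligned with `p`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

#' Stratify a cohort metadata table into comparison groups
#'
#' Schemes: `"moca"` dichotomizes at the MOCA cut-off of 26 (score <= 26 is
#' the impaired side); `"cdr"` yields the three CDR severity levels
#' 0.5 / 1 / 2; `"diagnosis"` contrasts normal (NC) vs impaired (IC)
#' cognition.  Subjects with a missing stratification field are excluded and
#' their number reported as attribute `n_excluded`.
#'
#' @param meta data.frame with columns `MOCA`, `CDR`, `diagnosis` as needed.
#' @param scheme `"moca"`, `"cdr"` or `"diagnosis"`.
#' @return factor of group labels aligned with `meta` rows (NA = excluded),
#'   with attribute `n_excluded`.
#' @export
stratify_cohort <- function(meta, scheme = c("diagnosis", "moca", "cdr")) {
  scheme <- match.arg(scheme)
  g <- switch(scheme,
    moca = {
      if (is.null(meta$MOCA)) stop("metadata has no MOCA column")
      factor(ifelse(meta$MOCA > 26, "MOCA>26", "MOCA<=26"),
             levels = c("MOCA>26", "MOCA<=26"))
    },
    cdr = {
      if (is.null(meta$CDR)) stop("metadata has no CDR column")
      bad <- !is.na(meta$CDR) & !meta$CDR %in% c(0.5, 1, 2)
      if (any(bad)) stop("unexpected CDR levels: ",
                         paste(unique(meta$CDR[bad]), collapse = ", "))
      factor(meta$CDR, levels = c(0.5, 1, 2))
    },
    diagnosis = {
      if (is.null(meta$diagnosis)) stop("metadata has no diagnosis column")
      factor(meta$diagnosis, levels = c("NC", "IC"))
    }
  )
  attr(g, "n_excluded") <- sum(is.na(g))
  g
}
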