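# Printed summary statistics of the reference clinical cohort (per-cell
# mean, SD and n of stratified perivascular plaque counts, with the
# published fold changes and p-values).  They serve two purposes: default
# parameterization of the synthetic cohort generator, and recomputation of
# the report cells that are derivable from summary statistics alone.

#' Reference cohort count summaries by diagnostic group
#'
#' Per-cell mean, SD and group size of stratified perivascular plaque
#' counts for the normal-cognition (NC, n = 9) and impaired-cognition
#' (IC, n = 19) groups of the reference cohort, with the published
#' one-decimal fold change and two-tailed p (`#` marks cells the reference
#' analysis compared by Mann-Whitney rather than the t test).
#'
#' @return data.frame: `scope` (perivascular/periV/periA), `category`,
#'   `mean_NC`, `sd_NC`, `n_NC`, `mean_IC`, `sd_IC`, `n_IC`,
#'   `fc_printed`, `p_printed`, `mann_whitney`.
#' @export
reference_cohort_summary <- function() {
  tab <- rbind(
    # scope        category         mNC    sNC  nNC  mIC    sIC   nIC  fc    p        mw
    c("perivascular", "total",           83.89, 32.04, 9, 89.26, 27.81, 19, 1.1, 0.65,    0),
    c("perivascular", "primary_total",   43.56, 35.12, 9, 24.32, 16.85, 19, 0.6, 0.20,    1),
    c("perivascular", "primary_main",    12.33,  7.28, 9,  7.32,  6.60, 19, 0.6, 0.080,   0),
    c("perivascular", "primary_small",   31.22, 29.55, 9, 17.00, 11.64, 19, 0.5, 0.35,    1),
    c("perivascular", "secondary_total", 19.78, 10.47, 9, 35.79, 13.18, 19, 1.8, 0.0037,  0),
    c("perivascular", "secondary_main",  10.33,  5.89, 9, 14.26,  6.36, 19, 1.4, 0.13,    0),
    c("perivascular", "secondary_small",  9.44,  8.14, 9, 21.53, 10.15, 19, 2.3, 0.0044,  0),
    c("perivascular", "tertiary",        19.56, 12.63, 9, 27.89, 19.33, 19, 1.4, 0.24,    1),
    c("periV",        "total",           32.11,  9.40, 9, 37.21, 13.86, 19, 1.2, 0.33,    0),
    c("periV",        "primary_total",   18.67, 13.17, 9, 11.68,  9.15, 19, 0.6, 0.11,    0),
    c("periV",        "primary_main",     7.89,  4.76, 9,  4.63,  5.05, 19, 0.6, 0.12,    0),
    c("periV",        "primary_small",   10.78,  9.67, 9,  7.05,  5.65, 19, 0.7, 0.21,    0),
    c("periV",        "secondary_total",  6.25,  4.59, 8, 13.39,  4.53, 18, 2.1, 0.0011,  0),
    c("periV",        "secondary_main",   3.11,  1.90, 9,  5.44,  2.99, 18, 1.8, 0.044,   0),
    c("periV",        "secondary_small",  3.25,  4.03, 8,  7.94,  3.90, 18, 2.4, 0.0098,  0),
    c("periV",        "tertiary",         4.43,  2.76, 7, 11.93,  8.23, 15, 2.7, 0.020,   1),
    c("periA",        "total",           51.78, 24.70, 9, 52.05, 17.55, 19, 1.0, 0.97,    0),
    c("periA",        "primary_total",   24.89, 24.43, 9, 12.63, 11.96, 19, 0.5, 0.24,    1),
    c("periA",        "primary_main",     4.44,  4.13, 9,  2.68,  2.77, 19, 0.6, 0.19,    0),
    c("periA",        "primary_small",   23.00, 21.27, 8, 10.50, 10.14, 18, 0.5, 0.21,    1),
    c("periA",        "secondary_total", 12.00,  5.70, 9, 23.11, 12.13, 19, 1.9, 0.015,   0),
    c("periA",        "secondary_main",   7.22,  4.35, 9,  9.11,  4.43, 19, 1.3, 0.30,    0),
    c("periA",        "secondary_small",  4.78,  3.60, 9, 14.00, 10.01, 19, 2.9, 0.0048,  1),
    c("periA",        "tertiary",        14.44,  9.89, 9, 16.56, 10.94, 18, 1.2, 0.63,    0)
  )
  out <- data.frame(scope = tab[, 1], category = tab[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:10], 2, as.numeric)
  colnames(num) <- c("mean_NC", "sd_NC", "n_NC", "mean_IC", "sd_IC", "n_IC",
                     "fc_printed", "p_printed")
  cbind(out, as.data.frame(num), mann_whitney = tab[, 11] == "1")
}

#' Reference cohort count summaries by MOCA stratum
#'
#' Selected per-cell summaries for the MOCA > 26 vs MOCA <= 26
#' dichotomization of the reference cohort (the cells whose contrasts are
#' recomputable and reported).
#'
#' @return data.frame shaped like [reference_cohort_summary()] with groups
#'   `hi` (MOCA > 26) and `lo` (MOCA <= 26).
#' @export
reference_cohort_summary_moca <- function() {
  tab <- rbind(
    c("perivascular", "secondary_total", 22.43, 11.24, 14, 37.62, 12.09, 13, 1.7, 0.002),
    c("periV",        "secondary_total",  7.64,  4.34, 14, 15.69,  3.77, 13, 2.0, 1e-04),
    c("periV",        "secondary_small",  3.50,  3.13, 14, 10.46,  3.26, 13, 3.0, 1e-04)
  )
  out <- data.frame(scope = tab[, 1], category = tab[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:10], 2, as.numeric)
  colnames(num) <- c("mean_hi", "sd_hi", "n_hi", "mean_lo", "sd_lo", "n_lo",
                     "fc_printed", "p_printed_bound")
  cbind(out, as.data.frame(num))
}
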