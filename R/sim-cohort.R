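# Synthetic cohort generator: per-subject stratified count tables drawn
# from group-specific cell summaries (defaults = the reference cohort's
# printed means/SDs), with exact within-order additivity by construction,
# plus clinical/volumetric metadata carrying planted marginal correlations
# with chosen count columns.

# base cells drawn directly; every total is derived from these
BASE_CELLS <- as.vector(outer(c("periV", "periA"),
  c("primary_main", "primary_small", "secondary_main", "secondary_small",
    "tertiary"), paste, sep = "_"))

#' Parameters for the synthetic cohort generator
#'
#' Count cells are drawn per subject from group-specific (mean, SD) pairs
#' for the ten base cells (vessel type x {primary main/small, secondary
#' main/small, tertiary}); totals are derived so the count-record
#' invariants hold exactly: order totals = main + small, type totals = sum
#' over orders, perivascular cells = peri-venular + peri-arteriolar, and
#' total = perivascular + non-perivascular.  Default cell summaries are the
#' reference cohort's printed values ([reference_cohort_summary()]).
#'
#' @param n_NC,n_IC group sizes.
#' @param cell_stats data.frame `cell`, `mean_NC`, `sd_NC`, `mean_IC`,
#'   `sd_IC` for the ten base cells plus `non_perivascular`.
#' @param noise_model `"truncnorm"` (normal, left-censored at 0, rounded)
#'   or `"negbin"` (negative binomial / Poisson matched to mean and SD).
#' @param planted_correlations data.frame `clinical`, `count_column`,
#'   `rho`, `mean`, `sd`, `round`, `lo`, `hi` describing metadata variables
#'   tied to count columns through a Gaussian copula; remaining metadata
#'   variables are drawn independently.
#' @return named parameter list.
#' @export
cohort_params <- function(n_NC = 9, n_IC = 19,
                          cell_stats = default_cell_stats(),
                          noise_model = c("truncnorm", "negbin"),
                          planted_correlations = default_planted_correlations()) {
  noise_model <- match.arg(noise_model)
  need <- c(BASE_CELLS, "non_perivascular")
  if (!all(need %in% cell_stats$cell))
    stop("cell_stats must cover: ", paste(setdiff(need, cell_stats$cell),
                                          collapse = ", "))
  if (any(cell_stats$mean_NC < 0 | cell_stats$mean_IC < 0 |
          cell_stats$sd_NC < 0 | cell_stats$sd_IC < 0))
    stop("cell means and SDs must be non-negative")
  as.list(environment())
}

#' Default base-cell summaries
#'
#' The ten base cells take the reference cohort's printed group means/SDs;
#' the non-perivascular cell uses a synthetic 1.3-fold IC excess (the
#' reference analysis reports the fold change and p but not the cell's
#' mean/SD).
#' @return data.frame `cell`, `mean_NC`, `sd_NC`, `mean_IC`, `sd_IC`.
#' @export
default_cell_stats <- function() {
  ref <- reference_cohort_summary()
  base <- ref[ref$scope %in% c("periV", "periA") &
                ref$category %in% c("primary_main", "primary_small",
                                    "secondary_main", "secondary_small",
                                    "tertiary"), ]
  df <- data.frame(cell = paste(base$scope, base$category, sep = "_"),
                   mean_NC = base$mean_NC, sd_NC = base$sd_NC,
                   mean_IC = base$mean_IC, sd_IC = base$sd_IC)
  rbind(df, data.frame(cell = "non_perivascular", mean_NC = 60, sd_NC = 25,
                       mean_IC = 78, sd_IC = 28))
}

#' Default planted metadata correlations
#'
#' Marginal Pearson correlations planted between metadata variables and
#' count columns, with signs matching the reference correlation tables
#' (e.g. hippocampal volume negatively tied to peri-venular tertiary
#' counts, white-matter-hyperintensity count positively tied to
#' peri-arteriolar secondary counts).
#' @return data.frame used by [generate_cohort()].
#' @export
default_planted_correlations <- function() {
  data.frame(
    clinical = c("MOCA", "HV", "WMHI_count", "RCFT_Copy", "ACS_TOPF",
                 "CVLT_II_LongDelay", "Trails_A"),
    count_column = c("periV_secondary_small", "periV_tertiary",
                     "periA_secondary_total", "periV_total",
                     "periV_secondary_small", "periV_secondary_total",
                     "periV_total"),
    rho = c(-0.5, -0.5, 0.5, -0.45, -0.49, -0.51, -0.42),
    mean = c(25, 3.2, 12, 0, 0, 0, 0),
    sd = c(5.6, 0.45, 6, 1, 1, 1, 1),
    round = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    lo = c(0, 0, 0, -Inf, -Inf, -Inf, -Inf),
    hi = c(32, Inf, Inf, Inf, Inf, Inf, Inf)
  )
}

draw_cell <- function(n, mean, sd, model) {
  if (model == "truncnorm") {
    round(pmax(0, stats::rnorm(n, mean, sd)))
  } else {
    if (mean <= 0) return(rep(0L, n))
    v <- sd^2
    if (v > mean) stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
    else stats::rpois(n, mean)
  }
}

#' Generate a synthetic cohort (counts + metadata)
#'
#' @param params see [cohort_params()].
#' @param seed integer RNG seed.
#' @return list `counts` (one row per subject, full count-record taxonomy),
#'   `meta` (subject metadata), `params`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  set.seed(seed)
  n <- params$n_NC + params$n_IC
  group <- c(rep("NC", params$n_NC), rep("IC", params$n_IC))
  counts <- data.frame(subject_id = sprintf("S%03d", seq_len(n)))
  cs <- params$cell_stats
  for (cell in c(BASE_CELLS, "non_perivascular")) {
    row <- cs[cs$cell == cell, ]
    v <- numeric(n)
    v[group == "NC"] <- draw_cell(params$n_NC, row$mean_NC, row$sd_NC,
                                  params$noise_model)
    v[group == "IC"] <- draw_cell(params$n_IC, row$mean_IC, row$sd_IC,
                                  params$noise_model)
    counts[[cell]] <- as.integer(v)
  }
  # derived totals: exact additivity by construction
  for (ty in c("periV", "periA")) {
    for (ord in c("primary", "secondary")) {
      counts[[paste(ty, ord, "total", sep = "_")]] <-
        counts[[paste(ty, ord, "main", sep = "_")]] +
        counts[[paste(ty, ord, "small", sep = "_")]]
    }
    counts[[paste0(ty, "_total")]] <- counts[[paste0(ty, "_primary_total")]] +
      counts[[paste0(ty, "_secondary_total")]] + counts[[paste0(ty, "_tertiary")]]
  }
  for (cat in c("total", BRANCH_CATEGORIES)) {
    counts[[paste0("perivascular_", cat)]] <-
      counts[[paste0("periV_", cat)]] + counts[[paste0("periA_", cat)]]
  }
  counts$total_AP <- counts$perivascular_total + counts$non_perivascular
  counts <- counts[, c("subject_id", count_columns())]

  meta <- data.frame(
    subject_id = counts$subject_id,
    diagnosis = group,
    age = round(stats::rnorm(n, 65, 7.4), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education_years = round(pmax(8, stats::rnorm(n, 17, 1.8))),
    CDR = local({
      # NC subjects sit at CDR 0.5 (questionable impairment); IC subjects
      # split ~14:3 between mild (1) and moderate (2), never fewer than two
      # at the top level so severity contrasts stay estimable
      n2 <- max(2L, round(params$n_IC * 3 / 17))
      ic_cdr <- sample(c(rep(1, params$n_IC - n2), rep(2, n2)))
      cdr <- rep(0.5, n); cdr[group == "IC"] <- ic_cdr; cdr
    }),
    ICV = round(stats::rnorm(n, 1450, 120), 1),
    ILVV = round(pmax(0.2, stats::rnorm(n, 1.5, 0.8)), 2),
    WMHI_volume = round(pmax(0, stats::rnorm(n, 2.5, 1.5)), 2)
  )
  pc <- params$planted_correlations
  for (i in seq_len(nrow(pc))) {
    z <- as.numeric(scale(counts[[pc$count_column[i]]]))
    if (all(!is.finite(z))) z <- stats::rnorm(n)
    val <- pc$mean[i] + pc$sd[i] *
      (pc$rho[i] * z + sqrt(1 - pc$rho[i]^2) * stats::rnorm(n))
    val <- pmin(pmax(val, pc$lo[i]), pc$hi[i])
    if (pc$round[i]) val <- round(val)
    meta[[pc$clinical[i]]] <- val
  }
  list(counts = counts, meta = meta, params = params, seed = seed)
}

#' Write / read cohort CSVs
#'
#' @param cohort output of [generate_cohort()] (or a list with `counts`
#'   and `meta` data.frames).
#' @param counts_path,meta_path output CSV paths.
#' @export
write_cohort_csv <- function(cohort, counts_path, meta_path) {
  utils::write.csv(cohort$counts, counts_path, row.names = FALSE)
  utils::write.csv(cohort$meta, meta_path, row.names = FALSE)
  invisible(c(counts_path, meta_path))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(counts_path, meta_path) {
  list(counts = utils::read.csv(counts_path),
       meta = utils::read.csv(meta_path))
}
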