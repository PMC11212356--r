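# Pipeline orchestration: quantification (image + annotation -> stratified
# counts and zone areas) and the statistics layer (counts + metadata ->
# group-contrast and correlation report tables), with deterministic outputs
# and provenance sidecars.

#' Default pipeline configuration
#'
#' @param interval_px diameter-sampling interval along centerlines (px).
#' @param small_ratio_threshold small-branch diameter ratio threshold.
#' @param cap_style perivascular band end caps, `"flat"` or `"round"`.
#' @param detection see [detection_params()].
#' @param quadrant optional analysis-region polygon (matrix of x, y).
#' @param gate_alpha normality-gate level.
#' @param holm_family `"column"` or `"global"` multiple-testing family for
#'   correlation tables.
#' @param seed seed recorded in provenance (the quantification itself is
#'   deterministic).
#' @return named configuration list.
#' @export
pipeline_config <- function(interval_px = 20, small_ratio_threshold = 0.6,
                            cap_style = "flat",
                            detection = detection_params(),
                            quadrant = NULL, gate_alpha = 0.05,
                            holm_family = "column", seed = 1L) {
  as.list(environment())
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipeline_config()] arguments; unspecified keys keep their
#' defaults.  Values passed in `overrides` (e.g. parsed command-line flags)
#' take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_config()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading config files requires the 'yaml' package")
    fromfile <- yaml::read_yaml(path)
    if (!is.null(fromfile$detection))
      fromfile$detection <- utils::modifyList(cfg$detection, fromfile$detection)
    cfg <- utils::modifyList(cfg, fromfile)
  }
  utils::modifyList(cfg, overrides)
}

#' Quantify perivascular plaque counts for one subject
#'
#' Runs the full quantification chain: diameter measurement at pre-set
#' intervals, branch-order classification, perivascular band construction
#' (3 x diameter stroke), plaque detection (or an externally supplied
#' plaque list), border-touch zone assignment, and stratified counting.
#' Deterministic for fixed inputs and configuration.
#'
#' @param image numeric matrix (rows = y), or path to a grayscale
#'   PNG/TIFF readable by EBImage.
#' @param annotation a `vessel_network` or path to an annotation JSON.
#' @param subject_id subject identifier for the count record.
#' @param config see [pipeline_config()].
#' @param plaques optional pre-detected `plaque_set` bypassing detection.
#' @param out_dir optional directory; when given, writes `counts.csv`,
#'   `areas.csv`, `plaques.csv` and a `provenance.json` sidecar.
#' @return list: `counts` (one-row count record), `areas` (zone area
#'   table), `plaques`, `memberships`, `network`, `zone_set`.
#' @export
run_quantify <- function(image, annotation, subject_id = "subject",
                         config = pipeline_config(), plaques = NULL,
                         out_dir = NULL) {
  if (is.character(image)) {
    img <- EBImage::imageData(EBImage::readImage(image))
    if (length(dim(img)) > 2) img <- img[, , 1]
    image <- t(img)                       # EBImage stores x as first index
  }
  network <- if (inherits(annotation, "vessel_network")) annotation
             else read_vessel_annotation(annotation)
  dims <- dim(image)
  ext <- do.call(rbind, lapply(network$segments, function(s)
    apply(s$points, 2, max)))
  if (max(ext[, 1]) > dims[2] || max(ext[, 2]) > dims[1])
    stop("frame mismatch: image is ", dims[1], "x", dims[2],
         " (height x width) but annotation extends to x = ",
         round(max(ext[, 1]), 1), ", y = ", round(max(ext[, 2]), 1))
  network <- measure_network_diameters(network, config$interval_px)
  network <- classify_branch_orders(network, config$small_ratio_threshold)
  zone_set <- build_zone_set(network, dims, cap_style = config$cap_style)
  if (is.null(plaques))
    plaques <- detect_plaques(image, config$detection, quadrant = config$quadrant)
  else if (!is.null(config$quadrant))
    plaques <- filter_plaques_quadrant(plaques, config$quadrant)
  memberships <- assign_plaques(plaques, zone_set)
  counts <- tabulate_counts(subject_id, plaques, memberships)
  areas <- zone_area_table(zone_set)
  res <- list(counts = counts, areas = areas, plaques = plaques,
              memberships = memberships, network = network,
              zone_set = zone_set)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
    utils::write.csv(areas, file.path(out_dir, "areas.csv"), row.names = FALSE)
    write_plaque_csv(plaques, subject_id, file.path(out_dir, "plaques.csv"))
    write_provenance(file.path(out_dir, "provenance.json"), config,
                     stage = "quantify",
                     io = list(n_segments = length(network$segments),
                               n_plaques = nrow(plaques)))
  }
  res
}

#' Run the cohort statistics layer
#'
#' Joins counts with metadata by `subject_id`, stratifies the cohort, and
#' emits (a) a group-contrast table per count column — normality-gated
#' pooled t or Mann-Whitney with fold change and Fieller CI for two-group
#' schemes, one-way ANOVA with Tukey pairs for the CDR scheme — and (b) a
#' Pearson correlation table against the clinical variables with
#' Holm-Bonferroni flags.  Output is invariant to subject row order.
#'
#' @param counts per-subject count table (or CSV path).
#' @param meta metadata table (or CSV path).
#' @param stratify `"diagnosis"`, `"moca"` or `"cdr"`.
#' @param clinical_vars metadata columns correlated against counts.
#' @param config see [pipeline_config()].
#' @param out_dir optional output directory for the CSV report tables.
#' @return list `group_table`, `anova` (CDR scheme only),
#'   `correlation_table`, `stratification` sizes.
#' @export
run_stats <- function(counts, meta, stratify = "diagnosis",
                      clinical_vars = c("MOCA", "CDR", "HV", "WMHI_count"),
                      config = pipeline_config(), out_dir = NULL) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  if (is.character(meta)) meta <- utils::read.csv(meta)
  dat <- merge(counts, meta, by = "subject_id")
  dat <- dat[order(dat$subject_id), ]
  groups <- stratify_cohort(dat, stratify)
  ccols <- intersect(count_columns(), names(dat))
  lv <- levels(groups)

  group_table <- NULL; anova_res <- NULL
  if (stratify == "cdr") {
    anova_res <- lapply(ccols, function(col)
      anova_tukey(dat[[col]], groups))
    names(anova_res) <- ccols
    group_table <- data.frame(
      variable = ccols,
      F = vapply(anova_res, `[[`, numeric(1), "F"),
      p = vapply(anova_res, `[[`, numeric(1), "p"), row.names = NULL)
  } else {
    if (any(table(groups) < 3))
      stop("stratification '", stratify, "' leaves a group with n < 3 (",
           paste(lv, table(groups)[lv], sep = "=", collapse = ", "), ")")
    rows <- lapply(ccols, function(col) {
      x <- dat[[col]][groups == lv[1]]
      y <- dat[[col]][groups == lv[2]]
      r <- group_comparison(x, y, variable = col, groups = lv,
                            gate_alpha = config$gate_alpha)
      data.frame(variable = col,
                 mean_1 = mean(x, na.rm = TRUE), sd_1 = stats::sd(x[!is.na(x)]),
                 n_1 = sum(!is.na(x)),
                 mean_2 = mean(y, na.rm = TRUE), sd_2 = stats::sd(y[!is.na(y)]),
                 n_2 = sum(!is.na(y)),
                 fc = r$fold_change, fc_lo = r$fc_ci95[1], fc_hi = r$fc_ci95[2],
                 p = r$p_two_tailed, test = r$test_used,
                 fc_display = format_fc(r$fold_change),
                 p_display = format_p(r$p_two_tailed))
    })
    group_table <- do.call(rbind, rows)
    attr(group_table, "groups") <- lv
  }

  clin <- dat[, intersect(clinical_vars, names(dat)), drop = FALSE]
  cor_table <- correlation_table(dat[, ccols, drop = FALSE], clin,
                                 family = config$holm_family)
  cor_table$r_display <- format_r(cor_table$r)
  cor_table$p_display <- format_p(cor_table$p)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(group_table,
                     file.path(out_dir, paste0("groups_", stratify, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cor_table,
                     file.path(out_dir, paste0("correlations_", stratify, ".csv")),
                     row.names = FALSE)
    write_provenance(file.path(out_dir, "provenance.json"), config,
                     stage = "stats",
                     io = list(n_subjects = nrow(dat),
                               stratify = stratify,
                               group_sizes = as.list(table(groups))))
  }
  list(group_table = group_table, anova = anova_res,
       correlation_table = cor_table,
       stratification = table(groups))
}

write_provenance <- function(path, config, stage, io = list()) {
  cfg <- config
  cfg$quadrant <- if (is.null(cfg$quadrant)) NULL else unclass(cfg$quadrant)
  jsonlite::write_json(list(
    stage = stage,
    package = "periplaque",
    version = as.character(utils::packageVersion("periplaque")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = cfg,
    io = io
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
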