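# Plaque spot detection and stratified perivascular counting.
#
# Detection is a transparent, fully parameterized operator: white top-hat
# background removal, robust global threshold, connected components filtered
# by area.  Externally detected plaque lists (CSV of centroids/footprints)
# can be supplied instead to bypass detection entirely.

#' Default plaque-detection parameters
#'
#' @param background_radius radius (px) of the disc structuring element for
#'   the white top-hat background removal; should exceed the plaque radius.
#' @param threshold_k threshold = median + `threshold_k` x MAD of the
#'   top-hat image.
#' @param min_area,max_area connected-component footprint area bounds (px^2).
#' @return named list of parameters.
#' @export
detection_params <- function(background_radius = 9, threshold_k = 6,
                             min_area = 4, max_area = 400) {
  list(background_radius = background_radius, threshold_k = threshold_k,
       min_area = min_area, max_area = max_area)
}

#' Detect hyperfluorescent plaque spots
#'
#' @param image numeric matrix (rows = y, cols = x), single channel.
#' @param params see [detection_params()].
#' @param quadrant optional polygon (matrix of x, y vertices) delimiting the
#'   analysis region; plaques whose centroid falls outside it are dropped.
#' @return data.frame of class `plaque_set`: `plaque_id`, `x`, `y`
#'   (continuous centroid, 0-based frame), `area_px2`, `peak_intensity`,
#'   with the pixel footprints attached as attribute `footprints` (list of
#'   1-based linear index vectors into the image matrix).
#' @export
detect_plaques <- function(image, params = detection_params(), quadrant = NULL) {
  stopifnot(is.matrix(image))
  empty <- plaque_table(numeric(0), numeric(0), numeric(0), numeric(0), list())
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("image is flat (empty or saturated); returning no plaques")
    return(empty)
  }
  brush <- EBImage::makeBrush(2L * params$background_radius + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(image, brush)
  scale <- stats::mad(th)
  if (scale == 0) scale <- stats::sd(th)
  cut <- stats::median(th) + params$threshold_k * scale
  bw <- th > cut
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw)
  npix <- tabulate(lab[lab > 0])
  keep <- which(npix >= params$min_area & npix <= params$max_area)
  if (!length(keep)) return(empty)
  H <- nrow(image)
  pix <- which(lab > 0)
  pix <- pix[lab[pix] %in% keep]
  groups <- split(pix, lab[pix])
  xs <- ys <- areas <- peaks <- numeric(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    jy <- (idx - 1L) %% H          # 0-based row (y)
    ix <- (idx - 1L) %/% H         # 0-based col (x)
    xs[g] <- mean(ix + 0.5); ys[g] <- mean(jy + 0.5)
    areas[g] <- length(idx)
    peaks[g] <- max(image[idx])
  }
  res <- plaque_table(xs, ys, areas, peaks, unname(groups))
  if (!is.null(quadrant)) res <- filter_plaques_quadrant(res, quadrant)
  res
}

plaque_table <- function(xs, ys, areas, peaks, footprints) {
  df <- data.frame(plaque_id = seq_along(xs), x = xs, y = ys,
                   area_px2 = areas, peak_intensity = peaks)
  attr(df, "footprints") <- footprints
  class(df) <- c("plaque_set", "data.frame")
  df
}

#' Restrict plaques to an analysis quadrant
#'
#' Keeps plaques whose centroid lies inside the polygon (even-odd rule);
#' everything outside the analyzed quadrant is ignored entirely.
#'
#' @param plaques a `plaque_set`.
#' @param polygon matrix of polygon vertices (x, y), implicitly closed.
#' @return filtered `plaque_set` (plaque ids renumbered).
#' @export
filter_plaques_quadrant <- function(plaques, polygon) {
  inside <- point_in_polygon(plaques$x, plaques$y, polygon)
  fp <- attr(plaques, "footprints")[inside]
  sub <- plaques[inside, , drop = FALSE]
  plaque_table(sub$x, sub$y, sub$area_px2, sub$peak_intensity, fp)
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(px, py, polygon) {
  n <- nrow(polygon)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Assign plaques to perivascular zones
#'
#' A plaque belongs to a zone iff its footprint shares at least one pixel
#' with the zone region — a spot touching the band border is perivascular
#' even if its body lies mostly outside.  A plaque may belong to several
#' zones.  Plaques supplied without footprints (external centroid lists) use
#' the single pixel containing the centroid.
#'
#' @param plaques a `plaque_set`.
#' @param zone_set a `zone_set`.
#' @return data.frame `plaque_id`, `segment_id`, `vessel_type`,
#'   `branch_class`, one row per (plaque, zone) membership.
#' @export
assign_plaques <- function(plaques, zone_set) {
  H <- zone_set$image_dim[1]
  fps <- attr(plaques, "footprints")
  if (is.null(fps) || !length(fps))
    fps <- lapply(seq_len(nrow(plaques)), function(i)
      floor(plaques$x[i]) * H + floor(plaques$y[i]) + 1L)
  zidx <- lapply(zone_set$zones, zone_linear_indices, image_dim = zone_set$image_dim)
  rows <- list()
  for (zi in seq_along(zidx)) {
    z <- zone_set$zones[[zi]]
    hit <- which(vapply(fps, function(f) any(f %in% zidx[[zi]]), logical(1)))
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        plaque_id = plaques$plaque_id[hit], segment_id = z$segment_id,
        vessel_type = z$vessel_type, branch_class = z$branch_class)
  }
  if (!length(rows))
    return(data.frame(plaque_id = integer(0), segment_id = character(0),
                      vessel_type = character(0), branch_class = character(0)))
  do.call(rbind, rows)
}

# scope x category count-table column names (Table-2-style taxonomy)
count_columns <- function() {
  scopes <- c("perivascular", "periV", "periA")
  cats <- c("total", BRANCH_CATEGORIES)
  c(as.vector(t(outer(scopes, cats, paste, sep = "_"))),
    "total_AP", "non_perivascular")
}

#' Tabulate stratified perivascular plaque counts for one subject
#'
#' Counts distinct plaques per scope (perivascular = either vessel type,
#' peri-venular, peri-arteriolar) and branch category.  Within each branch
#' order, a plaque touching both a main and a small zone is attributed to
#' the main category, so `main + small = total` holds exactly per order; a
#' plaque touching both an arteriolar and a venular zone increments both
#' type scopes but the perivascular scope once.
#'
#' @param subject_id subject identifier.
#' @param plaques a `plaque_set`.
#' @param memberships output of [assign_plaques()].
#' @return one-row data.frame with columns `subject_id`, every
#'   scope x category count, `total_AP` and `non_perivascular`.
#' @export
tabulate_counts <- function(subject_id, plaques, memberships) {
  out <- as.list(stats::setNames(rep(0L, length(count_columns())), count_columns()))
  out$total_AP <- nrow(plaques)
  scope_rows <- list(
    perivascular = memberships,
    periV = memberships[memberships$vessel_type == "vein", , drop = FALSE],
    periA = memberships[memberships$vessel_type == "artery", , drop = FALSE]
  )
  for (scope in names(scope_rows)) {
    m <- scope_rows[[scope]]
    out[[paste0(scope, "_total")]] <- length(unique(m$plaque_id))
    for (ord in c("primary", "secondary")) {
      in_ord <- m[m$branch_class %in% paste0(ord, c("_main", "_small")), , drop = FALSE]
      tot <- unique(in_ord$plaque_id)
      main <- unique(in_ord$plaque_id[in_ord$branch_class == paste0(ord, "_main")])
      out[[paste0(scope, "_", ord, "_total")]] <- length(tot)
      out[[paste0(scope, "_", ord, "_main")]] <- length(main)
      out[[paste0(scope, "_", ord, "_small")]] <- length(setdiff(tot, main))
    }
    out[[paste0(scope, "_tertiary")]] <-
      length(unique(m$plaque_id[m$branch_class == "tertiary"]))
  }
  out$non_perivascular <- out$total_AP - out$perivascular_total
  cbind(data.frame(subject_id = subject_id), as.data.frame(out))
}

#' Write / read plaque list CSV
#'
#' Columns: `subject_id`, `plaque_id`, `x`, `y`, `area_px2`,
#' `peak_intensity`.  Footprints are not serialized; assignment from a CSV
#' list uses the centroid pixel.
#'
#' @param plaques a `plaque_set`.
#' @param subject_id subject identifier.
#' @param path output CSV.
#' @export
write_plaque_csv <- function(plaques, subject_id, path) {
  df <- cbind(data.frame(subject_id = subject_id), as.data.frame(plaques))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plaque_csv
#' @export
read_plaque_csv <- function(path) {
  df <- utils::read.csv(path)
  plaque_table(df$x, df$y, df$area_px2, df$peak_intensity, list())
}
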