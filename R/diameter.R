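# Vessel diameter measurement: widths sampled at pre-set intervals along the
# centerline, always including the most proximal and most distal positions,
# with the mean diameter taken as the arithmetic mean of the samples.

#' Arc positions for diameter sampling
#'
#' Returns `{0, interval, 2*interval, ..., L}` with the total length `L`
#' always appended, so both endpoints are sampled for any interval choice.
#' A centerline shorter than one interval is sampled only at its two ends.
#' @keywords internal
diameter_sample_positions <- function(length_px, interval_px) {
  stopifnot(interval_px > 0, length_px > 0)
  pos <- seq(0, length_px, by = interval_px)
  if (pos[length(pos)] < length_px) pos <- c(pos, length_px)
  pos
}

#' Measure a segment's diameter profile
#'
#' Samples the vessel width at pre-set intervals along the centerline
#' (endpoints always included) and averages the samples into the segment's
#' mean diameter.  Width at each sample comes either from the segment's
#' annotated width profile (linearly interpolated along arc length) or, when
#' a binary vessel mask is supplied, from the perpendicular chord through the
#' mask at the sample point.
#'
#' @param segment a [vessel_segment()].
#' @param interval_px sampling interval along the centerline (px).
#' @param mask optional logical/0-1 matrix (rows = y, cols = x, 0-based pixel
#'   indexing) marking vessel pixels; used when the segment carries no width
#'   profile.
#' @return the segment with `diameter_samples` (data.frame `pos`, `width`)
#'   and `mean_diameter` filled in.
#' @export
measure_diameter <- function(segment, interval_px = 20, mask = NULL) {
  stopifnot(inherits(segment, "vessel_segment"))
  if (interval_px <= 0) stop("interval_px must be positive")
  L <- polyline_arclength(segment$points)
  pos <- diameter_sample_positions(L, interval_px)
  if (!is.null(segment$widths)) {
    cl <- polyline_cumlen(segment$points)
    w <- stats::approx(cl, segment$widths, xout = pos, rule = 2)$y
  } else if (!is.null(mask)) {
    w <- vapply(pos, function(s) chord_width(segment$points, s, mask), numeric(1))
  } else {
    stop("segment '", segment$id,
         "' has no width profile and no mask was supplied")
  }
  if (any(w <= 0))
    stop("segment '", segment$id, "': zero measured width at arc position ",
         paste(round(pos[w <= 0], 1), collapse = ", "),
         " - broken vessel mask?")
  segment$diameter_samples <- data.frame(pos = pos, width = w)
  segment$mean_diameter <- mean(w)
  segment
}

# Perpendicular chord width through a binary mask at arc position s.
# Marches outward from the centerline point in both normal directions at
# quarter-pixel steps until the mask is left.
chord_width <- function(points, s, mask) {
  p <- polyline_point_at(points, s)
  tg <- polyline_tangent_at(points, s)
  nx <- -tg[2]; ny <- tg[1]
  step <- 0.25
  inside <- function(x, y) {
    i <- floor(x); j <- floor(y)             # 0-based pixel indices
    if (j < 0 || i < 0 || j >= nrow(mask) || i >= ncol(mask)) return(FALSE)
    mask[j + 1L, i + 1L] > 0
  }
  if (!inside(p[1], p[2])) return(0)
  reach <- function(sign) {
    d <- 0
    while (inside(p[1] + sign * (d + step) * nx, p[2] + sign * (d + step) * ny))
      d <- d + step
    d
  }
  # total chord = extent on both sides plus the center pixel's own step
  reach(1) + reach(-1) + step
}

#' Measure diameters for every segment in a network
#'
#' @param network a `vessel_network`.
#' @param interval_px sampling interval (px).
#' @param mask optional binary vessel mask shared by all segments.
#' @return the network with diameters set on every segment.
#' @export
measure_network_diameters <- function(network, interval_px = 20, mask = NULL) {
  network$segments <- lapply(network$segments, measure_diameter,
                             interval_px = interval_px, mask = mask)
  network
}
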