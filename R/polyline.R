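# Polyline geometry helpers shared by the vessel model and zone construction.
#
# Coordinate convention: continuous pixel coordinates, origin at the image
# top-left, x rightward, y downward.  Raster pixel (i, j) (0-based column i,
# row j) covers [i, i+1) x [j, j+1) and is sampled at its center
# (i + 0.5, j + 0.5), so integer-coordinate annotations rasterize without a
# half-pixel bias.

#' Arc length of a polyline
#'
#' @param points numeric matrix with two columns (x, y), one row per vertex.
#' @return total arc length (pixels).
#' @keywords internal
polyline_arclength <- function(points) {
  sum(polyline_seglengths(points))
}

# per-edge lengths
polyline_seglengths <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(numeric(0))
  sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
}

# cumulative arc positions of vertices, starting at 0
polyline_cumlen <- function(points) {
  c(0, cumsum(polyline_seglengths(points)))
}

#' Point on a polyline at a given arc position
#'
#' Positions are clamped to [0, L].
#' @keywords internal
polyline_point_at <- function(points, s) {
  cl <- polyline_cumlen(points)
  L <- cl[length(cl)]
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, cl, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(points) - 1L)
  seg_len <- cl[idx + 1L] - cl[idx]
  frac <- ifelse(seg_len > 0, (s - cl[idx]) / seg_len, 0)
  cbind(
    points[idx, 1] + frac * (points[idx + 1L, 1] - points[idx, 1]),
    points[idx, 2] + frac * (points[idx + 1L, 2] - points[idx, 2])
  )
}

#' Unit tangent of a polyline at a given arc position
#' @keywords internal
polyline_tangent_at <- function(points, s) {
  cl <- polyline_cumlen(points)
  idx <- findInterval(pmin(pmax(s, 0), cl[length(cl)]), cl, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(points) - 1L)
  dx <- points[idx + 1L, 1] - points[idx, 1]
  dy <- points[idx + 1L, 2] - points[idx, 2]
  len <- sqrt(dx^2 + dy^2)
  cbind(dx / len, dy / len)
}

#' Minimum distance from points to a polyline
#'
#' Vectorized over query points; exact point-to-segment distance, so the
#' implied band has flat caps at the polyline ends.
#'
#' @param px,py query coordinates.
#' @param points polyline vertex matrix.
#' @return numeric vector of distances.
#' @keywords internal
polyline_min_dist <- function(px, py, points) {
  n <- nrow(points)
  best <- rep(Inf, length(px))
  for (k in seq_len(n - 1L)) {
    ax <- points[k, 1]; ay <- points[k, 2]
    bx <- points[k + 1L, 1]; by <- points[k + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    vv <- vx^2 + vy^2
    if (vv == 0) next
    t <- ((px - ax) * vx + (py - ay) * vy) / vv
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
    best <- pmin(best, d)
  }
  best
}

# Distance with *flat* caps: points whose projection falls beyond the segment
# ends on every edge are reported as Inf (outside), so no disk extends past
# the endpoints.  Lateral distance is still required to be within reach.
polyline_flatcap_dist <- function(px, py, points) {
  n <- nrow(points)
  best <- rep(Inf, length(px))
  for (k in seq_len(n - 1L)) {
    ax <- points[k, 1]; ay <- points[k, 2]
    bx <- points[k + 1L, 1]; by <- points[k + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    vv <- vx^2 + vy^2
    if (vv == 0) next
    t <- ((px - ax) * vx + (py - ay) * vy) / vv
    inside <- t >= 0 & t <= 1
    d <- abs((px - ax) * vy - (py - ay) * vx) / sqrt(vv)
    d[!inside] <- Inf
    # interior vertices still act as joints: use true segment distance there
    best <- pmin(best, d)
  }
  if (n > 2L) {
    # joints between consecutive edges would otherwise leave wedge-shaped
    # gaps on the outer side of a bend; fill them with vertex disks for the
    # interior vertices only.  Disk contributions are clipped by the two
    # end-cap planes so nothing extends beyond the endpoints (assumes a
    # forward-progressing centerline, as traced vessels are).
    t1 <- points[2, ] - points[1, ]
    tn <- points[n, ] - points[n - 1L, ]
    ahead <- (px - points[1, 1]) * t1[1] + (py - points[1, 2]) * t1[2] >= 0
    before <- (px - points[n, 1]) * tn[1] + (py - points[n, 2]) * tn[2] <= 0
    inside_caps <- ahead & before
    for (k in 2:(n - 1L)) {
      d <- sqrt((px - points[k, 1])^2 + (py - points[k, 2])^2)
      d[!inside_caps] <- Inf
      best <- pmin(best, d)
    }
  }
  best
}
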