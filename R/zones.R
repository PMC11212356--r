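# Perivascular zone construction.  The zone around a traced vessel is the
# band of one vessel diameter on either side of the centerline: a stroke
# three diameters wide centered on the vessel (half-width 1.5 x mean
# diameter), including the lumen strip itself.

#' Build the perivascular band around one segment
#'
#' The zone is the set of raster pixels whose center lies within
#' `1.5 * mean_diameter` of the centerline polyline.  End caps are flat by
#' default (no disk extends beyond the endpoints); round caps are available.
#' The band is clipped to the image frame.
#'
#' @param segment a `vessel_segment` with `mean_diameter` set.
#' @param image_dim integer c(height, width) of the image frame (px).
#' @param cap_style `"flat"` (default) or `"round"`.
#' @return object of class `perivascular_zone`: fields `segment_id`,
#'   `vessel_type`, `branch_class`, `half_width`, `bbox` (0-based `x0`,
#'   `y0`), `mask` (logical matrix, rows = y), `area_px2`.
#' @export
build_perivascular_band <- function(segment, image_dim,
                                    cap_style = c("flat", "round")) {
  cap_style <- match.arg(cap_style)
  d <- segment$mean_diameter
  if (is.na(d) || d <= 0)
    stop("segment '", segment$id, "' has no positive mean_diameter")
  half <- 1.5 * d
  H <- image_dim[1]; W <- image_dim[2]
  pts <- segment$points
  x0 <- max(0L, floor(min(pts[, 1]) - half - 1))
  x1 <- min(W - 1L, ceiling(max(pts[, 1]) + half + 1))
  y0 <- max(0L, floor(min(pts[, 2]) - half - 1))
  y1 <- min(H - 1L, ceiling(max(pts[, 2]) + half + 1))
  if (x1 < x0 || y1 < y0)
    stop("segment '", segment$id, "' lies entirely outside the image frame")
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  cx <- rep(xs + 0.5, each = length(ys))   # pixel centers, column-major
  cy <- rep(ys + 0.5, times = length(xs))
  dist <- if (cap_style == "flat") polyline_flatcap_dist(cx, cy, pts)
          else polyline_min_dist(cx, cy, pts)
  mask <- matrix(dist <= half, nrow = length(ys), ncol = length(xs))
  structure(
    list(segment_id = segment$id, vessel_type = segment$vessel_type,
         branch_class = segment$branch_class, half_width = half,
         bbox = c(x0 = as.integer(x0), y0 = as.integer(y0)),
         mask = mask, area_px2 = sum(mask), image_dim = as.integer(image_dim)),
    class = "perivascular_zone"
  )
}

# 1-based linear indices of a zone's member pixels in the full H x W frame
# (column-major over a matrix with rows = y, cols = x).
zone_linear_indices <- function(zone, image_dim = zone$image_dim) {
  H <- image_dim[1]
  w <- which(zone$mask)                       # within-bbox column-major
  nby <- nrow(zone$mask)
  jy <- (w - 1L) %% nby + zone$bbox[["y0"]]   # 0-based full-frame y
  ix <- (w - 1L) %/% nby + zone$bbox[["x0"]]  # 0-based full-frame x
  ix * H + jy + 1L
}

#' Build perivascular zones for every segment of a network
#'
#' @param network a classified, diameter-measured `vessel_network`.
#' @param image_dim integer c(height, width).
#' @param cap_style passed to [build_perivascular_band()].
#' @return object of class `zone_set`: `zones` (list keyed by segment id),
#'   `image_dim`.
#' @export
build_zone_set <- function(network, image_dim, cap_style = c("flat", "round")) {
  cap_style <- match.arg(cap_style)
  zones <- lapply(network$segments, build_perivascular_band,
                  image_dim = image_dim, cap_style = cap_style)
  structure(list(zones = zones, image_dim = as.integer(image_dim)),
            class = "zone_set")
}

#' Total perivascular area for one vessel type
#'
#' Area of the union of all the type's zones: pixels shared by overlapping
#' zones are counted once.
#'
#' @param zone_set a `zone_set`.
#' @param vessel_type `"artery"` or `"vein"`.
#' @return area in px^2.
#' @export
total_perivascular_area <- function(zone_set, vessel_type) {
  vessel_type <- match.arg(vessel_type, c("artery", "vein"))
  sel <- Filter(function(z) z$vessel_type == vessel_type, zone_set$zones)
  if (!length(sel)) return(0L)
  idx <- unique(unlist(lapply(sel, zone_linear_indices,
                              image_dim = zone_set$image_dim)))
  length(idx)
}

#' Per-zone area table
#'
#' @param zone_set a `zone_set`.
#' @return data.frame with `segment_id`, `vessel_type`, `branch_class`,
#'   `area_px2`.
#' @export
zone_area_table <- function(zone_set) {
  data.frame(
    segment_id = vapply(zone_set$zones, `[[`, character(1), "segment_id"),
    vessel_type = vapply(zone_set$zones, `[[`, character(1), "vessel_type"),
    branch_class = vapply(zone_set$zones, function(z)
      if (is.null(z$branch_class) || is.na(z$branch_class)) NA_character_
      else z$branch_class, character(1)),
    area_px2 = vapply(zone_set$zones, function(z) as.numeric(z$area_px2),
                      numeric(1)),
    row.names = NULL
  )
}

#' Export zones as a label-map TIFF
#'
#' Pixel value = zone index (1-based, in `zone_area_table()` row order);
#' later zones overwrite earlier ones where bands overlap; background 0.
#'
#' @param zone_set a `zone_set`.
#' @param path output TIFF path.
#' @return invisibly, the integer label matrix.
#' @export
export_zone_labelmap <- function(zone_set, path) {
  H <- zone_set$image_dim[1]; W <- zone_set$image_dim[2]
  lab <- matrix(0L, H, W)
  for (k in seq_along(zone_set$zones))
    lab[zone_linear_indices(zone_set$zones[[k]], zone_set$image_dim)] <- k
  EBImage::writeImage(EBImage::Image(t(lab) / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(lab)
}

#' Export zones as GeoJSON polygons
#'
#' Each zone is exported as the analytic offset polygon of its centerline
#' (flat caps, mitered joints); the raster mask remains the authoritative
#' region definition used for plaque assignment.
#'
#' @param zone_set a `zone_set`; zones need access to centerlines, so pass
#'   the source `network` too.
#' @param network the `vessel_network` the zones were built from.
#' @param path output GeoJSON path.
#' @export
export_zone_geojson <- function(zone_set, network, path) {
  features <- lapply(names(zone_set$zones), function(id) {
    z <- zone_set$zones[[id]]
    pts <- network$segments[[id]]$points
    ring <- offset_polygon(pts, z$half_width)
    list(
      type = "Feature",
      properties = list(segment_id = z$segment_id,
                        vessel_type = z$vessel_type,
                        branch_class = z$branch_class,
                        area_px2 = z$area_px2),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                        as.numeric(ring[i, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# closed offset ring around a polyline at distance h: left offsets forward,
# right offsets backward, averaged (normalized-miter) normals at joints
offset_polygon <- function(pts, h) {
  n <- nrow(pts)
  tg <- matrix(0, n, 2)
  seg <- diff(pts)
  seg <- seg / sqrt(rowSums(seg^2))
  tg[1, ] <- seg[1, ]; tg[n, ] <- seg[n - 1, ]
  if (n > 2) for (k in 2:(n - 1)) {
    v <- seg[k - 1, ] + seg[k, ]
    tg[k, ] <- v / sqrt(sum(v^2))
  }
  nrm <- cbind(-tg[, 2], tg[, 1])
  left <- pts + h * nrm
  right <- pts - h * nrm
  ring <- rbind(left, right[n:1, , drop = FALSE], left[1, , drop = FALSE])
  colnames(ring) <- c("x", "y")
  ring
}
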