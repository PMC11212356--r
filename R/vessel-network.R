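# Vessel network container: optic-disc-rooted trees of labeled centerline
# segments, the substrate for branch-order classification and perivascular
# zone construction.

#' Create a vessel segment
#'
#' A segment is one traced centerline between two branch points (or between
#' the optic disc and the first branch point), with an arteriole/venule label
#' inherited from the annotation.
#'
#' @param id character identifier, unique within a network.
#' @param vessel_type `"artery"` or `"vein"`.
#' @param points numeric matrix (n x 2) of centerline coordinates, proximal
#'   end first.
#' @param parent id of the parent segment, or `NA` for a root.
#' @param widths optional numeric vector of local vessel widths (px), one per
#'   centerline vertex, used instead of a mask when measuring diameters.
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, vessel_type, points, parent = NA_character_,
                           widths = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L)
    stop("segment '", id, "': centerline needs at least 2 points")
  if (any(polyline_seglengths(points) == 0))
    stop("segment '", id, "': consecutive centerline points must be distinct")
  vessel_type <- match.arg(vessel_type, c("artery", "vein"))
  if (!is.null(widths)) {
    widths <- as.numeric(widths)
    if (length(widths) != nrow(points))
      stop("segment '", id, "': widths must have one value per centerline point")
    if (any(widths <= 0))
      stop("segment '", id, "': widths must be positive")
  }
  structure(
    list(id = as.character(id), vessel_type = vessel_type, points = points,
         parent = if (is.na(parent)) NA_character_ else as.character(parent),
         widths = widths, diameter_samples = NULL, mean_diameter = NA_real_,
         branch_class = NA_character_),
    class = "vessel_segment"
  )
}

#' Assemble a vessel network
#'
#' Validates the rooted-forest structure: every non-root segment names an
#' existing parent of the same vessel type (arteriolar and venular trees are
#' disjoint), no cycles, and every root's proximal end lies within
#' `root_radius` of the optic disc center.
#'
#' @param optic_disc numeric length-2, optic disc center (x, y).
#' @param segments list of [vessel_segment()] objects.
#' @param root_radius maximum distance (px) from the optic disc center at
#'   which a parentless segment is accepted as a tree root.
#' @return an object of class `vessel_network`.
#' @export
vessel_network <- function(optic_disc, segments, root_radius = 60) {
  ids <- vapply(segments, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate segment ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(segments) <- ids
  for (seg in segments) {
    p <- seg$parent
    if (!is.na(p)) {
      if (!p %in% ids)
        stop("segment '", seg$id, "' names unknown parent '", p, "'")
      if (segments[[p]]$vessel_type != seg$vessel_type)
        stop("segment '", seg$id, "' crosses vessel types to parent '", p,
             "': arteriolar and venular trees must be disjoint")
    }
  }
  # cycle check by walking parents
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(segments[[cur]]$parent)) {
      if (cur %in% seen)
        stop("cycle detected in annotation: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- segments[[cur]]$parent
    }
    if (cur %in% seen)
      stop("cycle detected in annotation: ", paste(c(seen, cur), collapse = " -> "))
  }
  roots <- ids[vapply(segments, function(s) is.na(s$parent), logical(1))]
  if (length(roots) == 0L) stop("network has no root segments")
  for (r in roots) {
    prox <- segments[[r]]$points[1, ]
    d <- sqrt(sum((prox - optic_disc)^2))
    if (d > root_radius)
      stop("root segment '", r, "' starts ", round(d, 1),
           " px from the optic disc (root_radius = ", root_radius, ")")
  }
  children <- lapply(ids, function(id)
    ids[vapply(segments, function(s) identical(s$parent, id), logical(1))])
  names(children) <- ids
  structure(
    list(optic_disc = as.numeric(optic_disc), segments = segments,
         children = children, roots = roots),
    class = "vessel_network"
  )
}

#' @export
print.vessel_network <- function(x, ...) {
  types <- vapply(x$segments, `[[`, character(1), "vessel_type")
  cat("<vessel_network> ", length(x$segments), " segments (",
      sum(types == "artery"), " arteriolar, ", sum(types == "vein"),
      " venular), ", length(x$roots), " roots, optic disc at (",
      paste(round(x$optic_disc, 1), collapse = ", "), ")\n", sep = "")
  cls <- vapply(x$segments, `[[`, character(1), "branch_class")
  if (!all(is.na(cls)))
    print(table(branch_class = cls, vessel_type = types))
  invisible(x)
}

#' Read a vessel annotation file
#'
#' The annotation dialect is JSON with fields `optic_disc` (`[x, y]`) and
#' `segments`, a list of objects with `id`, `type` ("artery"/"vein"),
#' `parent` (id or null), `points` (`[[x, y], ...]`) and optional `widths`.
#'
#' @param path file path.
#' @param root_radius passed to [vessel_network()].
#' @return a `vessel_network`.
#' @export
read_vessel_annotation <- function(path, root_radius = 60) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  segs <- j$segments
  if (is.data.frame(segs)) segs <- split(segs, seq_len(nrow(segs)))
  segments <- lapply(segs, function(s) {
    if (is.data.frame(s)) s <- as.list(s)
    pts <- s$points
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    if (is.list(pts) && is.data.frame(pts)) pts <- as.matrix(pts)
    if (is.list(pts)) pts <- pts[[1]]
    parent <- s$parent
    if (is.null(parent) || length(parent) == 0L || is.na(parent)) parent <- NA_character_
    w <- s$widths
    if (is.list(w)) w <- unlist(w)
    if (length(w) == 0L) w <- NULL
    vessel_segment(s$id, s$type, pts, parent = parent, widths = w)
  })
  vessel_network(unlist(j$optic_disc), segments, root_radius = root_radius)
}

#' Write a vessel annotation file
#'
#' Emits the same JSON dialect accepted by [read_vessel_annotation()], with
#' `branch_class` and `mean_diameter` added when present.
#'
#' @param network a `vessel_network`.
#' @param path output file path.
#' @export
write_vessel_annotation <- function(network, path) {
  segs <- lapply(unname(network$segments), function(s) {
    out <- list(
      id = s$id, type = s$vessel_type,
      parent = if (is.na(s$parent)) NULL else s$parent,
      points = unname(apply(s$points, 1, function(r) as.numeric(r), simplify = FALSE))
    )
    if (!is.null(s$widths)) out$widths <- as.numeric(s$widths)
    if (!is.na(s$mean_diameter)) out$mean_diameter <- s$mean_diameter
    if (!is.na(s$branch_class)) out$branch_class <- s$branch_class
    out
  })
  jsonlite::write_json(
    list(optic_disc = as.numeric(network$optic_disc), segments = segs),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
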