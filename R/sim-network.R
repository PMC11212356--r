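# Synthetic vascular tree generator.  Emulates the supero-temporal quadrant
# geometry: one main venule and one main arteriole leaving the optic disc
# (vein caliber > artery caliber), advancing through main bifurcations with
# thin protruding "small" branches, tortuous centerlines, and diameters
# decreasing with depth.  Every segment carries a ground-truth branch label
# derived from the construction itself, serving as the oracle for the
# branch-order classifier.

#' Parameters for the synthetic vascular tree generator
#'
#' @param n_primary number of primary (root) vessels per vessel type.
#' @param depth number of main branching levels (1 = unbranched roots,
#'   3 = secondary mains bifurcate again into tertiary branches).
#' @param field image frame c(height, width) in px.
#' @param optic_disc disc center c(x, y); roots start on its rim.
#' @param root_diameter_vein,root_diameter_artery root calibers (px);
#'   the venular caliber must exceed the arteriolar one.
#' @param main_ratio_range daughter/parent diameter ratio range for
#'   comparable-caliber bifurcation daughters (kept above the small-branch
#'   threshold).
#' @param small_ratio_range ratio range for thin protruding branches (kept
#'   below the threshold).
#' @param p_small probability that a main segment carries a protruding
#'   small branch at its distal node.
#' @param p_continuation probability that a main-branch node is a
#'   continuation (single comparable daughter) rather than a bifurcation.
#' @param segment_length base centerline length (px), shrinking with depth.
#' @param tortuosity_amp lateral sinusoidal perturbation amplitude (px).
#' @param taper distal/proximal width ratio within one segment.
#' @return named parameter list.
#' @export
vascular_tree_params <- function(n_primary = 1, depth = 3,
                                 field = c(560, 768),
                                 optic_disc = c(48, 280),
                                 root_diameter_vein = 14,
                                 root_diameter_artery = 11,
                                 main_ratio_range = c(0.72, 0.85),
                                 small_ratio_range = c(0.30, 0.45),
                                 p_small = 0.7, p_continuation = 0.25,
                                 segment_length = 150,
                                 tortuosity_amp = 6, taper = 0.9) {
  stopifnot(root_diameter_vein > root_diameter_artery,
            all(small_ratio_range < min(main_ratio_range)))
  as.list(environment())
}

#' Generate a synthetic vessel network with ground-truth branch labels
#'
#' Seeded and reproducible: identical seed and parameters give identical
#' networks.  If a drawn branch direction would leave the field the draw is
#' retried (up to 25 times, then the generator errors).
#'
#' @param params see [vascular_tree_params()].
#' @param seed integer RNG seed.
#' @return list with `network` (a `vessel_network`, widths attached,
#'   diameters/classes unset), `truth` (named character vector of
#'   ground-truth branch classes by segment id), and `params`.
#' @export
generate_vessel_network <- function(params = vascular_tree_params(), seed = 1) {
  set.seed(seed)
  H <- params$field[1]; W <- params$field[2]
  segments <- list()
  truth <- character(0)
  counter <- 0L

  new_id <- function(ty) {
    counter <<- counter + 1L
    sprintf("%s%03d", if (ty == "vein") "V" else "A", counter)
  }

  in_field <- function(p) p[1] >= 4 && p[1] <= W - 4 && p[2] >= 4 && p[2] <= H - 4

  # draw a tortuous centerline; retry the direction if it exits the field,
  # then shorten the branch (with a warning) before giving up
  draw_centerline <- function(start, base_angle, length, spread) {
    for (shrink in 0:5) {
      len <- length * 0.7^shrink
      if (shrink > 0)
        warning("branch left the field; retrying at length ", round(len, 1))
      for (try in 1:25) {
        # once plain shrinking fails, steer the branch back toward the
        # field center with a widening angular search
        base <- if (shrink < 2) base_angle
                else atan2(H / 2 - start[2], W / 2 - start[1])
        ang <- base + stats::runif(1, -1, 1) * (spread + 0.15 * shrink)
        dir <- c(cos(ang), sin(ang))
        nrm <- c(-dir[2], dir[1])
        s <- seq(0, len, by = 12)
        if (len - s[length(s)] > 1e-6) s <- c(s, len) else s[length(s)] <- len
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- params$tortuosity_amp * stats::runif(1, 0.4, 1)
        pts <- t(vapply(s, function(si)
          start + si * dir + amp * sin(2 * pi * si / len + phase) * nrm,
          numeric(2)))
        # anchor the proximal end exactly at the start point
        pts[1, ] <- start
        if (all(apply(pts, 1, in_field))) return(list(points = pts, angle = ang))
      }
    }
    stop("infeasible geometry: could not keep a branch inside the ",
         H, "x", W, " field")
  }

  add_segment <- function(ty, parent, start, angle, spread, length, diameter,
                          label) {
    cl <- draw_centerline(start, angle, length, spread)
    id <- new_id(ty)
    widths <- seq(diameter, diameter * params$taper,
                  length.out = nrow(cl$points))
    segments[[id]] <<- vessel_segment(id, ty, cl$points, parent = parent,
                                      widths = widths)
    truth[[id]] <<- label
    list(id = id, end = cl$points[nrow(cl$points), ], angle = cl$angle,
         diameter = diameter * (1 + params$taper) / 2)
  }

  grow <- function(ty, node, order, level_left, can_continue = TRUE) {
    # protruding small branch off this main segment's distal node
    if (stats::runif(1) < params$p_small && order <= 2) {
      ratio <- stats::runif(1, params$small_ratio_range[1],
                            params$small_ratio_range[2])
      lab <- paste0(c("primary", "secondary")[order], "_small")
      sm <- add_segment(ty, node$id, node$end,
                        node$angle + sample(c(-1, 1), 1) * stats::runif(1, 0.7, 1.2),
                        0.1, params$segment_length * 0.45,
                        node$diameter * ratio, lab)
      # descendants of small branches are grouped with tertiary
      if (stats::runif(1) < 0.15)
        add_segment(ty, sm$id, sm$end, sm$angle, 0.3,
                    params$segment_length * 0.3,
                    sm$diameter * 0.8, "tertiary")
    }
    if (level_left == 0) return(invisible())
    if (order <= 2 && can_continue && stats::runif(1) < params$p_continuation) {
      # continuation: one comparable daughter keeps the parent's order
      ratio <- stats::runif(1, params$main_ratio_range[1],
                            params$main_ratio_range[2])
      lab <- if (order >= 3) "tertiary"
             else paste0(c("primary", "secondary")[order], "_main")
      child <- add_segment(ty, node$id, node$end, node$angle, 0.25,
                           params$segment_length * 0.8^order,
                           node$diameter * ratio, lab)
      grow(ty, child, order, level_left, can_continue = FALSE)
    } else {
      # bifurcation: both comparable daughters advance one order
      next_order <- order + 1L
      lab <- if (next_order >= 3) "tertiary"
             else paste0(c("primary", "secondary")[next_order], "_main")
      for (side in c(-1, 1)) {
        ratio <- stats::runif(1, params$main_ratio_range[1],
                              params$main_ratio_range[2])
        child <- add_segment(ty, node$id, node$end,
                             node$angle + side * stats::runif(1, 0.35, 0.6),
                             0.1, params$segment_length * 0.8^order,
                             node$diameter * ratio, lab)
        if (next_order < 3) grow(ty, child, next_order, level_left - 1L)
        else if (stats::runif(1) < 0.5)   # tertiary keeps subdividing a bit
          add_segment(ty, child$id, child$end, child$angle, 0.4,
                      params$segment_length * 0.4, child$diameter * 0.85,
                      "tertiary")
      }
    }
  }

  for (ty in c("vein", "artery")) {
    d0 <- if (ty == "vein") params$root_diameter_vein
          else params$root_diameter_artery
    for (k in seq_len(params$n_primary)) {
      base <- (k - 0.5) / params$n_primary * 0.9 - 0.45 +
        if (ty == "vein") -0.12 else 0.12
      root <- add_segment(ty, NA_character_, params$optic_disc, base, 0.12,
                          params$segment_length, d0, "primary_main")
      grow(ty, root, 1L, params$depth - 1L)
    }
  }

  net <- vessel_network(params$optic_disc, segments, root_radius = 10)
  list(network = net, truth = truth, params = params)
}
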