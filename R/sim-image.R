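# Synthetic fundus fluorescence image generator: plants hyperfluorescent
# spots from an inhomogeneous spatial process (background rate outside the
# perivascular zones, multiplied rates inside each zone), renders them as
# Gaussian profiles over a noisy background with faint vessel strokes, and
# records per-plant ground truth including zone memberships computed by an
# independent brute-force footprint/mask intersection.

#' Parameters for plaque placement and rendering
#'
#' @param lambda_bg background plaque rate (expected plants per 1e4 px^2
#'   outside every zone).
#' @param multipliers named per-category rate multipliers inside zones;
#'   names are `<type>_<class>` with type `artery`/`vein` and class a
#'   branch class (e.g. `artery_secondary_main`); unnamed categories use
#'   `default_multiplier`.
#' @param default_multiplier multiplier for zone categories not listed.
#' @param amplitude_range spot peak amplitude range (image units).
#' @param sigma_range spot Gaussian radius range (px).
#' @param noise_sd additive Gaussian noise SD; amplitude_range[1]/noise_sd
#'   is the minimum spot SNR.
#' @param background level of the flat image background.
#' @param vessel_amplitude intensity bump of the rendered vessel strokes.
#' @param min_separation minimum center-to-center distance between planted
#'   spots (rejection-sampled; keeps spots resolvable).
#' @return named parameter list.
#' @export
plaque_placement_params <- function(lambda_bg = 1.2, multipliers = c(
                                      artery_secondary_main = 3,
                                      artery_secondary_small = 3,
                                      vein_secondary_main = 2,
                                      vein_secondary_small = 2),
                                    default_multiplier = 1.5,
                                    amplitude_range = c(0.30, 0.55),
                                    sigma_range = c(1.3, 1.9),
                                    noise_sd = 0.02, background = 0.15,
                                    vessel_amplitude = 0.02,
                                    min_separation = 9) {
  stopifnot(lambda_bg >= 0, all(multipliers >= 0), default_multiplier >= 0)
  as.list(environment())
}

#' Render a fluorescence image with planted plaques
#'
#' Builds perivascular zones from the network (ground-truth widths), plants
#' spot centers at rate `lambda_bg` per 1e4 px^2 outside all zones and
#' `lambda_bg * multiplier` inside each zone category, renders Gaussian
#' spots on a noisy background, and returns the image together with the
#' ground-truth plant table.
#'
#' @param network_truth output of [generate_vessel_network()], or a
#'   classified measured `vessel_network`.
#' @param params see [plaque_placement_params()].
#' @param seed integer RNG seed.
#' @param image_dim c(height, width); defaults to the generator field.
#' @return list: `image` (matrix), `truth` (data.frame with `plaque_id`,
#'   `x`, `y`, `sigma`, `amplitude`, `planted_in` zone category or
#'   `"background"`), `truth_memberships` (data.frame `plaque_id`,
#'   `segment_id`, `vessel_type`, `branch_class` from the generator's own
#'   footprint test), `zone_set`, `network` (measured + classified), and
#'   `params`.
#' @export
place_plaques_and_render <- function(network_truth,
                                     params = plaque_placement_params(),
                                     seed = 1, image_dim = NULL) {
  set.seed(seed)
  net <- if (inherits(network_truth, "vessel_network")) network_truth
         else network_truth$network
  if (is.null(image_dim)) {
    image_dim <- if (!inherits(network_truth, "vessel_network")) {
      network_truth$params$field
    } else {
      # frame large enough for every centerline plus its widest band
      ext <- do.call(rbind, lapply(net$segments, function(s)
        apply(s$points, 2, max)))
      margin <- 30
      c(ceiling(max(ext[, 2])) + margin, ceiling(max(ext[, 1])) + margin)
    }
  }
  H <- image_dim[1]; W <- image_dim[2]
  cls <- vapply(net$segments, function(s)
    if (is.na(s$branch_class)) "" else s$branch_class, character(1))
  if (any(cls == "")) {
    net <- measure_network_diameters(net, interval_px = 20)
    net <- classify_branch_orders(net)
  }
  zones <- build_zone_set(net, image_dim)

  # pixel-resolution category map: 0 = background, otherwise zone index;
  # where zones overlap the higher-multiplier category wins the rate
  zone_cat <- vapply(zones$zones, function(z)
    paste(z$vessel_type, z$branch_class, sep = "_"), character(1))
  mult <- vapply(zone_cat, function(ct) {
    m <- params$multipliers[ct]
    if (is.na(m)) params$default_multiplier else unname(m)
  }, numeric(1))
  rate_map <- matrix(params$lambda_bg / 1e4, H, W)
  owner <- matrix(0L, H, W)
  for (k in order(mult)) {
    idx <- zone_linear_indices(zones$zones[[k]], image_dim)
    rate_map[idx] <- params$lambda_bg * mult[k] / 1e4
    owner[idx] <- k
  }

  # inhomogeneous Poisson by thinning a homogeneous process at the max rate
  max_rate <- max(rate_map)
  n_cand <- stats::rpois(1, max_rate * H * W)
  cx <- stats::runif(n_cand, 0, W); cy <- stats::runif(n_cand, 0, H)
  pix <- floor(cx) * H + floor(cy) + 1L
  keep <- stats::runif(n_cand) < rate_map[pix] / max_rate
  cx <- cx[keep]; cy <- cy[keep]
  # enforce minimum separation (greedy thinning, deterministic order)
  sel <- integer(0)
  for (i in seq_along(cx)) {
    if (!length(sel) ||
        min(sqrt((cx[sel] - cx[i])^2 + (cy[sel] - cy[i])^2)) >=
          params$min_separation)
      sel <- c(sel, i)
  }
  cx <- cx[sel]; cy <- cy[sel]
  n <- length(cx)
  sig <- stats::runif(n, params$sigma_range[1], params$sigma_range[2])
  amp <- stats::runif(n, params$amplitude_range[1], params$amplitude_range[2])
  own <- owner[floor(cx) * H + floor(cy) + 1L]
  planted_in <- ifelse(own == 0L, "background", zone_cat[own])

  # render: flat background + faint vessel strokes + spots + noise
  img <- matrix(params$background, H, W)
  if (params$vessel_amplitude > 0) {
    for (s in net$segments) {
      half <- s$mean_diameter / 2
      x0 <- max(0L, floor(min(s$points[, 1]) - half - 1))
      x1 <- min(W - 1L, ceiling(max(s$points[, 1]) + half + 1))
      y0 <- max(0L, floor(min(s$points[, 2]) - half - 1))
      y1 <- min(H - 1L, ceiling(max(s$points[, 2]) + half + 1))
      xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
      px <- rep(xs + 0.5, each = length(ys)); py <- rep(ys + 0.5, length(xs))
      d <- polyline_flatcap_dist(px, py, s$points)
      hit <- d <= half
      lin <- (rep(xs, each = length(ys))[hit]) * H + rep(ys, length(xs))[hit] + 1L
      img[lin] <- img[lin] + params$vessel_amplitude
    }
  }
  for (i in seq_len(n)) {
    r <- ceiling(3 * sig[i])
    xs <- max(0, floor(cx[i]) - r):min(W - 1, floor(cx[i]) + r)
    ys <- max(0, floor(cy[i]) - r):min(H - 1, floor(cy[i]) + r)
    gx <- exp(-((xs + 0.5 - cx[i])^2) / (2 * sig[i]^2))
    gy <- exp(-((ys + 0.5 - cy[i])^2) / (2 * sig[i]^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amp[i] * outer(gy, gx)
  }
  img <- img + matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W)

  truth <- data.frame(plaque_id = seq_len(n), x = cx, y = cy, sigma = sig,
                      amplitude = amp, planted_in = planted_in)

  # ground-truth memberships: brute-force disc-footprint vs zone mask test,
  # independent of assign_plaques()
  rows <- list()
  for (i in seq_len(n)) {
    r <- 2 * sig[i]
    xs <- max(0, floor(cx[i] - r)):min(W - 1, floor(cx[i] + r))
    ys <- max(0, floor(cy[i] - r)):min(H - 1, floor(cy[i] + r))
    fp <- expand.grid(x = xs, y = ys)
    fp <- fp[(fp$x + 0.5 - cx[i])^2 + (fp$y + 0.5 - cy[i])^2 <= r^2, ]
    for (k in seq_along(zones$zones)) {
      z <- zones$zones[[k]]
      zx <- fp$x - z$bbox[["x0"]]; zy <- fp$y - z$bbox[["y0"]]
      ok <- zx >= 0 & zy >= 0 & zx < ncol(z$mask) & zy < nrow(z$mask)
      if (any(ok) && any(z$mask[cbind(zy[ok] + 1L, zx[ok] + 1L)]))
        rows[[length(rows) + 1L]] <- data.frame(
          plaque_id = i, segment_id = z$segment_id,
          vessel_type = z$vessel_type, branch_class = z$branch_class)
    }
  }
  truth_memberships <- if (length(rows)) do.call(rbind, rows)
    else data.frame(plaque_id = integer(0), segment_id = character(0),
                    vessel_type = character(0), branch_class = character(0))

  list(image = img, truth = truth, truth_memberships = truth_memberships,
       zone_set = zones, network = net, params = params, seed = seed)
}

#' Ground-truth plants as a `plaque_set`
#'
#' Converts the generator's truth table into the plaque container used by
#' [assign_plaques()], with disc footprints of radius two spot sigmas.
#'
#' @param rendered output of [place_plaques_and_render()].
#' @return a `plaque_set`.
#' @export
truth_plaque_set <- function(rendered) {
  tr <- rendered$truth
  H <- nrow(rendered$image); W <- ncol(rendered$image)
  fps <- lapply(seq_len(nrow(tr)), function(i) {
    r <- 2 * tr$sigma[i]
    xs <- max(0, floor(tr$x[i] - r)):min(W - 1, floor(tr$x[i] + r))
    ys <- max(0, floor(tr$y[i] - r)):min(H - 1, floor(tr$y[i] + r))
    g <- expand.grid(x = xs, y = ys)
    g <- g[(g$x + 0.5 - tr$x[i])^2 + (g$y + 0.5 - tr$y[i])^2 <= r^2, ]
    as.integer(g$x * H + g$y + 1L)
  })
  plaque_table(tr$x, tr$y, vapply(fps, length, numeric(1)),
               tr$amplitude, fps)
}
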