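# Shared fixtures and independent brute-force oracles.  Oracles are written
# as plain loops, deliberately independent of the package's vectorized
# implementations.

# straight horizontal segment with constant (or linearly varying) width
straight_seg <- function(id = "s1", type = "vein", x0 = 10, y0 = 50,
                         len = 100, w0 = 10, w1 = w0) {
  vessel_segment(id, type, cbind(c(x0, x0 + len), c(y0, y0)),
                 widths = c(w0, w1))
}

# hand-built network: root d=12 splitting into comparable daughters d=9 and
# d=8 plus a protruding twig d=3
toy_split_network <- function() {
  root <- vessel_segment("r", "vein", cbind(c(0, 100), c(0, 0)),
                         widths = c(12, 12))
  d1 <- vessel_segment("d1", "vein", cbind(c(100, 180), c(0, 40)),
                       parent = "r", widths = c(9, 9))
  d2 <- vessel_segment("d2", "vein", cbind(c(100, 180), c(0, -40)),
                       parent = "r", widths = c(8, 8))
  tw <- vessel_segment("tw", "vein", cbind(c(100, 130), c(0, 60)),
                       parent = "r", widths = c(3, 3))
  vessel_network(c(0, 0), list(root, d1, d2, tw), root_radius = 5)
}

classify_toy <- function(net, thr = 0.6) {
  classify_branch_orders(measure_network_diameters(net), thr)
}

branch_classes_of <- function(net) {
  vapply(net$segments, `[[`, character(1), "branch_class")
}

# pixel-exhaustive band oracle: plain double loop over every pixel of an
# H x W frame, flat-cap point-to-polyline distance computed edge by edge
oracle_band_mask <- function(points, half, H, W) {
  mask <- matrix(FALSE, H, W)
  nseg <- nrow(points) - 1L
  n <- nrow(points)
  t1 <- points[2, ] - points[1, ]
  tn <- points[n, ] - points[n - 1L, ]
  for (j in 0:(H - 1L)) for (i in 0:(W - 1L)) {
    px <- i + 0.5; py <- j + 0.5
    best <- Inf
    in_caps <-
      (px - points[1, 1]) * t1[1] + (py - points[1, 2]) * t1[2] >= 0 &&
      (px - points[n, 1]) * tn[1] + (py - points[n, 2]) * tn[2] <= 0
    for (k in seq_len(nseg)) {
      ax <- points[k, 1]; ay <- points[k, 2]
      bx <- points[k + 1L, 1]; by <- points[k + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      tt <- ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)
      if (tt >= 0 && tt <= 1) {
        d <- abs((px - ax) * vy - (py - ay) * vx) / sqrt(vx^2 + vy^2)
        if (d < best) best <- d
      }
      if (k > 1L && in_caps) {   # interior vertex disk, clipped by end caps
        d <- sqrt((px - ax)^2 + (py - ay)^2)
        if (d < best) best <- d
      }
    }
    mask[j + 1L, i + 1L] <- best <= half
  }
  mask
}

# full-frame logical mask of a zone
zone_full_mask <- function(zone, H, W) {
  m <- matrix(FALSE, H, W)
  nby <- nrow(zone$mask)
  w <- which(zone$mask)
  jy <- (w - 1L) %% nby + zone$bbox[["y0"]]
  ix <- (w - 1L) %/% nby + zone$bbox[["x0"]]
  m[cbind(jy + 1L, ix + 1L)] <- TRUE
  m
}

# brute-force Mann-Whitney U: pairwise wins of y over x plus half ties
oracle_U <- function(y, x) {
  u <- 0
  for (yy in y) for (xx in x) u <- u + (yy > xx) + 0.5 * (yy == xx)
  u
}

# hand step-down Holm rejections at level alpha
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}

# full-frame union mask over every zone in a set
zone_full_mask_any <- function(zs) {
  H <- zs$image_dim[1]; W <- zs$image_dim[2]
  m <- matrix(FALSE, H, W)
  for (z in zs$zones) m <- m | zone_full_mask(z, H, W)
  m
}

# unadjusted pairwise p inside the one-way ANOVA framework (pooled residual
# MSE and its df) — the quantity Tukey's adjustment must dominate
oracle_anova_pairwise_p <- function(v, g, lv) {
  g <- factor(g)
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  dfr <- length(v) - nlevels(g)
  mse <- ssw / dfr
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  t <- (mean(v[g == lv[1]]) - mean(v[g == lv[2]])) /
    sqrt(mse * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), dfr)
}

# deterministic single-spot image
spot_image <- function(H = 64, W = 64, cx = 30.2, cy = 25.7, amp = 0.6,
                       sigma = 1.6, bg = 0.15, noise_sd = 0.01, seed = 99) {
  set.seed(seed)
  img <- matrix(bg, H, W) + matrix(rnorm(H * W, 0, noise_sd), H, W)
  for (j in 0:(H - 1)) for (i in 0:(W - 1))
    img[j + 1, i + 1] <- img[j + 1, i + 1] +
      amp * exp(-((i + 0.5 - cx)^2 + (j + 0.5 - cy)^2) / (2 * sigma^2))
  img
}
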