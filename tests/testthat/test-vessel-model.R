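# Vessel model: diameter sampling, branch-order rules, category aggregation.

test_that("diameter sampling averages pre-set intervals including both endpoints", {
  # constant width: mean equals the width for any interval
  seg <- measure_diameter(straight_seg(w0 = 8), interval_px = 17)
  expect_equal(seg$mean_diameter, 8.0)
  expect_equal(seg$diameter_samples$pos[1], 0)
  expect_equal(tail(seg$diameter_samples$pos, 1), 100)

  # linear taper 10 -> 6 over 100 px, interval 25: chord widths at the five
  # sample positions are 10, 9, 8, 7, 6 (direct average = 8), the oracle
  # being the linear width profile itself
  seg <- measure_diameter(straight_seg(w0 = 10, w1 = 6), interval_px = 25)
  expect_equal(seg$diameter_samples$width, c(10, 9, 8, 7, 6))
  expect_equal(seg$mean_diameter, 8.0)

  # endpoints are present for a non-divisor interval too
  seg <- measure_diameter(straight_seg(), interval_px = 33)
  expect_equal(seg$diameter_samples$pos,  c(0, 33, 66, 99, 100))

  # shorter than one interval: only the two endpoints
  seg <- measure_diameter(straight_seg(len = 12), interval_px = 40)
  expect_equal(seg$diameter_samples$pos, c(0, 12))
})

test_that("mask-based chord measurement recovers the drawn width", {
  H <- 40; W <- 140
  mask <- matrix(0L, H, W)
  mask[17:24, 11:110] <- 1L   # 8 px wide strip, rows y = 16..23 (0-based)
  seg <- vessel_segment("m", "artery", cbind(c(15, 105), c(20, 20)))
  seg <- measure_diameter(seg, interval_px = 20, mask = mask)
  expect_true(all(abs(seg$diameter_samples$width - 8) <= 0.5))

  # broken mask under a sample point signals an error
  mask2 <- mask; mask2[, 55:58] <- 0L   # gap under the arc-40 sample point
  seg2 <- vessel_segment("m2", "artery", cbind(c(15, 105), c(20, 20)))
  expect_error(measure_diameter(seg2, interval_px = 20, mask = mask2),
               "zero measured width")
})

test_that("mean diameter is monotone under pointwise width increase", {
  a <- measure_diameter(straight_seg(w0 = 10, w1 = 6), interval_px = 10)
  b <- measure_diameter(straight_seg(w0 = 11, w1 = 7), interval_px = 10)
  expect_gt(b$mean_diameter, a$mean_diameter)
})

test_that("branch rules: roots, bifurcation daughters, protruding twigs", {
  # single unbranched root
  net <- vessel_network(c(0, 0), list(straight_seg(x0 = 0, y0 = 0)),
                        root_radius = 15)
  net <- classify_toy(net)
  expect_equal(unname(branch_classes_of(net)), "primary_main")

  # root d=12 -> comparable daughters d=9, d=8 advance to secondary_main;
  # the d=3 twig (< 0.6 x 12) is primary_small
  cls <- branch_classes_of(classify_toy(toy_split_network()))
  expect_equal(cls[["r"]], "primary_main")
  expect_equal(cls[["d1"]], "secondary_main")
  expect_equal(cls[["d2"]], "secondary_main")
  expect_equal(cls[["tw"]], "primary_small")
})

test_that("everything after the second main bifurcation is tertiary", {
  mk <- function(id, par, x0, y0, x1, y1, w)
    vessel_segment(id, "vein", cbind(c(x0, x1), c(y0, y1)), parent = par,
                   widths = c(w, w))
  segs <- list(
    mk("r", NA, 0, 0, 80, 0, 12),
    mk("a", "r", 80, 0, 150, 30, 9), mk("b", "r", 80, 0, 150, -30, 9),
    mk("aa", "a", 150, 30, 210, 50, 7), mk("ab", "a", 150, 30, 210, 10, 7),
    # deeper splits below tertiary stay tertiary regardless of caliber
    mk("aaa", "aa", 210, 50, 250, 70, 6), mk("aab", "aa", 210, 50, 250, 40, 6),
    mk("aaaa", "aaa", 250, 70, 280, 80, 5)
  )
  net <- classify_toy(vessel_network(c(0, 0), segs, root_radius = 5))
  cls <- branch_classes_of(net)
  expect_equal(cls[["aa"]], "tertiary")
  expect_equal(cls[["ab"]], "tertiary")
  expect_equal(cls[["aaa"]], "tertiary")
  expect_equal(cls[["aaaa"]], "tertiary")
})

test_that("continuation and all-small splits do not advance the order", {
  mk <- function(id, par, x1, y1, w)
    vessel_segment(id, "vein",
                   cbind(c(if (is.na(par)) 0 else 100, x1),
                         c(if (is.na(par)) 0 else 0, y1)),
                   parent = par, widths = c(w, w))
  # one comparable daughter (continuation) + one twig
  segs <- list(mk("r", NA, 100, 0, 10),
               mk("cont", "r", 200, 10, 8),   # 0.8 ratio: comparable
               mk("tw", "r", 130, 40, 3))
  cls <- branch_classes_of(classify_toy(vessel_network(c(0, 0), segs, 5)))
  expect_equal(cls[["cont"]], "primary_main")
  expect_equal(cls[["tw"]], "primary_small")

  # all daughters small: no bifurcation event
  segs <- list(mk("r", NA, 100, 0, 10),
               mk("t1", "r", 150, 30, 3), mk("t2", "r", 150, -30, 4))
  cls <- branch_classes_of(classify_toy(vessel_network(c(0, 0), segs, 5)))
  expect_equal(unname(cls[c("t1", "t2")]),
               c("primary_small", "primary_small"))
})

test_that("trifurcations advance all comparable daughters with a note", {
  mk <- function(id, par, y1, w)
    vessel_segment(id, "vein",
                   cbind(c(if (is.na(par)) 0 else 100, if (is.na(par)) 100 else 170),
                         c(0, y1)), parent = par, widths = c(w, w))
  segs <- list(mk("r", NA, 0, 12), mk("a", "r", 40, 9), mk("b", "r", 0, 9),
               mk("c", "r", -40, 8))
  expect_message(net <- classify_toy(vessel_network(c(0, 0), segs, 5)),
                 "trifurcation")
  cls <- branch_classes_of(net)
  expect_equal(unname(cls[c("a", "b", "c")]), rep("secondary_main", 3))
})

test_that("classification requires diameters and a rooted network", {
  net <- toy_split_network()
  expect_error(classify_branch_orders(net), "mean_diameter missing")
})

test_that("classification is invariant under rigid motion and scaling", {
  base <- suppressWarnings(generate_vessel_network(seed = 21))
  ref <- branch_classes_of(classify_toy(base$network))
  th <- 0.7; sc <- 2.5; shift <- c(310, -40)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  segs <- lapply(base$network$segments, function(s) {
    p <- sweep(sc * (s$points %*% R), 2, -shift)
    vessel_segment(s$id, s$vessel_type, p, parent = s$parent,
                   widths = sc * s$widths)
  })
  od <- sc * (base$network$optic_disc %*% R) + shift
  net2 <- vessel_network(as.numeric(od), segs, root_radius = 10 * sc)
  expect_equal(branch_classes_of(classify_toy(net2)), ref)
})

test_that("categories partition the segments and totals are unions", {
  # 1 primary_main + 2 primary_small venules -> primary_total has 3
  mk <- function(id, par, y1, w)
    vessel_segment(id, "vein",
                   cbind(c(if (is.na(par)) 0 else 100, if (is.na(par)) 100 else 140),
                         c(0, y1)), parent = par, widths = c(w, w))
  net <- classify_toy(vessel_network(c(0, 0),
    list(mk("r", NA, 0, 10), mk("s1", "r", 30, 3), mk("s2", "r", -30, 3)), 5))
  agg <- aggregate_categories(net)
  expect_setequal(agg$vein$primary_total, c("r", "s1", "s2"))
  expect_equal(agg$vein$secondary_total, character(0))   # present but empty
  expect_named(agg$artery, c("primary_total", "primary_main", "primary_small",
                             "secondary_total", "secondary_main",
                             "secondary_small", "tertiary"))

  # partition property across generated trees
  for (sd in c(3, 14, 27)) {
    g <- suppressWarnings(generate_vessel_network(seed = sd))
    net <- classify_toy(g$network)
    agg <- aggregate_categories(net)
    leaf_cats <- c("primary_main", "primary_small", "secondary_main",
                   "secondary_small", "tertiary")
    for (ty in c("artery", "vein")) {
      ids <- unlist(agg[[ty]][leaf_cats])
      expect_equal(anyDuplicated(ids), 0L)
      expect_setequal(agg[[ty]]$primary_total,
                      c(agg[[ty]]$primary_main, agg[[ty]]$primary_small))
      expect_setequal(agg[[ty]]$secondary_total,
                      c(agg[[ty]]$secondary_main, agg[[ty]]$secondary_small))
    }
    all_ids <- c(unlist(agg$artery[leaf_cats]), unlist(agg$vein[leaf_cats]))
    expect_setequal(all_ids, names(net$segments))
  }
})

test_that("network validation rejects cycles, bad parents, mixed types", {
  s1 <- vessel_segment("a", "vein", cbind(c(0, 50), c(0, 0)), parent = "b",
                       widths = c(5, 5))
  s2 <- vessel_segment("b", "vein", cbind(c(50, 90), c(0, 10)), parent = "a",
                       widths = c(5, 5))
  expect_error(vessel_network(c(0, 0), list(s1, s2)), "cycle")
  s3 <- vessel_segment("c", "vein", cbind(c(0, 50), c(0, 0)), parent = "zz")
  expect_error(vessel_network(c(0, 0), list(s3)), "unknown parent")
  r <- vessel_segment("r", "vein", cbind(c(0, 50), c(0, 0)), widths = c(5, 5))
  x <- vessel_segment("x", "artery", cbind(c(50, 90), c(0, 0)), parent = "r")
  expect_error(vessel_network(c(0, 0), list(r, x)), "disjoint")
  far <- vessel_segment("f", "vein", cbind(c(500, 550), c(0, 0)))
  expect_error(vessel_network(c(0, 0), list(far), root_radius = 60),
               "optic disc")
})

test_that("annotation JSON round-trips geometry, labels and diameters", {
  g <- suppressWarnings(generate_vessel_network(seed = 9))
  net <- classify_toy(g$network)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_vessel_annotation(net, f1)
  back <- read_vessel_annotation(f1, root_radius = 10)
  expect_setequal(names(back$segments), names(net$segments))
  id <- names(net$segments)[5]
  expect_equal(back$segments[[id]]$points, unname(net$segments[[id]]$points))
  expect_equal(back$segments[[id]]$vessel_type, net$segments[[id]]$vessel_type)
  # writer is deterministic: identical bytes on rewrite
  write_vessel_annotation(net, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
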