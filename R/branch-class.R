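# Branch-order taxonomy.  Vessels originating at the optic disc are the
# primary main branch; each bifurcation of a main branch advances the order
# of its comparable-caliber daughters, thin protruding daughters are "small"
# branches of the parent's order, and everything beyond the second main
# bifurcation is grouped as tertiary.

BRANCH_CLASSES <- c("primary_main", "primary_small",
                    "secondary_main", "secondary_small", "tertiary")

BRANCH_CATEGORIES <- c("primary_total", "primary_main", "primary_small",
                       "secondary_total", "secondary_main", "secondary_small",
                       "tertiary")

#' Classify branch orders across a vessel network
#'
#' Roots (segments leaving the optic disc) are `primary_main`.  At a split of
#' a main branch, daughters thinner than `small_ratio_threshold` times the
#' parent's mean diameter are "small" protruding vessels of the parent's
#' order; when at least two daughters are of comparable caliber
#' (i.e. non-small) the split is a bifurcation and those daughters advance
#' one order; a split with exactly one non-small daughter continues the
#' parent's order.  Every segment downstream of the second main bifurcation
#' — and any descendant of a small branch — is `tertiary`.  A trifurcation is
#' treated as a single bifurcation event with all comparable daughters
#' advancing together (a note is emitted).
#'
#' @param network a `vessel_network` with `mean_diameter` set on every
#'   segment (see [measure_network_diameters()]).
#' @param small_ratio_threshold daughter/parent diameter ratio below which a
#'   daughter counts as a small protruding vessel (default 0.6).
#' @return the network with `branch_class` set on every segment.
#' @export
classify_branch_orders <- function(network, small_ratio_threshold = 0.6) {
  stopifnot(inherits(network, "vessel_network"))
  d <- vapply(network$segments, `[[`, numeric(1), "mean_diameter")
  if (any(is.na(d)))
    stop("mean_diameter missing on segments: ",
         paste(names(d)[is.na(d)], collapse = ", "),
         " - run measure_network_diameters() first")

  # state: order (1/2/3) and whether the segment sits on a main path
  order_of <- stats::setNames(rep(NA_integer_, length(network$segments)),
                              names(network$segments))
  main_of <- stats::setNames(rep(NA, length(network$segments)),
                             names(network$segments))
  class_of <- stats::setNames(rep(NA_character_, length(network$segments)),
                              names(network$segments))

  label <- function(id, ord, main) {
    order_of[[id]] <<- ord
    main_of[[id]] <<- main
    class_of[[id]] <<- if (ord >= 3L) "tertiary"
      else paste0(c("primary", "secondary")[ord], if (main) "_main" else "_small")
  }

  queue <- network$roots
  for (r in queue) label(r, 1L, TRUE)
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    kids <- network$children[[id]]
    if (!length(kids)) next
    ord <- order_of[[id]]; main <- main_of[[id]]
    if (ord >= 3L || !main) {
      # beyond the second main bifurcation, or off a small branch: tertiary
      for (k in kids) label(k, 3L, FALSE)
    } else {
      small <- d[kids] < small_ratio_threshold * d[[id]]
      n_comparable <- sum(!small)
      if (n_comparable >= 3L)
        message("segment '", id, "': trifurcation with ", n_comparable,
                " comparable daughters treated as one bifurcation event")
      for (k in kids[small]) label(k, ord, FALSE)
      if (n_comparable >= 2L) {
        for (k in kids[!small]) label(k, ord + 1L, TRUE)
      } else if (n_comparable == 1L) {
        label(kids[!small], ord, TRUE)
      }
    }
    queue <- c(queue, kids)
  }

  if (any(is.na(class_of)))
    stop("unrooted segments could not be classified: ",
         paste(names(class_of)[is.na(class_of)], collapse = ", "))
  for (id in names(class_of)) network$segments[[id]]$branch_class <- class_of[[id]]
  network
}

#' Aggregate segments into reporting categories
#'
#' For each vessel type, returns segment-id sets for the seven reporting
#' categories: primary and secondary totals (main plus small protruding
#' branches combined into one measurement), their main/small components, and
#' tertiary.
#'
#' @param network a classified `vessel_network`.
#' @return nested list: `result[[vessel_type]][[category]]` = character
#'   vector of segment ids (categories always present, possibly empty).
#' @export
aggregate_categories <- function(network) {
  cls <- vapply(network$segments, `[[`, character(1), "branch_class")
  if (any(is.na(cls)))
    stop("branch classes not assigned - run classify_branch_orders() first")
  types <- vapply(network$segments, `[[`, character(1), "vessel_type")
  out <- list()
  for (ty in c("artery", "vein")) {
    ids <- names(cls)[types == ty]
    byclass <- function(cl) ids[cls[ids] %in% cl]
    out[[ty]] <- list(
      primary_total   = byclass(c("primary_main", "primary_small")),
      primary_main    = byclass("primary_main"),
      primary_small   = byclass("primary_small"),
      secondary_total = byclass(c("secondary_main", "secondary_small")),
      secondary_main  = byclass("secondary_main"),
      secondary_small = byclass("secondary_small"),
      tertiary        = byclass("tertiary")
    )
  }
  out
}
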