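# Region-merging segmentation of the (A0, A1, A2) feature space into
# spatially contiguous phenological units.
#
# Heterogeneity model (per candidate merge of segments 1 and 2 into m):
#   dh_color = sum_b w_b * [ n_m sd_m,b - (n_1 sd_1,b + n_2 sd_2,b) ]
#   dh_shape = cw * dh_cmpct + (1 - cw) * dh_smooth
#     with compactness n * l / sqrt(n) and smoothness n * l / b
#     (l = 4-edge perimeter, b = bounding-box perimeter 2 * (w + h))
#   cost = (1 - sw) * dh_color + sw * dh_shape,  clamped at 0
# A merge is accepted while cost < scale^2. Standard deviations are
# population (n-weighted), maintained from running sums and
# sums-of-squares with negative-variance clamping.

#' Segmentation parameters
#'
#' Defaults are the reference parameterization for 250 m seasonal Fourier
#' images: scale 500, shape weight 0.2, compactness weight 0.8, minimum
#' unit size 25 pixels. On small synthetic scenes much smaller scales are
#' appropriate (the threshold is scale^2 on the heterogeneity increase).
#'
#' @param scale dimensionless scale parameter (> 0); merges are accepted
#'   while the heterogeneity increase stays below `scale^2`.
#' @param shape_weight weight of the shape criterion in `[0, 1]`.
#' @param compactness_weight weight of compactness (vs smoothness) within
#'   the shape criterion, in `[0, 1]`.
#' @param band_weights nonnegative per-band weights (default equal).
#' @param min_pixels minimum unit size enforced by [enforce_min_size()].
#' @param connectivity 4 (edge-adjacency, default) or 8.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(scale = 500, shape_weight = 0.2,
                       compactness_weight = 0.8,
                       band_weights = c(1, 1, 1),
                       min_pixels = 25, connectivity = 4) {
  stopifnot(scale > 0,
            shape_weight >= 0, shape_weight <= 1,
            compactness_weight >= 0, compactness_weight <= 1,
            all(band_weights >= 0), any(band_weights > 0),
            min_pixels >= 1, connectivity %in% c(4, 8))
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight,
                 band_weights = band_weights,
                 min_pixels = as.integer(min_pixels),
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

#' Segment running state from its member pixels
#'
#' Builds the running statistics (pixel count, per-band sum and
#' sum-of-squares, 4-edge perimeter, bounding box) that [merge_cost()]
#' consumes, directly from raw pixel values and coordinates. Used as the
#' explicit (brute-force) route to the statistics the merger maintains
#' incrementally.
#'
#' @param values numeric matrix, one row per member pixel, one column per
#'   band.
#' @param coords integer matrix of the same row count with columns
#'   `row`, `col`.
#' @return list of class `segment_state`.
#' @export
segment_state <- function(values, coords) {
  values <- rbind(values); coords <- rbind(coords)
  stopifnot(nrow(values) == nrow(coords), ncol(coords) == 2)
  n <- nrow(values)
  key <- paste(coords[, 1], coords[, 2])
  nbr <- c(paste(coords[, 1] + 1L, coords[, 2]),
           paste(coords[, 1], coords[, 2] + 1L))
  internal <- sum(nbr %in% key)
  structure(list(n = n,
                 sum = colSums(values),
                 sumsq = colSums(values^2),
                 l = 4L * n - 2L * internal,
                 bbox = c(minr = min(coords[, 1]), maxr = max(coords[, 1]),
                          minc = min(coords[, 2]), maxc = max(coords[, 2]))),
            class = "segment_state")
}

pop_sd_term <- function(s, ss, n) {
  v <- ss / n - (s / n)^2
  n * sqrt(pmax(v, 0))
}

#' Heterogeneity increase of merging two adjacent segments
#'
#' @param s1,s2 [segment_state()] objects.
#' @param params [seg_params()].
#' @param shared_edges number of pixel edges shared by the two segments
#'   (>= 1 for edge-adjacent segments; 0 encodes diagonal-only adjacency
#'   under 8-connectivity).
#' @return nonnegative merge cost (dimensionless).
#' @export
merge_cost <- function(s1, s2, params, shared_edges = 1L) {
  stopifnot(inherits(s1, "segment_state"), inherits(s2, "segment_state"),
            inherits(params, "seg_params"))
  if (shared_edges < 1L && params$connectivity == 4L)
    stop("segments are not adjacent (no shared pixel edge)")
  w <- params$band_weights
  nm <- s1$n + s2$n
  d_color <- sum(w * (pop_sd_term(s1$sum + s2$sum, s1$sumsq + s2$sumsq, nm) -
                      pop_sd_term(s1$sum, s1$sumsq, s1$n) -
                      pop_sd_term(s2$sum, s2$sumsq, s2$n)))
  d_shape <- 0
  if (params$shape_weight > 0) {
    lm <- s1$l + s2$l - 2L * shared_edges
    cmp <- function(n, l) sqrt(n) * l
    bbp <- function(b) 2 * ((b["maxc"] - b["minc"] + 1) +
                            (b["maxr"] - b["minr"] + 1))
    bb_m <- c(minr = min(s1$bbox["minr"], s2$bbox["minr"]),
              maxr = max(s1$bbox["maxr"], s2$bbox["maxr"]),
              minc = min(s1$bbox["minc"], s2$bbox["minc"]),
              maxc = max(s1$bbox["maxc"], s2$bbox["maxc"]))
    names(bb_m) <- c("minr", "maxr", "minc", "maxc")
    smo <- function(n, l, b) n * l / b
    d_cmpct <- cmp(nm, lm) - cmp(s1$n, s1$l) - cmp(s2$n, s2$l)
    d_smooth <- smo(nm, lm, bbp(bb_m)) - smo(s1$n, s1$l, bbp(s1$bbox)) -
      smo(s2$n, s2$l, bbp(s2$bbox))
    d_shape <- params$compactness_weight * d_cmpct +
      (1 - params$compactness_weight) * d_smooth
  }
  unname(max((1 - params$shape_weight) * d_color +
             params$shape_weight * d_shape, 0))
}

#' Segment a Fourier image into phenological units
#'
#' Iterative local mutual-best-fitting merging: starting from single-pixel
#' segments, each pass visits the live segments in ascending-id order and a
#' segment merges with its minimum-cost neighbor only if the choice is
#' mutual and the cost is below `scale^2` (ties to the lower neighbor id);
#' passes repeat until no merge occurs. Nodata pixels are excluded and
#' never bridged. With `enforce_min = TRUE` the minimum-size cleanup of
#' [enforce_min_size()] is applied afterwards.
#'
#' @param image a `fourier_image` (or any nrow x ncol x B numeric array
#'   with a `grid` attribute).
#' @param params [seg_params()].
#' @param enforce_min apply the minimum-size cleanup (default TRUE).
#' @return a `seg_labels`: integer [pheno_grid()] of unit ids (contiguous
#'   from 1; `NA` = nodata) with a `units` attribute, the per-unit summary
#'   table of [unit_features()].
#' @export
segment_image <- function(image, params = seg_params(), enforce_min = TRUE) {
  stopifnot(inherits(params, "seg_params"))
  g <- attr(image, "grid")
  if (is.null(g)) stop("image lacks a `grid` attribute")
  vals <- matrix(as.vector(unclass(image)), g$nrow * g$ncol,
                 dim(image)[3])
  if (length(params$band_weights) != ncol(vals))
    stop("band_weights length does not match band count")
  if (!any(stats::complete.cases(vals))) stop("no valid pixels")
  res <- fnea_merge_cpp(vals, g$nrow, g$ncol,
                        params$scale, params$shape_weight,
                        params$compactness_weight,
                        as.numeric(params$band_weights),
                        params$connectivity)
  lab0 <- res$labels0
  lab <- match(lab0, sort(unique(lab0[lab0 >= 0L])))   # contiguous from 1
  lab[lab0 < 0L] <- NA_integer_
  m <- matrix(as.integer(lab), g$nrow, g$ncol)
  out <- pheno_grid(m, xll = g$xll, yll = g$yll, cellsize = g$cellsize)
  out <- label_with_units(out, image)
  attr(out, "audit") <- res[c("seg_id", "seg_n", "seg_l",
                              "seg_sum", "seg_sumsq")]
  if (enforce_min) out <- enforce_min_size(out, image, params)
  out
}

label_with_units <- function(labels, image) {
  attr(labels, "units") <- unit_features(labels, image)
  class(labels) <- unique(c("seg_labels", class(labels)))
  labels
}

#' @export
print.seg_labels <- function(x, ...) {
  u <- attr(x, "units")
  cat(sprintf("<seg_labels> %d unit(s) over %d valid pixel(s)\n",
              nrow(u), sum(!is.na(x))))
  cat(sprintf("  unit size: %d-%d pixels (median %g)\n",
              min(u$n_pixels), max(u$n_pixels),
              stats::median(u$n_pixels)))
  invisible(x)
}

# unordered adjacency pairs of a label matrix (4-connectivity)
unit_adjacency <- function(m) {
  a <- c(m[-nrow(m), ], m[, -ncol(m)])
  b <- c(m[-1, ], m[, -1])
  keep <- !is.na(a) & !is.na(b) & a != b
  if (!any(keep)) return(matrix(integer(), 0, 2))
  unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
}

#' Absorb undersized units into their most similar neighbor
#'
#' While any unit has fewer than `min_pixels` member pixels, the smallest
#' such unit (ties to the lower id) is merged into the edge-adjacent unit
#' with the minimal color-heterogeneity increase (shape ignored, ties to
#' the lower id). Idempotent on conforming inputs; an isolated undersized
#' unit with no neighbor is left in place with a warning.
#'
#' @param labels a `seg_labels` from [segment_image()].
#' @param image the Fourier image the labels were derived from.
#' @param params [seg_params()]; only `band_weights` and `min_pixels` are
#'   used.
#' @return relabeled `seg_labels` with every unit of size >= `min_pixels`.
#' @export
enforce_min_size <- function(labels, image, params = seg_params()) {
  m <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  vals <- matrix(as.vector(unclass(image)), length(m), dim(image)[3])
  w <- params$band_weights
  ids <- sort(unique(m[!is.na(m)]))
  grp <- split(which(!is.na(m)), m[!is.na(m)])  # member pixels per unit
  stat <- lapply(grp, function(px)
    list(n = length(px), sum = colSums(vals[px, , drop = FALSE]),
         sumsq = colSums(vals[px, , drop = FALSE]^2)))
  pairs <- unit_adjacency(m)
  adj <- lapply(ids, function(i)
    sort(c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])))
  names(adj) <- ids
  merged_into <- stats::setNames(ids, ids)     # final unit of each input id
  repeat {
    n_all <- vapply(stat, `[[`, 0, "n")
    small <- names(stat)[n_all < params$min_pixels]
    if (!length(small)) break
    tgt <- small[which.min(n_all[small])]
    nbrs <- adj[[tgt]]
    if (!length(nbrs)) {
      warning("unit ", tgt, " is undersized but has no neighbor; kept")
      break
    }
    s1 <- stat[[tgt]]
    dcol <- vapply(as.character(nbrs), function(j) {
      s2 <- stat[[j]]
      sum(w * (pop_sd_term(s1$sum + s2$sum, s1$sumsq + s2$sumsq,
                           s1$n + s2$n) -
               pop_sd_term(s1$sum, s1$sumsq, s1$n) -
               pop_sd_term(s2$sum, s2$sumsq, s2$n)))
    }, numeric(1))
    into <- as.character(nbrs[which.min(dcol)])
    stat[[into]] <- list(n = stat[[into]]$n + s1$n,
                         sum = stat[[into]]$sum + s1$sum,
                         sumsq = stat[[into]]$sumsq + s1$sumsq)
    stat[[tgt]] <- NULL
    adj[[into]] <- sort(setdiff(union(adj[[into]], adj[[tgt]]),
                                as.integer(c(tgt, into))))
    for (k in as.character(adj[[tgt]]))
      if (k != into)
        adj[[k]] <- sort(union(setdiff(adj[[k]], as.integer(tgt)),
                               as.integer(into)))
    adj[[tgt]] <- NULL
    merged_into[merged_into == as.integer(tgt)] <- as.integer(into)
  }
  new_ids <- sort(as.integer(names(stat)))
  m2 <- matrix(match(merged_into[as.character(m)], new_ids),
               nrow(m), ncol(m))
  out <- pheno_grid(m2, xll = attr(labels, "xll"), yll = attr(labels, "yll"),
                    cellsize = attr(labels, "cellsize"))
  label_with_units(out, image)
}
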