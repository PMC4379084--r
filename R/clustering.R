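# Grouping phenological units into phenological fuel classes (PFCs):
# UPGMA (average linkage) on Euclidean distances over the unit-mean Fourier
# components, a dendrogram cut at k groups, and an optional spatial split of
# the largest class.

#' Per-unit summary of a segmentation
#'
#' @param labels a `seg_labels` (or integer label [pheno_grid()]).
#' @param fourier the co-registered `fourier_image`.
#' @return data.frame with one row per unit: `unit_id`, `n_pixels`,
#'   `area_km2`, `mean_A0`, `mean_A1`, `mean_A2`, `x`, `y` (centroid of
#'   pixel centers, map units).
#' @export
unit_features <- function(labels, fourier) {
  g <- attr(fourier, "grid")
  tl <- grid_template(labels)
  if (!isTRUE(all.equal(tl[c("xll", "yll", "cellsize", "nrow", "ncol")],
                        g[c("xll", "yll", "cellsize", "nrow", "ncol")],
                        tolerance = 1e-9)))
    stop("labels and Fourier image are not co-registered")
  lab <- as.vector(unclass(labels))
  fm <- fourier_matrix(fourier)
  ids <- sort(unique(lab[!is.na(lab)]))
  xy <- xy_from_cell(labels)
  rows <- lapply(ids, function(i) {
    px <- which(!is.na(lab) & lab == i)
    if (!length(px)) stop("unit ", i, " has zero pixels")
    v <- fm[px, , drop = FALSE]
    if (anyNA(v)) stop("unit ", i, " covers masked Fourier pixels")
    means <- as.data.frame(t(colMeans(v)))
    names(means) <- paste0("mean_", colnames(fm))
    cbind(data.frame(unit_id = i, n_pixels = length(px),
                     area_km2 = length(px) * cell_area_km2(labels)),
          means,
          data.frame(x = mean(xy$x[px]), y = mean(xy$y[px])))
  })
  do.call(rbind, rows)
}

#' UPGMA linkage of units in Fourier feature space
#'
#' Unweighted pair-group average linkage on Euclidean distances over
#' `(mean_A0, mean_A1, mean_A2)`. Features may optionally be z-scored
#' first; the default leaves them on the NDVI scale so the additive term
#' and the amplitudes enter with their natural magnitudes.
#'
#' @param features a [unit_features()] table (>= 2 units, finite means).
#' @param standardize z-score each feature column before the distance
#'   (default FALSE).
#' @return an object of classes `pheno_linkage` and `hclust`; heights are
#'   average inter-cluster Euclidean distances, labels are unit ids.
#'   [stats::cophenetic()] applies.
#' @export
upgma_linkage <- function(features, standardize = FALSE) {
  X <- as.matrix(features[, c("mean_A0", "mean_A1", "mean_A2")])
  if (nrow(X) < 2L) stop("need at least 2 units to cluster")
  if (any(!is.finite(X))) stop("non-finite unit features")
  if (standardize) X <- scale(X)
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "average")
  hc$labels <- as.character(features$unit_id)
  class(hc) <- c("pheno_linkage", "hclust")
  hc
}

#' @export
print.pheno_linkage <- function(x, ...) {
  cat(sprintf("<pheno_linkage> UPGMA over %d unit(s); merge heights [%g, %g]\n",
              length(x$order), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut the dendrogram into phenological fuel classes
#'
#' Removes the k-1 highest merges and labels the resulting clusters
#' `PFC1..PFCk` in order of decreasing mean seasonal amplitude (`mean_A1`
#' averaged over member units), so PFC1 is the most seasonal class.
#'
#' @param tree a [upgma_linkage()] result.
#' @param k number of classes, `1 <= k <= n_units`.
#' @param features the [unit_features()] table used to build the tree.
#' @return a `pfc_assignment`: data.frame `unit_id`, `pfc` (factor
#'   `PFC1..PFCk`), with per-class area summary in attribute `classes`.
#' @export
cut_to_classes <- function(tree, k, features) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  grp <- stats::cutree(tree, k = k)
  grp <- grp[as.character(features$unit_id)]
  a1 <- tapply(features$mean_A1, grp, mean)
  ord <- order(-a1)                       # most seasonal first
  rank <- match(grp, as.integer(names(a1))[ord])
  lab <- factor(paste0("PFC", rank), levels = paste0("PFC", seq_len(k)))
  out <- data.frame(unit_id = features$unit_id, pfc = lab)
  class(out) <- c("pfc_assignment", "data.frame")
  attr(out, "classes") <- class_summary(out, features)
  out
}

class_summary <- function(assignment, features) {
  sp <- split(features, assignment$pfc)
  do.call(rbind, lapply(names(sp), function(g) data.frame(
    pfc = g, n_units = nrow(sp[[g]]),
    area_km2 = sum(sp[[g]]$area_km2),
    mean_A0 = stats::weighted.mean(sp[[g]]$mean_A0, sp[[g]]$n_pixels),
    mean_A1 = stats::weighted.mean(sp[[g]]$mean_A1, sp[[g]]$n_pixels),
    mean_A2 = stats::weighted.mean(sp[[g]]$mean_A2, sp[[g]]$n_pixels))))
}

#' @export
print.pfc_assignment <- function(x, ...) {
  cs <- attr(x, "classes")
  cat(sprintf("<pfc_assignment> %d unit(s) in %d class(es)\n",
              nrow(x), nrow(cs)))
  print(cs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Split the largest class into two spatial subgroups
#'
#' A surrogate for an expert-knowledge subdivision of the largest (by
#' area) class: 2-means on unit centroids (50 restarts under a fixed
#' seed), with subgroup `a` the one whose units sit closer on average to
#' the convex hull of the scene's unit centroids (a coastal-proximity
#' proxy) and `b` the inner one. Other classes are untouched; the split
#' class labels become e.g. `PFC2a`/`PFC2b`.
#'
#' @param assignment a [cut_to_classes()] result.
#' @param features the matching [unit_features()] table.
#' @param seed RNG seed for the k-means restarts.
#' @return a new `pfc_assignment` with k+1 labels.
#' @export
split_largest_spatial <- function(assignment, features, seed = 1L) {
  cs <- attr(assignment, "classes")
  big <- cs$pfc[which.max(cs$area_km2)]
  members <- assignment$unit_id[assignment$pfc == big]
  if (length(members) < 2L)
    stop("largest class ", big, " has a single unit; nothing to split")
  idx <- match(members, features$unit_id)
  P <- as.matrix(features[idx, c("x", "y")])
  if (all(apply(P, 2, stats::sd) == 0))
    stop("all unit centroids of ", big, " coincide; split is degenerate")
  set.seed(seed)
  km <- stats::kmeans(P, centers = 2, nstart = 50)
  hull <- grDevices::chull(features$x, features$y)
  hx <- features$x[hull]; hy <- features$y[hull]
  edge_dist <- function(px, py) {
    # min distance from point to the hull boundary segments
    n <- length(hx)
    d <- vapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      vx <- hx[j] - hx[i]; vy <- hy[j] - hy[i]
      tt <- ((px - hx[i]) * vx + (py - hy[i]) * vy) / (vx^2 + vy^2)
      tt <- min(max(tt, 0), 1)
      sqrt((px - hx[i] - tt * vx)^2 + (py - hy[i] - tt * vy)^2)
    }, numeric(1))
    min(d)
  }
  dmean <- vapply(1:2, function(g) {
    pts <- P[km$cluster == g, , drop = FALSE]
    mean(vapply(seq_len(nrow(pts)),
                function(r) edge_dist(pts[r, 1], pts[r, 2]), numeric(1)))
  }, numeric(1))
  sub <- ifelse(km$cluster == which.min(dmean), "a", "b")
  lab <- as.character(assignment$pfc)
  lab[assignment$pfc == big] <- paste0(big, sub)
  lv <- unique(lab[order(lab)])
  out <- data.frame(unit_id = assignment$unit_id,
                    pfc = factor(lab, levels = lv))
  class(out) <- c("pfc_assignment", "data.frame")
  attr(out, "classes") <- class_summary(out, features)
  attr(out, "split") <- list(class = as.character(big), seed = seed,
                             withinss = sum(km$withinss))
  out
}

#' Rasterize a class assignment
#'
#' @param labels the `seg_labels` the assignment refers to.
#' @param assignment a `pfc_assignment`.
#' @return integer [pheno_grid()] of class indices (levels of
#'   `assignment$pfc`), with the level table in attribute `pfc_levels`.
#' @export
pfc_raster <- function(labels, assignment) {
  idx <- match(as.vector(unclass(labels)), assignment$unit_id)
  m <- matrix(as.integer(assignment$pfc)[idx], nrow(labels), ncol(labels))
  out <- pheno_grid(m, xll = attr(labels, "xll"), yll = attr(labels, "yll"),
                    cellsize = attr(labels, "cellsize"))
  attr(out, "pfc_levels") <- levels(assignment$pfc)
  out
}
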