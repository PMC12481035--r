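#' DBSCAN cluster labels for 2D points
#'
#' Density-based spatial clustering with the conventions used throughout
#' this package: a point is a core point when at least `min_pts` points
#' (itself included) lie within `radius` of it, with an inclusive distance
#' test (`d <= radius`); clusters are the connected components of core
#' points, plus border points; a border point reachable from several
#' clusters is assigned to the cluster of its lowest-index core neighbor.
#' Labels are renumbered so cluster 1 contains the lowest-index core
#' point, which makes the output deterministic and independent of row
#' order up to that tie rule. Neighbor queries go through a uniform-grid
#' spatial index; results are exact.
#'
#' @param x,y point coordinates, nm (finite).
#' @param radius neighborhood radius, nm.
#' @param min_pts core-point threshold, counting the point itself.
#' @return Integer vector of cluster labels; `0` marks noise.
#' @export
dbscan_labels <- function(x, y, radius, min_pts) {
  stopifnot(length(x) == length(y))
  stop_if_not_number(radius, "radius", min = .Machine$double.eps)
  stop_if_not_number(min_pts, "min_pts", min = 1)
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  idx <- grid_index(x, y, cell = radius)
  nbrs <- lapply(seq_len(n), function(i) grid_neighbors(idx, i, radius))
  is_core <- lengths(nbrs) >= min_pts
  labels <- integer(n)                 # 0 = unassigned / noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (!is_core[k] || labels[k] != 0L) next
        labels[k] <- cl
        queue <- c(queue, k)
      }
    }
  }
  # border points: lowest-index core neighbor decides the cluster
  for (i in seq_len(n)) {
    if (is_core[i] || labels[i] != 0L) next
    core_nb <- nbrs[[i]][is_core[nbrs[[i]]]]
    if (length(core_nb)) labels[i] <- labels[min(core_nb)]
  }
  labels
}
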