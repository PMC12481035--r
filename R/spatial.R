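#' Nearest-neighbor distances between trace centers
#'
#' Exact Euclidean distance from every center to its closest other center.
#' The search runs on a uniform-grid spatial index with an expanding-ring
#' strategy; results are contractually identical to exhaustive search.
#'
#' @param centers a `trace_centers` data.frame (or anything with `x_nm`,
#'   `y_nm` columns).
#' @return Numeric vector of nearest-neighbor distances, nm, in row order.
#' @export
nearest_neighbor_distances <- function(centers) {
  df <- as.data.frame(centers)
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 centers for nearest-neighbor analysis",
                   call. = FALSE)
  span <- max(diff(range(df$x_nm)), diff(range(df$y_nm)))
  cell <- max(span / max(1, ceiling(sqrt(n))), 1e-9)
  idx <- grid_index(df$x_nm, df$y_nm, cell = cell)
  grid_nn(idx)$dist
}

new_pair_set <- function(pairs, search_radius) {
  d <- pairs$distance_nm
  structure(list(
    pairs = pairs,
    search_radius = search_radius,
    summary = list(count = nrow(pairs),
                   mean_nm = if (length(d)) mean(d) else NA_real_,
                   median_nm = if (length(d)) stats::median(d) else NA_real_,
                   sd_nm = if (length(d) > 1L) stats::sd(d) else NA_real_,
                   distances_nm = d)),
    class = "pair_set")
}

#' Detect isolated pairs of trace centers
#'
#' Runs DBSCAN with `min_pts = 2` at the search radius and keeps exactly
#' the clusters of size 2. By DBSCAN chaining, a size-2 cluster already
#' implies that no third center lies within the search radius of either
#' member — the two centers are mutual nearest neighbors in an empty
#' neighborhood. That isolation property is re-verified on every detected
#' pair (a violation is a programming error and stops), and the distance
#' from the pair to its third-nearest center is recorded alongside the
#' exact member separation.
#'
#' @param centers a `trace_centers` data.frame.
#' @param search_radius pair search radius, nm (default 40).
#' @return A `pair_set`: list with `pairs` (data.frame `id_a,id_b,
#'   distance_nm,mid_x_nm,mid_y_nm,third_nn_nm` and member coordinates)
#'   and `summary` (count, mean, median, sd, full distance list).
#' @export
find_isolated_pairs <- function(centers, search_radius = 40) {
  df <- as.data.frame(centers)
  stop_if_not_number(search_radius, "search_radius", min = .Machine$double.eps)
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      distance_nm = numeric(0), mid_x_nm = numeric(0),
                      mid_y_nm = numeric(0), third_nn_nm = numeric(0),
                      ax_nm = numeric(0), ay_nm = numeric(0),
                      bx_nm = numeric(0), by_nm = numeric(0))
  if (nrow(df) < 2L) return(new_pair_set(empty, search_radius))
  lab <- dbscan_labels(df$x_nm, df$y_nm, radius = search_radius, min_pts = 2L)
  sizes <- tabulate(lab)
  twos <- which(sizes == 2L)
  if (!length(twos)) return(new_pair_set(empty, search_radius))
  rows <- lapply(twos, function(cl) {
    m <- which(lab == cl)
    a <- m[1]; b <- m[2]
    dist_ab <- sqrt((df$x_nm[a] - df$x_nm[b])^2 + (df$y_nm[a] - df$y_nm[b])^2)
    others <- setdiff(seq_len(nrow(df)), m)
    third <- if (length(others)) {
      min(sqrt(pmin((df$x_nm[others] - df$x_nm[a])^2 +
                      (df$y_nm[others] - df$y_nm[a])^2,
                    (df$x_nm[others] - df$x_nm[b])^2 +
                      (df$y_nm[others] - df$y_nm[b])^2)))
    } else Inf
    stopifnot(dist_ab <= search_radius, third > search_radius)
    data.frame(id_a = df$trace_id[a], id_b = df$trace_id[b],
               distance_nm = dist_ab,
               mid_x_nm = (df$x_nm[a] + df$x_nm[b]) / 2,
               mid_y_nm = (df$y_nm[a] + df$y_nm[b]) / 2,
               third_nn_nm = third,
               ax_nm = df$x_nm[a], ay_nm = df$y_nm[a],
               bx_nm = df$x_nm[b], by_nm = df$y_nm[b])
  })
  new_pair_set(do.call(rbind, rows), search_radius)
}

#' @export
print.pair_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Isolated pairs (radius %g nm): %d pairs", x$search_radius,
              s$count))
  if (s$count) {
    cat(sprintf("; distance mean %.2f, median %.2f, sd %s nm",
                s$mean_nm, s$median_nm,
                if (is.na(s$sd_nm)) "NA" else sprintf("%.2f", s$sd_nm)))
  }
  cat("\n")
  invisible(x)
}

#' Cluster-analysis parameters
#'
#' @param search_radius DBSCAN radius, nm (default 40).
#' @param min_cluster_size minimum members per reported cluster (default
#'   4; also used as the DBSCAN `min_pts`).
#' @export
cluster_params <- function(search_radius = 40, min_cluster_size = 4L) {
  stop_if_not_number(search_radius, "search_radius", min = .Machine$double.eps)
  stop_if_not_number(min_cluster_size, "min_cluster_size", min = 2)
  structure(list(search_radius = search_radius,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Characterize multi-center clusters
#'
#' DBSCAN with `min_pts = min_cluster_size` at the search radius; every
#' component with at least `min_cluster_size` members is reported with its
#' composition (member count), size (maximum pairwise member distance,
#' nm), convex-hull area (nm^2), and density (composition / area).
#' Collinear or duplicate member sets have no hull area; they fall back to
#' a 1-nm-wide ribbon (`area = size * 1 nm`) and are flagged `degenerate`.
#'
#' @param centers a `trace_centers` data.frame.
#' @param params a [cluster_params()].
#' @return A `cluster_set`: list with `clusters` (one row per cluster) and
#'   `summary` (count and mean composition/size/density).
#' @export
cluster_analysis <- function(centers, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  df <- as.data.frame(centers)
  empty <- data.frame(cluster = integer(0), composition = integer(0),
                      size_nm = numeric(0), area_nm2 = numeric(0),
                      density_per_nm2 = numeric(0), degenerate = logical(0),
                      centroid_x_nm = numeric(0), centroid_y_nm = numeric(0))
  lab <- if (nrow(df)) {
    dbscan_labels(df$x_nm, df$y_nm, radius = params$search_radius,
                  min_pts = params$min_cluster_size)
  } else integer(0)
  keep <- which(tabulate(lab) >= params$min_cluster_size)
  rows <- lapply(seq_along(keep), function(k) {
    m <- which(lab == keep[k])
    x <- df$x_nm[m]; y <- df$y_nm[m]
    dmax <- max(stats::dist(cbind(x, y)))
    hull <- grDevices::chull(x, y)
    area <- polygon_area(x[hull], y[hull])
    degen <- area <= .Machine$double.eps * max(1, dmax^2)
    if (degen) area <- dmax * 1       # 1-nm ribbon fallback
    data.frame(cluster = k, composition = length(m), size_nm = dmax,
               area_nm2 = area,
               density_per_nm2 = if (area > 0) length(m) / area else NA_real_,
               degenerate = degen,
               centroid_x_nm = mean(x), centroid_y_nm = mean(y),
               members = I(list(df$trace_id[m])))
  })
  cl <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(
    clusters = cl,
    params = unclass(params),
    summary = list(count = nrow(cl),
                   mean_composition = if (nrow(cl)) mean(cl$composition) else NA_real_,
                   mean_size_nm = if (nrow(cl)) mean(cl$size_nm) else NA_real_,
                   mean_density_per_nm2 = if (nrow(cl)) mean(cl$density_per_nm2) else NA_real_)),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Clusters (radius %g nm, min size %d): %d clusters",
              x$params$search_radius, x$params$min_cluster_size, s$count))
  if (s$count) {
    cat(sprintf("; mean composition %.2f, mean size %.1f nm",
                s$mean_composition, s$mean_size_nm))
  }
  cat("\n")
  invisible(x)
}

#' Compare per-cell statistics between two conditions
#'
#' Two-sided Mann-Whitney U test. With 8 or fewer observations per group
#' and no ties the p-value is exact (full enumeration of the U null
#' distribution); otherwise a normal approximation with tie correction and
#' continuity correction is used. U counts, over all cross-condition
#' pairs, how often a value from `sample_a` exceeds one from `sample_b`
#' (ties count 1/2), so swapping the samples maps U to `n1*n2 - U`.
#'
#' @param sample_a,sample_b numeric vectors of per-cell statistics.
#' @return List with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), and the group sizes.
#' @export
compare_conditions <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n1 <= 8L && n2 <= 8L && !ties) {
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(a, b))
    N <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(0, z)))
    }
    method <- "normal_approx"
  }
  list(U = U, p_value = p, method = method, n = c(n1, n2))
}
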