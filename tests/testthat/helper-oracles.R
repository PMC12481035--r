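# Independent brute-force references used to validate the package's
# spatial-index implementations, plus small fixture builders.

# O(n^2) DBSCAN over a full distance matrix.  Written independently of the
# package: region queries by matrix row, components by iterative flood
# fill over core points, border points assigned to the cluster of their
# lowest-index core neighbor.
bf_dbscan <- function(x, y, radius, min_pts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= radius))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i]) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        for (k in nb[[j]]) {
          if (core[k] && !labels[k]) { labels[k] <- cl; nxt <- c(nxt, k) }
        }
      }
      frontier <- nxt
    }
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i]) next
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Renumber cluster labels by first appearance so two labelings of the same
# partition compare equal; noise (0) is kept as 0.
canon_labels <- function(lab) {
  pos <- lab != 0L
  u <- unique(lab[pos])
  out <- lab
  out[pos] <- match(lab[pos], u)
  out
}

# Exhaustive nearest-neighbor distances.
bf_nn <- function(x, y) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  diag(D) <- Inf
  apply(D, 1, min)
}

# Row-by-row reference for the localization quality filter.
bf_filter <- function(df, efo_max, cfr_max, min_locs) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$efo_hz[i] > efo_max || df$cfr[i] > cfr_max) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  for (id in unique(df$trace_id)) {
    if (sum(df$trace_id == id) < min_locs) df <- df[df$trace_id != id, , drop = FALSE]
  }
  df
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (valid only without ties).
enum_mw <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  u_stat <- function(ia) {
    aa <- vals[ia]; bb <- vals[-ia]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  p <- 2 * min(mean(all_u <= obs), mean(all_u >= obs))
  list(U = obs, p = min(1, p))
}

# Direct-count Ripley K (no edge correction).
bf_ripley_k <- function(x, y, radii, area) {
  n <- length(x)
  vapply(radii, function(r) {
    cnt <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) cnt <- cnt + 1L
      }
    }
    area / (n * (n - 1)) * cnt
  }, numeric(1))
}

# Ground truth holding only dimers on a regular grid (spacing apart, so
# each pair is isolated); partner direction random under the current RNG.
grid_dimer_truth <- function(cfg, n_dimers, spacing = 250) {
  nx <- ceiling(sqrt(n_dimers))
  anchors <- expand.grid(x = seq_len(nx), y = seq_len(nx))[seq_len(n_dimers), ]
  ax <- anchors$x * spacing
  ay <- anchors$y * spacing
  th <- stats::runif(n_dimers, 0, 2 * pi)
  px <- ax + cfg$pair_separation_d * cos(th)
  py <- ay + cfg$pair_separation_d * sin(th)
  mol <- data.frame(
    mol_id = seq_len(2L * n_dimers),
    x_nm = c(rbind(ax, px)), y_nm = c(rbind(ay, py)),
    class = "dimer", group_id = rep(seq_len(n_dimers), each = 2L),
    labeled = stats::runif(2L * n_dimers) < cfg$label_efficiency_p)
  structure(list(molecules = mol,
                 bounds = c(xmin = 0, xmax = (nx + 1) * spacing,
                            ymin = 0, ymax = (nx + 1) * spacing),
                 config = cfg),
            class = "ground_truth")
}

random_loc_table <- function(n, n_traces = max(1L, n %/% 5L)) {
  loc_table(data.frame(
    trace_id = sample(seq_len(n_traces), n, replace = TRUE),
    time = seq_len(n) * 1e-3,
    x_nm = stats::runif(n, 0, 1000),
    y_nm = stats::runif(n, 0, 1000),
    efo_hz = stats::runif(n, 0, 1e5),
    cfr = stats::runif(n, 0, 1.5)))
}
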