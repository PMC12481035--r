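# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_if_not_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# Truncated-at-1 Poisson sampler; mean is lambda / (1 - exp(-lambda)).
rtpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  if (lambda <= 0) return(rep.int(1L, n))
  u <- stats::runif(n, min = stats::ppois(0, lambda), max = 1)
  pmax(1L, stats::qpois(u, lambda))
}

# Uniform-grid spatial index over 2D points.  Bucket size >= some positive
# cell width; used for fixed-radius neighbor queries and nearest-neighbor
# search.  Results are exact (candidates are verified by distance).
grid_index <- function(x, y, cell) {
  stopifnot(length(x) == length(y), cell > 0)
  x0 <- if (length(x)) min(x) else 0
  y0 <- if (length(y)) min(y) else 0
  cx <- as.integer(floor((x - x0) / cell))
  cy <- as.integer(floor((y - y0) / cell))
  key <- paste(cx, cy, sep = ",")
  buckets <- split(seq_along(x), key)
  list(x = x, y = y, cell = cell, x0 = x0, y0 = y0,
       cx = cx, cy = cy, buckets = buckets)
}

grid_bucket <- function(idx, cx, cy) {
  idx$buckets[[paste(cx, cy, sep = ",")]]
}

# Indices of all points within `radius` (inclusive) of point i, including i.
grid_neighbors <- function(idx, i, radius) {
  span <- as.integer(ceiling(radius / idx$cell))
  cand <- integer(0)
  for (dx in -span:span) {
    for (dy in -span:span) {
      b <- grid_bucket(idx, idx$cx[i] + dx, idx$cy[i] + dy)
      if (!is.null(b)) cand <- c(cand, b)
    }
  }
  d2 <- (idx$x[cand] - idx$x[i])^2 + (idx$y[cand] - idx$y[i])^2
  sort(cand[d2 <= radius^2])
}

# Nearest other point for each point, via expanding ring search on the grid.
# Exact: search stops only when no unexplored cell can beat the best found.
grid_nn <- function(idx) {
  n <- length(idx$x)
  out_d <- numeric(n)
  out_i <- integer(n)
  for (i in seq_len(n)) {
    best_d2 <- Inf
    best_j <- NA_integer_
    ring <- 0L
    repeat {
      lo <- (ring - 1L) * idx$cell          # min distance to a ring-`ring` cell
      if (ring > 0L && is.finite(best_d2) && lo > 0 && lo^2 > best_d2) break
      cells <- if (ring == 0L) {
        list(c(idx$cx[i], idx$cy[i]))
      } else {
        cs <- list()
        for (dx in -ring:ring) {
          cs[[length(cs) + 1L]] <- c(idx$cx[i] + dx, idx$cy[i] - ring)
          cs[[length(cs) + 1L]] <- c(idx$cx[i] + dx, idx$cy[i] + ring)
        }
        if (ring > 1L) {
          for (dy in (-ring + 1L):(ring - 1L)) {
            cs[[length(cs) + 1L]] <- c(idx$cx[i] - ring, idx$cy[i] + dy)
            cs[[length(cs) + 1L]] <- c(idx$cx[i] + ring, idx$cy[i] + dy)
          }
        } else {
          cs[[length(cs) + 1L]] <- c(idx$cx[i] - ring, idx$cy[i])
          cs[[length(cs) + 1L]] <- c(idx$cx[i] + ring, idx$cy[i])
        }
        cs
      }
      for (cc in cells) {
        b <- grid_bucket(idx, cc[1], cc[2])
        if (is.null(b)) next
        for (j in b) {
          if (j == i) next
          d2 <- (idx$x[j] - idx$x[i])^2 + (idx$y[j] - idx$y[i])^2
          if (d2 < best_d2) { best_d2 <- d2; best_j <- j }
        }
      }
      ring <- ring + 1L
      if (ring > 4L && !is.finite(best_d2)) {
        # sparse pattern: widen aggressively rather than cell-by-cell
        span <- diff(range(idx$x)) + diff(range(idx$y)) + idx$cell
        if ((ring - 1L) * idx$cell > span) break
      }
    }
    out_d[i] <- sqrt(best_d2)
    out_i[i] <- best_j
  }
  list(dist = out_d, which = out_i)
}

# Shoelace polygon area for points in hull order.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
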