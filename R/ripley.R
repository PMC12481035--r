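#' Ripley K, L, and H curves
#'
#' Second-order point-pattern statistics over a radius grid. The estimator
#' is
#' \deqn{\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} e_{ij}\, 1[d_{ij} \le r]}
#' with \eqn{e_{ij} = 1} (no edge correction) or the translation
#' correction \eqn{e_{ij} = A / ((w - |\Delta x_{ij}|)(h - |\Delta
#' y_{ij}|))} on a rectangular region of interest of width `w`, height `h`
#' and area `A`. Then \eqn{L(r) = \sqrt{K(r)/\pi}} and \eqn{H(r) = L(r) -
#' r}: H above 0 indicates clustering at scale r, below 0 dispersion.
#'
#' @param centers a `trace_centers` data.frame (or any `x_nm`/`y_nm`
#'   data.frame).
#' @param radii positive ascending radius grid, nm; the default is 5 to
#'   200 nm in 5 nm steps. The largest radius may not exceed half the
#'   shorter ROI side.
#' @param roi rectangle `c(xmin, xmax, ymin, ymax)` in nm; defaults to the
#'   bounding rectangle of the centers.
#' @param edge_correction `"translation"` (default) or `"none"`.
#' @return A `ripley_curve` data.frame with columns `r_nm,K,L,H` and
#'   attributes `edge_correction`, `n_points`, `roi`.
#' @export
ripley_h <- function(centers, radii = seq(5, 200, by = 5), roi = NULL,
                     edge_correction = c("translation", "none")) {
  edge_correction <- match.arg(edge_correction)
  df <- as.data.frame(centers)
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 centers for Ripley analysis", call. = FALSE)
  if (!length(radii) || any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be positive and strictly ascending", call. = FALSE)
  }
  if (is.null(roi)) {
    roi <- c(min(df$x_nm), max(df$x_nm), min(df$y_nm), max(df$y_nm))
  }
  w <- roi[2] - roi[1]; h <- roi[4] - roi[3]
  if (w <= 0 || h <= 0) stop("roi must have positive area", call. = FALSE)
  inside <- df$x_nm >= roi[1] & df$x_nm <= roi[2] &
    df$y_nm >= roi[3] & df$y_nm <= roi[4]
  if (!all(inside)) {
    df <- df[inside, , drop = FALSE]
    n <- nrow(df)
    if (n < 2L) stop("fewer than 2 centers inside roi", call. = FALSE)
  }
  if (max(radii) > min(w, h) / 2) {
    stop("largest radius exceeds half the shorter roi side", call. = FALSE)
  }
  A <- w * h
  dx <- abs(outer(df$x_nm, df$x_nm, "-"))
  dy <- abs(outer(df$y_nm, df$y_nm, "-"))
  up <- upper.tri(dx)
  dij <- sqrt(dx[up]^2 + dy[up]^2)
  wij <- if (edge_correction == "translation") {
    A / ((w - dx[up]) * (h - dy[up]))
  } else {
    rep.int(1, length(dij))
  }
  ord <- order(dij)
  csum <- cumsum(wij[ord])
  pos <- findInterval(radii, dij[ord])
  # each unordered pair counts twice in the sum over i != j
  K <- ifelse(pos > 0, 2 * csum[pmax(pos, 1L)], 0) * A / (n * (n - 1))
  L <- sqrt(K / pi)
  H <- L - radii
  out <- data.frame(r_nm = radii, K = K, L = L, H = H)
  attr(out, "edge_correction") <- edge_correction
  attr(out, "n_points") <- n
  attr(out, "roi") <- roi
  class(out) <- c("ripley_curve", "data.frame")
  out
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf("Ripley curve: %d radii in [%g, %g] nm, %d points, %s edge correction\n",
              nrow(x), min(x$r_nm), max(x$r_nm), attr(x, "n_points"),
              attr(x, "edge_correction")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r_nm, x$H, type = "l", xlab = "r (nm)", ylab = "H(r)",
                 main = "Ripley H", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
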