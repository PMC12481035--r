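#' Quality-filter parameters
#'
#' Defaults follow standard MINFLUX practice: localizations with
#' background-corrected emission rate (efo) strictly above 50,000 Hz or
#' center frequency ratio (cfr) strictly above 0.95 are discarded, and any
#' trace left with fewer than 3 localizations is dropped entirely.
#' Boundary values are kept (the cuts are strict inequalities).
#'
#' @param efo_max maximum efo, Hz.
#' @param cfr_max maximum cfr.
#' @param min_locs_per_trace minimum surviving localizations per trace.
#' @export
filter_params <- function(efo_max = 50000, cfr_max = 0.95,
                          min_locs_per_trace = 3L) {
  stop_if_not_number(efo_max, "efo_max", min = .Machine$double.eps)
  stop_if_not_number(cfr_max, "cfr_max", min = .Machine$double.eps)
  stop_if_not_number(min_locs_per_trace, "min_locs_per_trace", min = 1)
  structure(list(efo_max = efo_max, cfr_max = cfr_max,
                 min_locs_per_trace = as.integer(min_locs_per_trace)),
            class = "filter_params")
}

#' Filter localizations on quality metrics
#'
#' Two passes, in this order: (1) drop rows with `efo_hz > efo_max` or
#' `cfr > cfr_max`; (2) drop every trace whose surviving localization
#' count is below `min_locs_per_trace`. Row order is preserved and the
#' removal counts are recorded in the `filter_counts` attribute. The
#' operation is idempotent.
#'
#' @param table a [loc_table()].
#' @param params a [filter_params()].
#' @return The filtered [loc_table()] with attribute `filter_counts`.
#' @export
filter_localizations <- function(table, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  md <- attr(table, "metadata") %||% list()
  df <- as.data.frame(table)
  n_in <- nrow(df)
  traces_in <- length(unique(df$trace_id))
  keep <- df$efo_hz <= params$efo_max & df$cfr <= params$cfr_max
  df1 <- df[keep, , drop = FALSE]
  n_loc_removed <- n_in - nrow(df1)
  cnt <- table(df1$trace_id)
  good <- as.integer(names(cnt)[cnt >= params$min_locs_per_trace])
  df2 <- df1[df1$trace_id %in% good, , drop = FALSE]
  out <- loc_table(df2, metadata = md)
  attr(out, "filter_counts") <- list(
    locs_in = n_in,
    locs_removed_quality = n_loc_removed,
    locs_removed_short_trace = nrow(df1) - nrow(df2),
    locs_out = nrow(df2),
    traces_in = traces_in,
    traces_out = length(unique(df2$trace_id)))
  attr(out, "trace_map") <- attr(table, "trace_map")
  out
}

#' Trace-center parameters
#'
#' Each trace is condensed to one 2D point by running DBSCAN on its own
#' localizations and averaging the largest cluster; defaults are a 4 nm
#' search radius with a 3-localization threshold.
#'
#' @param dbscan_radius search radius, nm.
#' @param dbscan_min_pts core-point threshold (the point itself counts).
#' @export
trace_center_params <- function(dbscan_radius = 4, dbscan_min_pts = 3L) {
  stop_if_not_number(dbscan_radius, "dbscan_radius", min = .Machine$double.eps)
  stop_if_not_number(dbscan_min_pts, "dbscan_min_pts", min = 1)
  structure(list(dbscan_radius = dbscan_radius,
                 dbscan_min_pts = as.integer(dbscan_min_pts)),
            class = "trace_center_params")
}

new_trace_centers <- function(df, provenance = list()) {
  df <- as.data.frame(df)
  if (anyDuplicated(df$trace_id)) stop("trace ids must be unique", call. = FALSE)
  df$trace_id <- as.integer(df$trace_id)
  df$n_locs <- as.integer(df$n_locs)
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("trace_centers", "data.frame")
  df
}

#' Compute trace centers by per-trace DBSCAN
#'
#' For every trace, DBSCAN (inclusive neighborhood `d <= radius`, min_pts
#' counting the point itself) is run on that trace's localizations alone —
#' never across traces, so nearby emitters are not conflated. The trace
#' center is the arithmetic mean of the largest cluster's points; noise
#' points never contribute. Traces with no cluster yield no center. When
#' two clusters tie for largest, the one containing the earliest-time
#' localization wins, making the result independent of row order.
#'
#' @param table a filtered [loc_table()].
#' @param params a [trace_center_params()].
#' @return A `trace_centers` data.frame (`trace_id,n_locs,x_nm,y_nm`) with
#'   a `provenance` attribute recording parameters and per-stage counts.
#' @export
compute_trace_centers <- function(table, params = trace_center_params()) {
  stopifnot(inherits(params, "trace_center_params"))
  df <- as.data.frame(table)
  ids <- unique(df$trace_id)
  groups <- split(seq_len(nrow(df)), factor(df$trace_id, levels = ids))
  res <- vector("list", length(ids))
  dropped <- 0L
  for (k in seq_along(ids)) {
    tr <- df[groups[[k]], , drop = FALSE]
    lab <- dbscan_labels(tr$x_nm, tr$y_nm,
                         radius = params$dbscan_radius,
                         min_pts = params$dbscan_min_pts)
    if (all(lab == 0L)) { dropped <- dropped + 1L; next }
    sizes <- tabulate(lab)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie: prefer the cluster holding the earliest-time localization
      first_t <- vapply(best, function(cl) min(tr$time[lab == cl]), numeric(1))
      best <- best[which.min(first_t)]
    }
    sel <- lab == best
    res[[k]] <- data.frame(trace_id = ids[k], n_locs = sum(sel),
                           x_nm = mean(tr$x_nm[sel]),
                           y_nm = mean(tr$y_nm[sel]))
  }
  out <- do.call(rbind, c(res, list(data.frame(trace_id = integer(0),
                                               n_locs = integer(0),
                                               x_nm = numeric(0),
                                               y_nm = numeric(0)))))
  prov <- list(filter = attr(table, "filter_counts"),
               params = unclass(params),
               traces_in = length(ids),
               traces_no_cluster = dropped,
               centers = nrow(out))
  new_trace_centers(out, provenance = prov)
}

#' @export
print.trace_centers <- function(x, ...) {
  cat(sprintf("Trace centers: %d centers\n", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
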