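#' Pipeline configuration
#'
#' Bundles every stage's parameters. A pipeline run analyzes one table =
#' one cell/ROI; condition-level comparisons consume per-cell summaries
#' via [compare_conditions()]. The input is either an existing
#' localization table (`input`: path or [loc_table()]) or a [sim_config()]
#' (`sim`), in which case the field is simulated first and the ground
#' truth attached to the report.
#'
#' @param input path to a localizations CSV, or a [loc_table()], or NULL.
#' @param sim a [sim_config()] or NULL; exactly one of `input`/`sim` must
#'   be given.
#' @param filter a [filter_params()].
#' @param centers a [trace_center_params()].
#' @param clusters a [cluster_params()].
#' @param pair_radius isolated-pair search radius, nm.
#' @param ripley_rmax,ripley_step Ripley radius grid, nm; the grid is
#'   truncated to half the shorter ROI side when necessary.
#' @param ripley_edge edge correction for [ripley_h()].
#' @param roi optional analysis rectangle `c(xmin,xmax,ymin,ymax)`, nm;
#'   defaults to field-of-view metadata or the data bounding box.
#' @param outdir optional directory; when set, filtered localizations,
#'   trace centers, the report JSON and the Ripley CSV are written there.
#' @param seed seed used when simulating.
#' @export
pipeline_config <- function(input = NULL, sim = NULL,
                            filter = filter_params(),
                            centers = trace_center_params(),
                            clusters = cluster_params(),
                            pair_radius = 40,
                            ripley_rmax = 200, ripley_step = 5,
                            ripley_edge = "translation",
                            roi = NULL, outdir = NULL, seed = 1L) {
  if (is.null(input) == is.null(sim)) {
    stop("exactly one of 'input' and 'sim' must be provided", call. = FALSE)
  }
  stopifnot(inherits(filter, "filter_params"),
            inherits(centers, "trace_center_params"),
            inherits(clusters, "cluster_params"))
  stop_if_not_number(pair_radius, "pair_radius", min = .Machine$double.eps)
  structure(list(input = input, sim = sim, filter = filter,
                 centers = centers, clusters = clusters,
                 pair_radius = pair_radius, ripley_rmax = ripley_rmax,
                 ripley_step = ripley_step, ripley_edge = ripley_edge,
                 roi = roi, outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on one cell/ROI
#'
#' Executes, in order: (simulate or load) -> quality filtering -> trace
#' centers -> isolated pairs -> cluster analysis -> nearest neighbors ->
#' Ripley H, logging stage counts along the way (`message()`; suppress
#' with `quiet = TRUE`). An empty or fully filtered table produces a
#' report with zeroed statistics and a warning, not an error.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return A `flux_report`: stage counts, pair statistics (count,
#'   mean/median/sd and the full distance list), cluster statistics, mean
#'   nearest-neighbor distance, the Ripley curve, and provenance (config
#'   echo, seed, package version). When simulating, the `ground_truth` and
#'   the detected `pair_set`/`cluster_set` ride along as attributes for
#'   [evaluate_recovery()].
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  truth <- NULL
  if (!is.null(config$sim)) {
    truth <- simulate_ground_truth(config$sim, seed = config$seed)
    tab <- simulate_localizations(truth, config$sim, seed = config$seed + 1L)
    log_("simulate: %d molecules -> %d localizations in %d traces",
         nrow(truth$molecules), nrow(tab), length(unique(tab$trace_id)))
  } else if (is.character(config$input)) {
    tab <- read_localizations(config$input)
    log_("load: %d localizations from %s", nrow(tab), config$input)
  } else {
    tab <- loc_table(config$input, attr(config$input, "metadata") %||% list())
  }

  filt <- filter_localizations(tab, config$filter)
  fc <- attr(filt, "filter_counts")
  log_("filter: %d -> %d localizations (%d quality, %d short-trace); %d -> %d traces",
       fc$locs_in, fc$locs_out, fc$locs_removed_quality,
       fc$locs_removed_short_trace, fc$traces_in, fc$traces_out)

  ctr <- compute_trace_centers(filt, config$centers)
  log_("centers: %d trace centers", nrow(ctr))

  roi <- config$roi
  if (is.null(roi)) {
    md <- attr(tab, "metadata") %||% list()
    if (!is.null(md$fov_xmin)) {
      roi <- as.numeric(c(md$fov_xmin, md$fov_xmax, md$fov_ymin, md$fov_ymax))
    } else if (nrow(ctr) >= 2L) {
      roi <- c(range(ctr$x_nm), range(ctr$y_nm))
    }
  }

  if (nrow(ctr) == 0L) {
    warning("no trace centers survive preprocessing; report is empty",
            call. = FALSE)
    pairs <- find_isolated_pairs(ctr, config$pair_radius)
    clus <- cluster_analysis(ctr, config$clusters)
    nnd <- numeric(0)
    rip <- NULL
  } else {
    pairs <- find_isolated_pairs(ctr, config$pair_radius)
    clus <- cluster_analysis(ctr, config$clusters)
    nnd <- if (nrow(ctr) >= 2L) nearest_neighbor_distances(ctr) else numeric(0)
    rip <- NULL
    if (nrow(ctr) >= 2L && !is.null(roi)) {
      rmax_ok <- min(roi[2] - roi[1], roi[4] - roi[3]) / 2
      radii <- seq(config$ripley_step,
                   min(config$ripley_rmax, rmax_ok),
                   by = config$ripley_step)
      if (length(radii)) {
        rip <- ripley_h(ctr, radii = radii, roi = roi,
                        edge_correction = config$ripley_edge)
      }
    }
  }
  log_("pairs: %d; clusters: %d; mean NN %.2f nm",
       pairs$summary$count, clus$summary$count,
       if (length(nnd)) mean(nnd) else NA_real_)

  report <- structure(list(
    counts = list(
      locs_in = fc$locs_in, locs_out = fc$locs_out,
      locs_removed_quality = fc$locs_removed_quality,
      locs_removed_short_trace = fc$locs_removed_short_trace,
      traces_in = fc$traces_in, traces_out = fc$traces_out,
      centers = nrow(ctr)),
    pairs = pairs$summary,
    clusters = clus$summary,
    nn = list(mean_nm = if (length(nnd)) mean(nnd) else NA_real_,
              median_nm = if (length(nnd)) stats::median(nnd) else NA_real_),
    pair_table = pairs$pairs,
    cluster_table = clus$clusters[setdiff(names(clus$clusters), "members")],
    ripley = if (!is.null(rip)) as.data.frame(rip) else NULL,
    provenance = list(
      seed = config$seed,
      pair_radius = config$pair_radius,
      filter = unclass(config$filter),
      trace_centers = unclass(config$centers),
      clusters = unclass(config$clusters),
      ripley = list(rmax = config$ripley_rmax, step = config$ripley_step,
                    edge = config$ripley_edge),
      roi = roi,
      simulated = !is.null(config$sim),
      version = as.character(utils::packageVersion("minfluxpairs")))),
    class = "flux_report")
  attr(report, "truth") <- truth
  attr(report, "pair_set") <- pairs
  attr(report, "cluster_set") <- clus
  attr(report, "centers") <- ctr

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_localizations(filt, file.path(config$outdir, "localizations_filtered.csv"))
    write_trace_centers(ctr, file.path(config$outdir, "trace_centers.csv"))
    if (!is.null(rip)) write_ripley_csv(rip, file.path(config$outdir, "ripley.csv"))
    if (!is.null(truth)) write_ground_truth(truth, file.path(config$outdir, "ground_truth.csv"))
    write_report(report, file.path(config$outdir, "report.json"))
  }
  report
}

#' @export
print.flux_report <- function(x, ...) {
  cat("MINFLUX pipeline report\n")
  cat(sprintf("  localizations: %d in -> %d kept; traces %d -> %d; centers %d\n",
              x$counts$locs_in, x$counts$locs_out, x$counts$traces_in,
              x$counts$traces_out, x$counts$centers))
  cat(sprintf("  isolated pairs: %d", x$pairs$count))
  if (isTRUE(x$pairs$count > 0)) {
    cat(sprintf(" (mean %.2f nm, median %.2f nm)", x$pairs$mean_nm,
                x$pairs$median_nm))
  }
  cat("\n")
  cat(sprintf("  clusters: %d", x$clusters$count))
  if (isTRUE(x$clusters$count > 0)) {
    cat(sprintf(" (mean composition %.2f, mean size %.1f nm)",
                x$clusters$mean_composition, x$clusters$mean_size_nm))
  }
  cat("\n")
  if (!is.null(x$nn$mean_nm) && !is.na(x$nn$mean_nm)) {
    cat(sprintf("  mean nearest-neighbor distance: %.2f nm\n", x$nn$mean_nm))
  }
  if (!is.null(x$ripley)) {
    i <- which.max(x$ripley$H)
    cat(sprintf("  Ripley H peak: %.2f at r = %g nm\n",
                x$ripley$H[i], x$ripley$r_nm[i]))
  }
  invisible(x)
}

#' @export
summary.flux_report <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Score detections against simulated ground truth
#'
#' Detected isolated pairs are matched to true dimers greedily, closest
#' match first: a detected pair matches a dimer when each of its two
#' centers lies within `match_tolerance` of a distinct dimer member (the
#' match cost is the larger of the two center-member distances under the
#' better of the two assignments). Recall is counted against all true
#' dimers — unlabeled partners therefore depress recall, which is the
#' point: with labeling efficiency p, recall approaches p^2 for isolated
#' dimers. With zero detections precision is reported as 1 and flagged
#' (`no_detections`), since there are no false positives among zero
#' detections. Cluster recall matches detected cluster centroids against
#' the centroid of each eligible true cluster's labeled members (same
#' tolerance, greedy).
#'
#' @param truth a `ground_truth` (or NULL to use the one attached to a
#'   simulated report).
#' @param report a `flux_report` from [run_pipeline()].
#' @param match_tolerance nm; default 10, about four times the trace-
#'   center precision under default simulation settings.
#' @param true_separation override for the true pair separation, nm; by
#'   default taken from the simulation config attached to `truth`.
#' @return A `recovery_metrics` list: pair precision/recall, distance
#'   bias (mean detected minus true separation), cluster count recall,
#'   and the underlying counts.
#' @export
evaluate_recovery <- function(truth, report, match_tolerance = 10,
                              true_separation = NULL) {
  if (is.null(truth)) truth <- attr(report, "truth")
  stopifnot(inherits(truth, "ground_truth"), inherits(report, "flux_report"))
  roi <- report$provenance$roi
  if (!is.null(roi) && !is.null(truth$bounds)) {
    b <- truth$bounds
    if (roi[2] < b[["xmin"]] || roi[1] > b[["xmax"]] ||
        roi[4] < b[["ymin"]] || roi[3] > b[["ymax"]]) {
      stop("consistency error: report roi does not overlap truth field bounds",
           call. = FALSE)
    }
  }
  ps <- attr(report, "pair_set")
  pairs <- if (!is.null(ps)) ps$pairs else report$pair_table
  mol <- truth$molecules
  dim_groups <- unique(mol$group_id[mol$class == "dimer"])
  true_sep <- true_separation %||%
    (if (!is.null(truth$config)) truth$config$pair_separation_d else NA_real_)

  # candidate matches: cost = max center-to-member distance, best assignment
  if (!is.data.frame(pairs)) pairs <- NULL
  n_det <- if (is.null(pairs)) 0L else nrow(pairs)
  cand <- NULL
  if (n_det && length(dim_groups)) {
    dl <- lapply(dim_groups, function(g) mol[mol$group_id == g, , drop = FALSE])
    cost <- matrix(Inf, n_det, length(dim_groups))
    for (i in seq_len(n_det)) {
      for (j in seq_along(dl)) {
        mx <- dl[[j]]$x_nm; my <- dl[[j]]$y_nm
        c1 <- sqrt((pairs$ax_nm[i] - mx)^2 + (pairs$ay_nm[i] - my)^2)
        c2 <- sqrt((pairs$bx_nm[i] - mx)^2 + (pairs$by_nm[i] - my)^2)
        cost[i, j] <- min(max(c1[1], c2[2]), max(c1[2], c2[1]))
      }
    }
    cand <- which(cost <= match_tolerance, arr.ind = TRUE)
    if (nrow(cand)) cand <- cand[order(cost[cand]), , drop = FALSE]
  }
  used_det <- logical(n_det); used_tru <- logical(length(dim_groups))
  tp <- 0L
  if (!is.null(cand) && nrow(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_det[i] && !used_tru[j]) {
        used_det[i] <- TRUE; used_tru[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  no_det <- n_det == 0L
  precision <- if (no_det) 1 else tp / n_det
  recall <- if (length(dim_groups)) tp / length(dim_groups) else NA_real_
  bias <- if (n_det && !is.na(true_sep)) mean(pairs$distance_nm) - true_sep else NA_real_

  # cluster recall: centroid of labeled members vs detected centroids
  cs <- attr(report, "cluster_set")
  cl_det <- if (!is.null(cs)) cs$clusters else report$cluster_table
  if (!is.data.frame(cl_det)) cl_det <- NULL
  clu_groups <- unique(mol$group_id[mol$class == "cluster"])
  min_sz <- report$provenance$clusters$min_cluster_size %||% 4L
  elig <- Filter(function(g) sum(mol$group_id == g & mol$labeled) >= min_sz,
                 clu_groups)
  cl_tp <- 0L
  if (length(elig) && !is.null(cl_det) && nrow(cl_det)) {
    tx <- vapply(elig, function(g) mean(mol$x_nm[mol$group_id == g & mol$labeled]), numeric(1))
    ty <- vapply(elig, function(g) mean(mol$y_nm[mol$group_id == g & mol$labeled]), numeric(1))
    cost <- outer(seq_len(nrow(cl_det)), seq_along(elig), Vectorize(function(i, j) {
      sqrt((cl_det$centroid_x_nm[i] - tx[j])^2 + (cl_det$centroid_y_nm[i] - ty[j])^2)
    }))
    cand <- which(cost <= match_tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(cost[cand]), , drop = FALSE]
      ud <- logical(nrow(cl_det)); ut <- logical(length(elig))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!ud[i] && !ut[j]) { ud[i] <- TRUE; ut[j] <- TRUE; cl_tp <- cl_tp + 1L }
      }
    }
  }
  structure(list(
    pair_precision = precision,
    pair_recall = recall,
    pair_distance_bias_nm = bias,
    cluster_count_recall = if (length(elig)) cl_tp / length(elig) else NA_real_,
    n_detected_pairs = n_det,
    n_true_dimers = length(dim_groups),
    n_matched_pairs = tp,
    n_eligible_clusters = length(elig),
    no_detections = no_det,
    match_tolerance_nm = match_tolerance),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Recovery: pair precision %.3f%s, recall %s (%d/%d), bias %s nm\n",
              x$pair_precision,
              if (x$no_detections) " (no detections)" else "",
              if (is.na(x$pair_recall)) "NA" else sprintf("%.3f", x$pair_recall),
              x$n_matched_pairs, x$n_true_dimers,
              if (is.na(x$pair_distance_bias_nm)) "NA"
              else sprintf("%+.3f", x$pair_distance_bias_nm)))
  if (!is.na(x$cluster_count_recall)) {
    cat(sprintf("  cluster count recall %.3f (%d eligible)\n",
                x$cluster_count_recall, x$n_eligible_clusters))
  }
  invisible(x)
}
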