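#' Simulation configuration
#'
#' Defines the generative model for a synthetic MINFLUX field: a flat,
#' synapse-sized rectangle populated with monomers, fluorophore pairs at a
#' fixed true separation, and small Gaussian clusters, imaged with
#' per-localization Gaussian precision and contaminated by background
#' traces whose efo/cfr mostly violate the quality filters.
#'
#' Densities are per square micrometer; lengths are nanometers. Defaults
#' describe a dimer-dominant synapse: pairs are the most common
#' multi-molecule species, clusters of 4 are rare (about 2 per 25 um^2
#' field), and labeling efficiency is below 1 so many pair partners appear
#' as lone centers.
#'
#' @param field_width,field_height field size, nm.
#' @param monomer_density,dimer_density,cluster_density molecules (or
#'   dimers / clusters) per um^2.
#' @param pair_separation_d true intra-pair fluorophore distance, nm.
#' @param cluster_size_n molecules per cluster.
#' @param cluster_sigma per-axis Gaussian spread of cluster members, nm.
#' @param label_efficiency_p probability a molecule carries a detectable
#'   fluorophore.
#' @param locs_per_trace_lambda mean of the >=1-truncated Poisson for
#'   localizations per trace (realized mean is lambda / (1 - exp(-lambda))).
#' @param sigma_loc per-axis Gaussian localization precision, nm.
#' @param reactivation_prob probability a fluorophore yields a second,
#'   independent trace (a confound: duplicate traces masquerade as ~0 nm
#'   pairs).
#' @param background_trace_rate spurious traces per um^2.
#' @param efo_signal_meanlog,efo_signal_sdlog log-normal parameters of
#'   signal efo (default median 20,000 Hz).
#' @param cfr_signal_min,cfr_signal_max uniform bounds of signal cfr.
#' @param efo_bg_meanlog,efo_bg_sdlog log-normal parameters of background
#'   efo (default median 80,000 Hz, mostly above the 50,000 Hz filter).
#' @param cfr_bg_min,cfr_bg_max uniform bounds of background cfr (default
#'   0.9-1.2, mostly above the 0.95 filter).
#' @param seed integer RNG seed; `simulate_ground_truth()` uses `seed` and
#'   `simulate_localizations()` uses `seed + 1` by default.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_width = 5000, field_height = 5000,
                       monomer_density = 1.0, dimer_density = 1.0,
                       cluster_density = 0.08,
                       pair_separation_d = 18,
                       cluster_size_n = 4L, cluster_sigma = 15,
                       label_efficiency_p = 0.7,
                       locs_per_trace_lambda = 8,
                       sigma_loc = 2.5,
                       reactivation_prob = 0,
                       background_trace_rate = 0.2,
                       efo_signal_meanlog = log(20000),
                       efo_signal_sdlog = 0.4,
                       cfr_signal_min = 0.1, cfr_signal_max = 0.9,
                       efo_bg_meanlog = log(80000), efo_bg_sdlog = 0.5,
                       cfr_bg_min = 0.9, cfr_bg_max = 1.2,
                       seed = 1L) {
  cfg <- list(field_width = field_width, field_height = field_height,
              monomer_density = monomer_density,
              dimer_density = dimer_density,
              cluster_density = cluster_density,
              pair_separation_d = pair_separation_d,
              cluster_size_n = as.integer(cluster_size_n),
              cluster_sigma = cluster_sigma,
              label_efficiency_p = label_efficiency_p,
              locs_per_trace_lambda = locs_per_trace_lambda,
              sigma_loc = sigma_loc,
              reactivation_prob = reactivation_prob,
              background_trace_rate = background_trace_rate,
              efo_signal_meanlog = efo_signal_meanlog,
              efo_signal_sdlog = efo_signal_sdlog,
              cfr_signal_min = cfr_signal_min,
              cfr_signal_max = cfr_signal_max,
              efo_bg_meanlog = efo_bg_meanlog,
              efo_bg_sdlog = efo_bg_sdlog,
              cfr_bg_min = cfr_bg_min, cfr_bg_max = cfr_bg_max,
              seed = as.integer(seed))
  stop_if_not_number(cfg$field_width, "field_width", min = .Machine$double.eps)
  stop_if_not_number(cfg$field_height, "field_height", min = .Machine$double.eps)
  for (nm in c("monomer_density", "dimer_density", "cluster_density",
               "pair_separation_d", "cluster_sigma", "locs_per_trace_lambda",
               "sigma_loc", "background_trace_rate")) {
    stop_if_not_number(cfg[[nm]], nm, min = 0)
  }
  for (nm in c("label_efficiency_p", "reactivation_prob")) {
    stop_if_not_number(cfg[[nm]], nm, min = 0, max = 1)
  }
  if (cfg$cluster_size_n < 2L) stop("cluster_size_n must be >= 2", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate ground-truth molecular positions
#'
#' Monomers follow a homogeneous Poisson process over the field. Each dimer
#' has a Poisson-placed anchor and a partner at exactly
#' `pair_separation_d` nm in a uniformly random direction. Each cluster has
#' a Poisson-placed center and `cluster_size_n` members at isotropic
#' Gaussian offsets (sd `cluster_sigma`). Every molecule is labeled
#' independently with probability `label_efficiency_p`. Molecules generated
#' relative to an in-field anchor may fall slightly outside the nominal
#' field edge; they are kept (edge effects are the analysis's problem, not
#' the generator's).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `ground_truth` object: list with `molecules` (data.frame
#'   `mol_id,x_nm,y_nm,class,group_id,labeled`), `bounds`, and `config`.
#' @export
simulate_ground_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  area_um2 <- config$field_width * config$field_height / 1e6
  if (area_um2 <= 0) stop("zero-area field", call. = FALSE)
  with_seed(seed, {
    n_mono <- stats::rpois(1, config$monomer_density * area_um2)
    n_dim  <- stats::rpois(1, config$dimer_density * area_um2)
    n_clu  <- stats::rpois(1, config$cluster_density * area_um2)

    runif_xy <- function(n) {
      cbind(stats::runif(n, 0, config$field_width),
            stats::runif(n, 0, config$field_height))
    }
    rows <- list()
    gid <- 0L
    if (n_mono > 0) {
      xy <- runif_xy(n_mono)
      rows[[length(rows) + 1L]] <- data.frame(
        x_nm = xy[, 1], y_nm = xy[, 2], class = "monomer",
        group_id = gid + seq_len(n_mono))
      gid <- gid + n_mono
    }
    if (n_dim > 0) {
      anchor <- runif_xy(n_dim)
      theta <- stats::runif(n_dim, 0, 2 * pi)
      partner <- anchor + config$pair_separation_d * cbind(cos(theta), sin(theta))
      ids <- gid + seq_len(n_dim)
      rows[[length(rows) + 1L]] <- data.frame(
        x_nm = c(rbind(anchor[, 1], partner[, 1])),
        y_nm = c(rbind(anchor[, 2], partner[, 2])),
        class = "dimer", group_id = rep(ids, each = 2L))
      gid <- gid + n_dim
    }
    if (n_clu > 0) {
      ctr <- runif_xy(n_clu)
      k <- config$cluster_size_n
      ids <- gid + seq_len(n_clu)
      x <- rep(ctr[, 1], each = k) + stats::rnorm(n_clu * k, 0, config$cluster_sigma)
      y <- rep(ctr[, 2], each = k) + stats::rnorm(n_clu * k, 0, config$cluster_sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        x_nm = x, y_nm = y, class = "cluster", group_id = rep(ids, each = k))
      gid <- gid + n_clu
    }
    mol <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(x_nm = numeric(0), y_nm = numeric(0),
                 class = character(0), group_id = integer(0))
    }
    mol$mol_id <- seq_len(nrow(mol))
    mol$labeled <- stats::runif(nrow(mol)) < config$label_efficiency_p
    mol <- mol[c("mol_id", "x_nm", "y_nm", "class", "group_id", "labeled")]
    structure(list(molecules = mol,
                   bounds = c(xmin = 0, xmax = config$field_width,
                              ymin = 0, ymax = config$field_height),
                   config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$molecules$class)
  cat(sprintf("Ground truth: %d molecules (%s), %d labeled, field %g x %g nm\n",
              nrow(x$molecules),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              sum(x$molecules$labeled),
              x$bounds["xmax"] - x$bounds["xmin"],
              x$bounds["ymax"] - x$bounds["ymin"]))
  invisible(x)
}

#' Simulate MINFLUX localizations from ground truth
#'
#' Each labeled molecule emits one trace (plus a second independent trace
#' with probability `reactivation_prob`). Trace length is >=1-truncated
#' Poisson; each localization is the molecule position plus independent
#' per-axis Gaussian noise of sd `sigma_loc`. Signal efo is log-normal and
#' signal cfr uniform; background traces arrive as a Poisson process over
#' the field with efo/cfr drawn so that most violate the default quality
#' filters. Trace ids are unique and times are monotone within a trace.
#'
#' @param truth a `ground_truth` from [simulate_ground_truth()].
#' @param config the same [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1` so truth and
#'   localizations use distinct streams.
#' @return A [loc_table()]; attribute `trace_map` maps `trace_id` to the
#'   originating `mol_id` (NA for background traces).
#' @export
simulate_localizations <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  mol <- truth$molecules
  area_um2 <- config$field_width * config$field_height / 1e6
  with_seed(seed, {
    lab <- mol[mol$labeled, , drop = FALSE]
    n_re <- if (nrow(lab)) stats::rbinom(nrow(lab), 1L, config$reactivation_prob) else integer(0)
    src_x <- rep(lab$x_nm, 1L + n_re)
    src_y <- rep(lab$y_nm, 1L + n_re)
    src_mol <- rep(lab$mol_id, 1L + n_re)
    n_bg <- stats::rpois(1, config$background_trace_rate * area_um2)
    if (n_bg > 0) {
      src_x <- c(src_x, stats::runif(n_bg, 0, config$field_width))
      src_y <- c(src_y, stats::runif(n_bg, 0, config$field_height))
      src_mol <- c(src_mol, rep(NA_integer_, n_bg))
    }
    n_tr <- length(src_x)
    m <- rtpois(n_tr, config$locs_per_trace_lambda)
    tot <- sum(m)
    tr <- rep(seq_len(n_tr), m)
    x <- src_x[tr] + stats::rnorm(tot, 0, config$sigma_loc)
    y <- src_y[tr] + stats::rnorm(tot, 0, config$sigma_loc)
    is_bg <- is.na(src_mol)[tr]
    efo <- numeric(tot); cfr <- numeric(tot)
    if (any(!is_bg)) {
      efo[!is_bg] <- stats::rlnorm(sum(!is_bg), config$efo_signal_meanlog,
                                   config$efo_signal_sdlog)
      cfr[!is_bg] <- stats::runif(sum(!is_bg), config$cfr_signal_min,
                                  config$cfr_signal_max)
    }
    if (any(is_bg)) {
      efo[is_bg] <- stats::rlnorm(sum(is_bg), config$efo_bg_meanlog,
                                  config$efo_bg_sdlog)
      cfr[is_bg] <- stats::runif(sum(is_bg), config$cfr_bg_min, config$cfr_bg_max)
    }
    within <- sequence(m) - 1L
    time <- (tr - 1L) * 1.0 + within * 1e-3
    md <- list(fov_xmin = min(0, x), fov_xmax = max(config$field_width, x),
               fov_ymin = min(0, y), fov_ymax = max(config$field_height, y),
               seed = seed, synthetic = "true")
    tab <- loc_table(data.frame(trace_id = tr, time = time, x_nm = x,
                                y_nm = y, efo_hz = efo, cfr = cfr),
                     metadata = md)
    attr(tab, "trace_map") <- data.frame(
      trace_id = seq_len(n_tr), mol_id = src_mol,
      kind = ifelse(is.na(src_mol), "background", "signal"))
    tab
  })
}

#' Expected measured distance between two noisy points
#'
#' Two fluorophores truly `d` nm apart, each localized (or reduced to a
#' trace center) with independent isotropic Gaussian error of per-axis sd
#' `sigma_point`, yield a measured separation following a Rice distribution
#' with location `d` and scale `sigma_point * sqrt(2)`. Its mean exceeds
#' `d` — the positive bias that makes measured pair distances overestimate
#' the true separation. Computed by adaptive numerical integration of the
#' Rice density (relative error below 1e-6); the noiseless and zero-
#' separation limits are exact.
#'
#' @param d true separation, nm (vectorized).
#' @param sigma_point per-axis sd of each point estimate, nm. For a trace
#'   center averaged from m localizations of precision sigma_loc this is
#'   approximately sigma_loc / sqrt(m).
#' @return Expected measured distance, nm.
#' @seealso [invert_pair_distance()] for the inverse mapping.
#' @export
expected_pair_distance <- function(d, sigma_point) {
  if (any(d < 0) || sigma_point < 0) {
    stop("d and sigma_point must be non-negative", call. = FALSE)
  }
  if (sigma_point == 0) return(d)
  s <- sigma_point * sqrt(2)           # per-axis sd of the difference vector
  vapply(d, function(di) {
    f <- function(r) {
      r^2 / s^2 * exp(-(r - di)^2 / (2 * s^2)) *
        besselI(r * di / s^2, 0, expon.scaled = TRUE)
    }
    stats::integrate(f, lower = max(0, di - 12 * s), upper = di + 12 * s,
                     rel.tol = 1e-9, abs.tol = 0)$value
  }, numeric(1))
}

#' Invert the pair-distance bias
#'
#' Given a mean measured pair distance and the per-point precision, solve
#' for the true separation whose Rice mean equals the measurement. Mean
#' distances at or below the zero-separation (Rayleigh) mean map to 0.
#'
#' @param mean_distance observed mean pair distance, nm.
#' @param sigma_point per-axis sd of each point estimate, nm.
#' @return Estimated true separation, nm.
#' @export
invert_pair_distance <- function(mean_distance, sigma_point) {
  stop_if_not_number(mean_distance, "mean_distance", min = 0)
  stop_if_not_number(sigma_point, "sigma_point", min = 0)
  if (sigma_point == 0) return(mean_distance)
  m0 <- expected_pair_distance(0, sigma_point)
  if (mean_distance <= m0) return(0)
  stats::uniroot(function(d) expected_pair_distance(d, sigma_point) - mean_distance,
                 lower = 0, upper = mean_distance, tol = 1e-10)$root
}

#' Write / read a ground-truth sidecar CSV
#'
#' Header `mol_id,x_nm,y_nm,class,group_id,labeled`.
#'
#' @param truth a `ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$molecules
  df$labeled <- as.integer(df$labeled)
  write_table_csv(df, path, metadata = as.list(truth$bounds))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- parse_metadata(lines[is_meta])
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  df$labeled <- as.logical(df$labeled)
  b <- c(xmin = meta$xmin %||% min(df$x_nm, 0),
         xmax = meta$xmax %||% max(df$x_nm, 0),
         ymin = meta$ymin %||% min(df$y_nm, 0),
         ymax = meta$ymax %||% max(df$y_nm, 0))
  structure(list(molecules = df, bounds = b, config = NULL),
            class = "ground_truth")
}
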