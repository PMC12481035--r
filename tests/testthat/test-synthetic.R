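test_that("generator is deterministic in the seed and sensitive to it", {
  cfg <- sim_config(seed = 42)
  t1 <- simulate_ground_truth(cfg)
  t2 <- simulate_ground_truth(cfg)
  expect_identical(t1$molecules, t2$molecules)
  l1 <- simulate_localizations(t1, cfg)
  l2 <- simulate_localizations(t2, cfg)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  t3 <- simulate_ground_truth(cfg, seed = 43)
  expect_false(identical(t1$molecules, t3$molecules))
})

test_that("zero densities give an empty field; zero area errors", {
  cfg <- sim_config(monomer_density = 0, dimer_density = 0,
                    cluster_density = 0, background_trace_rate = 0, seed = 1)
  truth <- simulate_ground_truth(cfg)
  expect_equal(nrow(truth$molecules), 0L)
  tab <- simulate_localizations(truth, cfg)
  expect_equal(nrow(tab), 0L)
  expect_error(sim_config(field_width = 0), "field_width")
})

test_that("dimer partners sit exactly pair_separation_d apart", {
  cfg <- sim_config(monomer_density = 0, cluster_density = 0,
                    dimer_density = 2, pair_separation_d = 18, seed = 9)
  truth <- simulate_ground_truth(cfg)
  mol <- truth$molecules
  for (g in unique(mol$group_id)) {
    m <- mol[mol$group_id == g, ]
    expect_equal(nrow(m), 2L)
    d <- sqrt(diff(m$x_nm)^2 + diff(m$y_nm)^2)
    expect_equal(d, 18, tolerance = 1e-9 / 18)
  }
})

test_that("dimer counts follow Poisson moments over seeds", {
  cfg <- sim_config(monomer_density = 0, cluster_density = 0,
                    dimer_density = 1, field_width = 5000,
                    field_height = 5000, seed = 1)
  counts <- vapply(1:200, function(s) {
    tr <- simulate_ground_truth(cfg, seed = s)
    sum(tr$molecules$class == "dimer") / 2
  }, numeric(1))
  mu <- 1 * 25                       # density x area in um^2
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("labeling, reactivation, and background control trace counts", {
  cfg0 <- sim_config(label_efficiency_p = 0, background_trace_rate = 1, seed = 3)
  truth <- simulate_ground_truth(cfg0)
  tab <- simulate_localizations(truth, cfg0)
  tm <- attr(tab, "trace_map")
  expect_true(all(tm$kind == "background"))

  cfg1 <- sim_config(label_efficiency_p = 1, background_trace_rate = 0,
                     reactivation_prob = 0, seed = 3)
  truth1 <- simulate_ground_truth(cfg1)
  tab1 <- simulate_localizations(truth1, cfg1)
  expect_equal(length(unique(tab1$trace_id)), nrow(truth1$molecules))
  expect_false(anyDuplicated(attr(tab1, "trace_map")$trace_id) > 0)
})

test_that("sigma_loc = 0 puts every localization exactly on its molecule", {
  cfg <- sim_config(sigma_loc = 0, background_trace_rate = 0,
                    label_efficiency_p = 1, seed = 8)
  truth <- simulate_ground_truth(cfg)
  tab <- simulate_localizations(truth, cfg)
  tm <- attr(tab, "trace_map")
  mol <- truth$molecules
  pos <- mol[match(tm$mol_id[tab$trace_id], mol$mol_id), ]
  expect_equal(tab$x_nm, pos$x_nm, tolerance = 0)
  expect_equal(tab$y_nm, pos$y_nm, tolerance = 0)
})

test_that("localization noise and trace lengths match the generative model", {
  cfg <- sim_config(field_width = 30000, field_height = 30000,
                    monomer_density = 16, dimer_density = 0,
                    cluster_density = 0, background_trace_rate = 0,
                    label_efficiency_p = 1, locs_per_trace_lambda = 8,
                    sigma_loc = 2.5, seed = 21)
  truth <- simulate_ground_truth(cfg)
  tab <- simulate_localizations(truth, cfg)
  expect_gt(nrow(tab), 1e5)
  tm <- attr(tab, "trace_map")
  mol <- truth$molecules
  pos <- mol[match(tm$mol_id[tab$trace_id], mol$mol_id), ]
  dev <- c(tab$x_nm - pos$x_nm, tab$y_nm - pos$y_nm)
  n <- length(dev)
  expect_lt(abs(sd(dev) - 2.5), 3 * 2.5 / sqrt(2 * n))

  m <- as.vector(table(tab$trace_id))
  lambda <- 8
  mu <- lambda / (1 - exp(-lambda))
  expect_lt(abs(mean(m) - mu), 3 * sd(m) / sqrt(length(m)))
})

test_that("expected pair distance matches exact limits and the MC oracle", {
  # noiseless limit and zero-separation (Rayleigh) closed form
  expect_identical(expected_pair_distance(10, 0), 10)
  expect_equal(expected_pair_distance(0, 2.5),
               2.5 * sqrt(2) * sqrt(pi / 2), tolerance = 1e-6)
  # frozen 1e7-draw Monte-Carlo oracle values (value, 3 * MC standard error)
  mc <- list(
    list(d = 17.8, s = 2.5, m = 18.15322, tol = 3 * 0.001107),
    list(d = 5, s = 2.5 / sqrt(8), m = 5.15935, tol = 3 * 0.000389),
    list(d = 10, s = 2.5 / sqrt(8), m = 10.07813, tol = 3 * 0.000394),
    list(d = 17.8, s = 2.5 / sqrt(8), m = 17.84351, tol = 3 * 0.000395),
    list(d = 25, s = 2.5 / sqrt(8), m = 25.03113, tol = 3 * 0.000395))
  for (cs in mc) {
    expect_lt(abs(expected_pair_distance(cs$d, cs$s) - cs$m), cs$tol)
  }
  expect_error(expected_pair_distance(-1, 1), "non-negative")
})

test_that("bias inversion recovers the true separation", {
  for (d in c(0, 3, 10, 17.8, 40)) {
    m <- expected_pair_distance(d, 1.7)
    expect_equal(invert_pair_distance(m, 1.7), d, tolerance = 1e-6)
  }
  expect_equal(invert_pair_distance(12, 0), 12)
  # below the Rayleigh floor the best explanation is zero separation
  expect_equal(invert_pair_distance(1, 2.5), 0)
})

test_that("measured center-to-center dimer distances follow the Rice mean", {
  cfg <- sim_config(pair_separation_d = 12, sigma_loc = 2.0,
                    locs_per_trace_lambda = 8, label_efficiency_p = 1,
                    background_trace_rate = 0, seed = 31)
  set.seed(31)
  truth <- grid_dimer_truth(cfg, 600)
  tab <- simulate_localizations(truth, cfg)
  ctr <- compute_trace_centers(filter_localizations(tab))
  ps <- find_isolated_pairs(ctr)
  d <- ps$summary$distances_nm
  expect_gt(length(d), 500)
  mbar <- 8 / (1 - exp(-8))
  pred <- expected_pair_distance(12, 2.0 / sqrt(mbar))
  expect_lt(abs(mean(d) - pred), 3 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("ground truth round-trips through its sidecar CSV", {
  cfg <- sim_config(seed = 2)
  truth <- simulate_ground_truth(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$molecules$x_nm, truth$molecules$x_nm, tolerance = 0)
  expect_identical(back$molecules$labeled, truth$molecules$labeled)
  expect_equal(unname(back$bounds), unname(truth$bounds))
})
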