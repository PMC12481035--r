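centers_from_xy <- function(x, y) {
  minfluxpairs:::new_trace_centers(data.frame(
    trace_id = seq_along(x), n_locs = 3L, x_nm = x, y_nm = y))
}

test_that("dbscan handles canonical small configurations", {
  expect_identical(dbscan_labels(0, 0, radius = 40, min_pts = 2), 0L)
  lab <- dbscan_labels(c(0, 18, 200), c(0, 0, 0), radius = 40, min_pts = 2)
  expect_identical(lab, c(1L, 1L, 0L))
  expect_identical(dbscan_labels(numeric(0), numeric(0), 40, 2), integer(0))
})

test_that("dbscan matches the O(n^2) oracle across random instances", {
  set.seed(1234)
  for (i in 1:60) {
    n <- sample(2:200, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    r <- runif(1, 5, 80); mp <- sample(2:6, 1)
    expect_identical(canon_labels(dbscan_labels(x, y, r, mp)),
                     canon_labels(bf_dbscan(x, y, r, mp)))
  }
})

test_that("nearest-neighbor distances are exact", {
  expect_equal(nearest_neighbor_distances(centers_from_xy(c(0, 18), c(0, 0))),
               c(18, 18))
  expect_equal(nearest_neighbor_distances(centers_from_xy(c(0, 10, 25), c(0, 0, 0))),
               c(10, 10, 15))
  expect_error(nearest_neighbor_distances(centers_from_xy(1, 1)),
               "at least 2")
  set.seed(88)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
    expect_equal(nearest_neighbor_distances(centers_from_xy(x, y)),
                 unname(bf_nn(x, y)), tolerance = 1e-12)
  }
  # clustered, highly non-uniform pattern stresses the ring search
  set.seed(89)
  x <- c(rnorm(100, 0, 5), rnorm(5, 5000, 5))
  y <- c(rnorm(100, 0, 5), rnorm(5, 5000, 5))
  expect_equal(nearest_neighbor_distances(centers_from_xy(x, y)),
               unname(bf_nn(x, y)), tolerance = 1e-12)
})

test_that("isolated pairs are exactly the size-2 DBSCAN clusters", {
  ps <- find_isolated_pairs(centers_from_xy(c(0, 18, 200), c(0, 0, 0)))
  expect_equal(ps$summary$count, 1L)
  expect_equal(ps$pairs$distance_nm, 18)
  expect_equal(ps$pairs$mid_x_nm, 9)

  # chaining: 0 -- 18 -- 50 links into one 3-cluster, so no pairs
  ps2 <- find_isolated_pairs(centers_from_xy(c(0, 18, 50), c(0, 0, 0)))
  expect_equal(ps2$summary$count, 0L)

  # every reported pair is mutually nearest with an empty neighborhood
  set.seed(21)
  for (i in 1:10) {
    n <- 150
    x <- runif(n, 0, 3000); y <- runif(n, 0, 3000)
    ctr <- centers_from_xy(x, y)
    ps3 <- find_isolated_pairs(ctr, 40)
    if (ps3$summary$count == 0) next
    nn <- nearest_neighbor_distances(ctr)
    for (k in seq_len(ps3$summary$count)) {
      a <- ps3$pairs$id_a[k]; b <- ps3$pairs$id_b[k]
      expect_equal(nn[a], ps3$pairs$distance_nm[k])
      expect_equal(nn[b], ps3$pairs$distance_nm[k])
      expect_gt(ps3$pairs$third_nn_nm[k], 40)
    }
  }
})

test_that("noiseless dimers are all recovered as exact-distance pairs", {
  cfg <- sim_config(pair_separation_d = 15, sigma_loc = 0,
                    label_efficiency_p = 1, background_trace_rate = 0,
                    seed = 5)
  set.seed(5)
  truth <- grid_dimer_truth(cfg, 100)
  tab <- simulate_localizations(truth, cfg)
  ctr <- compute_trace_centers(filter_localizations(tab))
  # dimers whose two traces both survive the 3-localization rule
  tm <- attr(tab, "trace_map")
  n_locs <- table(tab$trace_id)
  ok_mol <- tm$mol_id[tm$trace_id %in% as.integer(names(n_locs)[n_locs >= 3])]
  grp <- truth$molecules$group_id[match(ok_mol, truth$molecules$mol_id)]
  complete <- sum(table(grp) == 2L)
  ps <- find_isolated_pairs(ctr)
  expect_equal(ps$summary$count, complete)
  expect_gte(complete, 95L)
  expect_equal(ps$summary$distances_nm, rep(15, complete),
               tolerance = 1e-9 / 15)
})

test_that("cluster characterization matches hand geometry", {
  sq <- centers_from_xy(c(0, 20, 20, 0), c(0, 0, 20, 20))
  cs <- cluster_analysis(sq, cluster_params(40, 4))
  expect_equal(cs$summary$count, 1L)
  expect_equal(cs$clusters$composition, 4L)
  expect_equal(cs$clusters$size_nm, 20 * sqrt(2))
  expect_equal(cs$clusters$area_nm2, 400)
  expect_equal(cs$clusters$density_per_nm2, 0.01)
  expect_false(cs$clusters$degenerate)

  # three points cannot form a min-size-4 cluster
  tri <- centers_from_xy(c(0, 10, 20), c(0, 10, 0))
  expect_equal(cluster_analysis(tri, cluster_params(40, 4))$summary$count, 0L)

  # collinear members: ribbon fallback, flagged
  line <- centers_from_xy(c(0, 10, 20, 30), c(0, 0, 0, 0))
  csl <- cluster_analysis(line, cluster_params(40, 4))
  expect_true(csl$clusters$degenerate)
  expect_equal(csl$clusters$area_nm2, 30)
})

test_that("pair and cluster detection are rigid-motion invariant", {
  set.seed(31)
  n <- 120
  x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
  th <- 0.73; dx <- 500; dy <- -200
  xr <- cos(th) * x - sin(th) * y + dx
  yr <- sin(th) * x + cos(th) * y + dy
  p1 <- find_isolated_pairs(centers_from_xy(x, y))
  p2 <- find_isolated_pairs(centers_from_xy(xr, yr))
  expect_equal(p1$summary$count, p2$summary$count)
  expect_equal(sort(p1$summary$distances_nm), sort(p2$summary$distances_nm))
  c1 <- cluster_analysis(centers_from_xy(x, y), cluster_params(60, 3))
  c2 <- cluster_analysis(centers_from_xy(xr, yr), cluster_params(60, 3))
  expect_equal(c1$summary$count, c2$summary$count)
  expect_equal(sort(c1$clusters$composition), sort(c2$clusters$composition))
  expect_equal(sort(c1$clusters$size_nm), sort(c2$clusters$size_nm))
})

test_that("cluster recovery finds well-separated simulated clusters", {
  cfg <- sim_config(monomer_density = 0, dimer_density = 0,
                    cluster_density = 0.04, cluster_size_n = 4,
                    cluster_sigma = 8, label_efficiency_p = 1,
                    locs_per_trace_lambda = 20,
                    background_trace_rate = 0, sigma_loc = 0,
                    field_width = 20000, field_height = 20000, seed = 47)
  truth <- simulate_ground_truth(cfg)
  tab <- simulate_localizations(truth, cfg)
  ctr <- compute_trace_centers(filter_localizations(tab))
  cs <- cluster_analysis(ctr, cluster_params(40, 4))
  n_true <- length(unique(truth$molecules$group_id))
  expect_equal(cs$summary$count, n_true)
})

test_that("Ripley K/L/H match hand computation and the direct-count oracle", {
  sq <- centers_from_xy(c(0, 10, 10, 0) + 45, c(0, 0, 10, 10) + 45)
  cur <- ripley_h(sq, radii = 10, roi = c(0, 100, 0, 100),
                  edge_correction = "none")
  expect_equal(cur$K, 10000 / 12 * 8, tolerance = 1e-12)
  expect_equal(cur$L, sqrt(cur$K / pi))
  expect_equal(cur$H, cur$L - 10)

  set.seed(61)
  x <- runif(60, 0, 1000); y <- runif(60, 0, 1000)
  radii <- seq(20, 300, by = 40)
  cur2 <- ripley_h(centers_from_xy(x, y), radii = radii,
                   roi = c(0, 1000, 0, 1000), edge_correction = "none")
  expect_equal(cur2$K, bf_ripley_k(x, y, radii, 1e6), tolerance = 1e-10)
  # identities hold at every radius
  expect_equal(cur2$H, cur2$L - radii)
  expect_equal(cur2$L, sqrt(cur2$K / pi))
  expect_true(all(diff(cur2$K) >= 0))
})

test_that("Ripley guards its preconditions and limits", {
  two <- centers_from_xy(c(0, 900), c(0, 900))
  cur <- ripley_h(two, radii = seq(50, 400, 50), roi = c(0, 1000, 0, 1000))
  expect_true(all(cur$K == 0))
  expect_equal(cur$H, -cur$r_nm)

  expect_error(ripley_h(two, radii = seq(100, 600, 100),
                        roi = c(0, 1000, 0, 1000)), "half")
  expect_error(ripley_h(centers_from_xy(1, 1), radii = 10), "at least 2")
  expect_error(ripley_h(two, radii = c(10, 5), roi = c(0, 1000, 0, 1000)),
               "ascending")
})

test_that("translation correction removes the CSR edge bias", {
  set.seed(99)
  h_tr <- h_un <- numeric(20)
  for (i in 1:20) {
    x <- runif(300, 0, 1000); y <- runif(300, 0, 1000)
    ctr <- centers_from_xy(x, y)
    roi <- c(0, 1000, 0, 1000)
    h_tr[i] <- ripley_h(ctr, radii = 200, roi = roi, "translation")$H
    h_un[i] <- ripley_h(ctr, radii = 200, roi = roi, "none")$H
  }
  expect_lt(abs(mean(h_tr)), 5)       # unbiased near CSR
  expect_lt(mean(h_un), -5)           # uncorrected is biased low at large r
  expect_gt(mean(h_tr) - mean(h_un), 10)
})

test_that("Mann-Whitney comparison is exact for small samples", {
  res <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$U, 4.5)
  expect_equal(res$p_value, 1)

  res2 <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res2$U, 0)
  expect_equal(res2$p_value, 0.1)
  expect_identical(res2$method, "exact")

  # against full-enumeration oracle on random tie-free samples
  set.seed(7)
  for (i in 1:25) {
    a <- runif(sample(3:7, 1), 0, 10)
    b <- runif(sample(3:7, 1), 2, 12)
    got <- compare_conditions(a, b)
    ref <- enum_mw(a, b)
    expect_equal(got$U, ref$U)
    expect_equal(got$p_value, ref$p)
  }

  # swapping samples reflects U and keeps p
  a <- c(0.3, 1.7, 2.2, 5.1); b <- c(0.9, 4.4, 6.6)
  r1 <- compare_conditions(a, b); r2 <- compare_conditions(b, a)
  expect_equal(r1$U, length(a) * length(b) - r2$U)
  expect_equal(r1$p_value, r2$p_value)

  expect_error(compare_conditions(numeric(0), 1), "non-empty")

  # large samples switch to the tie-corrected normal approximation
  set.seed(12)
  big <- compare_conditions(rnorm(30), rnorm(30, 1))
  expect_identical(big$method, "normal_approx")
  expect_lt(big$p_value, 0.05)
})
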