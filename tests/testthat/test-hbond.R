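test_that("coordinate series convert to Euclidean distances", {
  expect_equal(distances_from_coordinates(matrix(1, 1, 3), matrix(1, 1, 3)), 0)
  expect_equal(distances_from_coordinates(matrix(c(0, 0, 0), 1),
                                          matrix(c(3, 4, 0), 1)), 5)
  # brute-force per-frame oracle on 100 random frames
  set.seed(51)
  d <- matrix(rnorm(300), 100, 3); a <- matrix(rnorm(300), 100, 3)
  brute <- vapply(1:100, function(i) sqrt(sum((d[i, ] - a[i, ])^2)),
                  numeric(1))
  expect_equal(distances_from_coordinates(d, a), brute, tolerance = 1e-12)
  expect_error(distances_from_coordinates(d, a[1:50, ]), "equal dimensions")
})

test_that("the synthetic generator reproduces the trajectory cadences", {
  g <- data.frame(system = "a1b2g2", state = c("+BIC", "+GABA"),
                  subunit = "b2", mean_A = c(2.9, 3.6), sd_A = c(0.15, 0.4))
  # 4 replicates x 500 ns at 2 ns -> 1000 frames per group
  s <- synth_distance_series(g, n_replicates = 4, duration_ns = 500,
                             cadence_ns = 2, seed = 7)
  expect_equal(unname(table(s$state)), rep(1000L, 2), ignore_attr = TRUE)
  expect_equal(max(s$time_ns), 500)
  # 5 replicates x 200 ns at 1 ns -> also 1000
  s2 <- synth_distance_series(g[1, ], n_replicates = 5, duration_ns = 200,
                              cadence_ns = 1, seed = 7)
  expect_equal(nrow(s2), 1000)

  # deterministic under seed; different seed differs
  s3 <- synth_distance_series(g, n_replicates = 4, duration_ns = 500,
                              cadence_ns = 2, seed = 7)
  expect_identical(s, s3)
  s4 <- synth_distance_series(g, n_replicates = 4, duration_ns = 500,
                              cadence_ns = 2, seed = 8)
  expect_false(identical(s, s4))

  # steric floor respected
  expect_true(all(s$distance_A > 2.2))

  # zero mixture weight degenerates to the single normal; large-sample mean
  gm <- data.frame(system = "x", state = "s", subunit = "u",
                   mean_A = 3.0, sd_A = 0.2, mean2_A = 5, sd2_A = 0.3,
                   weight2 = 0)
  sm <- synth_distance_series(gm, n_replicates = 1, duration_ns = 1e5,
                              cadence_ns = 1, seed = 9)
  expect_equal(mean(sm$distance_A), 3.0,
               tolerance = 3 * 0.2 / sqrt(1e5) / 3.0)
})

test_that("aggregation pools replicates and normalizes densities", {
  g <- data.frame(system = "a1b2g2", state = c("+BIC", "+GABA"),
                  subunit = "b2", mean_A = c(2.9, 3.6), sd_A = c(0.15, 0.4))
  s <- synth_distance_series(g, seed = 7)
  sums <- aggregate_distances(s)
  expect_equal(length(sums), 2)
  for (sm in sums) {
    expect_equal(sm$n, 1000)
    expect_equal(sm$n, sum(sm$counts))
    # histogram densities integrate to 1
    expect_equal(sum(sm$density) * diff(sm$breaks[1:2]), 1, tolerance = 1e-9)
    expect_true(sm$frac_le_cutoff >= 0 && sm$frac_le_cutoff <= 1)
  }

  # permutation invariance: relabelling replicates changes nothing pooled
  sp <- s; sp$replicate <- ((sp$replicate + 1) %% 4) + 1
  sums_p <- aggregate_distances(sp)
  expect_equal(sums_p[[1]]$counts, sums[[1]]$counts)
  expect_equal(sums_p[[1]]$median, sums[[1]]$median)

  # constant distances: mean = median = d, SD = 0
  k <- data.frame(system = "x", state = "s", replicate = 1, subunit = "u",
                  time_ns = 1:10, distance_A = 3.3)
  sk <- aggregate_distances(k)[[1]]
  expect_equal(sk$mean, 3.3); expect_equal(sk$median, 3.3)
  expect_equal(sk$sd, 0)

  # fraction below cutoff is monotone in the cutoff
  fr <- vapply(c(2.5, 3.0, 3.5, 4.0, 6.0), function(ct)
    aggregate_distances(s, cutoff = ct)[[2]]$frac_le_cutoff, numeric(1))
  expect_true(all(diff(fr) >= 0))

  expect_error(aggregate_distances(s, group_by = "nonsense"), "unknown")
  expect_error(validate_distance_series <- aggregate_distances(
    data.frame(system = 1)), "columns")
})

test_that("state shifts separate closed-like from activated-like bonds", {
  g <- data.frame(system = "a1b2g2", state = c("closed", "open"),
                  subunit = "b2", mean_A = c(2.9, 3.6), sd_A = c(0.15, 0.4))
  s <- synth_distance_series(g, n_replicates = 4, duration_ns = 500,
                             cadence_ns = 2, seed = 13)
  sums <- aggregate_distances(s)
  sh <- state_shift(sums[[1]], sums[[2]])
  expect_equal(sh$median_shift_A, 0.7, tolerance = 0.05 / 0.7)
  expect_lt(sh$overlap, 0.35)

  # identical distributions: zero shift, overlap 1
  same <- state_shift(sums[[1]], sums[[1]])
  expect_equal(same$median_shift_A, 0)
  expect_equal(same$overlap, 1, tolerance = 1e-9)

  # disjoint supports: overlap ~ 0
  gd <- data.frame(system = "x", state = c("a", "b"), subunit = "u",
                   mean_A = c(2.6, 5.4), sd_A = c(0.05, 0.05))
  sd_ <- aggregate_distances(synth_distance_series(gd, seed = 3))
  expect_lt(state_shift(sd_[[1]], sd_[[2]])$overlap, 1e-6)

  # incompatible binning refused
  other <- aggregate_distances(s, binwidth_A = 0.1)
  expect_error(state_shift(sums[[1]], other[[2]]), "incompatible")
})

test_that("distance series round-trip as delimited text, with coordinates", {
  g <- data.frame(system = "x", state = "s", subunit = "u",
                  mean_A = 3, sd_A = 0.2)
  s <- synth_distance_series(g, n_replicates = 2, duration_ns = 20,
                             cadence_ns = 2, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_distance_series(s, f)
  s2 <- read_distance_series(f)
  expect_equal(s2$distance_A, s$distance_A, tolerance = 1e-12)

  # coordinate dialect: distances computed on read
  co <- data.frame(system = "x", state = "s", replicate = 1, subunit = "u",
                   time_ns = 1:3,
                   donor_x = 0, donor_y = 0, donor_z = 0,
                   acceptor_x = c(3, 0, 1), acceptor_y = c(4, 3, 0),
                   acceptor_z = c(0, 4, 0))
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(co, f2, row.names = FALSE)
  s3 <- read_distance_series(f2)
  expect_equal(s3$distance_A, c(5, 5, 1))
  unlink(c(f, f2))
})
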