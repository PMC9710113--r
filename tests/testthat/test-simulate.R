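test_that("random networks are reproducible, self-loop free and density-consistent", {
  net <- random_network(20, density = 0.15, seed = 3)
  expect_identical(net, random_network(20, density = 0.15, seed = 3))
  expect_true(all(net$regulator != net$target))
  expect_true(all(abs(net$weight) >= 0.25 & abs(net$weight) <= 1))
  n_pairs <- 20 * 19
  se <- sqrt(n_pairs * 0.15 * 0.85)
  expect_lt(abs(nrow(net) - 0.15 * n_pairs), 3 * se)
  expect_error(random_network(10, density = 1.2),
               class = "splsnet_config_error")
  tf_net <- random_network(10, density = 0.2, n_tfs = 3, seed = 1)
  expect_equal(network_tfs(tf_net), c("G1", "G2", "G3"))
})

test_that("hand-built networks validate their edges", {
  net <- grn_network(data.frame(regulator = "A", target = "B"),
                     gene_ids = c("A", "B", "C"))
  expect_equal(network_genes(net), c("A", "B", "C"))
  expect_equal(net$weight, 1)
  expect_error(grn_network(data.frame(regulator = "A", target = "A")),
               class = "splsnet_input_error")
  expect_error(grn_network(data.frame(regulator = "A", target = "B",
                                      weight = 0)),
               class = "splsnet_input_error")
})

test_that("time-series simulation is shaped, deterministic and hits the fixed point", {
  net <- random_network(8, density = 0.2, seed = 5)
  ts <- simulate_timeseries(net, n_series = 12, times = seq(0, 200, 50),
                            seed = 5)
  expect_equal(dim(ts$values), c(12, 5, 8))
  expect_true(all(ts$values >= 0))
  ts2 <- simulate_timeseries(net, n_series = 12, times = seq(0, 200, 50),
                             seed = 5)
  expect_identical(ts$values, ts2$values)

  # no edges, no noise: every gene relaxes to production * sigmoid(basal) / decay
  empty <- grn_network(data.frame(regulator = character(),
                                  target = character(),
                                  weight = numeric()),
                       gene_ids = paste0("G", 1:4))
  det <- simulate_timeseries(empty, n_series = 3, times = c(0, 3000),
                             noise_sd = 0, basal = 0, seed = 2)
  expect_equal(unname(det$values[, 2, ]),
               matrix(1, 3, 4), tolerance = 0.01)

  expect_error(simulate_timeseries(net, times = c(0, 50, 50)),
               class = "splsnet_config_error")
})

test_that("cell-count sampling schemes match the published table", {
  sc50 <- sampling_scheme(50)
  expect_equal(sc50$time, c(0, 500))
  expect_equal(sc50$n_at_point, c(25, 25))
  sc10 <- sampling_scheme(10)
  expect_equal(sc10$time, c(0, 500))
  expect_equal(sc10$n_at_point, c(5, 5))
  sc500 <- sampling_scheme(500)
  expect_equal(sc500$time, seq(0, 900, 100))
  expect_equal(unique(sc500$n_at_point), 50)
  sc100 <- sampling_scheme(100)
  expect_equal(sc100$time, seq(0, 900, 100))
  expect_equal(unique(sc100$n_at_point), 10)
  # 20 time points for the two largest sets, not 21
  expect_equal(sampling_scheme(1000)$time, seq(0, 950, 50))
  expect_equal(sampling_scheme(5000)$time, seq(0, 950, 50))
  expect_equal(unique(sampling_scheme(5000)$n_at_point), 250)
  # generic fallback spreads evenly from the earliest point
  sc37 <- sampling_scheme(37, times = seq(0, 1000, 50))
  expect_equal(sum(sc37$n_at_point), 37)
  expect_lte(max(sc37$n_at_point) - min(sc37$n_at_point), 1)
})

test_that("cells are drawn from distinct series at each scheme time point", {
  # encode (series, time) in the values so draws can be decoded
  n_series <- 60
  times <- seq(0, 1000, 50)
  vals <- array(0, c(n_series, length(times), 3))
  for (s in seq_len(n_series)) for (t in seq_along(times)) {
    vals[s, t, ] <- c(s, t, s + 1000 * t)
  }
  ts <- structure(list(values = vals, times = times,
                       genes = c("series", "timeidx", "combo")),
                  class = "grn_timeseries")
  expr <- sample_cells(ts, 50, seed = 4)
  expect_equal(nrow(expr), 50)
  expect_equal(sort(unique(expr$timeidx)), c(1, 11)) # times 0 and 500
  for (tix in unique(expr$timeidx)) {
    drawn <- expr$series[expr$timeidx == tix]
    expect_length(drawn, 25)
    expect_false(any(duplicated(drawn))) # without replacement
  }
  expect_error(sample_cells(ts, 5000), class = "splsnet_input_error")
})

test_that("dropout induction only touches each gene's lowest-quantile entries", {
  set.seed(6)
  m <- matrix(rexp(2000) + 0.01, 100, 20)
  colnames(m) <- paste0("g", 1:20)
  expect_identical(induce_dropout(m, rate = 0, seed = 1), m)
  expect_identical(induce_dropout(m, rate = 0.5, bern_prob = 0, seed = 1), m)

  # certain masking of the lowest half: exactly the 50 smallest become 0
  out <- induce_dropout(m, rate = 0.5, bern_prob = 1, seed = 1)
  for (g in 1:20) {
    low <- order(m[, g])[1:50]
    expect_true(all(out[low, g] == 0))
    expect_identical(out[-low, g], m[-low, g])
  }

  # under random masking, entries above the quantile are never modified
  for (seed in 1:10) {
    out2 <- induce_dropout(m, rate = 0.3, bern_prob = 0.5, seed = seed)
    changed <- which(out2 != m, arr.ind = TRUE)
    expect_true(all(out2[changed] == 0))
    for (g in unique(changed[, 2])) {
      eligible <- order(m[, g])[1:30]
      expect_true(all(changed[changed[, 2] == g, 1] %in% eligible))
    }
  }

  # tibble input round-trips its identifier column
  df <- as_expr_tibble(m)
  out3 <- induce_dropout(df, rate = 0.2, bern_prob = 0.5, seed = 2)
  expect_identical(out3$cell, df$cell)
  expect_s3_class(out3, "tbl_df")
})

test_that("knockout steady states have the right shape and edge response", {
  empty <- grn_network(data.frame(regulator = character(),
                                  target = character(),
                                  weight = numeric()),
                       gene_ids = paste0("G", 1:4))
  ko <- simulate_knockouts(empty, seed = 2)
  expect_equal(dim(ko), c(5, 4))
  for (g in 1:4) {
    expect_equal(ko[g + 1, g], 0)
    expect_equal(ko[g + 1, -g], ko["wildtype", -g], tolerance = 1e-6)
  }

  act <- grn_network(data.frame(regulator = "A", target = "B", weight = 0.9))
  ko2 <- simulate_knockouts(act, seed = 2)
  expect_lt(ko2["ko_A", "B"], ko2["wildtype", "B"]) # losing an activator

  # a repressilator cycle has no stable fixed point at this gain: error
  rep3 <- grn_network(data.frame(regulator = c("A", "B", "C"),
                                 target = c("B", "C", "A"),
                                 weight = c(-1, -1, -1)))
  expect_error(simulate_knockouts(rep3, seed = 1),
               class = "splsnet_simulation_error")
})
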