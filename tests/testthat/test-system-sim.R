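test_that("event records are additive, bounded and reproducible", {
  cfg <- sim_config(n_events = 5000, seed = 31)
  ev <- simulate_events(cfg)
  expect_equal(ev$total_min,
               ev$clinical_min + ev$pts_min + ev$wait_min +
                 ev$drone_service_min + ev$lab_min)
  expect_equal(ev$drone_min, ev$wait_min + ev$drone_service_min)
  expect_true(all(ev$wait_min >= 0 & ev$wait_min < 15))
  # increment factors keep each component within [x, 1.2x]
  expect_true(all(ev$drone_service_min >= 7.6 &
                    ev$drone_service_min <= 7.6 * 1.2))
  expect_identical(ev, simulate_events(cfg))
  expect_false(identical(ev, simulate_events(cfg, seed = 32)))
})

test_that("degenerate components isolate the drone leg", {
  zero <- dist_point_mass(0)
  cfg <- sim_config(n_events = 2000, increment_max = 0, seed = 5,
                    components = list(clinical = zero, pts = zero,
                                      lab = zero))
  ev <- simulate_events(cfg)
  expect_true(all(ev$total_min >= 7.6 & ev$total_min < 22.6))
  expect_equal(ev$total_min, ev$wait_min + 7.6)
  rep <- run_simulation(sim_config(n_events = 2000, n_replicates = 2,
                                   increment_max = 0, seed = 5,
                                   components = list(clinical = zero,
                                                     pts = zero, lab = zero)))
  # wait < 15 and dft 7.6 < 15: nothing violates any allowance
  expect_true(all(rep$replicates == 0))
})

test_that("mean drone time matches the uniform-wait oracle", {
  cfg <- sim_config(n_events = 10000, seed = 77)
  ev <- simulate_events(cfg)
  # wait ~ U(0, 15), service = 7.6 * U(1, 1.2): mean 7.5 + 7.6 * 1.1
  oracle <- 15 / 2 + 7.6 * 1.1
  se <- sqrt((15^2 / 12 + (7.6 * 0.2)^2 / 12) / nrow(ev))
  expect_lt(abs(mean(ev$drone_min) - oracle), 3 * se)
})

test_that("laboratory exceedance matches the numeric-integration oracle", {
  cfg <- sim_config(n_events = 20000, n_replicates = 3, seed = 13)
  rep <- run_simulation(cfg)
  oracle <- exceedance_oracle(cfg$components$lab, 15, 0.20)
  p_hat <- mean(rep$replicates[, "frac_lab_gt_15"])
  se <- sqrt(oracle * (1 - oracle) / (3 * 20000))
  expect_lt(abs(p_hat - oracle), 4 * se)
  # with the median anchored at the threshold the exceedance sits just
  # above one half
  expect_gt(oracle, 0.5)
  expect_lt(oracle, 0.53)
})

test_that("violation fractions are monotone in thresholds and increment", {
  cfg <- sim_config(n_events = 10000, seed = 21)
  ev <- simulate_events(cfg)
  for (col in c("clinical_min", "pts_min", "lab_min", "total_min")) {
    fr <- vapply(c(5, 10, 15, 30, 60), function(th) mean(ev[[col]] > th),
                 numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
  # larger increment, same seed: every violation fraction at least as large
  r_small <- run_simulation(sim_config(n_events = 5000, n_replicates = 3,
                                       increment_max = 0.05, seed = 21))
  r_big <- run_simulation(sim_config(n_events = 5000, n_replicates = 3,
                                     increment_max = 0.30, seed = 21))
  expect_true(all(r_big$replicates >= r_small$replicates))
})

test_that("fractions converge between 10k and 100k events", {
  cfg <- sim_config(seed = 8)
  p1 <- mean(simulate_events(cfg, n = 10000)$lab_min > 15)
  p2 <- mean(simulate_events(cfg, n = 100000, seed = 9)$lab_min > 15)
  pbar <- (p1 + p2) / 2
  half_width <- 2.58 * sqrt(pbar * (1 - pbar) * (1 / 10000 + 1 / 100000))
  expect_lt(abs(p1 - p2), half_width)
})

test_that("replicate summaries are plain mean/sd/min/max rows", {
  m <- rbind(a = c(0.30, 0.1, 0, 0, 0), b = c(0.34, 0.1, 0, 0, 0))
  colnames(m) <- c("frac_total_gt_limit", "frac_pts_gt_5",
                   "frac_clinical_gt_15", "frac_lab_gt_15",
                   "frac_drone_gt_15")
  s <- summarize_replicates(m)
  expect_equal(s["frac_total_gt_limit", "mean"], 0.32)
  expect_equal(s["frac_total_gt_limit", "min"], 0.30)
  expect_equal(s["frac_total_gt_limit", "max"], 0.34)
  expect_equal(s["frac_total_gt_limit", "sd"], sd(c(0.30, 0.34)))
  # identical replicates: zero spread
  s2 <- summarize_replicates(rbind(m[1, ], m[1, ]))
  expect_equal(s2$sd, rep(0, 5))
  # a single replicate has no spread estimate and is flagged
  s1 <- summarize_replicates(m[1, , drop = FALSE])
  expect_true(all(is.na(s1$sd)))
  expect_true(isTRUE(attr(s1, "single_replicate")))
})

test_that("replicates in a report differ only by child seeds", {
  rep <- run_simulation(sim_config(n_events = 2000, n_replicates = 3,
                                   seed = 55))
  rep2 <- run_simulation(sim_config(n_events = 2000, n_replicates = 3,
                                    seed = 55))
  expect_identical(rep$replicates, rep2$replicates)
  expect_false(all(rep$replicates[1, ] == rep$replicates[2, ]))
  expect_true(all(rep$summary$min <= rep$summary$mean &
                    rep$summary$mean <= rep$summary$max))
})
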