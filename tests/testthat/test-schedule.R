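test_that("single samples, empty streams and overweight samples behave", {
  one <- data.frame(sample_id = 1L, arrival_min = 7, weight_g = 10)
  res <- assign_to_flights(one, schedule_spec(15, 3500))
  expect_equal(res$assignment$departure_min, 15)
  expect_equal(res$assignment$wait_min, 8)
  expect_equal(res$carryover_count, 0L)

  # arrival exactly at a departure boards that flight
  at_dep <- data.frame(sample_id = 1L, arrival_min = 15, weight_g = 10)
  expect_equal(assign_to_flights(at_dep,
                                 schedule_spec(15))$assignment$wait_min, 0)

  empty <- assign_to_flights(data.frame(arrival_min = numeric(0),
                                        weight_g = numeric(0)),
                             schedule_spec(15, 3500))
  expect_equal(nrow(empty$flights), 0L)
  expect_equal(empty$carryover_count, 0L)

  heavy <- data.frame(sample_id = 7L, arrival_min = 1, weight_g = 4000)
  err <- expect_error(assign_to_flights(heavy, schedule_spec(15, 3500)),
                      class = "dronelab_unshippable_sample")
  expect_match(conditionMessage(err), "7")
})

test_that("capacity overflow carries over in arrival order", {
  five <- data.frame(sample_id = 1:5,
                     arrival_min = c(2, 4, 6, 8, 10),
                     weight_g = rep(1000, 5))
  res <- assign_to_flights(five, schedule_spec(15, 3500))
  expect_equal(res$assignment$departure_min, c(15, 15, 15, 30, 30))
  expect_equal(res$flights$payload_g[res$flights$departure_min == 15], 3000)
  expect_equal(res$carryover_count, 2L)
  # the trailing partial flight departs
  expect_equal(max(res$flights$departure_min), 30)
  expect_equal(sum(res$flights$payload_g), 5000)
})

test_that("assignment matches the brute-force oracle on tiny instances", {
  for (sd in 1:8) {
    set.seed(sd)
    n <- sample(2:6, 1)
    arrival <- sort(round(runif(n, 0, 40), 1))
    weight <- sample(c(500, 1000, 2000, 3000), n, replace = TRUE)
    stream <- data.frame(sample_id = seq_len(n), arrival_min = arrival,
                         weight_g = weight)
    res <- assign_to_flights(stream, schedule_spec(15, 3500))
    oracle <- brute_force_assignment(arrival, weight, 15, 3500)
    expect_equal(res$assignment$departure_min, oracle,
                 info = paste("seed", sd))
  }
})

test_that("conservation, FIFO and capacity hold on random streams", {
  for (sd in c(3, 17, 52)) {
    stream <- random_stream(250, horizon = 400, seed = sd)
    sch <- schedule_spec(15, 3500)
    res <- assign_to_flights(stream, sch)
    # conservation: every sample appears exactly once
    expect_setequal(res$assignment$sample_id, stream$sample_id)
    expect_equal(sum(res$flights$payload_g), sum(stream$weight_g))
    expect_equal(sum(res$flights$n_samples), nrow(stream))
    # FIFO: departures non-decreasing in arrival order
    expect_false(is.unsorted(res$assignment$departure_min))
    # capacity and fill fraction
    expect_true(all(res$flights$payload_g <= sch$capacity))
    expect_true(all(res$flights$fill_fraction >= 0 &
                      res$flights$fill_fraction <= 1))
    expect_true(all(res$assignment$wait_min >= 0))

    # with unlimited capacity every wait is below one interval
    unl <- assign_to_flights(stream, schedule_spec(15, Inf))
    expect_true(all(unl$assignment$wait_min < 15))
    expect_equal(unl$carryover_count, 0L)

    # halving the interval never increases any sample's wait
    for (cap in c(Inf, 3500)) {
      w30 <- assign_to_flights(stream, schedule_spec(30, cap))$assignment
      w15 <- assign_to_flights(stream, schedule_spec(15, cap))$assignment
      expect_true(all(w15$wait_min[order(w15$sample_id)] <=
                        w30$wait_min[order(w30$sample_id)]))
    }
  }
})

test_that("payload series sums flights into bins and conserves weight", {
  one <- data.frame(sample_id = 1L, arrival_min = 30, weight_g = 3000)
  res <- assign_to_flights(one, schedule_spec(30, 3500))
  expect_equal(payload_series(res, bin = 30), c(3000))
  two <- data.frame(sample_id = 1:2, arrival_min = c(10, 40),
                    weight_g = c(1000, 500))
  res2 <- assign_to_flights(two, schedule_spec(15, 3500))
  expect_equal(sum(payload_series(res2, bin = 60)), 1500)
  expect_equal(payload_series(res2, bin = 60)[1], 1500)

  stream <- random_stream(150, seed = 5)
  res3 <- assign_to_flights(stream, schedule_spec(15, 3500))
  expect_equal(sum(payload_series(res3, bin = 60)), sum(stream$weight_g))
})

test_that("filling windows measure accumulated capacity fractions", {
  sch <- schedule_spec(15, 3500)
  none <- filling_windows(data.frame(arrival_min = numeric(0),
                                     weight_g = numeric(0)), sch)
  expect_equal(none$fill_fraction, rep(0, 20))
  expect_equal(nrow(none), 20L)
  expect_equal(none$start_min, seq(0, by = 5, length.out = 20))

  # constant 3500 g per 15-min window saturates every window
  sat <- data.frame(arrival_min = seq(1, 115), weight_g = 3500 / 15)
  fw <- filling_windows(sat, sch, count = 10)
  expect_equal(fw$fill_fraction, rep(1, 10), tolerance = 1e-9)
  expect_false(any(fw$overflow))

  over <- data.frame(arrival_min = rep(5, 2), weight_g = c(3500, 100))
  fw2 <- filling_windows(over, sch, count = 1)
  expect_equal(fw2$fill_fraction, 1)
  expect_true(fw2$overflow)
})

test_that("the feasible-interval search returns the largest fitting interval", {
  # printed component means with worst-case wait: only 15 min fits 60 min
  best <- feasible_max_interval(c(15, 30, 45, 60),
                                component_means = c(3.5, 3.2, 28.1), dft = 8)
  expect_equal(as.numeric(best), 15)
  expect_equal(attr(best, "margin"), 60 - (3.5 + 3.2 + 15 + 8 + 28.1))

  # a slack budget admits the largest candidate
  expect_equal(as.numeric(
    feasible_max_interval(c(15, 30, 45, 60),
                          time_budget(t_em = 1000),
                          component_means = c(3.5, 3.2, 28.1), dft = 8)), 60)

  # 3.5 + 3.2 + 20 + 8 + 28.1 = 62.8 > 60: infeasible, margins reported
  err <- expect_error(
    feasible_max_interval(20, component_means = c(3.5, 3.2, 28.1), dft = 8),
    class = "dronelab_infeasible")
  expect_equal(err$margin, 60 - 62.8, tolerance = 1e-9)

  # mean-wait mode halves the wait term
  expect_equal(as.numeric(
    feasible_max_interval(c(15, 30), component_means = c(3.5, 3.2, 28.1),
                          dft = 8, wait = "mean")), 30)
})
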