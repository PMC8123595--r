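test_that("flight leg time is distance over speed in minutes", {
  expect_equal(compute_leg_time(3.6, 60), 3.6)
  expect_equal(compute_leg_time(0, 60), 0)
  expect_equal(compute_leg_time(1.8, 60), 1.8)
  expect_error(compute_leg_time(3.6, 0), class = "dronelab_invalid_parameter")
  expect_error(compute_leg_time(3.6, -5), class = "dronelab_invalid_parameter")
  # dimensional round trip km -> min -> km
  d <- 2.7183
  expect_equal(compute_leg_time(d, 37.5) * 37.5 / 60, d, tolerance = 1e-12)
})

test_that("drone flight time decomposes into takeoff + leg + landing", {
  expect_equal(compute_dft(flight_params()), 1 + 3.6 + 3)
  expect_lte(compute_dft(flight_params()), 8) # within the planning value
  expect_equal(compute_dft(flight_params(distance = 7.2)), 11.2)
  # monotone: increasing in distance, decreasing in speed
  expect_gt(compute_dft(flight_params(distance = 5)),
            compute_dft(flight_params(distance = 3.6)))
  expect_lt(compute_dft(flight_params(speed = 90)),
            compute_dft(flight_params(speed = 60)))
  tm <- drone_timing()
  expect_equal(tm$dft, tm$t_toff + tm$t_flig + tm$t_desc)
  expect_equal(tm$d_t, tm$t_load + tm$dft + tm$t_offl)
  expect_equal(drone_timing()$t_offl, 0)
})

test_that("allowed drone time subtracts the non-drone components", {
  b <- time_budget()
  expect_equal(as.numeric(allowed_drone_time(b, 3.5, 3.2, 28.1)), 25.2)
  expect_equal(as.numeric(allowed_drone_time(b, 0, 0, 0)), 60)
  x <- allowed_drone_time(b, 30, 10, 25)
  expect_equal(as.numeric(x), -5)
  expect_true(attr(x, "infeasible"))
  # strictly decreasing in each component
  base <- as.numeric(allowed_drone_time(b, 5, 5, 5))
  expect_lt(as.numeric(allowed_drone_time(b, 6, 5, 5)), base)
  expect_lt(as.numeric(allowed_drone_time(b, 5, 6, 5)), base)
  expect_lt(as.numeric(allowed_drone_time(b, 5, 5, 6)), base)
})

test_that("maximum loading time closes the budget identity", {
  b <- time_budget()
  expect_equal(as.numeric(max_load_time(b, dft = 7.6)), 17.4)
  expect_equal(as.numeric(max_load_time(b, dft = 8)), 17)
  expect_equal(as.numeric(max_load_time(time_budget(t_em = 60), 0))
               + 15 + 5 + 15, 60)
  # at the component allowances, allowed time = drone allowance + slack and
  # load + flight + offload can never exceed it
  for (b2 in list(time_budget(), time_budget(t_em = 90, post_limit = 30),
                  time_budget(45, 10, 5, 10, 10))) {
    at_limits <- as.numeric(
      allowed_drone_time(b2, b2$pre_limit, b2$transport_limit, b2$post_limit))
    slack <- b2$t_em - (b2$pre_limit + b2$transport_limit + b2$post_limit +
                          b2$drone_limit)
    expect_equal(at_limits, b2$drone_limit + slack)
    for (dft in c(0, 5, 9)) {
      expect_lte(as.numeric(max_load_time(b2, dft)) + dft + 0, at_limits)
    }
  }
  infeasible <- max_load_time(time_budget(), dft = 30)
  expect_true(attr(infeasible, "infeasible"))
})

test_that("non-drone totals are component sums with a documented caveat", {
  tab <- list(
    clinical = c(mean = 3.5, sd = 3.2, min = 1.0, max = 180),
    pts = c(mean = 3.2, sd = 1.4, min = 0.1, max = 28),
    lab = c(mean = 28.1, sd = 10.5, min = 9.1, max = 125)
  )
  tot <- total_nondrone_stats(tab)
  expect_equal(unname(tot["max"]), 333)
  expect_equal(unname(tot["mean"]), 34.8)
  expect_equal(unname(tot["min"]), 10.2)
  expect_match(attr(tot, "caveat"), "bounds")

  zero <- c(mean = 0, sd = 0, min = 0, max = 0)
  expect_equal(unname(total_nondrone_stats(list(zero, zero, zero))),
               c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_error(total_nondrone_stats(tab[1:2]),
               class = "dronelab_invalid_input")
  expect_error(total_nondrone_stats(list(zero, zero, c(mean = 1, sd = 1))),
               class = "dronelab_invalid_input")
})
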