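#' Sample container specification
#'
#' A container type with its filled weight and nominal volume. Filled
#' density (weight/volume) must be physically plausible for biological
#' samples, between 0.7 and 3.3 g/mL; a 0.05 g/mL tolerance absorbs
#' rounding of printed reference weights (the 166 g / 50 mL blood-culture
#' bottle rounds to 3.32 g/mL).
#'
#' @param name label for the container type.
#' @param filled_weight weight when filled as recommended, grams > 0.
#' @param volume nominal volume, millilitres > 0.
#' @return A \code{container_spec} object.
#' @export
container_spec <- function(name, filled_weight, volume) {
  stopifnot(is.character(name), length(name) == 1L,
            is_number(filled_weight), filled_weight > 0,
            is_number(volume), volume > 0)
  density <- filled_weight / volume
  tol <- 0.05
  if (density < 0.7 - tol || density > 3.3 + tol) {
    stop_dronelab(
      sprintf("container '%s' density %.2f g/mL outside plausible [0.7, 3.3]",
              name, density),
      "dronelab_invalid_container"
    )
  }
  structure(list(name = name, filled_weight = filled_weight, volume = volume,
                 density = density),
            class = "container_spec")
}

#' Default container set
#'
#' The two printed reference containers — a 7 g / 10 mL blood tube and a
#' 166 g / 50 mL bottle — plus two intermediate types spanning the
#' observed weight range.
#'
#' @return List of \code{container_spec} objects.
#' @export
default_containers <- function() {
  list(
    container_spec("tube_10ml",   7,  10),
    container_spec("gel_tube_5ml", 9,  5),
    container_spec("urine_cup_40ml", 60, 40),
    container_spec("bottle_50ml", 166, 50)
  )
}

# Hour-of-day multipliers of the weekday demand profile, as fractions of the
# peak hour. Trapezoidal: ramp 6-8 a.m., plateau 8-12 a.m. (the busiest
# block), decay through the afternoon to a low positive overnight constant
# so that emergency demand is present around the clock.
weekday_profile_default <- function() {
  c(rep(0.10, 6),              # 00-05
    0.45, 0.75,                # 06, 07 ramp
    1.00, 1.00, 1.00, 1.00,    # 08-11 plateau
    0.85, 0.70, 0.60, 0.50,    # 12-15 decay
    0.40, 0.30, 0.25, 0.20,    # 16-19
    0.15, 0.12, 0.10, 0.10)    # 20-23
}

#' Weekly activity calendar for laboratory sample demand
#'
#' Encodes the arrival intensity of sample orders (orders per minute on a
#' 1-minute grid, piecewise constant per hour), the emergency share, and
#' the container mix per priority class. The default shape is a trapezoidal
#' weekday profile peaking 8--12 a.m. Monday--Thursday with weekends at 40%
#' of weekday level, and is calibrated so the expected peak hourly payload
#' (intensity times mean sample weight, maximised over the week) equals
#' \code{peak_payload_g}.
#'
#' @param weekday_profile 24 hourly multipliers (fractions of the peak
#'   hour) for Monday--Thursday; all > 0 so emergency demand exists at
#'   every hour.
#' @param friday_factor,weekend_factor scale of the weekday profile applied
#'   on Friday and on Saturday/Sunday.
#' @param emergency_fraction share of orders that are emergency analyses;
#'   default 0.235.
#' @param containers list of \code{container_spec}; must contain the two
#'   reference containers (7 g tube, 166 g bottle).
#' @param container_mix probabilities per container, same length as
#'   \code{containers}, summing to 1. The default gives the standard tube
#'   85\% of orders and spreads the remainder with the heavy 50 mL bottle
#'   at 1\%: large containers are a small fraction of a biochemistry
#'   laboratory's volume, and the observed demand never strayed more than
#'   20\% above its mean maximum, which a fatter large-container share
#'   would violate.
#' @param peak_payload_g expected peak hourly payload to calibrate to, in
#'   grams; default 8000. Use \code{NA} to skip calibration and keep the
#'   profile with a nominal peak of \code{peak_orders_per_min}.
#' @param peak_orders_per_min nominal peak intensity before calibration.
#' @return An \code{activity_calendar}: list with the 7 x 1440 intensity
#'   matrix (rows Monday..Sunday, columns minute-of-day), emergency
#'   fraction and weight mix.
#' @export
activity_calendar <- function(weekday_profile = weekday_profile_default(),
                              friday_factor = 0.85,
                              weekend_factor = 0.40,
                              emergency_fraction = 0.235,
                              containers = default_containers(),
                              container_mix = c(0.85, 0.10, 0.04, 0.01),
                              peak_payload_g = 8000,
                              peak_orders_per_min = 1) {
  stopifnot(is.numeric(weekday_profile), length(weekday_profile) == 24L,
            all(is.finite(weekday_profile)),
            is_number(emergency_fraction),
            emergency_fraction > 0, emergency_fraction < 1,
            is.numeric(container_mix),
            length(container_mix) == length(containers),
            all(container_mix >= 0), abs(sum(container_mix) - 1) < 1e-8,
            is_number(peak_orders_per_min), peak_orders_per_min > 0)
  if (any(weekday_profile < 0)) {
    stop_dronelab("intensity profile must be non-negative",
                  "dronelab_invalid_calendar")
  }
  if (any(weekday_profile <= 0)) {
    stop_dronelab("24-h emergency demand requires strictly positive intensity",
                  "dronelab_invalid_calendar")
  }
  containers <- lapply(containers, function(x) {
    if (!inherits(x, "container_spec")) {
      do.call(container_spec, x[c("name", "filled_weight", "volume")])
    } else x
  })
  weights <- vapply(containers, `[[`, numeric(1), "filled_weight")
  if (!any(abs(weights - 7) < 1e-9) || !any(abs(weights - 166) < 1e-9)) {
    stop_dronelab("containers must include the 7 g tube and 166 g bottle",
                  "dronelab_invalid_calendar")
  }
  day_factors <- c(1, 1, 1, 1, friday_factor, weekend_factor, weekend_factor)
  hourly <- outer(day_factors, weekday_profile) * peak_orders_per_min
  intensity <- hourly[, rep(seq_len(24), each = 60)]
  dimnames(intensity) <- list(
    c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), NULL)
  cal <- structure(
    list(intensity = intensity,
         emergency_fraction = emergency_fraction,
         containers = containers,
         container_mix = container_mix),
    class = "activity_calendar"
  )
  if (!is.na(peak_payload_g)) {
    cal <- calibrate_peak_payload(cal, peak_payload_g)
  }
  cal
}

#' @export
print.activity_calendar <- function(x, ...) {
  hourly <- hourly_intensity(x)
  cat("Weekly activity calendar (orders/min, piecewise-constant per hour)\n")
  cat(sprintf("  peak intensity: %.3f orders/min (%s %02d:00)\n",
              max(x$intensity),
              rownames(hourly)[which(hourly == max(hourly),
                                     arr.ind = TRUE)[1, 1]],
              which(hourly == max(hourly), arr.ind = TRUE)[1, 2] - 1L))
  cat(sprintf("  expected orders/week: %.0f\n", sum(x$intensity)))
  cat(sprintf("  emergency fraction: %.3f\n", x$emergency_fraction))
  cat(sprintf("  mean sample weight: %.1f g over %d container types\n",
              mean_sample_weight(x), length(x$containers)))
  cat(sprintf("  expected peak hourly payload: %.0f g\n",
              expected_peak_payload(x)))
  invisible(x)
}

# 7 x 24 matrix of orders/min per (day, hour)
hourly_intensity <- function(cal) {
  m <- cal$intensity[, seq(1, 1440, by = 60), drop = FALSE]
  colnames(m) <- sprintf("%02d", 0:23)
  m
}

#' Mean sample weight under a calendar's container mix
#'
#' @param cal an \code{activity_calendar}.
#' @return Expected filled weight in grams of a random order.
#' @export
mean_sample_weight <- function(cal) {
  stopifnot(inherits(cal, "activity_calendar"))
  w <- vapply(cal$containers, `[[`, numeric(1), "filled_weight")
  sum(w * cal$container_mix)
}

#' Calibrate a calendar to a target expected peak hourly payload
#'
#' Rescales the intensity surface by a single factor so that the expected
#' maximum hourly payload over the week — hourly order intensity times the
#' mean sample weight — equals \code{target_hourly_peak} grams. Linear, so
#' calibration is idempotent and doubling the target doubles the intensity.
#'
#' @param cal an \code{activity_calendar}.
#' @param target_hourly_peak target expected peak hourly payload, grams > 0.
#' @return The rescaled calendar.
#' @export
calibrate_peak_payload <- function(cal, target_hourly_peak) {
  stopifnot(inherits(cal, "activity_calendar"),
            is_number(target_hourly_peak), target_hourly_peak > 0)
  # orders/hour per (hour, day) cell, without assuming per-hour constancy
  peak_rate <- max(rowsum(t(cal$intensity), rep(seq_len(24), each = 60)))
  if (peak_rate <= 0) {
    stop_dronelab("cannot calibrate a calendar with zero intensity",
                  "dronelab_cannot_calibrate")
  }
  current_peak <- peak_rate * mean_sample_weight(cal)
  cal$intensity <- cal$intensity * (target_hourly_peak / current_peak)
  cal
}

#' Expected peak hourly payload of a calendar
#'
#' @param cal an \code{activity_calendar}.
#' @return Grams: maximum over the week's (day, hour) cells of expected
#'   hourly order count times mean sample weight.
#' @export
expected_peak_payload <- function(cal) {
  stopifnot(inherits(cal, "activity_calendar"))
  max(rowsum(t(cal$intensity), rep(seq_len(24), each = 60))) *
    mean_sample_weight(cal)
}
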