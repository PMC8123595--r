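#' Drone flight parameters
#'
#' Defaults describe the studied inner-city link: a 1.8 km Euclidean
#' separation flown as a 3.6 km route at 60 km/h, with 1 min for takeoff
#' and 3 min for descent and landing.
#'
#' @param distance flight distance, km > 0.
#' @param speed cruise speed, km/h > 0.
#' @param takeoff,landing minutes >= 0.
#' @return A \code{flight_params} object.
#' @export
flight_params <- function(distance = 3.6, speed = 60, takeoff = 1,
                          landing = 3) {
  if (!is_number(speed) || speed <= 0) {
    stop_dronelab("speed must be a positive finite number (km/h)",
                  "dronelab_invalid_parameter")
  }
  stopifnot(is_number(distance), distance > 0,
            is_number(takeoff), takeoff >= 0,
            is_number(landing), landing >= 0)
  structure(list(distance = distance, speed = speed, takeoff = takeoff,
                 landing = landing),
            class = "flight_params")
}

#' Time budget for emergency analyses
#'
#' The emergency turnaround limit and the per-component allowances used
#' both in the feasibility algebra and as the violation thresholds of the
#' Monte Carlo study.
#'
#' @param t_em total emergency limit from test ordering to completed
#'   analysis, minutes; default 60.
#' @param pre_limit clinical-time allowance, default 15.
#' @param transport_limit tube-transport allowance, default 5.
#' @param post_limit laboratory-time allowance, default 15.
#' @param drone_limit drone-time allowance, default 15.
#' @return A \code{time_budget} object.
#' @export
time_budget <- function(t_em = 60, pre_limit = 15, transport_limit = 5,
                        post_limit = 15, drone_limit = 15) {
  stopifnot(is_number(t_em), t_em > 0,
            is_number(pre_limit), pre_limit > 0,
            is_number(transport_limit), transport_limit > 0,
            is_number(post_limit), post_limit > 0,
            is_number(drone_limit), drone_limit > 0)
  if (t_em <= pre_limit + transport_limit + post_limit) {
    stop_dronelab(
      "total limit must exceed the sum of pre, transport and post allowances",
      "dronelab_invalid_parameter"
    )
  }
  structure(list(t_em = t_em, pre_limit = pre_limit,
                 transport_limit = transport_limit, post_limit = post_limit,
                 drone_limit = drone_limit),
            class = "time_budget")
}

#' Flight leg time
#'
#' @param distance km >= 0.
#' @param speed km/h > 0.
#' @return Minutes: \code{60 * distance / speed}.
#' @examples
#' compute_leg_time(3.6, 60) # 3.6 min
#' @export
compute_leg_time <- function(distance, speed) {
  if (!is_number(speed) || speed <= 0) {
    stop_dronelab("speed must be a positive finite number (km/h)",
                  "dronelab_invalid_parameter")
  }
  stopifnot(is_number(distance), distance >= 0)
  60 * distance / speed
}

#' Drone flight time (DFT)
#'
#' Air time from takeoff to touchdown: takeoff + cruise leg + descent and
#' landing. Loading and offloading are excluded.
#'
#' @param params a \code{flight_params}.
#' @return Minutes; 7.6 under the defaults.
#' @export
compute_dft <- function(params = flight_params()) {
  stopifnot(inherits(params, "flight_params"))
  params$takeoff + compute_leg_time(params$distance, params$speed) +
    params$landing
}

#' Drone timing decomposition
#'
#' Total drone system time per flight is loading + takeoff + cruise +
#' descent + offloading; the middle three form the drone flight time (DFT).
#' Offloading defaults to zero (box exchange at the laboratory reception).
#'
#' @param t_load,t_toff,t_flig,t_desc,t_offl component minutes >= 0.
#' @return A \code{drone_timing} list with derived \code{dft} and
#'   \code{d_t}.
#' @export
drone_timing <- function(t_load = 0, t_toff = 1, t_flig = 3.6, t_desc = 3,
                         t_offl = 0) {
  for (v in c(t_load, t_toff, t_flig, t_desc, t_offl)) {
    stopifnot(is_number(v), v >= 0)
  }
  structure(list(t_load = t_load, t_toff = t_toff, t_flig = t_flig,
                 t_desc = t_desc, t_offl = t_offl,
                 dft = t_toff + t_flig + t_desc,
                 d_t = t_load + t_toff + t_flig + t_desc + t_offl),
            class = "drone_timing")
}

#' Allowed drone-system time given observed non-drone components
#'
#' The time left for the whole drone leg once clinical, transport and
#' laboratory times are spent against the emergency limit:
#' \code{t_em - c_t - t_t - l_t}. A negative result means the non-drone
#' components alone already exhaust the budget; it is returned flagged
#' (attribute \code{infeasible}) rather than raised, so simulations can
#' count infeasible events.
#'
#' @param budget a \code{time_budget}.
#' @param c_t,t_t,l_t observed clinical, transport and laboratory minutes,
#'   each >= 0 (vectorised).
#' @return Minutes, with logical attribute \code{infeasible}.
#' @export
allowed_drone_time <- function(budget = time_budget(), c_t, t_t, l_t) {
  stopifnot(inherits(budget, "time_budget"),
            is.numeric(c_t), is.numeric(t_t), is.numeric(l_t),
            all(c_t >= 0), all(t_t >= 0), all(l_t >= 0))
  out <- budget$t_em - c_t - t_t - l_t
  attr(out, "infeasible") <- out < 0
  out
}

#' Maximum loading time under the component allowances
#'
#' The loading window that keeps the worst allowed case inside the
#' emergency limit: \code{t_em - (pre_limit + transport_limit) - post_limit
#' - dft - t_offl}. Negative values are flagged, not raised.
#'
#' @param budget a \code{time_budget}.
#' @param dft drone flight time, minutes >= 0.
#' @param t_offl offloading time, minutes >= 0 (default 0).
#' @return Minutes with attribute \code{infeasible}.
#' @export
max_load_time <- function(budget = time_budget(), dft, t_offl = 0) {
  stopifnot(inherits(budget, "time_budget"),
            is.numeric(dft), all(dft >= 0),
            is.numeric(t_offl), all(t_offl >= 0))
  out <- budget$t_em - (budget$pre_limit + budget$transport_limit) -
    budget$post_limit - dft - t_offl
  attr(out, "infeasible") <- out < 0
  out
}

#' Aggregate non-drone component summaries
#'
#' Combines per-component \code{mean, sd, min, max} summaries of the three
#' non-drone components into a total row by summation. Summing means and
#' maxima is exact for the total of the three components; summed standard
#' deviations and minima are upper bounds that only hold with equality
#' under perfect dependence, and are reported with that caveat (attribute
#' \code{caveat}).
#'
#' @param component_summaries list of exactly three named numeric vectors,
#'   each with elements \code{mean, sd, min, max}.
#' @return Named numeric vector \code{mean, sd, min, max} with a
#'   \code{caveat} attribute.
#' @export
total_nondrone_stats <- function(component_summaries) {
  if (!is.list(component_summaries) || length(component_summaries) != 3L) {
    stop_dronelab("exactly three component summaries are required",
                  "dronelab_invalid_input")
  }
  need <- c("mean", "sd", "min", "max")
  mats <- lapply(component_summaries, function(s) {
    if (!is.numeric(s) || !all(need %in% names(s))) {
      stop_dronelab("each summary needs named elements mean, sd, min, max",
                    "dronelab_invalid_input")
    }
    s[need]
  })
  out <- Reduce(`+`, mats)
  attr(out, "caveat") <-
    "sd and min are summed component values: bounds, not exact totals"
  out
}
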