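#' Default run configuration
#'
#' The fully-resolved default configuration of the pipeline as a nested
#' list, mirroring the YAML/JSON schema: sections \code{calendar},
#' \code{components}, \code{flight}, \code{budget}, \code{schedule},
#' \code{simulation}, \code{generate}, \code{ground}, \code{output} and
#' the root \code{seed}. Every run echoes its resolved configuration.
#'
#' @return Nested list of class \code{run_config}.
#' @export
default_config <- function() {
  structure(list(
    seed = 20210426L,
    calendar = list(
      weekday_profile = weekday_profile_default(),
      friday_factor = 0.85,
      weekend_factor = 0.40,
      emergency_fraction = 0.235,
      container_mix = c(0.85, 0.10, 0.04, 0.01),
      peak_payload_g = 8000,
      containers = lapply(default_containers(), function(x) {
        list(name = x$name, filled_weight = x$filled_weight,
             volume = x$volume)
      })
    ),
    components = list(
      clinical = list(p_lo = 0.50, v_lo = 11, p_hi = 0.95, v_hi = 75,
                      lower = 0, upper = 180),
      pts = list(p_lo = 0.50, v_lo = 3, p_hi = 0.95, v_hi = 7,
                 lower = 0, upper = 28),
      lab = list(p_lo = 0.50, v_lo = 15, p_hi = 0.95, v_hi = 116,
                 lower = 0, upper = 125)
    ),
    flight = list(distance_km = 3.6, speed_kmh = 60, takeoff_min = 1,
                  landing_min = 3),
    budget = list(t_em = 60, pre_limit = 15, transport_limit = 5,
                  post_limit = 15, drone_limit = 15),
    schedule = list(interval_min = 15, capacity_g = 3500),
    simulation = list(n_events = 10000, increment_max = 0.20,
                      n_replicates = 10),
    generate = list(weeks = 8),
    ground = list(mode = "taxi", n_draws = 100000),
    output = list(dir = ".")
  ), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults section by section;
#' unknown keys at any level are rejected with a field-level message, so
#' typos never silently fall back to defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file;
#'   \code{NULL} returns the defaults.
#' @return A \code{run_config}.
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) {
    stop_dronelab(sprintf("config file not found: %s", path),
                  "dronelab_missing_input")
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  merged <- merge_config(unclass(base), user, path = "config")
  class(merged) <- "run_config"
  validate_config(merged)
  merged
}

merge_config <- function(base, user, path) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    stop_dronelab(sprintf("unknown config key: %s.%s", path, unknown[1]),
                  "dronelab_invalid_config")
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        nm != "containers") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste(path, nm, sep = "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  # constructors below perform the real validation; build each section once
  invisible(resolve_config(config))
}

#' Resolve a run configuration into model objects
#'
#' @param config a \code{run_config}.
#' @return List with \code{calendar}, \code{components}, \code{flight},
#'   \code{budget}, \code{schedule}, \code{sim} (a \code{sim_config}) and
#'   \code{seed}.
#' @export
resolve_config <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  cl <- config$calendar
  containers <- lapply(cl$containers, function(x) {
    container_spec(x$name, x$filled_weight, x$volume)
  })
  calendar <- activity_calendar(
    weekday_profile = as.numeric(cl$weekday_profile),
    friday_factor = cl$friday_factor,
    weekend_factor = cl$weekend_factor,
    emergency_fraction = cl$emergency_fraction,
    containers = containers,
    container_mix = as.numeric(cl$container_mix),
    peak_payload_g = cl$peak_payload_g
  )
  components <- lapply(config$components, function(cc) {
    fit_truncated_lognormal(c(cc$p_lo, cc$v_lo), c(cc$p_hi, cc$v_hi),
                            lower = cc$lower, upper = cc$upper)
  })
  flight <- flight_params(distance = config$flight$distance_km,
                          speed = config$flight$speed_kmh,
                          takeoff = config$flight$takeoff_min,
                          landing = config$flight$landing_min)
  budget <- do.call(time_budget, config$budget)
  schedule <- schedule_spec(interval = config$schedule$interval_min,
                            capacity = config$schedule$capacity_g)
  sim <- sim_config(n_events = config$simulation$n_events,
                    increment_max = config$simulation$increment_max,
                    n_replicates = config$simulation$n_replicates,
                    seed = config$seed, budget = budget,
                    schedule = schedule, flight = flight,
                    components = components)
  list(calendar = calendar, components = components, flight = flight,
       budget = budget, schedule = schedule, sim = sim,
       seed = config$seed, config = config)
}

#' Write a configuration to YAML or JSON
#'
#' @param config a \code{run_config}.
#' @param path output path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Print the fully-resolved configuration
#'
#' @param config a \code{run_config}.
#' @param file connection or "" for stdout.
#' @return The config, invisibly.
#' @export
show_config <- function(config = default_config(), file = "") {
  cat(yaml::as.yaml(unclass(config)), file = file)
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  show_config(x)
  invisible(x)
}
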