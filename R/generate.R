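#' Generate a synthetic order stream
#'
#' Draws sample orders from an inhomogeneous Poisson process on a 1-minute
#' grid: the number of orders in each minute is Poisson with the calendar's
#' intensity for that (weekday, minute-of-day), repeated over \code{weeks}
#' weeks starting on a Monday. Each order independently receives a priority
#' class (emergency with the calendar's emergency fraction), a container —
#' hence a weight — from the calendar's mix, and the three service-time
#' components drawn from their \code{dist_spec}s. All randomness derives
#' from \code{seed} through fixed child streams, so streams are reproducible
#' byte for byte and extending one stage never perturbs the others.
#'
#' @param calendar an \code{activity_calendar}.
#' @param weeks number of whole weeks to generate, >= 1.
#' @param components named list with \code{clinical}, \code{pts}, \code{lab}
#'   \code{dist_spec}s; default \code{\link{default_components}()}.
#' @param seed integer root seed.
#' @return A \code{data.frame} of class \code{order_stream} with columns
#'   \code{order_time_min} (minutes since the stream start, 1-min grid),
#'   \code{priority} ("routine"/"emergency"), \code{weight_g},
#'   \code{clinical_min}, \code{pts_min}, \code{lab_min}, sorted by
#'   loading-site arrival time \code{order_time_min + clinical_min +
#'   pts_min} (attribute column \code{arrival_min} is included for
#'   convenience).
#' @export
generate_orders <- function(calendar, weeks, components = default_components(),
                            seed = 1L) {
  stopifnot(inherits(calendar, "activity_calendar"), is_count(weeks))
  stopifnot(is.list(components),
            all(c("clinical", "pts", "lab") %in% names(components)))
  if (any(calendar$intensity < 0)) {
    stop_dronelab("calendar intensity must be non-negative",
                  "dronelab_invalid_calendar")
  }
  lambda <- rep(as.vector(t(calendar$intensity)), weeks) # minute-by-minute
  n_min <- length(lambda)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  set.seed(child_seed(seed, 1L))
  counts <- stats::rpois(n_min, lambda)
  n <- sum(counts)
  if (n == 0L) {
    return(empty_order_stream())
  }
  order_time <- rep.int(seq_len(n_min) - 1L, counts)

  set.seed(child_seed(seed, 2L))
  emergency <- stats::runif(n) < calendar$emergency_fraction

  set.seed(child_seed(seed, 3L))
  weight <- draw_weights(calendar, n)

  set.seed(child_seed(seed, 4L))
  clinical <- dist_draw(components$clinical, n)
  set.seed(child_seed(seed, 5L))
  pts <- dist_draw(components$pts, n)
  set.seed(child_seed(seed, 6L))
  lab <- dist_draw(components$lab, n)

  out <- data.frame(
    order_time_min = as.numeric(order_time),
    priority = ifelse(emergency, "emergency", "routine"),
    weight_g = weight,
    clinical_min = clinical,
    pts_min = pts,
    lab_min = lab,
    stringsAsFactors = FALSE
  )
  out$arrival_min <- out$order_time_min + out$clinical_min + out$pts_min
  out <- out[order(out$arrival_min), , drop = FALSE]
  rownames(out) <- NULL
  out$sample_id <- seq_len(nrow(out))
  class(out) <- c("order_stream", "data.frame")
  out
}

empty_order_stream <- function() {
  out <- data.frame(order_time_min = numeric(0), priority = character(0),
                    weight_g = numeric(0), clinical_min = numeric(0),
                    pts_min = numeric(0), lab_min = numeric(0),
                    arrival_min = numeric(0), sample_id = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("order_stream", "data.frame")
  out
}

draw_weights <- function(calendar, n) {
  w <- vapply(calendar$containers, `[[`, numeric(1), "filled_weight")
  if (length(w) == 1L) return(rep(w, n))
  w[sample.int(length(w), n, replace = TRUE, prob = calendar$container_mix)]
}

# save/restore the global RNG state so generator calls do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write an order stream to CSV
#'
#' Writes the six documented columns \code{order_time_min, priority,
#' weight_g, clinical_min, pts_min, lab_min} (comma-separated, header row,
#' "." decimal).
#'
#' @param stream an \code{order_stream}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_order_stream <- function(stream, path) {
  cols <- c("order_time_min", "priority", "weight_g",
            "clinical_min", "pts_min", "lab_min")
  utils::write.csv(as.data.frame(stream)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an order stream written by \code{write_order_stream}
#'
#' @param path CSV file path.
#' @return An \code{order_stream} (arrival time and sample ids recomputed).
#' @export
read_order_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("order_time_min", "priority", "weight_g",
            "clinical_min", "pts_min", "lab_min")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_dronelab(paste("order-stream CSV lacks columns:",
                        paste(missing, collapse = ", ")),
                  "dronelab_invalid_input")
  }
  df$arrival_min <- df$order_time_min + df$clinical_min + df$pts_min
  df <- df[order(df$arrival_min), , drop = FALSE]
  rownames(df) <- NULL
  df$sample_id <- seq_len(nrow(df))
  class(df) <- c("order_stream", "data.frame")
  df
}
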