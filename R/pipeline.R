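#' Run a pipeline stage and write its artifacts
#'
#' Orchestrates the standard analysis stages over one configuration.
#' Subcommands:
#' \describe{
#'   \item{generate}{write the synthetic order stream
#'     (\code{orders.csv}, six documented columns).}
#'   \item{schedule}{assign the stream to fixed-interval flights; write
#'     \code{flights.csv} (departure_min, n_samples, payload_g,
#'     fill_fraction) and \code{assignment.csv} (sample_id, arrival_min,
#'     departure_min, wait_min).}
#'   \item{simulate}{run the Monte Carlo turnaround study; write
#'     \code{simulation.json} with per-fraction replicate summaries, a
#'     config echo and the seed.}
#'   \item{compare}{compare drone transport times from the schedule stage
#'     with the ground model; write \code{comparison.json} and
#'     \code{ground_quantiles.csv}.}
#'   \item{report}{assemble \code{report.csv}: component summary rows
#'     (mean/sd/min/max, with the summed total row) followed by the
#'     violation-fraction rows.}
#' }
#' Each stage appends a line-oriented \code{key=value} record to
#' \code{run.log} with the seed, package version and timing. Stages that
#' need upstream artifacts (\code{schedule}, \code{compare}) generate them
#' in memory when the CSVs are absent.
#'
#' @param config_path path to a YAML/JSON config, or \code{NULL} for the
#'   defaults.
#' @param subcommand one of \code{"generate"}, \code{"schedule"},
#'   \code{"simulate"}, \code{"compare"}, \code{"report"},
#'   \code{"show-config"}.
#' @param out_dir output directory; overrides the config's
#'   \code{output$dir}.
#' @param seed optional root-seed override.
#' @param interval optional departure-interval override (minutes).
#' @param n_events optional event-count override for \code{simulate}.
#' @return Invisible list of written artifact paths.
#' @export
run_pipeline <- function(config_path = NULL,
                         subcommand = c("generate", "schedule", "simulate",
                                        "compare", "report", "show-config"),
                         out_dir = NULL, seed = NULL, interval = NULL,
                         n_events = NULL) {
  subcommand <- match.arg(subcommand)
  config <- load_config(config_path)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(interval)) config$schedule$interval_min <- interval
  if (!is.null(n_events)) config$simulation$n_events <- n_events
  if (!is.null(out_dir)) config$output$dir <- out_dir

  if (subcommand == "show-config") {
    show_config(config)
    return(invisible(character(0)))
  }

  dir <- config$output$dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r <- resolve_config(config)
  t0 <- proc.time()[["elapsed"]]
  paths <- character(0)

  orders_path <- file.path(dir, "orders.csv")
  flights_path <- file.path(dir, "flights.csv")
  assignment_path <- file.path(dir, "assignment.csv")

  get_stream <- function() {
    if (file.exists(orders_path)) read_order_stream(orders_path)
    else generate_orders(r$calendar, config$generate$weeks, r$components,
                         seed = config$seed)
  }

  if (subcommand == "generate") {
    stream <- generate_orders(r$calendar, config$generate$weeks,
                              r$components, seed = config$seed)
    write_order_stream(stream, orders_path)
    paths <- orders_path
  } else if (subcommand == "schedule") {
    stream <- get_stream()
    res <- assign_to_flights(stream, r$schedule)
    utils::write.csv(res$flights, flights_path, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(res$assignment, assignment_path, row.names = FALSE,
                     quote = FALSE)
    paths <- c(flights_path, assignment_path)
  } else if (subcommand == "simulate") {
    rep <- run_simulation(r$sim)
    sim_path <- file.path(dir, "simulation.json")
    payload <- list(
      seed = config$seed,
      thresholds = as.list(rep$thresholds),
      replicates = as.data.frame(rep$replicates),
      summary = cbind(fraction = rownames(rep$summary), rep$summary),
      # config echo without the output section, which names run-local paths
      config = unclass(config)[setdiff(names(config), "output")]
    )
    jsonlite::write_json(payload, sim_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    paths <- sim_path
  } else if (subcommand == "compare") {
    stream <- get_stream()
    res <- assign_to_flights(stream, r$schedule)
    dft <- compute_dft(r$flight)
    drone_times <- res$assignment$wait_min + dft
    ground <- build_ground_model(config$ground$mode)
    cmp <- compare_modes(ground, drone_times,
                         n_draws = config$ground$n_draws,
                         seed = config$seed)
    cmp_path <- file.path(dir, "comparison.json")
    q_path <- file.path(dir, "ground_quantiles.csv")
    jsonlite::write_json(
      list(mode = cmp$mode, p_drone_faster = cmp$p_drone_faster,
           p_ground_faster = cmp$p_ground_faster, p_tie = cmp$p_tie,
           n_draws = cmp$n_draws, seed = config$seed),
      cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(cmp$quantiles, q_path, row.names = FALSE, quote = FALSE)
    paths <- c(cmp_path, q_path)
  } else if (subcommand == "report") {
    rep_path <- file.path(dir, "report.csv")
    utils::write.csv(build_report(r, config), rep_path, row.names = FALSE,
                     quote = FALSE)
    paths <- rep_path
  }

  log_line <- sprintf(
    "stage=%s seed=%s version=%s elapsed_s=%.2f artifacts=%s",
    subcommand, format(config$seed),
    as.character(utils::packageVersion("dronelab")),
    proc.time()[["elapsed"]] - t0,
    paste(basename(paths), collapse = ","))
  cat(log_line, "\n", sep = "", file = file.path(dir, "run.log"),
      append = TRUE)
  invisible(paths)
}

# component stats rows (from the fitted components, by large-sample draws)
# followed by violation-fraction rows from the Monte Carlo study
build_report <- function(r, config, n_draws = 100000) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  summ <- lapply(names(r$components), function(nm) {
    set.seed(child_seed(config$seed, 200L + match(nm, names(r$components))))
    x <- dist_draw(r$components[[nm]], n_draws)
    c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
  })
  names(summ) <- names(r$components)
  total <- total_nondrone_stats(summ)
  comp_rows <- do.call(rbind, c(summ, list(total_nondrone = total)))
  comp <- data.frame(section = "component_minutes",
                     measure = rownames(comp_rows),
                     round(as.data.frame(comp_rows), 3))

  rep <- run_simulation(r$sim)
  viol <- data.frame(section = "violation_fraction",
                     measure = rownames(rep$summary),
                     round(rep$summary, 4))
  rownames(comp) <- rownames(viol) <- NULL
  rbind(comp, viol)
}
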