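#' Serialise a scenario configuration to JSON
#'
#' The snapshot suffices to bit-reproduce the trajectory: numbers are written
#' at full precision and [scenario_from_json()] rebuilds an identical
#' configuration.
#'
#' @param config A [scenario_config()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string (invisibly when written to a file).
#' @export
scenario_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  x <- list(id = config$id, t0 = config$t0, t1 = config$t1,
            params = unclass(config$params),
            total_area = config$total_area,
            plan = if (!is.null(config$plan)) unclass(config$plan),
            initial_on = config$initial_on, initial_tn = config$initial_tn,
            protection = config$protection, dt = config$dt,
            seeding = config$seeding,
            initial_forest = if (!is.null(config$initial_forest))
              list(ages = config$initial_forest$ages,
                   areas = config$initial_forest$areas))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Rebuild a scenario configuration from a JSON snapshot
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [scenario_to_json()].
#' @return A [scenario_config()].
#' @export
scenario_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  p <- do.call(nest_params, as.list(x$params))
  plan <- if (!is.null(x$plan))
    rotation_plan(x$plan$rotation_age, x$plan$cut_interval,
                  x$plan$first_cut_year, x$plan$mode)
  forest <- if (!is.null(x$initial_forest))
    cohort_forest(x$initial_forest$ages, x$initial_forest$areas)
  seeding <- if (!is.null(x$seeding)) list(pairs = x$seeding$pairs)
  scenario_config(x$id, x$t0, x$t1, params = p, total_area = x$total_area,
                  plan = plan, initial_on = x$initial_on,
                  initial_tn = x$initial_tn, protection = x$protection,
                  dt = x$dt, seeding = seeding, initial_forest = forest)
}

#' Write the artifacts of a run to a directory
#'
#' Exports the tidy trajectory CSV (one row per calendar year), the clearcut
#' events CSV and the JSON configuration snapshot, under the scenario's id.
#'
#' @param traj A `"nest_trajectory"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_run <- function(traj, dir) {
  stopifnot(inherits(traj, "nest_trajectory"))
  cfg <- attr(traj, "config")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    trajectory = file.path(dir, paste0(cfg$id, "_trajectory.csv")),
    events = file.path(dir, paste0(cfg$id, "_events.csv")),
    config = file.path(dir, paste0(cfg$id, "_config.json")))
  utils::write.csv(format(as.data.frame(traj), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   paths$trajectory, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(attr(traj, "events"), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   paths$events, row.names = FALSE, quote = FALSE)
  scenario_to_json(cfg, paths$config)
  invisible(paths)
}

#' Generate a synthetic observed occupancy series
#'
#' Produces an integer-valued yearly count series following a logistic rise
#' with noise, emulating field counts of occupied nests during a colonisation
#' phase. Used to exercise the trajectory-comparison utilities; it is a
#' synthetic stand-in, not field data.
#'
#' @param start_year,end_year Calendar window (inclusive).
#' @param capacity Asymptotic number of occupied nests.
#' @param growth_rate Logistic growth rate (1/yr).
#' @param midpoint_year Year at which the logistic reaches half capacity.
#' @param noise_sd Standard deviation of the count noise; 0 gives the rounded
#'   noiseless logistic.
#' @param seed Integer seed; the series is deterministic per seed.
#' @return A data.frame with columns `year` and `observed` (non-negative
#'   integers).
#' @export
generate_synthetic_observed <- function(start_year, end_year, capacity,
                                        growth_rate = 0.15,
                                        midpoint_year = (start_year + end_year) / 2,
                                        noise_sd = 1, seed = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  years <- seq.int(start_year, end_year)
  mu <- capacity / (1 + exp(-growth_rate * (years - midpoint_year)))
  obs <- if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    mu + stats::rnorm(length(mu), sd = noise_sd)
  } else mu
  data.frame(year = years, observed = pmax(0L, as.integer(round(obs))))
}

#' Compare a simulated trajectory with an observed count series
#'
#' Root-mean-square error and mean bias (simulated minus observed) of the
#' simulated occupancy over the overlapping years.
#'
#' @param traj A `"nest_trajectory"`.
#' @param observed A data.frame with columns `year` and `observed` (e.g. from
#'   [generate_synthetic_observed()]), or the path to such a CSV.
#' @return A list: `rmse`, `bias`, `n` (overlapping years).
#' @export
compare_to_observed <- function(traj, observed) {
  if (is.character(observed)) observed <- utils::read.csv(observed)
  m <- merge(as.data.frame(traj)[, c("year", "on")], observed, by = "year")
  if (nrow(m) < 3)
    stop("invalid input: fewer than 3 overlapping years", call. = FALSE)
  d <- m$on - m$observed
  list(rmse = sqrt(mean(d^2)), bias = mean(d), n = nrow(m))
}

# save/restore the global RNG state so generators do not disturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
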