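#' Capacity gap of a trajectory
#'
#' Percentage by which mean occupancy falls below mean carrying capacity over
#' a window: `100 * (mean(moc) - mean(on)) / mean(moc)`, computed on the
#' annual samples (window inclusive). Negative values mean occupancy spent
#' part of the window above the (reduced) capacity, e.g. while pairs abandon
#' after a habitat loss.
#'
#' @param traj A `"nest_trajectory"` from [simulate_scenario()].
#' @param window Length-2 numeric `c(from, to)` in calendar years, or `NULL`
#'   for the whole trajectory.
#' @return Gap in percent.
#' @examples
#' u <- simulate_scenario(build_unmanaged_2010())
#' capacity_gap_percent(u) # ~0: run starts and stays at capacity
#' @export
capacity_gap_percent <- function(traj, window = NULL) {
  x <- window_rows(traj, window)
  m <- mean(x$moc)
  if (m <= 0) stop("undefined gap: mean carrying capacity is zero",
                   call. = FALSE)
  100 * (m - mean(x$on)) / m
}

#' Maximum reduction in occupancy versus a reference run
#'
#' Largest annual percentage shortfall of occupancy relative to a reference
#' trajectory on the same annual grid:
#' `max over years of 100 * (on_ref - on) / on_ref`.
#'
#' @param traj,ref_traj Trajectories on identical annual grids; the reference
#'   must have strictly positive occupancy throughout.
#' @return Maximum reduction in percent (0 for identical runs).
#' @export
max_reduction_vs_reference <- function(traj, ref_traj) {
  if (nrow(traj) != nrow(ref_traj) || any(traj$year != ref_traj$year))
    stop("invalid input: trajectories are not on the same annual grid",
         call. = FALSE)
  if (any(ref_traj$on <= 0))
    stop("invalid input: reference occupancy must be positive everywhere",
         call. = FALSE)
  max(100 * (ref_traj$on - traj$on) / ref_traj$on)
}

#' First year occupancy reaches carrying capacity
#'
#' First calendar year with `on >= fraction * moc(t)`; `NA` if never reached.
#'
#' @inheritParams capacity_gap_percent
#' @param fraction Fraction of capacity counting as "reached" (default 0.99).
#' @return Calendar year, or `NA_integer_`.
#' @export
time_to_capacity <- function(traj, fraction = 0.99) {
  hit <- which(traj$on >= fraction * traj$moc)
  if (length(hit) == 0) NA_integer_ else as.integer(traj$year[hit[1]])
}

#' Is the community extinct at the end of a run?
#'
#' The continuous model never reaches exactly zero from a positive state, so
#' extinction is read as final occupancy rounding to zero pairs:
#' `on(t1) < threshold` (default 0.5).
#'
#' @inheritParams capacity_gap_percent
#' @param threshold Extinction threshold in pairs.
#' @return Logical.
#' @export
is_extinct <- function(traj, threshold = 0.5) {
  traj$on[nrow(traj)] < threshold
}

#' Summary row for a scenario run
#'
#' Means and standard deviations (across the window's annual samples) of
#' carrying capacity and occupancy, the capacity gap, time to capacity and
#' the extinction flag — the machine-readable analogue of a
#' scenario-comparison bar chart.
#'
#' @inheritParams capacity_gap_percent
#' @return A one-row data.frame: `id`, `mean_moc`, `sd_moc`, `mean_on`,
#'   `sd_on`, `gap_percent`, `time_to_capacity`, `final_on`, `extinct`.
#' @export
summarize_run <- function(traj, window = NULL) {
  x <- window_rows(traj, window)
  cfg <- attr(traj, "config")
  data.frame(
    id = if (is.null(cfg)) NA_character_ else cfg$id,
    mean_moc = mean(x$moc), sd_moc = stats::sd(x$moc),
    mean_on = mean(x$on), sd_on = stats::sd(x$on),
    gap_percent = if (mean(x$moc) > 0)
      100 * (mean(x$moc) - mean(x$on)) / mean(x$moc) else NA_real_,
    time_to_capacity = time_to_capacity(traj),
    final_on = traj$on[nrow(traj)],
    extinct = is_extinct(traj),
    stringsAsFactors = FALSE)
}

#' Summary table over several runs
#'
#' @param trajs A list of `"nest_trajectory"` objects.
#' @param window Optional window passed to [summarize_run()].
#' @return A data.frame with one row per run.
#' @export
summarize_scenarios <- function(trajs, window = NULL) {
  do.call(rbind, lapply(trajs, summarize_run, window = window))
}

window_rows <- function(traj, window) {
  stopifnot(is.data.frame(traj))
  if (is.null(window)) return(traj)
  traj[traj$year >= window[1] & traj$year <= window[2], , drop = FALSE]
}
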