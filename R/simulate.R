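#' One explicit-Euler step of the occupancy stocks
#'
#' Advances the two stocks by `dt` years under a fixed carrying capacity:
#' `on += (onir - onar) * dt`, `tn += (nb - ndr) * dt`, then clamps both at 0.
#' Clearcut pulse losses are events, applied between continuous steps by
#' [simulate_scenario()], never inside this update.
#'
#' The clamp is a numerical guard, not a model mechanism: if a step overshoots
#' zero by more than a tolerance (`1e-3 * (1 + stock)`), the step size is too
#' large for the current flow magnitudes and an error asks for a smaller `dt`
#' rather than silently losing mass. With the model's ratio-clamped flows all
#' per-capita rates are bounded by ~`cr`, so the default `dt` never trips it.
#'
#' @param state Named list or vector with elements `t`, `tn`, `on`.
#' @param params A [nest_params()] object.
#' @param moc Carrying capacity during the step (pairs, `>= 0`).
#' @param dt Step length (yr, `> 0`).
#' @return The updated state (list with `t`, `tn`, `on`).
#' @export
step_nest <- function(state, params, moc, dt) {
  stopifnot(inherits(params, "nest_params"))
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.finite(moc) || moc < 0)
    stop("invalid state: `moc` must be finite and non-negative", call. = FALSE)
  f <- flow_rates(state$on, state$tn, moc, params)
  on_new <- state$on + (f$onir - f$onar) * dt
  tn_new <- state$tn + (f$nb - f$ndr) * dt
  if (!is.finite(on_new) || !is.finite(tn_new))
    stop("numerical instability: non-finite stock; reduce `dt`", call. = FALSE)
  if (on_new < -1e-3 * (1 + state$on) || tn_new < -1e-3 * (1 + state$tn))
    stop("numerical instability: stock overshoot beyond clamp tolerance; ",
         "reduce `dt`", call. = FALSE)
  list(t = state$t + dt, tn = max(0, tn_new), on = max(0, on_new))
}

#' Simulate a scenario
#'
#' Runs the coupled forest / occupancy model over the scenario's window and
#' returns the annual trajectory. The yearly cycle is: (1) the forest submodel
#' advances and any scheduled clearcut event fires, removing
#' [clearcut_nest_loss()] platforms instantaneously; (2) the state is sampled
#' for that calendar year (year-start, post-event); (3) the continuous flows
#' are integrated by fixed-step explicit Euler across the year under that
#' year's carrying capacity.
#'
#' The model is fully deterministic: identical configurations give identical
#' trajectories.
#'
#' @param config A [scenario_config()] (or the id of a built-in scenario, see
#'   [build_scenario()]).
#' @return A data.frame of class `"nest_trajectory"`, one row per calendar
#'   year, with columns `year`, `tn`, `on`, `moc`, `mature_area`, `anr`,
#'   `occ_ratio`, `onir`, `onar`, `nb`, `ndr`, `nlfc_pulse`. The scenario
#'   configuration is attached as attribute `"config"` and the clearcut event
#'   log (year, area_cut, mfcr, nests_lost) as attribute `"events"`.
#' @examples
#' traj <- simulate_scenario(build_burete_base())
#' round(traj$on[traj$year == 2018]) # 33 occupied nests
#' @export
simulate_scenario <- function(config) {
  if (is.character(config)) config <- build_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params

  forest <- mature_series(config$plan, config$total_area, config$t0, config$t1,
                          maturity_age = p$maturity_age,
                          initial_forest = config$initial_forest)
  n <- nrow(forest)
  moc_year <- carrying_capacity(forest$mature_area, p$mfap)

  out <- data.frame(year = forest$year, tn = NA_real_, on = NA_real_,
                    moc = moc_year, mature_area = forest$mature_area,
                    anr = NA_real_, occ_ratio = NA_real_, onir = NA_real_,
                    onar = NA_real_, nb = NA_real_, ndr = NA_real_,
                    nlfc_pulse = 0)
  events <- data.frame(year = integer(0), area_cut = numeric(0),
                       mfcr = numeric(0), nests_lost = numeric(0))

  on <- config$initial_on
  tn <- config$initial_tn
  seeded <- is.null(config$seeding) # no seeding rule: already seeded
  nsub <- max(1L, round(1 / config$dt))
  dt <- 1 / nsub

  for (i in seq_len(n)) {
    if (forest$mfcr[i] > 0) {
      lost <- clearcut_nest_loss(tn, forest$mfcr[i],
                                 protected = config$protection,
                                 protection_factor = p$protection_factor)
      tn <- tn - lost
      out$nlfc_pulse[i] <- lost
      events <- rbind(events, data.frame(
        year = forest$year[i], area_cut = forest$area_cut[i],
        mfcr = forest$mfcr[i], nests_lost = lost))
    }
    if (!seeded && forest$mature_area[i] > 0) {
      on <- on + config$seeding$pairs
      tn <- max(tn + config$seeding$pairs, on)
      seeded <- TRUE
    }
    f <- flow_rates(on, tn, moc_year[i], p)
    out$tn[i] <- tn; out$on[i] <- on
    out$anr[i] <- f$anr; out$occ_ratio[i] <- f$occ_ratio
    out$onir[i] <- f$onir; out$onar[i] <- f$onar
    out$nb[i] <- f$nb; out$ndr[i] <- f$ndr

    if (i < n) {
      state <- list(t = forest$year[i], tn = tn, on = on)
      for (k in seq_len(nsub))
        state <- step_nest(state, p, moc_year[i], dt)
      on <- state$on; tn <- state$tn
    }
  }

  attr(out, "config") <- config
  attr(out, "events") <- events
  class(out) <- c("nest_trajectory", "data.frame")
  out
}

#' @export
print.nest_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Nest-occupancy trajectory '%s': %d annual samples (%d-%d)\n",
              if (is.null(cfg)) "?" else cfg$id, nrow(x),
              min(x$year), max(x$year)))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 0)
    cat(sprintf("  %d clearcut event(s), %.1f nests lost in total\n",
                nrow(ev), sum(ev$nests_lost)))
  cat(sprintf("  final state %d: on = %.2f pairs, tn = %.2f nests, moc = %.2f\n",
              max(x$year), x$on[nrow(x)], x$tn[nrow(x)], x$moc[nrow(x)]))
  invisible(x)
}
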