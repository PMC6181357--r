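#' Scenario configuration
#'
#' A fully specified, deterministic model run: time window, parameters, forest
#' regime, initial stocks, protection flag and integration step. A scenario is
#' unmanaged when `plan` is `NULL` and no `initial_forest` is given: the whole
#' `total_area` then counts as mature for the entire window.
#'
#' @param id Character scenario identifier.
#' @param t0,t1 First and last calendar years (inclusive).
#' @param params A [nest_params()] object.
#' @param total_area Total forest area (ha).
#' @param plan A [rotation_plan()] or `NULL` (unmanaged).
#' @param initial_on Initial occupied nests (pairs).
#' @param initial_tn Initial total nests.
#' @param protection Logical; nest protection active at clearcut events?
#' @param dt Euler step (yr). The default 1/256 keeps the halving-convergence
#'   error of annual values under 0.1% of capacity on all built-in scenarios.
#' @param seeding `NULL`, or `list(pairs = <n>)` to inject that many pairs
#'   (and nests) at the first year with positive mature area — used for
#'   reforestation runs that start with no habitat.
#' @param initial_forest Optional [cohort_forest()] initial state (otherwise
#'   the plan's equilibrium distribution, or all-mature if unmanaged).
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(id, t0, t1, params = nest_params(),
                            total_area = params$mfa, plan = NULL,
                            initial_on = 1, initial_tn = 1,
                            protection = FALSE, dt = 1 / 256,
                            seeding = NULL, initial_forest = NULL) {
  stopifnot(inherits(params, "nest_params"))
  if (t0 >= t1) stop("invalid config: empty time window", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("invalid config: `dt` must be positive", call. = FALSE)
  if (initial_on < 0 || initial_tn < 0)
    stop("invalid config: initial stocks must be non-negative", call. = FALSE)
  if (!is.null(plan)) stopifnot(inherits(plan, "rotation_plan"))
  if (!is.null(initial_forest)) stopifnot(inherits(initial_forest, "cohort_forest"))
  if (!is.null(seeding) && (is.null(seeding$pairs) || seeding$pairs < 0))
    stop("invalid config: `seeding` must be NULL or list(pairs = n >= 0)",
         call. = FALSE)
  structure(list(id = id, t0 = t0, t1 = t1, params = params,
                 total_area = total_area, plan = plan,
                 initial_on = initial_on, initial_tn = initial_tn,
                 protection = isTRUE(protection), dt = dt,
                 seeding = seeding, initial_forest = initial_forest),
            class = "scenario_config")
}

#' Historical base run: mature-forest colonisation from one pair
#'
#' Unmanaged run over 1890-2018 with the whole study area (10,000 ha) mature
#' throughout and a single breeding pair (and nest) at the start. Reproduces
#' the historical build-up of the raptor community to carrying capacity
#' (about 33 pairs).
#'
#' @param t0,t1 Window (defaults 1890-2018).
#' @param params A [nest_params()] object.
#' @return A [scenario_config()].
#' @export
build_burete_base <- function(t0 = 1890, t1 = 2018, params = nest_params()) {
  scenario_config("burete_base", t0, t1, params,
                  total_area = params$mfa, initial_on = 1, initial_tn = 1)
}

#' Validation run: reforested landscape colonised at first maturity
#'
#' An independent-area run: the forest starts as one-year-old stands (a
#' reforestation) over `total_area` hectares in 1910 and simply ages; the
#' first mature habitat appears when the stand reaches the maturity age (1943
#' with the default 34 yr), at which point one breeding pair (with one nest)
#' is seeded and occupancy grows toward the area's capacity.
#'
#' @param total_area Forest area (ha); default 20,000.
#' @param t0,t1 Window (defaults 1910-2018).
#' @param params A [nest_params()] object.
#' @param seed_pairs Pairs injected at first maturity (default 1).
#' @return A [scenario_config()].
#' @export
build_espuna_validation <- function(total_area = 20000, t0 = 1910, t1 = 2018,
                                    params = nest_params(), seed_pairs = 1) {
  scenario_config("espuna", t0, t1, params, total_area = total_area,
                  initial_on = 0, initial_tn = 0,
                  seeding = list(pairs = seed_pairs),
                  initial_forest = cohort_forest(1L, total_area))
}

#' Unmanaged projection 2010-2050 started at capacity
#'
#' The reference scenario for the management experiments: no cutting, whole
#' area mature, stocks at the long-run equilibrium (on = moc, tn =
#' moc*nbr*nlf), so the trajectory is constant.
#'
#' @param params A [nest_params()] object.
#' @return A [scenario_config()].
#' @export
build_unmanaged_2010 <- function(params = nest_params()) {
  moc <- carrying_capacity(params$mfa, params$mfap)
  scenario_config("unmanaged_2010", 2010, 2050, params,
                  total_area = params$mfa, initial_on = moc,
                  initial_tn = equilibrium_total_nests(moc, params$nbr,
                                                       params$nlf))
}

#' Managed scenario: decadal clearcut rotation 2010-2050
#'
#' Clearcutting of all trees at or above `rotation_age` every 10 years over
#' 2010-2050, with or without nest protection. The forest starts at the
#' rotation's long-term equilibrium age distribution; the first cut event
#' lands in 2020 by default. Initial occupancy is the base run's maximum
#' (33.33 pairs) and the initial nest stock its equilibrium companion
#' (moc*nbr*nlf = 96.51 nests).
#'
#' @param rotation_age Age of cut trees (40, 50, 60 or 70 in the published
#'   scenarios; other values are allowed with a warning).
#' @param protection Logical; protect nests at cut events?
#' @param mode Cohort mechanics, `"pulse"` (default) or `"smoothed"`; see
#'   [rotation_plan()].
#' @param first_cut_year Calendar year of the first cut event (pulse mode).
#' @param params A [nest_params()] object.
#' @return A [scenario_config()].
#' @export
build_managed <- function(rotation_age, protection = FALSE,
                          mode = c("pulse", "smoothed"),
                          first_cut_year = 2020, params = nest_params()) {
  mode <- match.arg(mode)
  if (!rotation_age %in% c(40, 50, 60, 70))
    warning("rotation_age ", rotation_age,
            " is outside the published scenario set {40, 50, 60, 70}")
  moc_max <- carrying_capacity(params$mfa, params$mfap)
  id <- sprintf("cut%d_%s", rotation_age,
                if (protection) "prot" else "noprot")
  scenario_config(id, 2010, 2050, params, total_area = params$mfa,
                  plan = rotation_plan(rotation_age, cut_interval = 10,
                                       first_cut_year = first_cut_year,
                                       mode = mode),
                  initial_on = moc_max,
                  initial_tn = equilibrium_total_nests(moc_max, params$nbr,
                                                       params$nlf),
                  protection = protection)
}

#' Built-in scenario ids
#'
#' The eleven study scenarios: the historical base run, the reforestation
#' validation run, the unmanaged 2010-2050 projection, and the four decadal
#' rotations (40/50/60/70 yr) each with and without nest protection.
#'
#' @return Character vector of scenario ids.
#' @export
list_scenarios <- function() {
  c("burete_base", "espuna", "unmanaged_2010",
    sprintf("cut%d_%s", rep(c(40, 50, 60, 70), each = 2),
            c("noprot", "prot")))
}

#' Build a built-in scenario by id
#'
#' @param id One of [list_scenarios()].
#' @param ... Passed on to the underlying builder (e.g. `mode` for managed
#'   scenarios).
#' @return A [scenario_config()].
#' @export
build_scenario <- function(id, ...) {
  if (id == "burete_base") return(build_burete_base(...))
  if (id == "espuna") return(build_espuna_validation(...))
  if (id == "unmanaged_2010") return(build_unmanaged_2010(...))
  m <- regmatches(id, regexec("^cut([0-9]+)_(prot|noprot)$", id))[[1]]
  if (length(m) == 3)
    return(build_managed(as.numeric(m[2]), protection = m[3] == "prot", ...))
  stop("unknown scenario id: '", id, "'; see list_scenarios()", call. = FALSE)
}
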