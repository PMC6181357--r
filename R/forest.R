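#' Age-cohort forest state
#'
#' A forest is a set of even-aged cohorts: integer tree ages (years) and the
#' area occupied by each (ha). Total area is conserved by every operation,
#' including clearcut events (cut area is replanted at age 0 immediately).
#'
#' @param ages Integer vector of cohort ages (years, `>= 0`).
#' @param areas Numeric vector of cohort areas (ha, `>= 0`), same length.
#' @return An object of class `"cohort_forest"`.
#' @export
cohort_forest <- function(ages, areas) {
  if (length(ages) != length(areas))
    stop("`ages` and `areas` must have the same length", call. = FALSE)
  if (any(areas < 0) || any(!is.finite(areas)))
    stop("cohort areas must be finite and non-negative", call. = FALSE)
  if (any(ages < 0) || any(ages != round(ages)))
    stop("cohort ages must be non-negative integers", call. = FALSE)
  structure(list(ages = as.integer(ages), areas = as.numeric(areas),
                 total_area = sum(areas)),
            class = "cohort_forest")
}

#' @export
print.cohort_forest <- function(x, ...) {
  cat(sprintf("Age-cohort forest: %d cohort(s), %.1f ha total\n",
              length(x$ages), x$total_area))
  if (length(x$ages) <= 12) {
    for (i in order(x$ages))
      cat(sprintf("  age %3d: %10.2f ha\n", x$ages[i], x$areas[i]))
  } else {
    cat(sprintf("  ages %d..%d\n", min(x$ages), max(x$ages)))
  }
  invisible(x)
}

#' Clearcut rotation plan
#'
#' Describes a clearcutting regime: all trees at or above `rotation_age` are
#' felled every `cut_interval` years, starting at `first_cut_year`. Two cohort
#' mechanics are supported, because the exact mechanics behind decadal
#' rotations are a genuine modelling choice:
#'
#' * `"pulse"` (default): the forest is aged continuously and every
#'   `cut_interval` years all over-age area is removed in one instantaneous
#'   event; the equilibrium state is a set of even-aged blocks spaced
#'   `cut_interval` years apart, and the mature area follows a sawtooth.
#' * `"smoothed"`: an idealisation in which the single cohort reaching
#'   `rotation_age` is cut every year, so the age distribution is uniform over
#'   ages 1..`rotation_age` and the mature area is constant at
#'   `total_area * (rotation_age - maturity_age + 1) / rotation_age`.
#'
#' @param rotation_age Tree age (yr) at which stands are clearcut.
#' @param cut_interval Years between cut events (`"pulse"` mode), default 10.
#' @param first_cut_year Calendar year of the first cut event.
#' @param mode `"pulse"` or `"smoothed"`.
#' @return An object of class `"rotation_plan"`.
#' @export
rotation_plan <- function(rotation_age, cut_interval = 10,
                          first_cut_year = 2020,
                          mode = c("pulse", "smoothed")) {
  mode <- match.arg(mode)
  if (!is.finite(rotation_age) || rotation_age < 1)
    stop("invalid plan: `rotation_age` must be >= 1", call. = FALSE)
  if (!is.finite(cut_interval) || cut_interval < 1)
    stop("invalid plan: `cut_interval` must be >= 1", call. = FALSE)
  if (mode == "pulse" && rotation_age %% cut_interval != 0)
    stop("invalid plan: in pulse mode `rotation_age` must be divisible by ",
         "`cut_interval`", call. = FALSE)
  structure(list(rotation_age = rotation_age, cut_interval = cut_interval,
                 first_cut_year = first_cut_year, mode = mode),
            class = "rotation_plan")
}

#' Long-term equilibrium age distribution under a rotation
#'
#' The periodic post-cut state of the forest under the plan. In `"pulse"` mode
#' this is `rotation_age / cut_interval` even-aged blocks of equal area at ages
#' `0, cut_interval, ..., rotation_age - cut_interval`. In `"smoothed"` mode it
#' is a uniform distribution of `total_area / rotation_age` per one-year class
#' over ages `1..rotation_age`.
#'
#' @param total_area Total forest area (ha).
#' @param plan A [rotation_plan()].
#' @return A [cohort_forest()].
#' @examples
#' equilibrium_forest(10000, rotation_plan(40)) # 4 blocks of 2500 ha
#' @export
equilibrium_forest <- function(total_area, plan) {
  stopifnot(inherits(plan, "rotation_plan"))
  if (total_area < 0) stop("`total_area` must be non-negative", call. = FALSE)
  if (total_area == 0) return(cohort_forest(integer(0), numeric(0)))
  if (plan$mode == "pulse") {
    n <- plan$rotation_age / plan$cut_interval
    cohort_forest(ages = seq(0L, by = plan$cut_interval, length.out = n),
                  areas = rep(total_area / n, n))
  } else {
    n <- plan$rotation_age
    cohort_forest(ages = seq_len(n), areas = rep(total_area / n, n))
  }
}

#' Advance the forest by one year
#'
#' Every cohort's age increments by one; area is conserved exactly.
#'
#' @param forest A [cohort_forest()].
#' @return The aged [cohort_forest()].
#' @export
advance_year <- function(forest) {
  stopifnot(inherits(forest, "cohort_forest"))
  cohort_forest(forest$ages + 1L, forest$areas)
}

#' Mature forest area
#'
#' Total area of cohorts at or above the minimum nesting age.
#'
#' @param forest A [cohort_forest()].
#' @param maturity_age Minimum tree age (yr) that counts as mature habitat.
#' @return Mature area (ha).
#' @export
mature_area <- function(forest, maturity_age = 34) {
  stopifnot(inherits(forest, "cohort_forest"))
  if (maturity_age < 0) stop("`maturity_age` must be >= 0", call. = FALSE)
  sum(forest$areas[forest$ages >= maturity_age])
}

#' Apply a clearcut event
#'
#' Removes all area in cohorts at or above the plan's rotation age and
#' replants it as a single age-0 cohort. The event's `mfcr` is the mature
#' share removed: (mature area cut) / (mature area before the cut), with
#' mature meaning age `>= maturity_age`; 0 if no mature area existed.
#'
#' @param forest A [cohort_forest()].
#' @param plan A [rotation_plan()].
#' @param maturity_age Minimum mature tree age (yr).
#' @param year Calendar year recorded on the event (metadata only).
#' @return A list with elements `forest` (post-cut [cohort_forest()]) and
#'   `event` (list: `year`, `area_cut`, `mature_area_before`, `mfcr`).
#' @examples
#' f <- cohort_forest(c(10, 20, 30, 40), rep(2500, 4))
#' apply_clearcut(f, rotation_plan(40))$event$mfcr # 1: the only mature block
#' @export
apply_clearcut <- function(forest, plan, maturity_age = 34, year = NA_integer_) {
  stopifnot(inherits(forest, "cohort_forest"), inherits(plan, "rotation_plan"))
  cut <- forest$ages >= plan$rotation_age
  mature_before <- mature_area(forest, maturity_age)
  area_cut <- sum(forest$areas[cut])
  mature_cut <- sum(forest$areas[cut & forest$ages >= maturity_age])
  mfcr <- if (mature_before > 0) mature_cut / mature_before else 0
  new_forest <- if (any(cut)) {
    cohort_forest(c(forest$ages[!cut], 0L), c(forest$areas[!cut], area_cut))
  } else {
    forest
  }
  list(forest = new_forest,
       event = list(year = year, area_cut = area_cut,
                    mature_area_before = mature_before, mfcr = mfcr))
}

#' Annual mature-area series under a rotation plan
#'
#' Drives the occupancy model in managed runs: advances the equilibrium forest
#' year by year from `t0` to `t1`, applying cut events on schedule, and
#' reports for each calendar year the mature area and any event's cut fraction
#' `mfcr`. The state for year `t0` is the plan's equilibrium distribution;
#' events land at year start, before that year's sample.
#'
#' In `"smoothed"` mode the forest is at its uniform steady state, so the
#' mature area is constant and every year after `t0` carries the constant
#' annual cut fraction `mfcr = (total_area / rotation_age) / mature_area`.
#'
#' @param plan A [rotation_plan()], or `NULL` for an unmanaged (all-mature,
#'   constant) forest.
#' @param total_area Total forest area (ha).
#' @param t0,t1 First and last calendar years (inclusive), `t0 < t1`.
#' @param maturity_age Minimum mature tree age (yr).
#' @param initial_forest Optional [cohort_forest()] overriding the equilibrium
#'   initial state (used e.g. for reforestation runs starting from age-1
#'   stands).
#' @return A data.frame with columns `year`, `mature_area`, `area_cut`,
#'   `mfcr` (`area_cut` and `mfcr` are zero in years without an event).
#' @export
mature_series <- function(plan, total_area, t0, t1, maturity_age = 34,
                          initial_forest = NULL) {
  if (t0 >= t1) stop("invalid window: `t0` must be before `t1`", call. = FALSE)
  years <- seq.int(t0, t1)
  out <- data.frame(year = years, mature_area = 0, area_cut = 0, mfcr = 0)

  if (is.null(plan) && is.null(initial_forest)) {
    out$mature_area <- total_area
    return(out)
  }
  if (!is.null(plan) && plan$mode == "smoothed" && is.null(initial_forest)) {
    f <- equilibrium_forest(total_area, plan)
    m <- mature_area(f, maturity_age)
    out$mature_area <- m
    cut <- total_area / plan$rotation_age
    out$area_cut[-1] <- cut
    out$mfcr[-1] <- if (m > 0) cut / m else 0
    return(out)
  }

  forest <- if (!is.null(initial_forest)) initial_forest
            else equilibrium_forest(total_area, plan)
  for (i in seq_along(years)) {
    y <- years[i]
    if (i > 1L) forest <- advance_year(forest)
    if (!is.null(plan) &&
        y >= plan$first_cut_year &&
        (y - plan$first_cut_year) %% plan$cut_interval == 0) {
      res <- apply_clearcut(forest, plan, maturity_age, year = y)
      forest <- res$forest
      out$area_cut[i] <- res$event$area_cut
      out$mfcr[i] <- res$event$mfcr
    }
    out$mature_area[i] <- mature_area(forest, maturity_age)
  }
  out
}
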