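#' Carrying capacity: maximum number of occupied nests
#'
#' The potential number of breeding pairs supported by the current mature
#' forest area: `moc = mfa / mfap`.
#'
#' @param mfa Mature forest area (ha), `>= 0`.
#' @param mfap Mature forest required per breeding pair (ha/pair), `> 0`.
#' @return Maximum occupied nests (pairs). 0 when `mfa = 0`.
#' @examples
#' carrying_capacity(10000, 300) # 33.33 pairs
#' @export
carrying_capacity <- function(mfa, mfap) {
  if (any(!is.finite(mfap)) || any(mfap <= 0))
    stop("invalid parameter: `mfap` must be positive", call. = FALSE)
  if (any(!is.finite(mfa)) || any(mfa < 0))
    stop("invalid parameter: `mfa` must be non-negative", call. = FALSE)
  mfa / mfap
}

#' Occupation increase rate
#'
#' Rate at which unoccupied nesting platforms become occupied by new breeding
#' pairs: `onir = anr * or * (tn - on) * cr`, where the available-nests ratio
#' `anr = (moc - on)/moc` slows settlement near carrying capacity and the
#' occupied ratio `or = on/moc` encodes conspecific attraction (settlement is
#' facilitated by established pairs; an empty landscape attracts no one, so
#' extinction is absorbing).
#'
#' Both ratios are ratios and are held in `[0, 1]`; over-capacity relaxation is
#' the abandonment flow's job (see [abandonment_rate()]). The nest-surplus
#' factor `(tn - on)` is not clamped: when a disturbance leaves more pairs than
#' standing platforms, `onir` turns negative and pulls occupancy back under the
#' number of nests.
#'
#' @param on Occupied nests (pairs), `>= 0`.
#' @param tn Total nests, `>= 0`.
#' @param moc Maximum occupied nests (pairs), `>= 0`. When `moc = 0` there is
#'   no mature forest, the ratios are undefined, and the rate is 0.
#' @param cr Change ratio (1/yr).
#' @return Occupation rate (pairs/yr).
#' @examples
#' occupation_increase_rate(on = 10, tn = 50, moc = 100 / 3) # 8.4 pairs/yr
#' @export
occupation_increase_rate <- function(on, tn, moc, cr = 1) {
  check_state(on = on, tn = tn, moc = moc)
  if (moc <= 0) return(0)
  anr <- min(1, max(0, (moc - on) / moc))
  or <- min(1, max(0, on / moc))
  anr * or * (tn - on) * cr
}

#' Abandonment rate of occupied nests
#'
#' When forest management reduces the mature area below what the current pairs
#' require, the surplus pairs abandon: `onar = (on - moc) * cr`, clamped at 0
#' while `on <= moc` (below capacity the raw expression would act as a
#' spurious growth term). With no mature forest left (`moc = 0`) all pairs are
#' under abandonment pressure and `onar = on * cr`.
#'
#' @inheritParams occupation_increase_rate
#' @return Abandonment rate (pairs/yr), `>= 0`.
#' @examples
#' abandonment_rate(on = 100 / 3, moc = 17.62) # 15.71 pairs/yr
#' @export
abandonment_rate <- function(on, moc, cr = 1) {
  check_state(on = on, moc = moc)
  max(0, (on - moc) * cr)
}

#' Nest building rate
#'
#' New platforms are built by established pairs: `nb = on * nbr`.
#'
#' @inheritParams occupation_increase_rate
#' @param nbr Nest building ratio (1/yr).
#' @return Nest building rate (nests/yr).
#' @export
nest_building_rate <- function(on, nbr) {
  check_state(on = on)
  on * nbr
}

#' Nest destruction rate
#'
#' Platforms decay with first-order mortality set by their life expectancy:
#' `ndr = tn / nlf`.
#'
#' @inheritParams occupation_increase_rate
#' @param nlf Average nest life expectancy (yr), `> 0`.
#' @return Nest destruction rate (nests/yr).
#' @export
nest_destruction_rate <- function(tn, nlf) {
  if (!is.finite(nlf) || nlf <= 0)
    stop("invalid parameter: `nlf` must be positive", call. = FALSE)
  check_state(tn = tn)
  tn / nlf
}

#' Nest loss from a clearcut event
#'
#' A clearcut removes the share of standing platforms proportional to the
#' fraction of mature forest cut: `nlfc = tn * mfcr`. With nest protection
#' (buffer zones retained around every platform, occupied or not) the loss is
#' reduced by `protection_factor` (default 90%). Applied as an instantaneous
#' pulse at cut events, not as a continuous flow.
#'
#' @inheritParams occupation_increase_rate
#' @param mfcr Fraction of the mature forest removed by the event, in `[0, 1]`.
#' @param protected Logical; is nest protection active?
#' @param protection_factor Fraction of the loss avoided under protection.
#' @return Nests lost at the event (nests).
#' @examples
#' clearcut_nest_loss(96.5, 0.2)                  # 19.3 nests
#' clearcut_nest_loss(96.5, 0.2, protected = TRUE) # 1.93 nests
#' @export
clearcut_nest_loss <- function(tn, mfcr, protected = FALSE,
                               protection_factor = 0.9) {
  if (!is.finite(mfcr) || mfcr < 0 || mfcr > 1)
    stop("invalid event: `mfcr` must lie in [0, 1]", call. = FALSE)
  check_state(tn = tn)
  loss <- tn * mfcr
  if (isTRUE(protected)) loss <- loss * (1 - protection_factor)
  loss
}

#' Equilibrium total nests at carrying capacity
#'
#' Closed-form fixed point of the nest stock when occupancy sits at capacity:
#' with `on = moc`, `d tn/dt = moc*nbr - tn/nlf = 0` gives
#' `tn* = moc * nbr * nlf`. Used to initialise managed scenarios and as the
#' analytic asymptote of unmanaged runs.
#'
#' @inheritParams occupation_increase_rate
#' @inheritParams nest_building_rate
#' @inheritParams nest_destruction_rate
#' @return Equilibrium total nests.
#' @examples
#' equilibrium_total_nests(100 / 3, 0.14, 20.68) # 96.51 nests
#' @export
equilibrium_total_nests <- function(moc, nbr, nlf) {
  check_state(moc = moc)
  moc * nbr * nlf
}

#' All instantaneous flows and diagnostics at a state
#'
#' Evaluates every flow of the occupancy model at a given state, for trajectory
#' reporting and diagnostics.
#'
#' @inheritParams occupation_increase_rate
#' @param params A [nest_params()] object.
#' @return A named list: `moc`, `anr`, `occ_ratio`, `onir`, `onar`, `nb`,
#'   `ndr`.
#' @export
flow_rates <- function(on, tn, moc, params) {
  stopifnot(inherits(params, "nest_params"))
  if (moc > 0) {
    anr <- min(1, max(0, (moc - on) / moc))
    occ_ratio <- min(1, max(0, on / moc))
    onar <- max(0, (on - moc) * params$cr)
  } else {
    anr <- 0
    occ_ratio <- 0
    onar <- on * params$cr
  }
  list(moc = moc, anr = anr, occ_ratio = occ_ratio,
       onir = if (moc > 0) anr * occ_ratio * (tn - on) * params$cr else 0,
       onar = onar,
       nb = on * params$nbr,
       ndr = tn / params$nlf)
}

# shared guard for state arguments: finite and non-negative
check_state <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(!is.finite(x)) || any(x < 0))
      stop("invalid state: `", nm, "` must be finite and non-negative",
           call. = FALSE)
  }
  invisible(TRUE)
}
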