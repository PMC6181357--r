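#' Model parameters for the nest-site dynamics model
#'
#' Bundles the field-estimated rates and habitat constants that drive the
#' two-stock occupancy model. Defaults are the published parameterisation for
#' an Aleppo pine forest raptor community in SE Spain (booted eagle, common
#' buzzard, northern goshawk, modelled as one pool).
#'
#' @param nbr Nest building ratio: average number of new nesting platforms
#'   built per breeding pair per year (1/yr).
#' @param nlf Average nest life expectancy: mean years a platform persists and
#'   remains occupiable (yr).
#' @param mfa Mature forest area (ha). Used directly only in unmanaged runs;
#'   managed runs take the mature area from the forest submodel each year.
#' @param mfap Mature forest area required per breeding pair (ha/pair).
#' @param cr Change ratio: first-order rate constant of the occupation and
#'   abandonment flows (1/yr).
#' @param protection_factor Fraction of clearcut nest loss avoided when nest
#'   protection (buffer zones around all nests) is active; in `[0, 1]`.
#' @param maturity_age Minimum tree age at which a stand counts as mature
#'   nesting habitat (yr).
#'
#' @return An object of class `"nest_params"` (a named list).
#' @examples
#' p <- nest_params()
#' carrying_capacity(p$mfa, p$mfap) # 33.3 pairs
#' @export
nest_params <- function(nbr = 0.14, nlf = 20.68, mfa = 10000, mfap = 300,
                        cr = 1, protection_factor = 0.9, maturity_age = 34) {
  p <- list(nbr = nbr, nlf = nlf, mfa = mfa, mfap = mfap, cr = cr,
            protection_factor = protection_factor, maturity_age = maturity_age)
  validate_nest_params(p)
  structure(p, class = "nest_params")
}

validate_nest_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("nbr", "nlf", "mfa", "mfap", "cr", "maturity_age")) {
    if (!num1(p[[f]]) || p[[f]] <= 0)
      stop("invalid parameter: `", f, "` must be a single positive number",
           call. = FALSE)
  }
  if (!num1(p$protection_factor) || p$protection_factor < 0 ||
      p$protection_factor > 1)
    stop("invalid parameter: `protection_factor` must lie in [0, 1]",
         call. = FALSE)
  invisible(p)
}

#' @export
print.nest_params <- function(x, ...) {
  cat("Nest-site model parameters\n")
  cat(sprintf("  nbr  (nest building ratio)      %.3f /yr\n", x$nbr))
  cat(sprintf("  nlf  (nest life expectancy)     %.2f yr\n", x$nlf))
  cat(sprintf("  mfa  (mature forest area)       %.0f ha\n", x$mfa))
  cat(sprintf("  mfap (mature forest per pair)   %.0f ha/pair\n", x$mfap))
  cat(sprintf("  cr   (change ratio)             %.2f /yr\n", x$cr))
  cat(sprintf("  protection factor               %.2f\n", x$protection_factor))
  cat(sprintf("  maturity age                    %d yr\n",
              as.integer(x$maturity_age)))
  invisible(x)
}
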