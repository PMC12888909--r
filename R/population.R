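#' Population incidence and competing-mortality model
#'
#' Holds the age-specific baseline breast-cancer hazard, the competing
#' all-cause (non-breast-cancer) mortality hazard, the population carrier
#' frequencies of the pathogenic-variant categories, and the per-age
#' calibration constant that divides the baseline hazard so that the
#' population-averaged hazard reproduces the registry incidence (see
#' [calibrate_baseline()]).
#'
#' @param age_grid strictly increasing integer ages (years).
#' @param incidence baseline annual breast-cancer hazard at each age.
#' @param mortality competing annual all-cause (non-BC) hazard at each age.
#' @param pv_frequencies named probability vector over the PV categories;
#'   must sum to 1 and every non-reference (carrier) frequency must be
#'   at most 0.01 (rare-disease assumption).
#' @param calibration per-age constant dividing the baseline hazard;
#'   defaults to 1 (uncalibrated).
#' @return an object of class `population_model`.
#' @export
population_model <- function(age_grid, incidence, mortality, pv_frequencies,
                             calibration = rep(1, length(age_grid))) {
  age_grid <- as.integer(age_grid)
  if (any(diff(age_grid) <= 0)) stop_("age_grid must be strictly increasing")
  if (length(incidence) != length(age_grid) ||
      length(mortality) != length(age_grid) ||
      length(calibration) != length(age_grid)) {
    stop_("incidence, mortality and calibration must match age_grid length")
  }
  if (any(!is.finite(incidence)) || any(incidence < 0)) {
    stop_("incidence must be finite and non-negative")
  }
  if (any(!is.finite(mortality)) || any(mortality < 0)) {
    stop_("mortality must be finite and non-negative")
  }
  if (is.null(names(pv_frequencies))) stop_("pv_frequencies must be named")
  if (abs(sum(pv_frequencies) - 1) > 1e-8) stop_("pv_frequencies must sum to 1")
  if (any(pv_frequencies[-1L] > 0.01 + 1e-12)) {
    stop_("each carrier frequency must be <= 0.01 (rare-disease assumption)")
  }
  structure(
    list(age_grid = age_grid, incidence = as.numeric(incidence),
         mortality = as.numeric(mortality),
         pv_frequencies = pv_frequencies,
         calibration = as.numeric(calibration)),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("population_model: ages %d-%d (%d points)\n",
              min(x$age_grid), max(x$age_grid), length(x$age_grid)))
  cat(sprintf("  incidence %.2e-%.2e /yr, mortality %.2e-%.2e /yr\n",
              min(x$incidence), max(x$incidence),
              min(x$mortality), max(x$mortality)))
  cat(sprintf("  PV carriers total %.4f; calibrated: %s\n",
              sum(x$pv_frequencies[-1L]),
              if (all(x$calibration == 1)) "no" else "yes"))
  invisible(x)
}

#' Default synthetic population model (ages 20-80)
#'
#' Age-specific annual breast-cancer incidence and competing all-cause
#' mortality for women, linearly interpolated between round-age anchors at
#' magnitudes typical of Western registry data, together with illustrative
#' carrier frequencies for the eight pathogenic-variant categories.  The
#' numbers are synthetic configuration, not registry estimates.
#'
#' @param ages integer age grid (default 20:80).
#' @return a [population_model()].
#' @export
default_population <- function(ages = 20:80) {
  anchor_age <- c(20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80)
  inc_per100k <- c(2, 10, 25, 60, 120, 170, 220, 230, 280, 330, 390, 410, 420)
  mort_per100k <- c(30, 35, 45, 65, 100, 150, 250, 380, 600, 950, 1600, 2700, 4500)
  incidence <- stats::approx(anchor_age, inc_per100k / 1e5, xout = ages)$y
  mortality <- stats::approx(anchor_age, mort_per100k / 1e5, xout = ages)$y
  # Carrier frequencies sit at the upper end of the rare range (all <= 0.01)
  # so that reference cohorts of a few thousand individuals contain every
  # PV category; real frequencies are lower for several genes.
  pv_freq <- c(none = NA, BRCA1 = 0.0020, BRCA2 = 0.0030, PALB2 = 0.0020,
               CHEK2 = 0.0060, ATM = 0.0050, BARD1 = 0.0020,
               RAD51C = 0.0015, RAD51D = 0.0015)
  pv_freq["none"] <- 1 - sum(pv_freq[-1L])
  population_model(ages, incidence, mortality, pv_freq)
}

pop_index <- function(pop, age) {
  i <- match(as.integer(age), pop$age_grid)
  if (is.na(i)) stop_("age %s outside the population age grid", age)
  i
}
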