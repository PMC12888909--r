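#' Index-individual profile
#'
#' One person's risk-factor record at assessment: age, prediction horizon,
#' and per-variable values where `NA` marks a risk factor that has not been
#' measured.
#'
#' @param age integer age (years) at assessment.
#' @param values named list or vector of covariate values; `NA` = missing.
#'   Continuous and binary variables are numeric, categorical/ordinal
#'   variables are character level labels.
#' @param horizon prediction horizon in years (default 10).
#' @param schema optional [risk_schema()]; when supplied, non-missing values
#'   are validated against their variable domains.
#' @return an object of class `individual_profile`.
#' @export
individual_profile <- function(age, values, horizon = 10, schema = NULL) {
  values <- as.list(values)
  if (is.null(names(values)) || any(names(values) == "")) {
    stop_("profile values must be named")
  }
  if (!is.null(schema)) {
    for (nm in schema_names(schema)) {
      if (!nm %in% names(values)) values[[nm]] <- NA
    }
    values <- values[schema_names(schema)]
    for (nm in names(values)) {
      v <- values[[nm]]
      if (length(v) != 1L) stop_("profile value '%s' must be scalar", nm)
      if (is.na(v)) next
      spec <- schema$variables[[nm]]
      if (spec$kind %in% c("categorical", "ordinal-count")) {
        if (!v %in% spec$levels) {
          stop_("value '%s' of '%s' is not a declared level", v, nm)
        }
      } else if (spec$kind == "binary") {
        if (!v %in% c(0, 1)) stop_("binary variable '%s' must be 0 or 1", nm)
      } else {
        if (!is.numeric(v)) stop_("variable '%s' must be numeric", nm)
        if (spec$kind != "continuous" && v < 0) {
          stop_("variable '%s' must be non-negative", nm)
        }
        if (spec$kind == "continuous-positive" && v <= 0) {
          stop_("variable '%s' must be positive", nm)
        }
      }
    }
  }
  structure(list(age = as.integer(age), horizon = as.integer(horizon),
                 values = values),
            class = "individual_profile")
}

#' @export
print.individual_profile <- function(x, ...) {
  miss <- names(x$values)[vapply(x$values, function(v) any(is.na(v)), logical(1))]
  cat(sprintf("individual_profile: age %d, horizon %d years\n",
              x$age, x$horizon))
  for (nm in names(x$values)) {
    v <- x$values[[nm]]
    cat(sprintf("  %-12s %s\n", nm, if (any(is.na(v))) "<missing>" else format(v)))
  }
  if (length(miss)) cat(sprintf("  (%d missing)\n", length(miss)))
  invisible(x)
}

profile_missing <- function(profile) {
  names(profile$values)[vapply(profile$values, function(v) any(is.na(v)),
                               logical(1))]
}

profile_as_row <- function(profile, schema) {
  vals <- profile$values[schema_names(schema)]
  df <- as.data.frame(lapply(vals, function(v) v), stringsAsFactors = FALSE,
                      optional = TRUE)
  names(df) <- schema_names(schema)
  df
}

#' Risk-category scheme
#'
#' Ordered risk cut-points and band labels.  The default reproduces the NICE
#' 10-year bands: near-population (<3%), moderate (3%-8%), high (>8%); both
#' cut-points belong to the moderate band.
#'
#' @param thresholds strictly increasing cut-points in (0,1).
#' @param labels one label per band (`length(thresholds) + 1`).
#' @return an object of class `category_scheme`.
#' @export
category_scheme <- function(thresholds = c(0.03, 0.08),
                            labels = c("near-population", "moderate", "high")) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1)) {
    stop_("thresholds must be strictly increasing and in (0,1)")
  }
  if (length(labels) != length(thresholds) + 1L) {
    stop_("need one label per band (thresholds + 1)")
  }
  structure(list(thresholds = thresholds, labels = labels),
            class = "category_scheme")
}

# Integer band index; boundary values belong to the middle band(s):
# risk < t1 -> band 1, risk > t_last -> last band, cut-points inclusive inward.
classify_index <- function(risk, scheme) {
  thr <- scheme$thresholds
  idx <- rep(1L, length(risk))
  for (t in thr) idx <- idx + (risk > t)
  idx[risk >= thr[1L] & idx == 1L] <- 2L
  idx
}

#' Classify a risk value into a category band
#'
#' @param risk probability (or vector of probabilities) in `[0,1]`.
#' @param scheme a [category_scheme()].
#' @return character vector of band labels.
#' @examples
#' classify(c(0.025, 0.05, 0.09), category_scheme())
#' @export
classify <- function(risk, scheme = category_scheme()) {
  if (any(!is.finite(risk)) || any(risk < 0 | risk > 1)) {
    stop_("risk must lie in [0,1]")
  }
  scheme$labels[classify_index(risk, scheme)]
}

# Vectorized log relative risk over a completed data.frame (schema order not
# required; looked up by name). Errors on missing entries.
log_rr_rows <- function(data, schema) {
  out <- numeric(nrow(data))
  for (spec in schema$variables) {
    x <- data[[spec$name]]
    if (anyNA(x)) {
      stop_(paste0("variable '%s' has missing entries; use the uncertainty ",
                   "module (risk_distribution) for profiles with missing data"),
            spec$name)
    }
    out <- out + switch(spec$kind,
      "continuous" = spec$risk_effect * (x - spec$center) / spec$scale,
      "continuous-positive" = {
        t_x <- if (spec$transform == "log") log(x) else x
        spec$risk_effect * (t_x - spec$center) / spec$scale
      },
      "semicontinuous-zero-inflated" = {
        pos <- x > 0
        contrib <- numeric(length(x))
        contrib[pos] <- spec$risk_effect[["positive"]] +
          spec$risk_effect[["per_sd"]] * (log(x[pos]) - spec$center) / spec$scale
        contrib
      },
      "binary" = spec$risk_effect * x,
      "categorical" = ,
      "ordinal-count" = unname(spec$risk_effect[match(x, spec$levels)])
    )
  }
  out
}

#' Multiplicative relative risk of a complete profile
#'
#' The product over risk factors of each factor's relative-risk contribution;
#' equals 1 when every factor sits at its reference value.  Continuous
#' factors contribute `exp(beta * (t(x) - center)/scale)` on their transform
#' scale; categorical factors contribute their level's relative risk.
#'
#' @param profile a complete [individual_profile()] (no missing entries).
#' @param schema a [risk_schema()].
#' @return positive scalar relative risk.
#' @export
relative_risk <- function(profile, schema) {
  exp(log_rr_rows(profile_as_row(profile, schema), schema))
}

#' Calibrate the baseline hazard to population incidence
#'
#' In a multiplicative model the population-averaged hazard at each age is
#' the baseline hazard times the cohort-mean relative risk.  Calibration
#' divides the baseline by that mean so the cohort-average annual hazard
#' equals the registry incidence at every age.  Risk effects here do not
#' depend on age, so the constant is the same at all ages; it is stored as a
#' per-age vector.
#'
#' @param pop a [population_model()].
#' @param schema a [risk_schema()].
#' @param cohort a complete `reference_cohort` (no missing entries).
#' @return the population model with its `calibration` set.
#' @export
calibrate_baseline <- function(pop, schema, cohort) {
  stopifnot(inherits(cohort, "reference_cohort"))
  if (nrow(cohort$data) == 0L) stop_("cohort is empty")
  if (anyNA(cohort$data)) stop_("cohort must be complete for calibration")
  mean_rr <- mean(exp(log_rr_rows(cohort$data, schema)))
  pop$calibration <- rep(mean_rr, length(pop$age_grid))
  pop
}

# Cumulative incidence with competing mortality for a vector of relative
# risks, per-year discrete hazards with exact within-year competing-risk
# split: sum_t S(t) * lambda/(lambda+mu) * (1 - exp(-(lambda+mu))).
cumulative_risk_rr <- function(rr, age, horizon, pop) {
  if (horizon == 0L) return(rep(0, length(rr)))
  i0 <- pop_index(pop, age)
  pop_index(pop, age + horizon)  # horizon end must lie on the grid
  surv <- rep(1, length(rr))
  risk <- rep(0, length(rr))
  for (t in seq_len(horizon) - 1L) {
    lam <- pop$incidence[i0 + t] / pop$calibration[i0 + t] * rr
    mu <- pop$mortality[i0 + t]
    tot <- lam + mu
    q <- ifelse(tot > 0, lam / tot * (1 - exp(-tot)), 0)
    risk <- risk + surv * q
    surv <- surv * exp(-tot)
  }
  risk
}

#' Absolute risk over the profile's horizon, with competing mortality
#'
#' Cumulative incidence of breast cancer over `[age, age + horizon)`,
#' accounting for the competing chance of dying of other causes first.
#' Hazards are piecewise constant on whole years; within each year the
#' cause-specific split is exact, so constant-hazard closed forms are
#' reproduced exactly.
#'
#' @param profile a complete [individual_profile()].
#' @param pop a calibrated [population_model()].
#' @param schema a [risk_schema()].
#' @return probability in `[0, 1)`.
#' @export
absolute_risk <- function(profile, pop, schema) {
  rr <- relative_risk(profile, schema)
  cumulative_risk_rr(rr, profile$age, profile$horizon, pop)
}
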