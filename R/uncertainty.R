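#' Monte Carlo risk distribution for an individual with missing data
#'
#' Runs [chained_impute()] to draw `M` completed covariate vectors for the
#' index individual, maps each through [absolute_risk()], and summarises the
#' resulting Monte Carlo risk distribution: point estimate (the sample mean,
#' i.e. the mean risk over unmeasured covariates), equal-tailed uncertainty
#' interval, and the probability of falling in each risk category after all
#' missing factors were measured.
#'
#' @param profile an [individual_profile()].
#' @param models fitted `imputation_models`.
#' @param pop a calibrated [population_model()].
#' @param schema a [risk_schema()]; defaults to the model set's schema.
#' @param M Monte Carlo samples (default 1000, the study convention).
#' @param seed integer seed.
#' @param scheme a [category_scheme()].
#' @param level uncertainty-interval level (default 0.95).
#' @param n_iter,n_chains passed to [chained_impute()].
#' @return an object of class `risk_distribution` with fields `samples`,
#'   `point_estimate`, `ui`, `category_probs`, `rhat`, `horizon`, `M`,
#'   `seed`.
#' @export
risk_distribution <- function(profile, models, pop, schema = models$schema,
                              M = 1000L, seed, scheme = category_scheme(),
                              level = 0.95, n_iter = 10L, n_chains = 4L) {
  cps <- chained_impute(profile, models, M = M, n_iter = n_iter,
                        n_chains = n_chains, seed = seed)
  samples <- cumulative_risk_rr(exp(log_rr_rows(cps$data, schema)),
                                profile$age, profile$horizon, pop)
  rep_ <- convergence_report(cps)
  new_risk_distribution(samples, profile, scheme, level, seed,
                        rhat = rep_$rhat)
}

new_risk_distribution <- function(samples, profile, scheme, level, seed,
                                  rhat = NULL) {
  structure(
    list(samples = samples,
         point_estimate = mean(samples),
         ui = uncertainty_interval(samples, level),
         level = level,
         category_probs = category_probabilities(samples, scheme),
         scheme = scheme,
         rhat = rhat,
         horizon = profile$horizon, age = profile$age,
         M = length(samples), seed = seed),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("risk_distribution: %d-year risk from age %d (M=%d)\n",
              x$horizon, x$age, x$M))
  cat(sprintf("  point estimate %.2f%%,  %d%% UI %.2f%%-%.2f%%\n",
              100 * x$point_estimate, round(100 * x$level),
              100 * x$ui[[1L]], 100 * x$ui[[2L]]))
  for (nm in names(x$category_probs)) {
    cat(sprintf("  P(%s) = %.3f\n", nm, x$category_probs[[nm]]))
  }
  invisible(x)
}

#' Equal-tailed empirical uncertainty interval
#'
#' Empirical quantile interval at probabilities `(1-level)/2` and
#' `1-(1-level)/2`, using the linear-interpolation quantile convention
#' (`stats::quantile` type 7) so that results are bit-reproducible.  At
#' `level = 0` both endpoints collapse to the median by convention.
#'
#' @param dist a `risk_distribution` or a numeric vector of samples.
#' @param level interval level in `[0, 1)` (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
uncertainty_interval <- function(dist, level = 0.95) {
  samples <- if (inherits(dist, "risk_distribution")) dist$samples else dist
  if (length(samples) < 2L) stop_("need at least 2 samples")
  if (level < 0 || level >= 1) stop_("level must lie in [0, 1)")
  if (level == 0) {
    m <- stats::quantile(samples, 0.5, type = 7, names = FALSE)
    return(c(lower = m, upper = m))
  }
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 7, names = FALSE)
  c(lower = q[[1L]], upper = q[[2L]])
}

#' Risk-category probabilities of a risk distribution
#'
#' Empirical frequency of each category among the Monte Carlo risk samples:
#' the probability that, after measuring all missing factors, the risk falls
#' in each band.  Frequencies sum to 1 exactly.
#'
#' @param dist a `risk_distribution` or numeric sample vector.
#' @param scheme a [category_scheme()].
#' @return named probability vector, one entry per category label.
#' @export
category_probabilities <- function(dist, scheme = category_scheme()) {
  samples <- if (inherits(dist, "risk_distribution")) dist$samples else dist
  idx <- classify_index(samples, scheme)
  counts <- tabulate(idx, nbins = length(scheme$labels))
  stats::setNames(counts / length(samples), scheme$labels)
}

#' Risk distributions across fixed polygenic-score percentiles
#'
#' For each requested percentile `p`, fixes the (missing) PGS at the
#' standard-normal quantile `qnorm(p/100)` and computes the Monte Carlo risk
#' distribution over the remaining missing covariates.  Used to show how the
#' location and spread of the uncertainty distribution vary with the PGS.
#'
#' @param profile an [individual_profile()] in which the PGS is missing.
#' @param models,pop,schema,M,seed,scheme,level,n_iter,n_chains as in
#'   [risk_distribution()].
#' @param percentiles PGS percentiles in (0, 100); default 10, 20, ..., 90.
#' @return named list of `risk_distribution` objects, in percentile order.
#' @export
pgs_sweep <- function(profile, models, pop, schema = models$schema,
                      percentiles = seq(10, 90, by = 10), M = 1000L, seed,
                      scheme = category_scheme(), level = 0.95,
                      n_iter = 10L, n_chains = 4L) {
  pgs_var <- schema$pgs_variable
  if (is.null(pgs_var)) stop_("schema declares no PGS variable")
  if (!is.na(profile$values[[pgs_var]])) {
    stop_("pgs_sweep requires the PGS ('%s') to be missing in the profile",
          pgs_var)
  }
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop_("percentiles must lie strictly between 0 and 100")
  }
  out <- vector("list", length(percentiles))
  names(out) <- paste0("p", percentiles)
  for (i in seq_along(percentiles)) {
    pr <- profile
    pr$values[[pgs_var]] <- stats::qnorm(percentiles[i] / 100)
    out[[i]] <- risk_distribution(pr, models, pop, schema, M = M,
                                  seed = child_seed(seed, i), scheme = scheme,
                                  level = level, n_iter = n_iter,
                                  n_chains = n_chains)
  }
  out
}
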