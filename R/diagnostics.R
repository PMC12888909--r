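#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `sqrt(((n-1)/n * W + B/n) / W)` from per-chain traces of a scalar
#' quantity, where `W` is the mean within-chain variance and `B` is `n` times
#' the variance of the chain means.  With zero between-chain variance the
#' statistic attains its floor `sqrt((n-1)/n)`.
#'
#' @param chains numeric matrix (one row per chain, one column per
#'   iteration) or list of equal-length numeric vectors.
#' @return the PSRF (R-hat); `Inf` when chains are internally constant but
#'   disagree, and 1 when all chains are identical constants.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(rbind, chains)
  if (!is.matrix(chains) || nrow(chains) < 2L || ncol(chains) < 2L) {
    stop_("need >= 2 chains with >= 2 iterations each")
  }
  if (anyNA(chains)) return(NA_real_)
  n <- ncol(chains)
  W <- mean(apply(chains, 1L, stats::var))
  B <- n * stats::var(rowMeans(chains))
  if (W == 0) {
    if (B > 0) return(Inf)
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for an imputation run
#'
#' Applies [gelman_rubin()] to the per-chain traces of the mean and SD of
#' every imputed variable recorded by [chained_impute()].
#'
#' @param cps a `completed_profiles` object.
#' @return an object of class `convergence_report` with the per-quantity
#'   R-hat vector and the raw traces.
#' @export
convergence_report <- function(cps) {
  stopifnot(inherits(cps, "completed_profiles"))
  if (is.null(cps$traces)) {
    return(structure(list(rhat = numeric(0), traces = NULL,
                          n_iter = cps$n_iter, n_chains = cps$n_chains),
                     class = "convergence_report"))
  }
  stats_nm <- dimnames(cps$traces)[[2L]]
  rhat <- vapply(stats_nm, function(s) {
    gelman_rubin(t(cps$traces[, s, ]))
  }, numeric(1))
  structure(list(rhat = rhat, traces = cps$traces,
                 n_iter = cps$n_iter, n_chains = cps$n_chains),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report: %d chains, %d iterations\n",
              x$n_chains, x$n_iter))
  if (!length(x$rhat)) {
    cat("  nothing was imputed; no monitored quantities\n")
    return(invisible(x))
  }
  for (nm in names(x$rhat)) {
    cat(sprintf("  %-20s R-hat = %.4f\n", nm, x$rhat[[nm]]))
  }
  invisible(x)
}

#' Trace plot of the monitored imputation quantities
#'
#' @param x a `convergence_report`.
#' @param quantities subset of monitored quantities (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.convergence_report <- function(x, quantities = NULL, ...) {
  if (is.null(x$traces)) {
    warning("no traces to plot")
    return(invisible(x))
  }
  quantities <- quantities %||% dimnames(x$traces)[[2L]]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(quantities)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (q in quantities) {
    graphics::matplot(x$traces[, q, ], type = "l", lty = 1,
                      xlab = "iteration", ylab = q, main = q, ...)
  }
  invisible(x)
}

#' Compare observed and imputed value distributions
#'
#' Imputes a cohort's missing entries once (single completed dataset, one
#' parameter draw per variable per cycle) and contrasts, per variable, the
#' distribution of originally observed values with the distribution of the
#' imputed ones: mean/SD and a two-sample Kolmogorov-Smirnov statistic for
#' continuous variables, level frequencies and total-variation distance for
#' discrete ones.  Under MCAR the two distributions should agree; under MAR
#' they may legitimately differ.
#'
#' @param cohort a `reference_cohort` carrying missingness.
#' @param models fitted `imputation_models`.
#' @param variables variables to check (default: all with missing entries).
#' @param seed integer seed.
#' @param n_iter chained-equations iterations (default 10).
#' @return an object of class `imputation_check`: one entry per variable
#'   with the summaries above; fully observed variables are skipped with a
#'   warning.
#' @export
compare_observed_imputed <- function(cohort, models, variables = NULL,
                                     seed, n_iter = 10L) {
  stopifnot(inherits(cohort, "reference_cohort"),
            inherits(models, "imputation_models"))
  data <- cohort$data
  schema <- models$schema
  variables <- variables %||%
    schema_names(schema)[vapply(schema_names(schema),
                                function(v) anyNA(data[[v]]), logical(1))]
  completed <- with_seed(seed, mice_rows(models, data, n_iter,
                                         per_row = FALSE))$data
  out <- list()
  for (v in variables) {
    miss <- is.na(data[[v]])
    if (!any(miss)) {
      warning(sprintf("variable '%s' has no missing entries; skipped", v))
      out[[v]] <- list(variable = v, skipped = TRUE)
      next
    }
    spec <- schema$variables[[v]]
    obs_vals <- data[[v]][!miss]
    imp_vals <- completed[[v]][miss]
    if (spec$kind %in% c("categorical", "ordinal-count", "binary")) {
      lev <- spec$levels %||% c("0", "1")
      p_obs <- table(factor(as.character(obs_vals), levels = lev))
      p_imp <- table(factor(as.character(imp_vals), levels = lev))
      p_obs <- as.numeric(p_obs) / sum(p_obs)
      p_imp <- as.numeric(p_imp) / sum(p_imp)
      out[[v]] <- list(variable = v, skipped = FALSE, kind = spec$kind,
                       levels = lev, freq_observed = p_obs,
                       freq_imputed = p_imp,
                       tv_distance = 0.5 * sum(abs(p_obs - p_imp)))
    } else {
      ks <- suppressWarnings(stats::ks.test(obs_vals, imp_vals))
      out[[v]] <- list(variable = v, skipped = FALSE, kind = spec$kind,
                       mean_observed = mean(obs_vals), sd_observed = stats::sd(obs_vals),
                       mean_imputed = mean(imp_vals), sd_imputed = stats::sd(imp_vals),
                       ks_statistic = unname(ks$statistic))
    }
  }
  structure(list(checks = out, seed = seed), class = "imputation_check")
}

#' @export
print.imputation_check <- function(x, ...) {
  cat("imputation_check: observed vs imputed distributions\n")
  for (ck in x$checks) {
    if (isTRUE(ck$skipped)) {
      cat(sprintf("  %-12s skipped (fully observed)\n", ck$variable))
    } else if (!is.null(ck$ks_statistic)) {
      cat(sprintf("  %-12s mean %.3f/%.3f  sd %.3f/%.3f  KS=%.4f\n",
                  ck$variable, ck$mean_observed, ck$mean_imputed,
                  ck$sd_observed, ck$sd_imputed, ck$ks_statistic))
    } else {
      cat(sprintf("  %-12s TV distance = %.4f\n", ck$variable, ck$tv_distance))
    }
  }
  invisible(x)
}
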