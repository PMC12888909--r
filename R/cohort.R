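#' Synthetic reference cohorts via a Gaussian copula
#'
#' `simulate_cohort()` draws a reference cohort with the mixed-type,
#' correlated covariate structure that breast-cancer risk models assume:
#' latent standard-normal scores with a user-supplied correlation matrix are
#' mapped through each variable's declared margin (normal, log-normal,
#' zero-inflated log-normal, Bernoulli, multinomial).  The family-history
#' count is not part of the copula: it is drawn conditionally on the
#' polygenic score and carrier status through a sequential logistic link, so
#' that family history is positively associated with the genetic factors.
#'
#' @param schema a [risk_schema()].
#' @param pop a [population_model()]; supplies the PV carrier frequencies.
#' @param n number of individuals (>= 1).
#' @param dependence correlation matrix over the latent scores of the
#'   non-family-history variables, with dimnames naming the variables;
#'   defaults to [default_dependence()].
#' @param seed integer seed; fixed seed gives byte-identical cohorts.
#' @return an object of class `reference_cohort`: a list with `data`
#'   (data.frame keyed by schema variable names), `schema`, and `provenance`
#'   (generator parameters and seed).
#' @export
simulate_cohort <- function(schema, pop, n, dependence = NULL, seed) {
  if (n < 1) stop_("n must be >= 1")
  copula_vars <- setdiff(schema_names(schema),
                         names(schema$variables)[schema_groups(schema) == "FH"])
  if (is.null(dependence)) dependence <- default_dependence(schema)
  dependence <- dependence[copula_vars, copula_vars]
  L <- tryCatch(chol(dependence), error = function(e) {
    stop_("dependence matrix is not positive definite")
  })
  data <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * length(copula_vars)), nrow = n) %*% L
    colnames(z) <- copula_vars
    cols <- lapply(copula_vars, function(nm) {
      margin_map(schema$variables[[nm]], z[, nm], pop)
    })
    names(cols) <- copula_vars
    df <- as.data.frame(cols, stringsAsFactors = FALSE,
                        check.names = FALSE, optional = TRUE)
    for (nm in setdiff(schema_names(schema), copula_vars)) {
      df[[nm]] <- draw_fh(schema$variables[[nm]], df, schema, n)
    }
    df[, schema_names(schema), drop = FALSE]
  })
  structure(
    list(data = data, schema = schema,
         provenance = list(
           generator = "gaussian-copula",
           n = n, seed = seed,
           dependence = dependence,
           pv_frequencies = as.list(pop$pv_frequencies)
         )),
    class = "reference_cohort"
  )
}

# Map latent standard-normal scores to one declared margin.
margin_map <- function(spec, z, pop) {
  m <- spec$margin
  u <- stats::pnorm(z)
  switch(spec$kind,
    "continuous" = m$mean + m$sd * z,
    "continuous-positive" = exp(m$meanlog + m$sdlog * z),
    "semicontinuous-zero-inflated" = {
      x <- numeric(length(u))
      pos <- u >= m$p_zero
      x[pos] <- stats::qlnorm((u[pos] - m$p_zero) / (1 - m$p_zero),
                              m$meanlog, m$sdlog)
      x
    },
    "binary" = as.integer(u > 1 - m$p),
    "categorical" = ,
    "ordinal-count" = {
      probs <- if (length(m$probs)) m$probs else as.numeric(pop$pv_frequencies)
      if (length(probs) != length(spec$levels)) {
        stop_("margin probabilities of '%s' do not match its levels", spec$name)
      }
      spec$levels[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
    },
    stop_("no margin generator for kind '%s'", spec$kind)
  )
}

# Family-history count via sequential logistic link on PGS and carrier status.
draw_fh <- function(spec, df, schema, n) {
  pgs <- df[[schema$pgs_variable]]
  carrier <- as.numeric(df[[schema$pv_variable]] !=
                          schema$variables[[schema$pv_variable]]$levels[1L])
  b1 <- spec$margin$b_any
  b2 <- spec$margin$b_two
  p_any <- stats::plogis(b1[["intercept"]] + b1[["pgs"]] * pgs +
                           b1[["carrier"]] * carrier)
  p_two <- stats::plogis(b2[["intercept"]] + b2[["pgs"]] * pgs +
                           b2[["carrier"]] * carrier)
  any1 <- stats::runif(n) < p_any
  two <- any1 & (stats::runif(n) < p_two)
  lev <- spec$levels
  out <- rep(lev[1L], n)
  out[any1] <- lev[2L]
  out[two] <- lev[3L]
  out
}

#' Default latent-score correlation matrix
#'
#' Identity with modest correlations among anthropometric/lifestyle scores:
#' BMI with mammographic density (negative, as heavier women tend to have
#' lower percent density), BMI with alcohol (small positive), HRT with
#' oral-contraceptive use (small negative).
#'
#' @param schema a [risk_schema()].
#' @return correlation matrix over the non-FH variables, with dimnames.
#' @export
default_dependence <- function(schema) {
  vars <- setdiff(schema_names(schema),
                  names(schema$variables)[schema_groups(schema) == "FH"])
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    if (all(c(a, b) %in% vars)) R[a, b] <<- R[b, a] <<- r
  }
  set_r("bmi", "md", -0.30)
  set_r("bmi", "alcohol", 0.10)
  set_r("hrt_use", "oc_use", -0.10)
  R
}

#' @export
print.reference_cohort <- function(x, ...) {
  nmiss <- sum(is.na(x$data))
  cat(sprintf("reference_cohort: %d x %d (%s missing entries)\n",
              nrow(x$data), ncol(x$data),
              if (nmiss) format(nmiss) else "no"))
  invisible(x)
}

#' Impose MCAR or MAR missingness on a cohort
#'
#' Flags entries as missing without removing rows.  MCAR masks each entry of
#' a variable independently with its stated rate; MAR masks with probability
#' `plogis(intercept + sum(slopes * drivers))`, a logistic model on fully
#' observed numeric driver variables.  If `intercepts` is omitted for MAR,
#' each variable's intercept is solved so that the expected missingness
#' fraction equals its `rates` entry.
#'
#' @param cohort a `reference_cohort`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rates named per-variable missingness probabilities in `[0,1]`;
#'   variables not named are left fully observed.
#' @param drivers character vector of fully observed numeric variables that
#'   drive MAR missingness.
#' @param slopes named numeric vector of logistic slopes, one per driver.
#' @param intercepts optional named per-variable logistic intercepts; when
#'   given, `rates` is ignored for those variables.
#' @param seed integer seed.
#' @return the cohort with entries flagged missing (`NA`) and provenance
#'   extended with the missingness parameters.
#' @export
apply_missingness <- function(cohort, mechanism = c("MCAR", "MAR"),
                              rates, drivers = NULL, slopes = NULL,
                              intercepts = NULL, seed) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(cohort, "reference_cohort"))
  if (any(!is.na(rates) & (rates < 0 | rates > 1))) {
    stop_("rates must lie in [0,1]")
  }
  if (anyNA(rates) && mechanism == "MCAR") {
    stop_("MCAR rates must not be NA")
  }
  data <- cohort$data
  vars <- names(rates)
  if (is.null(vars)) stop_("rates must be a named vector")
  if (!all(vars %in% names(data))) stop_("rates name unknown variables")
  if (mechanism == "MAR") {
    if (is.null(drivers) || is.null(slopes)) {
      stop_("MAR requires drivers and slopes")
    }
    for (d in drivers) {
      if (anyNA(data[[d]])) {
        stop_("MAR driver '%s' has missing entries; drivers must be fully observed", d)
      }
      if (!is.numeric(data[[d]])) stop_("MAR driver '%s' must be numeric", d)
    }
    eta_drv <- as.matrix(data[, drivers, drop = FALSE]) %*% slopes[drivers]
  }
  data <- with_seed(seed, {
    for (v in vars) {
      p <- if (mechanism == "MCAR") {
        rep(rates[[v]], nrow(data))
      } else {
        a <- if (!is.null(intercepts) && v %in% names(intercepts)) {
          intercepts[[v]]
        } else {
          solve_mar_intercept(eta_drv, rates[[v]])
        }
        stats::plogis(a + eta_drv)
      }
      hit <- stats::runif(nrow(data)) < p
      data[[v]][hit] <- NA
    }
    data
  })
  cohort$data <- data
  cohort$provenance$missingness <- list(
    mechanism = mechanism, rates = as.list(rates),
    drivers = drivers, slopes = as.list(slopes %||% numeric()),
    seed = seed
  )
  cohort
}

# Solve the intercept so the average masking probability matches the target.
solve_mar_intercept <- function(eta, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - rate,
                 interval = c(-50, 50), tol = 1e-10)$root
}
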