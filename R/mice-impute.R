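# Chained-equations draws.  Each missing value is redrawn from its fitted
# conditional model; "proper" imputation first perturbs the model parameters
# with a draw from their asymptotic sampling distribution.  Draw mode:
#   per-row     every row is its own imputed dataset with its own parameter
#               draw each cycle (index-individual Monte Carlo samples)
#   per-dataset one parameter draw per variable per cycle shared by all rows
#               (single completed dataset, e.g. cohort-level checks)

draw_gaussian_values <- function(fit, X, per_row) {
  Xk <- X[, fit$keep, drop = FALSE]
  n <- nrow(Xk)
  p <- length(fit$coef)
  if (per_row) {
    s2 <- fit$sigma2 * fit$df / stats::rchisq(n, fit$df)
    B <- matrix(stats::rnorm(n * p), n) %*% fit$chol_V * sqrt(s2)
    eta <- drop(Xk %*% fit$coef) + rowSums(Xk * B)
    stats::rnorm(n, eta, sqrt(s2))
  } else {
    s2 <- fit$sigma2 * fit$df / stats::rchisq(1L, fit$df)
    b <- fit$coef + sqrt(s2) * drop(crossprod(fit$chol_V, stats::rnorm(p)))
    stats::rnorm(n, drop(Xk %*% b), sqrt(s2))
  }
}

draw_logistic_prob <- function(fit, X, per_row) {
  n <- nrow(X)
  p <- length(fit$coef)
  if (per_row) {
    B <- matrix(stats::rnorm(n * p), n) %*% fit$chol_V
    stats::plogis(drop(X %*% fit$coef) + rowSums(X * B))
  } else {
    b <- fit$coef + drop(crossprod(fit$chol_V, stats::rnorm(p)))
    stats::plogis(drop(X %*% b))
  }
}

draw_multinom_level <- function(fit, X, per_row, levels) {
  n <- nrow(X)
  p <- ncol(X)
  k1 <- fit$k - 1L
  q <- length(fit$coef_vec)
  eta <- matrix(0, n, fit$k)
  if (per_row) {
    B <- matrix(stats::rnorm(n * q), n) %*% fit$chol_V
    B <- sweep(B, 2L, fit$coef_vec, "+")
    for (k in seq_len(k1)) {
      cols <- ((k - 1L) * p + 1L):(k * p)
      eta[, k + 1L] <- rowSums(X * B[, cols, drop = FALSE])
    }
  } else {
    b <- fit$coef_vec + drop(crossprod(fit$chol_V, stats::rnorm(q)))
    Bm <- matrix(b, nrow = k1, byrow = TRUE)
    eta[, -1L] <- X %*% t(Bm)
  }
  eta <- eta - apply(eta, 1L, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  cs <- P
  for (k in 2:ncol(cs)) cs[, k] <- cs[, k - 1L] + P[, k]
  idx <- rowSums(stats::runif(n) > cs) + 1L
  levels[pmin(idx, length(levels))]
}

# One conditional draw of `model`'s target for the given predictor rows.
draw_conditional <- function(model, X, per_row) {
  switch(model$kind,
    "continuous" = draw_gaussian_values(model$fit, X, per_row),
    "continuous-positive" = {
      y <- draw_gaussian_values(model$fit, X, per_row)
      if (model$transform == "log") exp(y) else y
    },
    "binary" = as.integer(stats::runif(nrow(X)) <
                            draw_logistic_prob(model$fit, X, per_row)),
    "semicontinuous-zero-inflated" = {
      p_zero <- draw_logistic_prob(model$fit$zero, X, per_row)
      zero <- stats::runif(nrow(X)) < p_zero
      y <- exp(draw_gaussian_values(model$fit$pos, X, per_row))
      y[zero] <- 0
      y
    },
    "categorical" = ,
    "ordinal-count" = draw_multinom_level(model$fit, X, per_row, model$levels)
  )
}

numeric_code <- function(x, spec) {
  if (spec$kind %in% c("categorical", "ordinal-count")) {
    as.numeric(match(x, spec$levels))
  } else {
    as.numeric(x)
  }
}

# Core chained-equations cycle over a data.frame whose NAs mark the values
# to draw.  Assumes the caller has set the RNG state.
mice_rows <- function(models, data, n_iter, per_row = TRUE,
                      monitor_chain = NULL) {
  schema <- models$schema
  na_rows <- lapply(schema_names(schema), function(v) which(is.na(data[[v]])))
  names(na_rows) <- schema_names(schema)
  active <- names(na_rows)[lengths(na_rows) > 0L]
  traces <- NULL
  if (!length(active)) return(list(data = data, traces = traces))

  for (v in active) {
    pool <- models$models[[v]]$marginal_pool
    data[[v]][na_rows[[v]]] <- sample(pool, length(na_rows[[v]]),
                                      replace = TRUE)
  }
  if (!is.null(monitor_chain)) {
    chains <- sort(unique(monitor_chain))
    stats_nm <- as.vector(outer(c("mean", "sd"), active,
                                function(s, v) paste0(v, "_", s)))
    traces <- array(NA_real_, dim = c(n_iter, length(stats_nm), length(chains)),
                    dimnames = list(NULL, stats_nm, paste0("chain", chains)))
  }
  for (it in seq_len(n_iter)) {
    for (v in intersect(models$visit_order, active)) {
      rows <- na_rows[[v]]
      X <- build_design(data[rows, , drop = FALSE], schema, v)
      data[[v]][rows] <- draw_conditional(models$models[[v]], X, per_row)
    }
    if (!is.null(monitor_chain)) {
      for (v in active) {
        nv <- numeric_code(data[[v]][na_rows[[v]]],
                           schema$variables[[v]])
        grp <- monitor_chain[na_rows[[v]]]
        traces[it, paste0(v, "_mean"), ] <-
          vapply(chains, function(g) mean(nv[grp == g]), numeric(1))
        traces[it, paste0(v, "_sd"), ] <-
          vapply(chains, function(g) stats::sd(nv[grp == g]), numeric(1))
      }
    }
  }
  list(data = data, traces = traces)
}

#' Multiple imputation of an individual's missing risk factors
#'
#' Draws `M` completed covariate vectors for one index individual by chained
#' equations: each sample initialises its missing entries with draws from the
#' observed marginals, then cycles through the variables in schema order for
#' `n_iter` iterations, each time drawing the conditional model's parameters
#' from their asymptotic sampling distribution (proper imputation) and then
#' drawing the missing value from the conditional model.  Observed entries
#' are never altered, and a pathogenic-variant draw is a single categorical
#' draw, so at most one PV per completed vector by construction.
#'
#' For diagnostics the `M` samples are partitioned into `n_chains` groups and
#' the mean and SD of every imputed variable are traced across iterations per
#' group; see [convergence_report()].
#'
#' @param profile an [individual_profile()].
#' @param models an `imputation_models` object from [fit_conditional_models()].
#' @param M number of imputed samples (the study default is 1000).
#' @param n_iter chained-equations iterations per sample (default 10).
#' @param n_chains chain groups used for diagnostics (default 4).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `completed_profiles`: `data` (M completed
#'   rows), `traces`, and the call's metadata.
#' @export
chained_impute <- function(profile, models, M, n_iter = 10L, n_chains = 4L,
                           seed) {
  stopifnot(inherits(models, "imputation_models"),
            inherits(profile, "individual_profile"))
  if (M < 1) stop_("M must be >= 1")
  schema <- models$schema
  row <- profile_as_row(profile, schema)
  data <- row[rep(1L, M), , drop = FALSE]
  rownames(data) <- NULL
  chain_id <- rep(seq_len(n_chains), length.out = M)
  res <- with_seed(seed, mice_rows(models, data, n_iter, per_row = TRUE,
                                   monitor_chain = chain_id))
  structure(
    list(data = res$data, traces = res$traces, profile = profile,
         schema = schema, M = M, n_iter = n_iter, n_chains = n_chains,
         chain_id = chain_id, seed = seed),
    class = "completed_profiles"
  )
}

#' @export
print.completed_profiles <- function(x, ...) {
  cat(sprintf("completed_profiles: M=%d samples, %d iterations, %d chains\n",
              x$M, x$n_iter, x$n_chains))
  cat(sprintf("  imputed variables: %s\n",
              paste(profile_missing(x$profile), collapse = ", ")))
  invisible(x)
}
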