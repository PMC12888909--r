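# Fitting the per-variable conditional models of the chained-equations
# engine.  Families by variable kind:
#   continuous(-positive)        linear regression on the transform scale
#   semicontinuous-zero-inflated two-part: logistic zero indicator +
#                                linear regression on log of positives
#   binary                       logistic regression
#   categorical / ordinal-count  multinomial logistic regression (ridge)

# Upper-triangular factor of a (near-)PSD covariance: symmetrize and floor
# the eigenvalues so rare-category information matrices cannot break chol().
chol_psd <- function(V) {
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(V, symmetric = TRUE)
  floor_ <- max(e$values, 0) * 1e-10 + 1e-12
  vals <- pmax(e$values, floor_)
  chol(e$vectors %*% (vals * t(e$vectors)))
}

# Gaussian fit by QR with rank handling; stores what parameter draws need.
fit_gaussian_part <- function(X, y) {
  qrx <- qr(X)
  rank <- qrx$rank
  keep <- qrx$pivot[seq_len(rank)]
  if (rank < ncol(X)) {
    X <- X[, keep, drop = FALSE]
    qrx <- qr(X)
  }
  coef <- qr.coef(qrx, y)
  res <- y - drop(X %*% coef)
  df <- max(nrow(X) - rank, 1L)
  sigma2 <- sum(res^2) / df
  V <- chol2inv(qr.R(qrx))
  list(coef = coef, chol_V = chol_psd(V), sigma2 = sigma2,
       df = df, keep = keep, p = ncol(X))
}

# Logistic regression by IRLS; on separation/divergence refits with a small
# ridge penalty (penalised information matrix supplies the covariance).
fit_logistic_part <- function(X, y, ridge = 1e-2) {
  fit <- irls_logistic(X, y, lambda = 0)
  if (!fit$ok) fit <- irls_logistic(X, y, lambda = ridge)
  if (!fit$ok) {
    stop_(paste0("logistic fit did not converge even with ridge penalty; ",
                 "increase the penalty or pool sparse categories"))
  }
  list(coef = fit$coef, chol_V = chol_psd(fit$V),
       penalized = fit$lambda > 0)
}

irls_logistic <- function(X, y, lambda = 0, maxit = 100L, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0  # never penalise the intercept
  ok <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- tryCatch(solve(H, XtW %*% z), error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { ok <- TRUE; break }
  }
  if (ok && max(abs(beta)) > 15 && lambda == 0) ok <- FALSE  # separation
  V <- tryCatch(solve(t(X * pmax(stats::plogis(drop(X %*% beta)) *
                                   (1 - stats::plogis(drop(X %*% beta))),
                                 1e-10)) %*% X + pen),
                error = function(e) NULL)
  if (is.null(V)) ok <- FALSE
  list(coef = beta, V = V, ok = ok, lambda = lambda)
}

# Multinomial logistic via nnet::multinom with a small weight-decay ridge;
# coefficient vector and covariance are stored equation-major, matching
# nnet's vcov ordering.
fit_multinom_part <- function(X, y, levels, decay = 1e-4) {
  yf <- factor(y, levels = levels)
  df <- as.data.frame(X[, -1L, drop = FALSE])
  names(df) <- make.names(colnames(X)[-1L])
  df$.y <- yf
  fit <- nnet::multinom(.y ~ ., data = df, Hess = TRUE, trace = FALSE,
                        maxit = 500, decay = decay, MaxNWts = 5000)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)  # two-level case
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V)) {
    fit <- nnet::multinom(.y ~ ., data = df, Hess = TRUE, trace = FALSE,
                          maxit = 500, decay = max(decay, 1e-2),
                          MaxNWts = 5000)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)
    V <- stats::vcov(fit)
  }
  list(coef_mat = cf,                       # (K-1) x p, intercept first
       coef_vec = as.vector(t(cf)),         # equation-major
       chol_V = chol_psd(V),
       k = length(levels))
}

#' Fit the conditional imputation models
#'
#' Fits one conditional model per schema variable, regressing it on all
#' other schema variables (categoricals reference-coded, semicontinuous
#' predictors encoded as a positivity indicator plus log of positives).
#' Each model is fitted on the cohort rows where its target is observed, so
#' a cohort that already carries missingness can be used directly.
#'
#' @param cohort a `reference_cohort`.
#' @param schema a [risk_schema()]; defaults to the cohort's own schema.
#' @param ridge ridge penalty used when a logistic fit separates, and the
#'   weight decay of the multinomial fits.
#' @return an object of class `imputation_models`.
#' @export
fit_conditional_models <- function(cohort, schema = cohort$schema,
                                   ridge = 1e-2) {
  data <- cohort$data
  n <- nrow(data)
  models <- list()
  for (nm in schema_names(schema)) {
    spec <- schema$variables[[nm]]
    obs <- !is.na(data[[nm]])
    rows <- data[obs, , drop = FALSE]
    # predictors may themselves be missing on these rows; the chained engine
    # only ever predicts from completed rows, but fitting needs complete
    # predictor rows too
    preds <- setdiff(schema_names(schema), nm)
    if (length(preds)) {
      cc <- stats::complete.cases(rows[, preds, drop = FALSE])
      rows <- rows[cc, , drop = FALSE]
    }
    X <- build_design(rows, schema, nm)
    if (nrow(X) < 10 * ncol(X)) {
      stop_("only %d complete rows for '%s' but %d predictors; need >= %d",
            nrow(X), nm, ncol(X), 10 * ncol(X))
    }
    y <- rows[[nm]]
    m <- list(name = nm, kind = spec$kind, transform = spec$transform,
              levels = spec$levels,
              design = colnames(X))
    if (spec$kind %in% c("categorical", "ordinal-count", "binary")) {
      observed_levels <- if (spec$kind == "binary") {
        as.character(sort(unique(y)))
      } else {
        unique(y)
      }
      declared <- if (spec$kind == "binary") c("0", "1") else spec$levels
      absent <- setdiff(declared, observed_levels)
      if (length(absent)) {
        stop_("level(s) %s of '%s' absent from the training data",
              paste(sQuote(absent), collapse = ", "), nm)
      }
    }
    m$fit <- switch(spec$kind,
      "continuous" = fit_gaussian_part(X, y),
      "continuous-positive" = fit_gaussian_part(
        X, if (spec$transform == "log") log(y) else y),
      "binary" = fit_logistic_part(X, y, ridge),
      "semicontinuous-zero-inflated" = {
        pos <- y > 0
        list(zero = fit_logistic_part(X, as.numeric(y == 0), ridge),
             pos = fit_gaussian_part(X[pos, , drop = FALSE], log(y[pos])))
      },
      "categorical" = ,
      "ordinal-count" = fit_multinom_part(X, y, spec$levels,
                                          decay = max(ridge * 1e-2, 1e-4))
    )
    pool <- data[[nm]][obs]
    if (length(pool) > 5000L) pool <- pool[seq(1L, length(pool),
                                               length.out = 5000L)]
    m$marginal_pool <- pool
    models[[nm]] <- m
  }
  structure(
    list(models = models, visit_order = schema_names(schema), schema = schema,
         provenance = list(
           n = n,
           cohort_hash = config_hash(paste(dim(data), collapse = "x")),
           ridge = ridge)),
    class = "imputation_models"
  )
}

#' @export
print.imputation_models <- function(x, ...) {
  cat(sprintf("imputation_models: %d conditional models (cohort n=%d)\n",
              length(x$models), x$provenance$n))
  for (m in x$models) cat(sprintf("  %-12s %s\n", m$name, m$kind))
  invisible(x)
}
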