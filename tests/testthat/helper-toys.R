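# Shared fixtures: all built in code, no stored data.

# Wrap a data.frame as a reference cohort without going through the
# generator (used for deterministic, exact-frequency toy cohorts).
make_cohort <- function(data, schema) {
  structure(list(data = data, schema = schema,
                 provenance = list(generator = "handmade")),
            class = "reference_cohort")
}

# Schema of p independent-by-default standard-normal continuous variables.
gaussian_schema <- function(p = 4) {
  vars <- lapply(seq_len(p), function(i) {
    variable_spec(paste0("x", i), "continuous", "QRF", risk_effect = 0,
                  center = 0, scale = 1, margin = list(mean = 0, sd = 1))
  })
  risk_schema(vars)
}

# Constant-hazard population model over ages 20-80 (mortality optional),
# calibration identity.
constant_pop <- function(lambda, mu = 0) {
  ages <- 20:80
  population_model(ages, rep(lambda, length(ages)), rep(mu, length(ages)),
                   pv_frequencies = c(none = 1))
}

# ---------------------------------------------------------------------------
# Two-binary-factor toy with exactly known joint law and closed-form risks.
#
# Joint law (set by exact cohort counts, n = 4000):
#   P(b1=0,b2=0)=0.4875  P(0,1)=0.1625  P(1,0)=0.0525  P(1,1)=0.2975
# so P(b1=1)=0.35, P(b2=1|b1=1)=0.85, P(b2=1|b1=0)=0.25.
# Risk function via constant hazard lambda0 with multiplicative RRs chosen so
#   r(0,0)=0.010, r(0,1)=0.020, r(1,0)=0.050 over a 10-year horizon (mu=0);
#   r(1,1) follows from multiplicativity: 1-(1-.01)^(RR1*RR2) = 0.09797.
# All conditional mean risks sit several inner-Monte-Carlo standard errors
# away from the 3%/8% category cut-points, so stage classifications are
# stable.  Both conditionals are saturated logistic models, so the fitted
# chained equations reproduce the empirical (= exact) law.
toy2_setup <- function() {
  lambda0 <- -log(1 - 0.010) / 10
  rr1 <- log(1 - 0.050) / log(1 - 0.010)   # 5.1036
  rr2 <- log(1 - 0.020) / log(1 - 0.010)   # 2.0101
  schema <- risk_schema(list(
    variable_spec("b1", "binary", "QRF", risk_effect = log(rr1),
                  margin = list(p = 0.35)),
    variable_spec("b2", "binary", "MD", risk_effect = log(rr2),
                  margin = list(p = 0.46))
  ))
  counts <- c("00" = 1950, "01" = 650, "10" = 210, "11" = 1190)
  data <- data.frame(
    b1 = rep(c(0L, 0L, 1L, 1L), counts),
    b2 = rep(c(0L, 1L, 0L, 1L), counts)
  )
  risks <- c("00" = 0.010, "01" = 0.020, "10" = 0.050,
             "11" = 1 - (1 - 0.010)^(rr1 * rr2))
  list(schema = schema, cohort = make_cohort(data, schema),
       pop = constant_pop(lambda0), risks = risks,
       joint = counts / sum(counts))
}

# Exact enumeration for the toy: distribution of risk given observed pattern.
# `obs` is a named list of observed values (b1 and/or b2), NULL = marginal.
toy2_enum <- function(toy, obs = list()) {
  cells <- expand.grid(b1 = 0:1, b2 = 0:1)
  key <- paste0(cells$b1, cells$b2)
  p <- toy$joint[key]
  keep <- rep(TRUE, 4L)
  for (nm in names(obs)) keep <- keep & cells[[nm]] == obs[[nm]]
  p <- ifelse(keep, p, 0)
  p <- p / sum(p)
  data.frame(b1 = cells$b1, b2 = cells$b2, prob = as.numeric(p),
             risk = as.numeric(toy$risks[key]))
}

# ---------------------------------------------------------------------------
# Three-binary-variable log-linear system with NO three-way interaction, so
# the full conditionals are exactly main-effects logistic.  Models are built
# by hand with zero parameter-draw covariance to isolate the Gibbs sampler.
toy3_params <- function() {
  list(a = c(-0.3, 0.2, -0.5), c12 = 0.8, c13 = 0.4, c23 = -0.6)
}

toy3_joint <- function() {
  p <- toy3_params()
  cells <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  logw <- p$a[1] * cells$b1 + p$a[2] * cells$b2 + p$a[3] * cells$b3 +
    p$c12 * cells$b1 * cells$b2 + p$c13 * cells$b1 * cells$b3 +
    p$c23 * cells$b2 * cells$b3
  cells$prob <- exp(logw) / sum(exp(logw))
  cells
}

# Hand-built binary conditional model with fixed (no-draw) coefficients.
fixed_logistic_model <- function(name, coef) {
  p <- length(coef)
  list(name = name, kind = "binary", transform = "identity", levels = NULL,
       fit = list(coef = coef, chol_V = matrix(0, p, p)),
       marginal_pool = c(0L, 1L))
}

toy3_models <- function() {
  p <- toy3_params()
  schema <- risk_schema(list(
    variable_spec("b1", "binary", "QRF", risk_effect = 0, margin = list(p = .5)),
    variable_spec("b2", "binary", "QRF", risk_effect = 0, margin = list(p = .5)),
    variable_spec("b3", "binary", "QRF", risk_effect = 0, margin = list(p = .5))
  ))
  # full conditionals of the log-linear joint; design order is
  # (Intercept), then the other two variables in schema order
  models <- list(
    b1 = fixed_logistic_model("b1", c(p$a[1], p$c12, p$c13)),
    b2 = fixed_logistic_model("b2", c(p$a[2], p$c12, p$c23)),
    b3 = fixed_logistic_model("b3", c(p$a[3], p$c13, p$c23))
  )
  structure(list(models = models, visit_order = names(models),
                 schema = schema, provenance = list(n = NA)),
            class = "imputation_models")
}

# Default-model pipeline fixture (schema, population, fitted models,
# calibrated population), sized for unit tests.
default_fixture <- function(n = 5000, seed = 421) {
  schema <- default_schema()
  pop <- default_population()
  cohort <- simulate_cohort(schema, pop, n, seed = seed)
  models <- fit_conditional_models(cohort)
  pop_cal <- calibrate_baseline(pop, schema, cohort)
  list(schema = schema, pop = pop_cal, cohort = cohort, models = models)
}
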