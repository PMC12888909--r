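test_that("intercept-only zero part recovers logit of the zero fraction", {
  # 40% zeros, no informative predictors: single-variable schema
  sch <- risk_schema(list(
    variable_spec("alcohol", "semicontinuous-zero-inflated", "QRF",
                  risk_effect = c(positive = 0, per_sd = 0),
                  transform = "log", center = 0, scale = 1,
                  margin = list(p_zero = 0.4, meanlog = 0, sdlog = 1))
  ))
  vals <- c(rep(0, 200), exp(rnorm(300)))
  co <- make_cohort(data.frame(alcohol = vals), sch)
  mods <- fit_conditional_models(co)
  intercept <- mods$models$alcohol$fit$zero$coef[[1]]
  se <- 1 / sqrt(500 * 0.4 * 0.6)
  expect_lt(abs(intercept - qlogis(0.4)), 3 * se)
})

test_that("linear conditional recovers a known regression slope", {
  sch <- gaussian_schema(2)
  set.seed(71)
  x1 <- rnorm(3000)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(3000)
  co <- make_cohort(data.frame(x1 = x1, x2 = x2), sch)
  mods <- fit_conditional_models(co)
  slope <- mods$models$x2$fit$coef[["x1"]]
  se <- sqrt(1 - 0.64) / sqrt(3000)
  expect_lt(abs(slope - 0.8), 3 * se)
})

test_that("the PV conditional is a multinomial with 8 non-reference equations", {
  fx <- default_fixture(n = 5000, seed = 421)
  cf <- fx$models$models$pv$fit$coef_mat
  expect_identical(nrow(cf), 8L)
  expect_identical(ncol(cf), length(fx$models$models$pv$design))
})

test_that("chained imputation reproduces the Gaussian conditional law", {
  sch <- gaussian_schema(2)
  dep <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x1", "x2"),
                                                      c("x1", "x2")))
  pop <- constant_pop(0.001)
  co <- simulate_cohort(sch, pop, 5000, dependence = dep, seed = 17)
  mods <- fit_conditional_models(co)

  x_obs <- 1.0
  prof <- individual_profile(40, list(x1 = x_obs, x2 = NA), schema = sch)
  cps <- chained_impute(prof, mods, M = 10000, seed = 18)
  y <- cps$data$x2

  # closed-form conditional from the cohort's empirical moments
  m <- colMeans(co$data); S <- cov(co$data)
  mu_c <- m[["x2"]] + S[1, 2] / S[1, 1] * (x_obs - m[["x1"]])
  v_c <- S[2, 2] - S[1, 2]^2 / S[1, 1]
  expect_lt(abs(mean(y) - mu_c), 3 * sd(y) / sqrt(10000))
  expect_lt(abs(var(y) - v_c) / v_c, 0.10)
})

test_that("Gibbs draws match exact conditionals on the discrete toy (enumeration)", {
  mods <- toy3_models()
  prof <- individual_profile(40, list(b1 = 1, b2 = NA, b3 = NA),
                             schema = mods$schema)
  cps <- chained_impute(prof, mods, M = 20000, n_iter = 20, seed = 29)

  joint <- toy3_joint()
  cond <- joint[joint$b1 == 1, ]
  cond$prob <- cond$prob / sum(cond$prob)
  for (i in seq_len(nrow(cond))) {
    p <- cond$prob[i]
    got <- mean(cps$data$b2 == cond$b2[i] & cps$data$b3 == cond$b3[i])
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("observed entries are immutable and full profiles pass through", {
  fx <- default_fixture(n = 5000, seed = 421)
  prof <- individual_profile(40, list(bmi = 27, fh = "1", pv = "none"),
                             schema = fx$schema)
  cps <- chained_impute(prof, fx$models, M = 200, seed = 3)
  expect_true(all(cps$data$bmi == 27))
  expect_true(all(cps$data$fh == "1"))
  expect_true(all(cps$data$pv == "none"))
  expect_false(anyNA(cps$data))
  # domains respected in the draws
  expect_true(all(cps$data$md > 0))
  expect_true(all(cps$data$alcohol >= 0))

  full_vals <- as.list(fx$cohort$data[1, ])
  full <- individual_profile(40, full_vals, schema = fx$schema)
  cps2 <- chained_impute(full, fx$models, M = 50, seed = 4)
  expect_true(all(vapply(seq_len(50), function(i)
    identical(as.list(cps2$data[i, ]), full_vals), logical(1))))

  expect_error(chained_impute(prof, fx$models, M = 0, seed = 1), "M must be")
})

test_that("imputation is byte-identical under a fixed seed", {
  fx <- default_fixture(n = 5000, seed = 421)
  prof <- individual_profile(40, list(fh = "2+"), schema = fx$schema)
  a <- chained_impute(prof, fx$models, M = 100, seed = 77)
  b <- chained_impute(prof, fx$models, M = 100, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$traces, b$traces)
})

test_that("gelman_rubin matches its formula and handles degeneracies", {
  # identical chains: floor sqrt((n-1)/n)
  ch <- rbind(rnorm(100), rnorm(100))
  ch[2, ] <- ch[1, ]
  expect_equal(gelman_rubin(ch), sqrt(99 / 100))

  # shifted chains: direct spreadsheet-style evaluation as oracle
  set.seed(5)
  c1 <- rnorm(100, 0, 1); c2 <- rnorm(100, 10, 1)
  got <- gelman_rubin(rbind(c1, c2))
  W <- (var(c1) + var(c2)) / 2
  B <- 100 * var(c(mean(c1), mean(c2)))
  expect_equal(got, sqrt(((99 / 100) * W + B / 100) / W))

  # degenerate cases
  expect_identical(gelman_rubin(rbind(rep(1, 10), rep(2, 10))), Inf)
  expect_identical(gelman_rubin(rbind(rep(1, 10), rep(1, 10))), 1)
  expect_error(gelman_rubin(matrix(1, 1, 10)), "chains")
})

test_that("well-mixed chains on the Gaussian toy converge (R-hat < 1.1)", {
  sch <- gaussian_schema(2)
  dep <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x1", "x2"),
                                                      c("x1", "x2")))
  co <- simulate_cohort(sch, constant_pop(0.001), 3000, dependence = dep,
                        seed = 21)
  mods <- fit_conditional_models(co)
  prof <- individual_profile(40, list(x1 = 0.5, x2 = NA), schema = sch)
  rep_ <- convergence_report(chained_impute(prof, mods, M = 2000,
                                            n_iter = 10, seed = 22))
  expect_true(all(rep_$rhat < 1.1))
})

test_that("observed-vs-imputed comparison behaves under MCAR and MAR", {
  sch <- gaussian_schema(2)
  dep <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x1", "x2"),
                                                      c("x1", "x2")))
  pop <- constant_pop(0.001)
  co <- simulate_cohort(sch, pop, 8000, dependence = dep, seed = 31)
  truth <- co$data$x2

  # MCAR: observed and imputed distributions agree (KS below 1% critical)
  mc <- apply_missingness(co, "MCAR", rates = c(x2 = 0.4), seed = 32)
  mods <- fit_conditional_models(mc)
  chk <- compare_observed_imputed(mc, mods, seed = 33)
  n1 <- sum(!is.na(mc$data$x2)); n2 <- sum(is.na(mc$data$x2))
  crit <- 1.628 * sqrt((n1 + n2) / (n1 * n2))
  expect_lt(chk$checks$x2$ks_statistic, crit)

  # fully observed variable is skipped with a warning
  expect_warning(compare_observed_imputed(mc, mods, variables = "x1",
                                          seed = 34),
                 "skipped")

  # MAR driven by x1: observed and imputed means differ, but the imputed
  # mean matches the suppressed truth (truth-holdout oracle)
  mar <- apply_missingness(co, "MAR", rates = c(x2 = 0.35), drivers = "x1",
                           slopes = c(x1 = 1.5), seed = 35)
  mods_mar <- fit_conditional_models(mar)
  chk_mar <- compare_observed_imputed(mar, mods_mar, seed = 36)$checks$x2
  expect_gt(abs(chk_mar$mean_observed - chk_mar$mean_imputed), 0.1)
  miss <- is.na(mar$data$x2)
  se <- sqrt(var(truth[miss]) * 2 / sum(miss))
  expect_lt(abs(chk_mar$mean_imputed - mean(truth[miss])), 3 * se)
})
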