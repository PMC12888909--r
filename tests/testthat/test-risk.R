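schema <- default_schema()

# a profile sitting exactly at every reference value
reference_profile <- function(age = 40) {
  individual_profile(age, list(
    bmi = exp(3.25), alcohol = 0, menarche_age = 13, parity = "0",
    hrt_use = 0, oc_use = 0, md = exp(3.0), pgs = 0, pv = "none", fh = "0"
  ), schema = schema)
}

test_that("relative risk is 1 at reference and exponential in single terms", {
  expect_equal(relative_risk(reference_profile(), schema), 1.0)

  p <- reference_profile()
  p$values$pgs <- 1
  expect_equal(relative_risk(p, schema), 1.6)

  p <- reference_profile()
  p$values$pv <- "BRCA1"
  expect_equal(relative_risk(p, schema), 10)
})

test_that("relative risk of an arbitrary profile equals the term product", {
  p <- reference_profile()
  p$values <- list(bmi = 31, alcohol = 12, menarche_age = 11, parity = "2",
                   hrt_use = 1, oc_use = 1, md = 42, pgs = 1.7,
                   pv = "CHEK2", fh = "1")
  # independent term-by-term oracle
  oracle <- exp(log(1.10) * (log(31) - 3.25) / 0.18) *
    exp(log(1.05) + log(1.08) * (log(12) - 1.8) / 0.8) *
    exp(log(0.95) * (11 - 13) / 1.5) *
    0.88 * 1.3 * 1.1 *
    exp(log(1.30) * (log(42) - 3.0) / 0.5) *
    exp(log(1.6) * 1.7) *
    2.5 * 1.8
  expect_equal(relative_risk(p, schema), oracle)
})

test_that("log-additivity: joint profile equals product of single deviations", {
  single <- function(var, val) {
    p <- reference_profile()
    p$values[[var]] <- val
    relative_risk(p, schema)
  }
  joint <- reference_profile()
  joint$values$pgs <- 0.8
  joint$values$md <- 35
  joint$values$fh <- "2+"
  expect_equal(relative_risk(joint, schema),
               single("pgs", 0.8) * single("md", 35) * single("fh", "2+"))
})

test_that("missing entries are refused with a pointer to the uncertainty path", {
  p <- reference_profile()
  p$values$pgs <- NA
  expect_error(relative_risk(p, schema), "uncertainty")
})

test_that("calibration reproduces the population incidence", {
  pop <- default_population()

  # identical all-reference individuals: constant must be 1
  ref_row <- as.data.frame(reference_profile()$values[names(schema$variables)])
  coh <- make_cohort(ref_row[rep(1, 50), ], schema)
  cal <- calibrate_baseline(pop, schema, coh)
  expect_equal(unique(cal$calibration), 1)

  # synthetic cohort: cohort-average hazard equals incidence to 1e-6 relative,
  # with the mean relative risk recomputed term-by-term as the oracle
  co <- simulate_cohort(schema, pop, 5000, seed = 99)
  cal <- calibrate_baseline(pop, schema, co)
  i50 <- match(50L, cal$age_grid)
  mean_rr_oracle <- mean(exp(rowSums(vapply(
    names(schema$variables),
    function(v) {
      pr <- co$data
      spec <- schema$variables[[v]]
      x <- pr[[v]]
      if (spec$kind == "continuous") {
        spec$risk_effect * (x - spec$center) / spec$scale
      } else if (spec$kind == "continuous-positive") {
        spec$risk_effect * (log(x) - spec$center) / spec$scale
      } else if (spec$kind == "semicontinuous-zero-inflated") {
        ifelse(x > 0, spec$risk_effect[["positive"]] +
                 spec$risk_effect[["per_sd"]] * (log(x) - spec$center) / spec$scale, 0)
      } else if (spec$kind == "binary") {
        spec$risk_effect * x
      } else {
        unname(spec$risk_effect[match(x, spec$levels)])
      }
    }, numeric(nrow(co$data))))))
  mean_hazard <- mean_rr_oracle * cal$incidence[i50] / cal$calibration[i50]
  expect_lt(abs(mean_hazard - cal$incidence[i50]) / cal$incidence[i50], 1e-6)

  expect_error(calibrate_baseline(pop, schema, make_cohort(ref_row[0, ], schema)),
               "empty")
})

test_that("absolute risk reproduces constant-hazard closed forms", {
  prof <- reference_profile(40)

  pop0 <- constant_pop(0.001, mu = 0)
  expect_equal(absolute_risk(prof, pop0, schema), 1 - exp(-0.01),
               tolerance = 1e-12)

  popm <- constant_pop(0.002, mu = 0.010)
  closed <- 0.002 / 0.012 * (1 - exp(-0.12))
  expect_equal(absolute_risk(prof, popm, schema), closed, tolerance = 1e-10)
})

test_that("age-varying hazards match a month-grid integration oracle", {
  pop <- default_population()
  pop$calibration <- rep(1, length(pop$age_grid))
  prof <- reference_profile(40)
  got <- absolute_risk(prof, pop, schema)

  # oracle: month-by-month survival product with piecewise-constant hazards
  risk <- 0; surv <- 1
  for (t in 0:9) {
    i <- match(40L + t, pop$age_grid)
    lam <- pop$incidence[i] / 12; mu <- pop$mortality[i] / 12
    for (m in 1:12) {
      risk <- risk + surv * lam / (lam + mu) * (1 - exp(-(lam + mu)))
      surv <- surv * exp(-(lam + mu))
    }
  }
  expect_lt(abs(got - risk) / risk, 0.005)
})

test_that("absolute risk is monotone, bounded, and handles edge cases", {
  pop <- default_population()
  co <- simulate_cohort(schema, pop, 2000, seed = 5)
  pop <- calibrate_baseline(pop, schema, co)

  prof <- reference_profile(40)
  risks <- vapply(0:20, function(h) {
    p <- prof; p$horizon <- h
    absolute_risk(p, pop, schema)
  }, numeric(1))
  expect_equal(risks[1], 0)                       # horizon 0
  expect_true(all(diff(risks) >= 0))              # increasing in horizon
  expect_true(all(risks >= 0 & risks < 1))

  # strictly increasing in a single log-RR
  pgs_risk <- vapply(seq(-2, 2, 0.5), function(g) {
    p <- prof; p$values$pgs <- g
    absolute_risk(p, pop, schema)
  }, numeric(1))
  expect_true(all(diff(pgs_risk) > 0))

  p <- prof; p$age <- 95L
  expect_error(absolute_risk(p, pop, schema), "age")
})

test_that("NICE-band classification uses the documented boundary rule", {
  sc <- category_scheme()
  expect_identical(classify(0.025, sc), "near-population")
  expect_identical(classify(0.05, sc), "moderate")
  expect_identical(classify(0.09, sc), "high")
  # boundaries belong to the moderate band
  expect_identical(classify(c(0.03, 0.08), sc), c("moderate", "moderate"))
  expect_error(classify(1.2, sc), "0,1")
  expect_error(category_scheme(c(0.08, 0.03)), "increasing")
})
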