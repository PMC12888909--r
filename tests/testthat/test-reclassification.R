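# enumeration of the toy's stepwise stages (see helper-toys.R):
#  baseline: mean risk 0.0399 -> moderate with probability 1
#  +QRF (b1): b1=0 (p=0.65) -> near-population (mean 0.0125);
#             b1=1 (p=0.35) -> high (mean 0.0908)
#  +MD  (b2): final law = joint; np 0.65, moderate 0.0525, high 0.2975
toy_enum_final <- c(`near-population` = 0.65, moderate = 0.0525, high = 0.2975)

test_that("stepwise flow matches exact enumeration and conserves mass", {
  toy <- toy2_setup()
  mods <- fit_conditional_models(toy$cohort)
  prof <- individual_profile(40, list(b1 = NA, b2 = NA), schema = toy$schema)
  fl <- stepwise_measurement(prof, mods, toy$pop,
                             group_order = c("QRF", "MD"), M = 4000,
                             M_inner = 300, n_iter = 3, seed = 41)

  expect_identical(fl$stage_labels, c("baseline", "+QRF", "+MD"))
  expect_identical(fl$baseline_category, "moderate")
  expect_equal(unname(fl$membership["baseline", ]), c(0, 1, 0))

  # stage memberships vs enumeration (3 binomial SEs at M = 4000)
  stage1 <- c(0.65, 0, 0.35)
  for (k in 1:3) {
    expect_lt(abs(fl$membership["+QRF", k] - stage1[k]),
              3 * sqrt(max(stage1[k] * (1 - stage1[k]), 1e-4) / 4000))
    p <- unname(toy_enum_final[k])
    expect_lt(abs(fl$membership["+MD", k] - p),
              3 * sqrt(p * (1 - p) / 4000))
  }

  # exact mass conservation (bookkeeping identities, not statistical)
  expect_equal(unname(rowSums(fl$membership)), rep(1, 3))
  for (s in seq_along(fl$transitions)) {
    expect_equal(unname(rowSums(fl$transitions[[s]])),
                 unname(fl$membership[s, ]))
    expect_equal(unname(colSums(fl$transitions[[s]])),
                 unname(fl$membership[s + 1, ]))
  }

  # reclassification probability vs enumeration: 1 - P(end moderate) = 0.9475
  rp <- reclassification_probability(fl)
  expect_lt(abs(rp - 0.9475), 3 * sqrt(0.0525 * 0.9475 / 4000))
})

test_that("fully observed profiles never reclassify", {
  toy <- toy2_setup()
  mods <- fit_conditional_models(toy$cohort)
  prof <- individual_profile(40, list(b1 = 0, b2 = 0), schema = toy$schema)
  w <- capture_warnings(
    fl <- stepwise_measurement(prof, mods, toy$pop,
                               group_order = c("QRF", "MD"), M = 100,
                               M_inner = 20, seed = 6))
  expect_length(w, 2)
  expect_match(w, "skipped", all = TRUE)
  expect_identical(fl$stage_labels, "baseline")
  expect_equal(max(fl$membership), 1)
  expect_equal(reclassification_probability(fl), 0)
})

test_that("a group with nothing missing is skipped, the rest still runs", {
  toy <- toy2_setup()
  mods <- fit_conditional_models(toy$cohort)
  prof <- individual_profile(40, list(b1 = 1, b2 = NA), schema = toy$schema)
  expect_warning(
    fl <- stepwise_measurement(prof, mods, toy$pop,
                               group_order = c("QRF", "MD"), M = 500,
                               M_inner = 100, n_iter = 3, seed = 7),
    "QRF")
  expect_identical(fl$stage_labels, c("baseline", "+MD"))
})

test_that("final-stage memberships are order invariant (enumeration endpoint)", {
  toy <- toy2_setup()
  mods <- fit_conditional_models(toy$cohort)
  prof <- individual_profile(40, list(b1 = NA, b2 = NA), schema = toy$schema)
  fwd <- stepwise_measurement(prof, mods, toy$pop,
                              group_order = c("QRF", "MD"), M = 4000,
                              M_inner = 300, n_iter = 3, seed = 51)
  rev <- stepwise_measurement(prof, mods, toy$pop,
                              group_order = c("MD", "QRF"), M = 4000,
                              M_inner = 300, n_iter = 3, seed = 52)
  last_f <- fwd$membership[nrow(fwd$membership), ]
  last_r <- rev$membership[nrow(rev$membership), ]
  for (k in 1:3) {
    p <- unname(toy_enum_final[k])
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(last_f[k] - last_r[k]), 3 * sqrt(2) * se)
    expect_lt(abs(last_f[k] - p), 3 * se)
    expect_lt(abs(last_r[k] - p), 3 * se)
  }
  # intermediate stages legitimately differ between orders: MD-first stage 1
  # puts mass on moderate, QRF-first puts it on high
  expect_gt(rev$membership["+MD", "moderate"], 0.3)
  expect_lt(fwd$membership["+QRF", "moderate"], 0.05)
})

test_that("flow_table is tidy and consistent with the transition matrices", {
  toy <- toy2_setup()
  mods <- fit_conditional_models(toy$cohort)
  prof <- individual_profile(40, list(b1 = NA, b2 = NA), schema = toy$schema)
  fl <- stepwise_measurement(prof, mods, toy$pop,
                             group_order = c("QRF", "MD"), M = 500,
                             M_inner = 100, n_iter = 3, seed = 61)
  tab <- flow_table(fl)
  expect_named(tab, c("stage_from", "stage_to", "category_from",
                      "category_to", "proportion"))
  # per stage pair, proportions add to 1
  sums <- tapply(tab$proportion, tab$stage_from, sum)
  expect_equal(as.numeric(sums[fl$stage_labels[1:2]]), c(1, 1))
})
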