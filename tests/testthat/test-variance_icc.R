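# Variance components, ICC and agreement bands.

test_that("compute_icc evaluates the component ratio", {
  comp <- structure(list(sigma2_patient = 2, sigma2_observer = 1,
                         sigma2_patient_observer = 1, sigma2_patient_time = 1,
                         sigma2_observer_time = 0.5, sigma2_residual = 0.5,
                         time_effect = 0), class = "variance_components")
  expect_equal(compute_icc(comp), 3 / 6)
  comp0 <- comp
  for (nm in names(comp0)) comp0[[nm]] <- 0
  expect_equal(compute_icc(comp0), 0)  # all-zero convention
  only_obs <- comp0; only_obs$sigma2_observer <- 4
  expect_equal(compute_icc(only_obs), 0)
  only_pat <- comp0; only_pat$sigma2_patient <- 4
  expect_equal(compute_icc(only_pat), 1)
})

test_that("classify_icc reproduces the printed agreement bands", {
  expect_equal(classify_icc(0.27), "slight")
  expect_equal(classify_icc(0.32), "slight")
  expect_equal(classify_icc(0.60), "fair")
  expect_equal(classify_icc(0.61), "moderate")
  expect_equal(classify_icc(0.65), "moderate")
  expect_equal(classify_icc(0.83), "substantial")
  expect_equal(classify_icc(0.86), "substantial")
  expect_equal(classify_icc(0.10), "virtually none")
  expect_equal(classify_icc(0.105), "slight")  # between printed endpoints
  expect_equal(classify_icc(0), "virtually none")
  expect_equal(classify_icc(1), "substantial")
  expect_error(classify_icc(1.2), "\\[0, 1\\]")
  expect_error(classify_icc(-0.1), "\\[0, 1\\]")
})

test_that("fit_components recovers a pure patient effect and degenerate data", {
  rec <- sim_anova_records(n_pat = 6, n_obs = 5, sd_p = 0, sd_o = 0, sd_res = 0)
  rec$volume <- c(10, 20, 30, 12, 22, 32)[as.integer(factor(rec$patient_id))]
  fc <- fit_components(rec, "sim")
  pm <- tapply(rec$volume, rec$patient_id, mean)
  expect_equal(fc$sigma2_patient, var(pm), tolerance = 1e-4)
  expect_lt(fc$sigma2_observer + fc$sigma2_patient_observer +
              fc$sigma2_observer_time + fc$sigma2_residual, 1e-4 * var(pm))
  expect_equal(compute_icc(fc), 1, tolerance = 1e-6)

  rec$volume <- 10
  fc0 <- fit_components(rec, "sim")
  expect_equal(compute_icc(fc0), 0)

  one_level <- rec[rec$scan_time == "plan", ]
  expect_error(fit_components(one_level, "sim"), "2 levels of scan_time")
})

test_that("REML equals the EMS method-of-moments oracle on balanced designs", {
  set.seed(202)
  n_checked <- 0
  for (rep in 1:6) {
    rec <- sim_anova_records(sd_p = 3, sd_o = 1.5, sd_po = 1.2, sd_pt = 1.4,
                             sd_ot = 1.1, sd_res = 1, time_effect = 0.8)
    oracle <- ems_oracle(rec)
    if (any(oracle <= 0)) next  # oracle interior only
    n_checked <- n_checked + 1
    fc <- fit_components(rec, "sim")
    est <- c(fc$sigma2_patient, fc$sigma2_observer, fc$sigma2_patient_observer,
             fc$sigma2_patient_time, fc$sigma2_observer_time, fc$sigma2_residual)
    expect_equal(est, unname(oracle), tolerance = 1e-6)
  }
  expect_gte(n_checked, 3)
})

test_that("unbalanced designs (excluded patient) agree with the lme4 oracle", {
  set.seed(77)
  rec <- sim_anova_records(sd_p = 3, sd_o = 1, sd_po = 0.6, sd_pt = 0.7,
                           sd_ot = 0.4, sd_res = 0.5, time_effect = 0.5)
  rec <- rec[rec$patient_id != "P4", ]  # the excluded-organ analogue
  fc <- fit_components(rec, "sim")
  lfit <- suppressMessages(suppressWarnings(lme4::lmer(
    volume ~ scan_time + (1 | patient_id) + (1 | observer_id) +
      (1 | patient_id:observer_id) + (1 | patient_id:scan_time) +
      (1 | observer_id:scan_time), data = rec, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                optCtrl = list(rhoend = 1e-10),
                                check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(lfit))
  v <- setNames(vc$vcov, vc$grp)
  expect_equal(fc$sigma2_patient, unname(v["patient_id"]), tolerance = 1e-4)
  expect_equal(fc$sigma2_residual, unname(v["Residual"]), tolerance = 1e-4)
  expect_equal(fc$time_effect, unname(lme4::fixef(lfit)["scan_timerep"]),
               tolerance = 1e-6)
})

test_that("property: ICC is invariant under shift/scale and monotone in observer variance", {
  set.seed(55)
  rec <- sim_anova_records(sd_p = 2.5, sd_o = 1, sd_res = 0.8)
  icc <- compute_icc(fit_components(rec, "sim"))
  rec2 <- rec; rec2$volume <- 5 + 3 * rec2$volume
  expect_equal(compute_icc(fit_components(rec2, "sim")), icc, tolerance = 1e-6)

  base <- structure(list(sigma2_patient = 2, sigma2_observer = 0.5,
                         sigma2_patient_observer = 0.3, sigma2_patient_time = 0.2,
                         sigma2_observer_time = 0.1, sigma2_residual = 0.4,
                         time_effect = 0), class = "variance_components")
  iccs <- vapply(seq(0, 5, by = 0.5), function(s2o) {
    b <- base; b$sigma2_observer <- s2o; compute_icc(b)
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("property: parameter recovery on the 3-point injected grid", {
  set.seed(808)
  # injected ICCs 0.82 / 0.44 / 0.29 span the clinically reported range
  grid <- list(c(sd_p = 3, sd_o = 1, sd_res = 1),
               c(sd_p = 2, sd_o = 2, sd_res = 1),
               c(sd_p = 1.2, sd_o = 1.6, sd_res = 1))
  for (gpt in grid) {
    inj_icc <- gpt["sd_p"]^2 /
      (gpt["sd_p"]^2 + gpt["sd_o"]^2 + gpt["sd_res"]^2)
    est <- replicate(17, {
      rec <- sim_anova_records(sd_p = gpt["sd_p"], sd_o = gpt["sd_o"],
                               sd_res = gpt["sd_res"])
      compute_icc(fit_components(rec, "sim"))
    })
    expect_lt(abs(mean(est) - inj_icc), 0.1)
  }
})
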