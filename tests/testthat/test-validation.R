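test_that("profile refitting recovers the generating parameters within 3 SE", {
  prof <- make_hospital_profile(list(annual_admissions = 10000))
  co <- synthesize_cohort(prof, years = 1, seed = 12)
  fit <- fit_profile_from_records(co, years = 1)
  info <- fit$fit_info
  expect_lt(abs(fit$p_onset_known - 0.60), 3 * info$se_p_onset_known)
  expect_lt(abs(info$ota$meanlog - log(95)), 3 * info$ota$se_meanlog)
  expect_lt(abs(info$a2s$meanlog - log(25)), 3 * info$a2s$se_meanlog)
  expect_lt(abs(info$s2n$meanlog - log(30)), 3 * info$s2n$se_meanlog)
  n_known <- sum(co$onset_known)
  expect_lt(abs(fit$p_arrive_within_4h - 0.58),
            3 * sqrt(0.58 * 0.42 / n_known))
  # binomial error plus the decision-rule calibration allowance (0.005)
  expect_lt(abs(fit$p_eligible - 0.40),
            3 * sqrt(0.4 * 0.6 / info$n_considered) + 0.005)
  expect_equal(round(fit$annual_admissions), 10000)
})

test_that("degenerate cohorts fit to the expected limits", {
  all_known <- synthesize_cohort(make_hospital_profile(list(
    p_onset_known = 1, annual_admissions = 300)), years = 1, seed = 2)
  expect_equal(fit_profile_from_records(all_known)$p_onset_known, 1)

  none_treated <- synthesize_cohort(make_hospital_profile(list(
    p_eligible = 0, annual_admissions = 300)), years = 1, seed = 2)
  fit0 <- fit_profile_from_records(none_treated)
  expect_equal(fit0$p_eligible, 0)
  expect_error(fit_profile_from_records(none_treated[1:10, ]), "at least")
})

test_that("the fitted pathway model exposes the standard S3 surface", {
  co <- synthesize_cohort(make_hospital_profile(list(annual_admissions = 700)),
                          years = 1, seed = 9)
  fit <- fit_pathway_model(co, years = 1)
  expect_s3_class(fit, "pathway_fit")
  cf <- coef(fit)
  expect_named(cf, c("p_onset_known", "p_arrive_within_4h", "p_ischaemic",
                     "p_eligible", "onset_to_arrival_median",
                     "arrival_to_scan_median", "scan_to_needle_median"))
  expect_output(print(fit), "observed thrombolysis use")
  expect_output(summary(fit), "scan-to-needle")
  sims <- simulate(fit, nsim = 10, seed = 3)
  expect_equal(nrow(sims), 10)
  pred <- predict(fit, scen = standard_scenarios()$B, n_runs = 10, seed = 3)
  expect_s3_class(pred, "sim_result")
  expect_equal(pred$scenario, "B")
  multi <- synthesize_cohorts(reference_hospital_profiles()[1:2], years = 0.5,
                              seed = 2)
  expect_error(fit_pathway_model(multi), "several hospitals")
})

test_that("self-consistent cohorts are reproduced by the fitted simulator", {
  profs <- reference_hospital_profiles()[c("H1", "H4", "H7")]
  co <- synthesize_cohorts(profs, years = 2, seed = 18)
  hc <- hospital_comparison(co, n_runs = 40, years = 2, seed = 3)
  expect_equal(nrow(hc), 3)
  expect_true(abs(attr(hc, "prediction_ratio") - 1) < 0.1)
  expect_gte(sum(hc$within_replicate_interval), 2)
  # a single hospital in gives a single row out
  hc1 <- hospital_comparison(co[co$hospital_id == "H1", ], n_runs = 10,
                             years = 2, seed = 3)
  expect_equal(nrow(hc1), 1)
})

test_that("bootstrap validation is self-consistent and guards its strata", {
  co <- synthesize_cohorts(reference_hospital_profiles()[c("H1", "H4")],
                           years = 1, seed = 19)
  bv <- bootstrap_validation(co, n_samples = 12, sample_size = 600,
                             n_runs_per_sample = 10, seed = 4)
  expect_equal(nrow(bv$samples), 12)
  expect_true(all(bv$samples$predicted_pct >= 0 & bv$samples$predicted_pct <= 100))
  expect_lt(abs(bv$slope_origin - 1), 0.15)
  expect_gt(bv$r_squared, 0.9)
  untreated_only <- co[!co$thrombolysis_given, ]
  expect_error(bootstrap_validation(untreated_only), "both treated and untreated")
})

test_that("scenario reports cover the hospital-by-scenario grid in order", {
  profs <- reference_hospital_profiles()[c("H2", "H5")]
  rep5 <- scenario_report(profs, standard_scenarios(), n_runs = 30, seed = 6)
  expect_equal(nrow(rep5), 10)
  for (h in c("H2", "H5")) {
    r <- rep5[rep5$hospital_id == h, ]
    base <- r$thrombolysis_pct[r$scenario == "base"]
    abc <- r$thrombolysis_pct[r$scenario == "ABC"]
    expect_true(all(r$thrombolysis_pct[r$scenario %in% c("A", "B", "C")] >= base))
    expect_true(all(r$thrombolysis_pct[r$scenario %in% c("A", "B", "C")] <= abc))
  }
  # empty scenario list falls back to base only
  rep0 <- scenario_report(profs, list(), n_runs = 5, seed = 6)
  expect_equal(unique(rep0$scenario), "base")
  expect_equal(nrow(rep0), 2)
  # the benchmark-driven scenario demands a trained benchmark rate
  expect_error(scenario_report(profs, list(alternative_scenario()), n_runs = 5),
               "benchmark")
  alt <- scenario_report(profs, list(alternative_scenario()), n_runs = 5,
                         seed = 6,
                         benchmark_p_eligible = c(H2 = 0.5, H5 = 0.5))
  expect_equal(nrow(alt), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenario_csv(rep5, path)
  expect_equal(nrow(utils::read.csv(path)), 10)
})
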