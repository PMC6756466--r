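test_that("treatment window is 4.5 h under 80 and 3 h at 80 and over", {
  expect_equal(treatment_window_min(79), 270)
  expect_equal(treatment_window_min(80), 180)
  expect_equal(treatment_window_min(100), 180)
  expect_equal(treatment_window_min(c(50, 90)), c(270, 180))
  expect_error(treatment_window_min(0), "positive")
})

test_that("degenerate pathways reduce to window arithmetic", {
  # 30 + 15 + 15 = 60 min, well inside any window
  d <- sample_pathway(degenerate_profile(age_mean = 70), n = 50, seed = 1)
  expect_true(all(d$treated))
  expect_true(all(d$onset_to_treatment_min == 60))
  # 170 + 15 + 15 = 200 min > 180 min window at age 80
  d2 <- sample_pathway(degenerate_profile(ota = 170, age_mean = 80), n = 50, seed = 1)
  expect_false(any(d2$treated))
  # same times at age 70: 200 <= 270, treated
  d3 <- sample_pathway(degenerate_profile(ota = 170, age_mean = 70), n = 50, seed = 1)
  expect_true(all(d3$treated))
  # 200 + 30 + 50 = 280 > 270: scanned with 40 min left but needle too slow
  d4 <- sample_pathway(degenerate_profile(ota = 200, a2s = 30, s2n = 50,
                                          age_mean = 70), n = 50, seed = 1)
  expect_true(all(d4$considered))
  expect_false(any(d4$treated))
  # closed first gate blocks everything
  p0 <- make_hospital_profile(list(p_onset_known = 0))
  expect_false(any(sample_pathway(p0, n = 200, seed = 1)$treated))
})

test_that("scenarios override profiles as specified", {
  p <- make_hospital_profile(list(p_onset_known = 0.44))
  sc <- standard_scenarios()

  a <- apply_scenario(p, sc$A)
  expect_equal(a$arrival_to_scan_dist$median, 15)
  expect_equal(a$arrival_to_scan_dist$dispersion, 0)
  expect_equal(a$scan_to_needle_dist$median, 15)
  expect_equal(a$scan_to_needle_dist$dispersion, 0)
  expect_equal(a$p_eligible, p$p_eligible)      # untouched

  b <- apply_scenario(p, sc$B)
  expect_equal(b$p_eligible, 0.60)

  cc <- apply_scenario(p, sc$C)
  expect_equal(cc$p_onset_known, 0.77)

  # the floor only raises hospitals currently below it
  alt <- alternative_scenario()
  hi <- make_hospital_profile(list(p_onset_known = 0.73))
  lo <- make_hospital_profile(list(p_onset_known = 0.44))
  expect_equal(apply_scenario(hi, alt, benchmark_p_eligible = 0.5)$p_onset_known, 0.73)
  expect_equal(apply_scenario(lo, alt, benchmark_p_eligible = 0.5)$p_onset_known, 0.67)
  expect_equal(apply_scenario(lo, alt, benchmark_p_eligible = 0.5)$p_not_scanned_within_4h, 0.10)

  expect_error(scenario("bad", fix_p_onset_known = 0.7, onset_known_floor = 0.6),
               "at most one")
  expect_error(scenario("bad", fix_p_eligible = 1.4), "\\[0, 1\\]")
  expect_error(apply_scenario(p, alt), "benchmark")
})

test_that("simulate_period tallies treated patients and validates input", {
  expect_error(simulate_period(degenerate_profile(), n_admissions = 0), ">= 1")
  res <- simulate_period(degenerate_profile(), n_admissions = 250, seed = 4)
  expect_equal(res$n_treated, 250)
  expect_equal(length(res$treated_ott_min), 250)
  # product-of-gates oracle at n = 10 000
  gates <- c(0.6, 0.8, 0.85, 0.5)
  res2 <- simulate_period(degenerate_profile(gates = gates), n_admissions = 10000,
                          seed = 9)
  target <- prod(gates)   # 0.204
  se <- sqrt(target * (1 - target) / 10000)
  expect_lt(abs(res2$n_treated / 10000 - target), 3 * se)
})

test_that("replicate runs summarise with CIs and default to 100 runs", {
  expect_equal(eval(formals(run_replicates)$n_runs), 100L)
  expect_error(run_replicates(degenerate_profile(), n_runs = 1), ">= 2")

  rr <- run_replicates(degenerate_profile(), n_runs = 10, seed = 1,
                       n_admissions = 100)
  expect_equal(unname(rr$thrombolysis_pct["mean"]), 100)
  expect_equal(unname(rr$thrombolysis_pct["hi"] - rr$thrombolysis_pct["lo"]), 0)
  expect_equal(unname(rr$good_outcomes_per_1000["hi"]),
               unname(rr$good_outcomes_per_1000["lo"]))
  # identical seeds reproduce; different seeds differ
  p <- make_hospital_profile()
  r1 <- run_replicates(p, n_runs = 5, seed = 2, n_admissions = 200)
  r2 <- run_replicates(p, n_runs = 5, seed = 2, n_admissions = 200)
  expect_identical(r1$rep_pct, r2$rep_pct)
  # percentile interval brackets the mean
  rp <- run_replicates(p, n_runs = 20, seed = 2, n_admissions = 200,
                       ci = "percentile")
  expect_true(rp$thrombolysis_pct["lo"] <= rp$thrombolysis_pct["mean"])
  expect_true(rp$thrombolysis_pct["hi"] >= rp$thrombolysis_pct["mean"])
})

test_that("confidence-interval width shrinks as 1/sqrt(n_runs)", {
  p <- make_hospital_profile()
  widths <- sapply(1:8, function(s) {
    w1 <- diff(range(run_replicates(p, n_runs = 40, seed = 100 * s,
                                    n_admissions = 300)$thrombolysis_pct[c("lo", "hi")]))
    w2 <- diff(range(run_replicates(p, n_runs = 80, seed = 100 * s + 50,
                                    n_admissions = 300)$thrombolysis_pct[c("lo", "hi")]))
    c(w1, w2)
  })
  ratio <- mean(widths[2, ]) / mean(widths[1, ])
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.15)
})

test_that("pathway outcomes are pathwise monotone under common random numbers", {
  base <- make_hospital_profile()
  n <- 5000
  d0 <- sample_pathway(base, n, seed = 77)

  # slower arrival-to-scan can only lose patients
  slow <- base
  slow$arrival_to_scan_dist <- time_dist(45, 0.5)
  d_slow <- sample_pathway(slow, n, seed = 77)
  expect_true(all(d0$treated | !d_slow$treated))

  # higher onset-known gate can only add patients
  up <- base
  up$p_onset_known <- 0.8
  d_up <- sample_pathway(up, n, seed = 77)
  expect_true(all(d_up$treated | !d0$treated))

  # higher eligibility gate can only add patients
  up2 <- base
  up2$p_eligible <- min(1, base$p_eligible + 0.2)
  d_up2 <- sample_pathway(up2, n, seed = 77)
  expect_true(all(d_up2$treated | !d0$treated))
})

test_that("no treated patient ever exceeds the age-dependent window", {
  set.seed(31)
  for (i in 1:10) {
    p <- make_hospital_profile(list(
      p_onset_known = runif(1, 0.3, 0.9),
      p_arrive_within_4h = runif(1, 0.4, 0.8),
      p_eligible = runif(1, 0.2, 0.7),
      onset_to_arrival_dist = time_dist(runif(1, 60, 150), runif(1, 0.3, 0.8),
                                        truncate_max = 240),
      arrival_to_scan_dist = time_dist(runif(1, 10, 60), runif(1, 0.3, 0.8)),
      scan_to_needle_dist = time_dist(runif(1, 15, 50), runif(1, 0.2, 0.6))))
    d <- sample_pathway(p, 5000, seed = 500 + i)
    tr <- d[d$treated, ]
    expect_true(all(tr$onset_to_treatment_min <= treatment_window_min(tr$age)))
    expect_equal(tr$onset_to_treatment_min,
                 tr$onset_to_arrival_min + tr$arrival_to_scan_min +
                   tr$scan_to_needle_min)
  }
})
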