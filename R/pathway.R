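#' Age-dependent thrombolysis treatment window
#'
#' Licensing allows 4.5 h from onset to treatment for patients aged under 80
#' and 3 h for patients aged 80 and over; the simulator applies this as a
#' strict cut-off.
#'
#' @param age age in years (> 0); vectorised.
#' @return window in minutes: 270 if age < 80, 180 otherwise.
#' @export
#' @examples
#' treatment_window_min(c(79, 80))  # 270 180
treatment_window_min <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive", call. = FALSE)
  ifelse(age < 80, 270, 180)
}

#' Draw patients through the emergency stroke pathway
#'
#' Samples `n` patients through the modelled sequence of steps from stroke
#' onset to thrombolysis. A patient is treated only if (1) the onset time is
#' known, (2) they arrive within 4 h of onset, (3) they have an ischaemic
#' stroke and are judged clinically eligible, and (4) the summed
#' onset-to-treatment time lies within the age-dependent window. The clinical
#' eligibility decision is made only for patients scanned with at least
#' 30 min left in their window.
#'
#' All random numbers are drawn as a fixed-layout block of uniforms (one
#' vector per pathway stage, drawn whether or not the stage is reached) and
#' mapped through quantile functions. Two calls with the same seed therefore
#' share common random numbers stage-by-stage, which makes paired scenario
#' comparisons low-variance and pathwise monotone in the profile parameters.
#'
#' @param profile a [make_hospital_profile()] object.
#' @param n number of patients to draw.
#' @param eligibility NULL (use `profile$p_eligible`), a single probability,
#'   or a function taking the data frame of upstream draws (columns `age`,
#'   `onset_to_arrival_min`, `arrival_to_scan_min`) and returning per-patient
#'   treat-decision probabilities.
#' @param seed optional seed; NULL draws from the current RNG stream.
#' @return data frame with one row per patient: `onset_known`,
#'   `arrived_within_4h`, `scanned`, `onset_to_arrival_min`,
#'   `arrival_to_scan_min`, `scan_to_needle_min`, `age`, `ischaemic`,
#'   `considered` (scanned with >= 30 min left), `clinically_eligible`,
#'   `treated`, `onset_to_treatment_min` (NA unless treated).
#' @export
sample_pathway <- function(profile, n = 1L, eligibility = NULL, seed = NULL) {
  stopifnot(inherits(profile, "hospital_profile"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    u_onset <- stats::runif(n)
    u_4h    <- stats::runif(n)
    u_ota   <- stats::runif(n)
    u_scan  <- stats::runif(n)
    u_a2s   <- stats::runif(n)
    u_age   <- stats::runif(n)
    u_isch  <- stats::runif(n)
    u_elig  <- stats::runif(n)
    u_s2n   <- stats::runif(n)

    onset_known <- u_onset < profile$p_onset_known
    arrived_4h  <- onset_known & (u_4h < profile$p_arrive_within_4h)
    ota <- q_time_dist(u_ota, profile$onset_to_arrival_dist)
    scanned <- u_scan >= profile$p_not_scanned_within_4h
    a2s <- q_time_dist(u_a2s, profile$arrival_to_scan_dist)
    age <- censor_age(pmax(stats::qnorm(u_age, profile$age_dist$mean,
                                        profile$age_dist$sd), 1))
    window <- treatment_window_min(age)
    ischaemic <- u_isch < profile$p_ischaemic
    time_left_at_scan <- window - ota - a2s
    considered <- arrived_4h & scanned & ischaemic & (time_left_at_scan >= 30)

    p_elig <- if (is.null(eligibility)) {
      profile$p_eligible
    } else if (is.function(eligibility)) {
      eligibility(data.frame(age = age, onset_to_arrival_min = ota,
                             arrival_to_scan_min = a2s))
    } else {
      stop_if_not_prob(eligibility, "eligibility")
    }
    clinically_eligible <- considered & (u_elig < p_elig)
    s2n <- q_time_dist(u_s2n, profile$scan_to_needle_dist)
    ott <- ota + a2s + s2n
    treated <- clinically_eligible & (ott <= window)

    data.frame(
      onset_known = onset_known,
      arrived_within_4h = arrived_4h,
      scanned = scanned,
      onset_to_arrival_min = ota,
      arrival_to_scan_min = a2s,
      scan_to_needle_min = s2n,
      age = age,
      ischaemic = ischaemic,
      considered = considered,
      clinically_eligible = clinically_eligible,
      treated = treated,
      onset_to_treatment_min = ifelse(treated, ott, NA_real_)
    )
  })
}

#' Simulate one period of admissions
#'
#' Draws `n_admissions` patient pathways (optionally under a scenario) and
#' tallies the treated count and the onset-to-treatment times of treated
#' patients.
#'
#' @inheritParams sample_pathway
#' @param scen optional [scenario()] applied to the profile first.
#' @param n_admissions number of admissions in the period (>= 1).
#' @param benchmark_p_eligible passed to [apply_scenario()] for
#'   benchmark-eligibility scenarios.
#' @param arrivals "fixed" simulates exactly `n_admissions`; "poisson" draws
#'   the admission count as Poisson(`n_admissions`).
#' @return list with `n_admissions`, `n_treated`, `treated_ott_min` (vector),
#'   and the full `draws` data frame.
#' @export
simulate_period <- function(profile, scen = NULL, n_admissions = NULL,
                            eligibility = NULL, seed = NULL,
                            benchmark_p_eligible = NULL,
                            arrivals = c("fixed", "poisson")) {
  arrivals <- match.arg(arrivals)
  prof <- apply_scenario(profile, scen, benchmark_p_eligible)
  n_admissions <- n_admissions %||% round(prof$annual_admissions)
  if (!is.numeric(n_admissions) || n_admissions < 1)
    stop("n_admissions must be >= 1", call. = FALSE)
  with_seed(seed, {
    n <- if (arrivals == "poisson") max(1L, stats::rpois(1, n_admissions)) else as.integer(n_admissions)
    draws <- sample_pathway(prof, n, eligibility = eligibility, seed = NULL)
    list(n_admissions = n,
         n_treated = sum(draws$treated),
         treated_ott_min = draws$onset_to_treatment_min[draws$treated],
         draws = draws)
  })
}

#' Run replicate one-year simulations
#'
#' Runs `n_runs` independent one-year simulations (each with a different
#' seed derived from `seed`) and summarises thrombolysis use and clinical
#' benefit with replicate means and 95% confidence intervals
#' (mean +/- 1.96 SD/sqrt(n_runs), or percentile intervals on request).
#' Calling with the same base `seed` under different scenarios pairs the
#' replicates by common random numbers.
#'
#' @inheritParams simulate_period
#' @param outcome OutcomeParams from [outcome_params()] used to convert
#'   onset-to-treatment times into additional good outcomes.
#' @param n_runs number of replicate years (>= 2); default 100.
#' @param seed integer base seed.
#' @param ci "normal" (default) or "percentile" for the 95% interval method.
#' @return a `sim_result`: `thrombolysis_pct` and `good_outcomes_per_1000`
#'   (each `c(mean, lo, hi)`), `median_onset_to_treatment_hr`, `n_runs`,
#'   plus the per-replicate vectors `rep_pct` and `rep_good_per_1000` and the
#'   year-to-year 2.5%/97.5% replicate interval `rep_interval_pct`.
#' @export
run_replicates <- function(profile, scen = NULL, outcome = outcome_params(),
                           n_runs = 100L, seed = 1L, n_admissions = NULL,
                           eligibility = NULL, benchmark_p_eligible = NULL,
                           ci = c("normal", "percentile"),
                           arrivals = c("fixed", "poisson")) {
  ci <- match.arg(ci)
  arrivals <- match.arg(arrivals)
  if (!is.numeric(n_runs) || n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  n_runs <- as.integer(n_runs)
  prof <- apply_scenario(profile, scen, benchmark_p_eligible)
  n_adm <- n_admissions %||% round(prof$annual_admissions)

  rep_pct <- numeric(n_runs)
  rep_good <- numeric(n_runs)
  ott_all <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    res <- simulate_period(prof, scen = NULL, n_admissions = n_adm,
                           eligibility = eligibility,
                           seed = seed + i, arrivals = arrivals)
    rep_pct[i] <- 100 * res$n_treated / res$n_admissions
    rep_good[i] <- good_outcomes_per_1000(res$treated_ott_min,
                                          res$n_admissions, outcome)
    ott_all[[i]] <- res$treated_ott_min
  }
  ott <- unlist(ott_all)
  ci_fun <- if (ci == "normal") ci_normal else ci_percentile
  structure(list(
    hospital_id = profile$hospital_id,
    scenario = if (is.null(scen)) "base" else scen$name,
    thrombolysis_pct = ci_fun(rep_pct),
    good_outcomes_per_1000 = ci_fun(rep_good),
    median_onset_to_treatment_hr =
      if (length(ott)) stats::median(ott) / 60 else NA_real_,
    n_runs = n_runs,
    rep_pct = rep_pct,
    rep_good_per_1000 = rep_good,
    rep_interval_pct = stats::quantile(rep_pct, c(0.025, 0.975), names = FALSE)
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Pathway simulation: hospital %s, scenario %s (%d one-year runs)\n",
              x$hospital_id, x$scenario, x$n_runs))
  cat(sprintf("  thrombolysis use:        %.1f%% (95%% CI %.1f-%.1f)\n",
              x$thrombolysis_pct["mean"], x$thrombolysis_pct["lo"],
              x$thrombolysis_pct["hi"]))
  cat(sprintf("  additional good outcomes: %.1f per 1000 admissions (95%% CI %.1f-%.1f)\n",
              x$good_outcomes_per_1000["mean"], x$good_outcomes_per_1000["lo"],
              x$good_outcomes_per_1000["hi"]))
  cat(sprintf("  median onset-to-treatment: %.1f h\n",
              x$median_onset_to_treatment_hr))
  invisible(x)
}
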