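#' Fit a hospital profile from audit records
#'
#' Estimates pathway-model parameters from patient-level records: gate
#' probabilities as observed proportions, and process-time distributions by
#' maximum likelihood on the log scale, honouring the truncation under which
#' each time is observed. Onset-to-arrival times (for patients arriving
#' within 4 h) are fitted as a log-normal truncated at 240 min; scan-to-needle
#' times are observed only for treated patients, i.e. only below each
#' patient's remaining window, and are fitted with the matching
#' per-observation truncated likelihood.
#'
#' The clinical-eligibility gate is the observed treated fraction among
#' ischaemic patients scanned with at least 30 min left in the window. Since
#' a decision to treat only becomes a recorded treatment when the
#' scan-to-needle time fits the remaining window, the raw fraction slightly
#' understates the decision rate; the returned `p_eligible` divides treated
#' counts by the fitted probability that the scan-to-needle time fits
#' (inverse-probability correction). Both values are kept in the `fit_info`
#' element.
#'
#' @param records cohort data frame (see [synthesize_cohort()] for columns).
#' @param years period the records span, used to derive annual admissions.
#' @param min_records minimum records required.
#' @param seed seed for decision-rule calibration of the returned profile.
#' @return a `hospital_profile` with an extra `fit_info` element holding
#'   estimates, standard errors and counts.
#' @export
fit_profile_from_records <- function(records, years = 2, min_records = 50L,
                                     seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n < min_records)
    stop(sprintf("need at least %d records to fit a profile (got %s)",
                 min_records, n %||% 0), call. = FALSE)
  ota <- records$onset_to_arrival_min
  a2s <- records$arrival_to_scan_min
  s2n <- records$scan_to_needle_min
  known <- records$onset_known
  treated <- records$thrombolysis_given

  p_onset <- mean(known)
  in4h <- known & !is.na(ota) & ota <= 240
  p_4h <- if (any(known)) mean(in4h[known]) else 0
  p_not_scanned <- mean(is.na(a2s))
  p_isch <- mean(records$stroke_type == "ischaemic")

  ota_fit <- if (sum(in4h) >= 2) fit_lnorm_trunc(ota[in4h], 240) else
    list(meanlog = log(95), sdlog = 0.55, se_meanlog = NA, se_sdlog = NA)
  a2s_obs <- a2s[!is.na(a2s)]
  a2s_fit <- if (length(a2s_obs) >= 2) fit_lnorm_trunc(a2s_obs, Inf) else
    list(meanlog = log(25), sdlog = 0.5, se_meanlog = NA, se_sdlog = NA)

  window <- treatment_window_min(records$age)
  remaining <- window - ota - a2s
  considered <- in4h & !is.na(a2s) & records$stroke_type == "ischaemic" &
    !is.na(remaining) & remaining >= 30
  n_considered <- sum(considered)
  n_treated <- sum(treated)

  if (n_treated >= 2) {
    s2n_fit <- fit_lnorm_trunc(s2n[treated], remaining[treated])
  } else {
    # no treated patients to learn speed from; fall back to reference values
    s2n_fit <- list(meanlog = log(30), sdlog = 0.4, se_meanlog = NA, se_sdlog = NA)
  }
  p_elig_raw <- if (n_considered) n_treated / n_considered else 0
  # correct for decisions lost to the window check between decision and needle
  p_fit <- stats::plnorm(remaining[considered], s2n_fit$meanlog,
                         max(s2n_fit$sdlog, 1e-12))
  p_elig <- if (n_considered && sum(p_fit) > 0) {
    min(1, n_treated / sum(p_fit))
  } else 0

  sev_frac <- pmin(pmax(records$nihss_total / 42, 0.005), 0.995)
  cm <- case_mix(sev_logit_mean = mean(stats::qlogis(sev_frac)),
                 sev_logit_sd = stats::sd(stats::qlogis(sev_frac)))

  prof <- make_hospital_profile(list(
    hospital_id = as.character(records$hospital_id[1]),
    annual_admissions = max(1, n / years),
    p_onset_known = p_onset,
    p_arrive_within_4h = p_4h,
    onset_to_arrival_dist = time_dist(exp(ota_fit$meanlog), ota_fit$sdlog,
                                      truncate_max = 240),
    arrival_to_scan_dist = time_dist(exp(a2s_fit$meanlog), a2s_fit$sdlog),
    scan_to_needle_dist = time_dist(exp(s2n_fit$meanlog), s2n_fit$sdlog),
    p_ischaemic = p_isch,
    p_eligible = p_elig,
    p_not_scanned_within_4h = p_not_scanned,
    age_dist = list(mean = mean(records$age), sd = max(stats::sd(records$age), 1)),
    case_mix = cm
  ), seed = seed)
  prof$fit_info <- list(
    n_records = n, n_considered = n_considered, n_treated = n_treated,
    p_eligible_raw = p_elig_raw,
    se_p_onset_known = sqrt(p_onset * (1 - p_onset) / n),
    ota = ota_fit, a2s = a2s_fit, s2n = s2n_fit
  )
  prof
}

#' Bootstrap validation of the pathway simulator
#'
#' Draws bootstrap samples of patients with varying overall thrombolysis use
#' (resampling separately from treated and untreated strata to hit target
#' rates across `rate_range`), fits a pathway profile to each sample,
#' simulates it, and compares predicted with actual thrombolysis use.
#'
#' @param records cohort data frame containing both treated and untreated
#'   patients.
#' @param n_samples number of bootstrap samples (default 100).
#' @param sample_size patients per sample (default 600, a typical acute
#'   stroke unit's annual admissions).
#' @param rate_range target thrombolysis-use range in percent (default
#'   1--25%).
#' @param n_runs_per_sample one-year simulation runs averaged per sample
#'   (default 100).
#' @param seed integer seed.
#' @param random_rates place target rates uniformly at random instead of
#'   evenly spaced (the default spacing is deterministic for
#'   reproducibility).
#' @return a `bootstrap_validation`: data frame `samples` with columns
#'   `actual_pct` and `predicted_pct`, plus `r_squared` (ordinary, of the
#'   regression of predicted on actual), `slope_origin` and
#'   `r_squared_origin` (through-origin fit), and `prediction_ratio`
#'   (mean predicted/actual).
#' @export
bootstrap_validation <- function(records, n_samples = 100L, sample_size = 600L,
                                 rate_range = c(1, 25),
                                 n_runs_per_sample = 100L, seed = 1L,
                                 random_rates = FALSE) {
  idx_t <- which(records$thrombolysis_given)
  idx_u <- which(!records$thrombolysis_given)
  if (!length(idx_t) || !length(idx_u))
    stop("records must contain both treated and untreated patients", call. = FALSE)
  rates <- if (random_rates) {
    with_seed(seed, stats::runif(n_samples, rate_range[1], rate_range[2]))
  } else {
    seq(rate_range[1], rate_range[2], length.out = n_samples)
  }
  actual <- predicted <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    n_t <- round(rates[s] / 100 * sample_size)
    samp <- with_seed(seed + 13L * s, {
      rows <- c(sample(idx_t, n_t, replace = TRUE),
                sample(idx_u, sample_size - n_t, replace = TRUE))
      records[rows, , drop = FALSE]
    })
    prof <- fit_profile_from_records(samp, years = 1, seed = 1L)
    rr <- run_replicates(prof, n_runs = max(2L, n_runs_per_sample),
                         seed = seed + 1000L + s,
                         n_admissions = sample_size)
    actual[s] <- 100 * n_t / sample_size
    predicted[s] <- rr$thrombolysis_pct[["mean"]]
  }
  slope_origin <- sum(actual * predicted) / sum(actual^2)
  r_squared <- stats::cor(actual, predicted)^2
  r_squared_origin <- 1 - sum((predicted - slope_origin * actual)^2) /
    sum(predicted^2)
  ok <- actual > 0
  structure(list(
    samples = data.frame(actual_pct = actual, predicted_pct = predicted),
    r_squared = r_squared,
    slope_origin = slope_origin,
    r_squared_origin = r_squared_origin,
    prediction_ratio = mean(predicted[ok] / actual[ok])
  ), class = "bootstrap_validation")
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat(sprintf("Bootstrap validation over %d samples\n", nrow(x$samples)))
  cat(sprintf("  R-squared (predicted vs actual): %.3f\n", x$r_squared))
  cat(sprintf("  through-origin slope:            %.3f (R-squared %.3f)\n",
              x$slope_origin, x$r_squared_origin))
  cat(sprintf("  mean predicted/actual ratio:     %.3f\n", x$prediction_ratio))
  invisible(x)
}

#' Scatter plot of predicted versus actual thrombolysis use
#'
#' @param x a [bootstrap_validation()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bootstrap_validation <- function(x, ...) {
  graphics::plot(x$samples$actual_pct, x$samples$predicted_pct,
                 xlab = "Actual thrombolysis use (%)",
                 ylab = "Predicted thrombolysis use (%)",
                 pch = 19, col = "steelblue", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(0, x$slope_origin, col = "firebrick")
  graphics::legend("topleft", bty = "n",
                   legend = c("identity", sprintf("fit (slope %.2f)", x$slope_origin)),
                   lty = c(2, 1), col = c("black", "firebrick"))
  invisible(x)
}

#' Compare actual with modelled hospital performance
#'
#' For each hospital: fits a profile from its records, runs replicate
#' one-year simulations, and tabulates observed versus modelled thrombolysis
#' use and onset-to-treatment time. The replicate interval columns give the
#' 2.5%/97.5% quantiles of the simulated yearly rates (expected year-to-year
#' variation).
#'
#' @param records multi-hospital cohort data frame.
#' @param n_runs replicate years per hospital (default 100).
#' @param years period the records span.
#' @param outcome an [outcome_params()] object.
#' @param seed integer seed.
#' @return a `hospital_comparison` data frame (one row per hospital) with
#'   attribute `prediction_ratio` (mean modelled/actual rate).
#' @export
hospital_comparison <- function(records, n_runs = 100L, years = 2,
                                outcome = outcome_params(), seed = 1L) {
  by_h <- split(records, as.character(records$hospital_id))
  rows <- lapply(names(by_h), function(h) {
    rec <- by_h[[h]]
    prof <- fit_profile_from_records(rec, years = years, seed = seed)
    rr <- run_replicates(prof, outcome = outcome, n_runs = n_runs, seed = seed)
    ott_obs <- with(rec, onset_to_arrival_min + arrival_to_scan_min +
                      scan_to_needle_min)[rec$thrombolysis_given]
    data.frame(
      hospital_id = h,
      n_records = nrow(rec),
      actual_pct = 100 * mean(rec$thrombolysis_given),
      model_pct = rr$thrombolysis_pct[["mean"]],
      model_ci_lo = rr$thrombolysis_pct[["lo"]],
      model_ci_hi = rr$thrombolysis_pct[["hi"]],
      rep_lo = rr$rep_interval_pct[1],
      rep_hi = rr$rep_interval_pct[2],
      actual_ott_hr = if (length(ott_obs)) stats::median(ott_obs) / 60 else NA_real_,
      model_ott_hr = rr$median_onset_to_treatment_hr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$within_replicate_interval <- out$actual_pct >= out$rep_lo &
    out$actual_pct <= out$rep_hi
  attr(out, "prediction_ratio") <- mean(out$model_pct / out$actual_pct)
  class(out) <- c("hospital_comparison", "data.frame")
  out
}

#' @export
print.hospital_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df, row.names = FALSE)
  cat(sprintf("\nMean modelled/actual thrombolysis ratio: %.3f\n",
              attr(x, "prediction_ratio")))
  invisible(x)
}

#' Scenario comparison report across hospitals
#'
#' Runs replicate simulations for every hospital under every scenario and
#' tabulates predicted thrombolysis use and clinical benefit. Scenarios with
#' `eligibility_source = "benchmark"` need per-hospital benchmark
#' eligibility rates (see [benchmark_eligibility()]); an informative error
#' is raised if they are missing.
#'
#' @param profiles named list of hospital profiles.
#' @param scenarios list of [scenario()] objects; empty list runs base only.
#' @param outcome an [outcome_params()] object.
#' @param n_runs replicate years (default 100).
#' @param seed integer base seed; the same seed is reused across scenarios so
#'   comparisons share common random numbers.
#' @param benchmark_p_eligible named numeric vector of benchmark eligibility
#'   rates per hospital (fractions), for benchmark scenarios.
#' @return a `scenario_report` data frame: one row per hospital x scenario
#'   with mean and 95% CI of thrombolysis % and good outcomes per 1000, and
#'   median onset-to-treatment hours.
#' @export
scenario_report <- function(profiles, scenarios = standard_scenarios(),
                            outcome = outcome_params(), n_runs = 100L,
                            seed = 1L, benchmark_p_eligible = NULL) {
  if (inherits(profiles, "hospital_profile")) profiles <- list(profiles)
  if (!length(scenarios)) scenarios <- list(base = scenario("base"))
  rows <- list()
  for (prof in profiles) {
    for (scen in scenarios) {
      bpe <- NULL
      if (scen$eligibility_source == "benchmark") {
        bpe <- benchmark_p_eligible[[prof$hospital_id]]
        if (is.null(bpe))
          stop("scenario '", scen$name, "' requires a trained benchmark ",
               "eligibility rate for hospital ", prof$hospital_id, call. = FALSE)
      }
      rr <- run_replicates(prof, scen = scen, outcome = outcome,
                           n_runs = n_runs, seed = seed,
                           benchmark_p_eligible = bpe)
      rows[[length(rows) + 1L]] <- data.frame(
        hospital_id = prof$hospital_id,
        scenario = scen$name,
        thrombolysis_pct = rr$thrombolysis_pct[["mean"]],
        thrombolysis_lo = rr$thrombolysis_pct[["lo"]],
        thrombolysis_hi = rr$thrombolysis_pct[["hi"]],
        good_per_1000 = rr$good_outcomes_per_1000[["mean"]],
        good_lo = rr$good_outcomes_per_1000[["lo"]],
        good_hi = rr$good_outcomes_per_1000[["hi"]],
        median_ott_hr = rr$median_onset_to_treatment_hr,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_report", "data.frame")
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  df <- as.data.frame(x)
  wide <- stats::reshape(
    df[, c("hospital_id", "scenario", "thrombolysis_pct")],
    idvar = "hospital_id", timevar = "scenario", direction = "wide")
  names(wide) <- sub("^thrombolysis_pct\\.", "", names(wide))
  num <- vapply(wide, is.numeric, logical(1))
  wide[num] <- lapply(wide[num], round, 1)
  cat("Predicted thrombolysis use (%), hospital x scenario:\n")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write a scenario report as CSV
#'
#' @param report a [scenario_report()] result.
#' @param path file path.
#' @export
write_scenario_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  invisible(path)
}
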