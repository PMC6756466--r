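#' Fit a stroke pathway model to audit records
#'
#' The modelling front end: fits the pathway parameters of one hospital from
#' its patient-level audit records (see [fit_profile_from_records()] for the
#' estimators) and returns a classed model object with the usual methods —
#' `print`, `summary`, `coef`, `simulate` and `predict` (the latter two run
#' replicate one-year simulations, optionally under a what-if scenario).
#'
#' @param records cohort data frame for a single hospital (a multi-hospital
#'   frame is accepted with `hospital_id` naming which one to fit).
#' @param hospital_id hospital to fit when `records` spans several.
#' @param years period the records span in years.
#' @param ... passed to [fit_profile_from_records()].
#' @return an object of class `pathway_fit`.
#' @export
#' @examples
#' co <- synthesize_cohort(make_hospital_profile(), years = 1, seed = 7)
#' fit <- fit_pathway_model(co, years = 1)
#' coef(fit)
#' predict(fit, scen = standard_scenarios()$A, n_runs = 20)
fit_pathway_model <- function(records, hospital_id = NULL, years = 2, ...) {
  ids <- unique(as.character(records$hospital_id))
  if (is.null(hospital_id)) {
    if (length(ids) > 1)
      stop("records span several hospitals; give 'hospital_id'", call. = FALSE)
    hospital_id <- ids
  }
  rec <- records[records$hospital_id == hospital_id, , drop = FALSE]
  profile <- fit_profile_from_records(rec, years = years, ...)
  structure(list(profile = profile,
                 n_records = nrow(rec),
                 observed_pct = 100 * mean(rec$thrombolysis_given),
                 years = years,
                 call = match.call()),
            class = "pathway_fit")
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat("Stroke pathway model fit:", x$profile$hospital_id, "\n")
  cat(sprintf("  %d records over %.3g year(s); observed thrombolysis use %.1f%%\n",
              x$n_records, x$years, x$observed_pct))
  print(x$profile)
  invisible(x)
}

#' @export
summary.pathway_fit <- function(object, ...) {
  info <- object$profile$fit_info
  cat("Stroke pathway model fit:", object$profile$hospital_id, "\n")
  cat(sprintf("  records: %d (considered for decision: %d, treated: %d)\n",
              info$n_records, info$n_considered, info$n_treated))
  cat(sprintf("  p_onset_known     %.3f (SE %.3f)\n",
              object$profile$p_onset_known, info$se_p_onset_known))
  cat(sprintf("  p_arrive_within_4h %.3f\n", object$profile$p_arrive_within_4h))
  cat(sprintf("  p_ischaemic       %.3f\n", object$profile$p_ischaemic))
  cat(sprintf("  p_eligible        %.3f (raw observed %.3f)\n",
              object$profile$p_eligible, info$p_eligible_raw))
  cat(sprintf("  onset-to-arrival meanlog %.3f (SE %.3f), sdlog %.3f\n",
              info$ota$meanlog, info$ota$se_meanlog, info$ota$sdlog))
  cat(sprintf("  arrival-to-scan  meanlog %.3f (SE %.3f), sdlog %.3f\n",
              info$a2s$meanlog, info$a2s$se_meanlog, info$a2s$sdlog))
  cat(sprintf("  scan-to-needle   meanlog %.3f (SE %.3f), sdlog %.3f\n",
              info$s2n$meanlog, info$s2n$se_meanlog, info$s2n$sdlog))
  invisible(object)
}

#' @export
coef.pathway_fit <- function(object, ...) {
  p <- object$profile
  c(p_onset_known = p$p_onset_known,
    p_arrive_within_4h = p$p_arrive_within_4h,
    p_ischaemic = p$p_ischaemic,
    p_eligible = p$p_eligible,
    onset_to_arrival_median = p$onset_to_arrival_dist$median,
    arrival_to_scan_median = p$arrival_to_scan_dist$median,
    scan_to_needle_median = p$scan_to_needle_dist$median)
}

#' Simulate replicate years from a fitted pathway model
#'
#' @param object a [fit_pathway_model()] object.
#' @param nsim number of replicate one-year simulations.
#' @param seed integer seed.
#' @param scen optional [scenario()].
#' @param ... passed to [run_replicates()].
#' @return data frame with one row per replicate: `thrombolysis_pct`,
#'   `good_per_1000`.
#' @export
simulate.pathway_fit <- function(object, nsim = 100, seed = 1L, scen = NULL, ...) {
  rr <- run_replicates(object$profile, scen = scen, n_runs = nsim,
                       seed = seed, ...)
  data.frame(thrombolysis_pct = rr$rep_pct,
             good_per_1000 = rr$rep_good_per_1000)
}

#' Predict pathway performance, optionally under a scenario
#'
#' @inheritParams simulate.pathway_fit
#' @param n_runs replicate years.
#' @return a `sim_result` (see [run_replicates()]).
#' @export
predict.pathway_fit <- function(object, scen = NULL, n_runs = 100L,
                                seed = 1L, ...) {
  run_replicates(object$profile, scen = scen, n_runs = n_runs, seed = seed, ...)
}
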