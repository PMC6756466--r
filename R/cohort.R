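#' Censor age to the 40--100 range
#'
#' Audit extracts censor extreme ages to protect anonymity: ages under 40 are
#' raised to 40 and ages over 100 lowered to 100. The synthetic generator
#' applies the same censoring.
#'
#' @param age age in years (> 0); vectorised.
#' @return censored age, `min(max(age, 40), 100)`.
#' @export
#' @examples
#' censor_age(c(35, 70, 104))  # 40 70 100
censor_age <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive", call. = FALSE)
  pmin(pmax(age, 40), 100)
}

#' Synthesize a hospital audit cohort
#'
#' Generates patient-level audit records with the statistical structure the
#' pathway and decision models assume. Each record is drawn through the
#' generative chain: onset known ~ Bernoulli; arrival within 4 h of onset ~
#' Bernoulli conditional on known onset, with onset-to-arrival sampled from
#' the profile's log-normal truncated at 240 min (late arrivers draw from the
#' conditional tail above 240 min); arrival-to-scan and scan-to-needle times
#' sampled independently; stroke type ~ Bernoulli(p_ischaemic); clinical
#' features drawn from the profile's case mix. The treatment label is stamped
#' by the profile's latent decision rule, applied only to ischaemic patients
#' scanned with at least 30 min left in the age-dependent window, and
#' treatment additionally requires the summed onset-to-treatment time to fall
#' inside the window.
#'
#' Times are recorded as integer minutes; onset-to-arrival is missing for
#' unknown-onset patients, arrival-to-scan for unscanned patients, and
#' scan-to-needle for untreated patients, mirroring audit extracts.
#'
#' @param profile a [make_hospital_profile()] object.
#' @param years cohort duration in years (> 0); the record count is
#'   `round(annual_admissions * years)`.
#' @param seed integer seed; identical (profile, years, seed) give identical
#'   cohorts.
#' @return data frame of patient records (one row per admission).
#' @export
#' @examples
#' co <- synthesize_cohort(make_hospital_profile(), years = 0.1, seed = 42)
#' mean(co$thrombolysis_given)
synthesize_cohort <- function(profile, years = 2, seed = 1L) {
  stopifnot(inherits(profile, "hospital_profile"))
  if (!is.numeric(years) || years <= 0) stop("years must be > 0", call. = FALSE)
  n <- round(profile$annual_admissions * years)
  with_seed(seed, {
    feats <- draw_clinical_features(n, profile$case_mix, profile$age_dist)
    onset_known <- stats::runif(n) < profile$p_onset_known
    arrived_4h <- onset_known & (stats::runif(n) < profile$p_arrive_within_4h)
    u_ota <- stats::runif(n)
    d <- profile$onset_to_arrival_dist
    ota <- ifelse(arrived_4h,
                  qlnorm_med_trunc(u_ota, d$median, d$dispersion, d$truncate_max),
                  qlnorm_med_above(u_ota, d$median, d$dispersion, d$truncate_max))
    ota[!onset_known] <- NA_real_
    scanned <- stats::runif(n) >= profile$p_not_scanned_within_4h
    a2s <- q_time_dist(stats::runif(n), profile$arrival_to_scan_dist)
    a2s[!scanned] <- NA_real_
    ischaemic <- stats::runif(n) < profile$p_ischaemic
    s2n <- q_time_dist(stats::runif(n), profile$scan_to_needle_dist)

    ota <- round(pmax(ota, 1))
    a2s <- round(pmax(a2s, 1))
    s2n <- round(pmax(s2n, 1))

    window <- treatment_window_min(feats$age)
    time_left <- window - ota - a2s
    considered <- arrived_4h & scanned & ischaemic &
      !is.na(time_left) & time_left >= 30
    p_treat <- rule_treat_prob(profile$decision_rule, feats)
    decided <- considered & (stats::runif(n) < p_treat)
    treated <- decided & ((ota + a2s + s2n) <= window)

    rec <- data.frame(
      hospital_id = rep(profile$hospital_id, n),
      onset_known = onset_known,
      onset_to_arrival_min = ota,
      arrival_to_scan_min = a2s,
      scan_to_needle_min = ifelse(treated, s2n, NA_real_),
      stroke_type = ifelse(ischaemic, "ischaemic", "haemorrhagic"),
      thrombolysis_given = treated,
      stringsAsFactors = FALSE
    )
    cbind(rec, feats)
  })
}

#' @rdname synthesize_cohort
#' @param profiles named list of profiles (e.g.
#'   [reference_hospital_profiles()]); each hospital draws an independent
#'   seed derived from `seed`.
#' @export
synthesize_cohorts <- function(profiles, years = 2, seed = 1L) {
  cohorts <- lapply(seq_along(profiles), function(i) {
    synthesize_cohort(profiles[[i]], years = years, seed = seed + 7919L * i)
  })
  do.call(rbind, cohorts)
}

#' Read and write patient cohorts as CSV
#'
#' One row per patient record with a fixed header; missing values (unknown
#' onset, not scanned, not treated) are written as empty cells and times as
#' integer minutes.
#'
#' @param records cohort data frame from [synthesize_cohort()].
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("onset_known", "thrombolysis_given"))
    if (!is.logical(rec[[col]])) rec[[col]] <- as.logical(rec[[col]])
  rec
}
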