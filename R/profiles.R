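#' Specify a positive process-time distribution
#'
#' Process times along the pathway (onset-to-arrival, arrival-to-scan,
#' scan-to-needle) are modelled as log-normal, parameterised by the median in
#' minutes and a geometric dispersion (the sdlog of the log-normal).
#' `dispersion = 0` gives a degenerate distribution fixed at the median, as
#' used by the "fixed at 15 min with no variation" what-if scenarios.
#'
#' @param median_min median time in minutes (> 0).
#' @param dispersion sdlog of the log-normal (>= 0).
#' @param truncate_max optional upper support bound in minutes; sampling is
#'   conditional on the time being below this bound. Used for onset-to-arrival,
#'   which is only sampled for patients arriving within 4 h (240 min).
#' @return a `time_dist` list.
#' @export
#' @examples
#' time_dist(15, 0)        # fixed 15 minutes
#' time_dist(95, 0.55, truncate_max = 240)
time_dist <- function(median_min, dispersion, truncate_max = NULL) {
  if (!is.numeric(median_min) || length(median_min) != 1L || !is.finite(median_min) || median_min <= 0)
    stop("time distribution median must be a single positive number of minutes", call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || !is.finite(dispersion) || dispersion < 0)
    stop("time distribution dispersion must be a single non-negative number", call. = FALSE)
  structure(list(median = median_min, dispersion = dispersion,
                 truncate_max = truncate_max), class = "time_dist")
}

q_time_dist <- function(u, dist) {
  if (is.null(dist$truncate_max)) {
    qlnorm_med(u, dist$median, dist$dispersion)
  } else {
    qlnorm_med_trunc(u, dist$median, dist$dispersion, dist$truncate_max)
  }
}

#' Latent clinical decision rule
#'
#' The rule the cohort synthesizer uses to stamp treatment labels for patients
#' who reach the clinical-decision point (ischaemic stroke, scanned with at
#' least 30 min left in the treatment window). The probability of a decision
#' to treat is a logistic function of stroke severity (NIHSS total), shifted
#' by a per-hospital aggressiveness offset and penalised for anticoagulant use
#' and significant pre-stroke disability:
#'
#' \deqn{P(treat) = logistic((NIHSS - threshold)/scale + aggressiveness
#'       - anticoag_penalty \cdot anticoag - disability_penalty \cdot (mRS \ge 3))}
#'
#' `scale = 0` gives the deterministic threshold rule `NIHSS >= threshold`
#' (penalties ignored), a perfectly separable rule useful for classifier
#' checks.
#'
#' @param threshold NIHSS total at which the logistic is centred.
#' @param scale logistic scale in NIHSS points; 0 = deterministic rule.
#' @param aggressiveness offset on the logit scale; larger treats more readily.
#' @param anticoag_penalty,disability_penalty logit penalties.
#' @return a `decision_rule` list.
#' @export
decision_rule <- function(threshold = 6, scale = 3, aggressiveness = 0,
                          anticoag_penalty = 1.0, disability_penalty = 0.8) {
  stopifnot(is.numeric(threshold), is.numeric(scale), scale >= 0)
  structure(list(threshold = threshold, scale = scale,
                 aggressiveness = aggressiveness,
                 anticoag_penalty = anticoag_penalty,
                 disability_penalty = disability_penalty),
            class = "decision_rule")
}

# Probability of a decision to treat, given clinical features.
rule_treat_prob <- function(rule, features) {
  if (rule$scale == 0) {
    return(as.numeric(features$nihss_total >= rule$threshold))
  }
  lp <- (features$nihss_total - rule$threshold) / rule$scale +
    rule$aggressiveness -
    rule$anticoag_penalty * features$on_anticoagulant -
    rule$disability_penalty * as.numeric(features$prestroke_mrs >= 3)
  stats::plogis(lp)
}

#' Default case-mix parameters for the synthetic cohort generator
#'
#' Governs the clinical-feature distributions of a synthetic hospital
#' population: the latent severity distribution (on the logit scale of the
#' per-item NIHSS score probability), sex, comorbidity and medication
#' prevalences, and the pre-stroke disability (mRS) distribution.
#'
#' @param sev_logit_mean,sev_logit_sd latent severity: each patient draws
#'   `p = plogis(N(mean, sd))` and NIHSS items are Binomial(max_item, p).
#' @param p_male probability of male sex.
#' @param p_afib,p_htn,p_diabetes,p_prior_stroke,p_hf,p_smoker comorbidity
#'   prevalences (atrial fibrillation, hypertension, diabetes, prior stroke,
#'   heart failure, current smoker).
#' @param p_anticoag_afib,p_anticoag_no_afib anticoagulant use conditional on
#'   atrial fibrillation status.
#' @param p_antiplatelet antiplatelet use.
#' @param prestroke_mrs_probs probabilities of pre-stroke mRS 0..5.
#' @return a `case_mix` list.
#' @export
case_mix <- function(sev_logit_mean = -1.4, sev_logit_sd = 0.8,
                     p_male = 0.52, p_afib = 0.20, p_htn = 0.55,
                     p_diabetes = 0.20, p_prior_stroke = 0.15, p_hf = 0.08,
                     p_smoker = 0.22, p_anticoag_afib = 0.35,
                     p_anticoag_no_afib = 0.05, p_antiplatelet = 0.30,
                     prestroke_mrs_probs = c(0.55, 0.20, 0.10, 0.08, 0.05, 0.02)) {
  stopifnot(length(prestroke_mrs_probs) == 6L, all(prestroke_mrs_probs >= 0))
  prestroke_mrs_probs <- prestroke_mrs_probs / sum(prestroke_mrs_probs)
  structure(list(sev_logit_mean = sev_logit_mean, sev_logit_sd = sev_logit_sd,
                 p_male = p_male, p_afib = p_afib, p_htn = p_htn,
                 p_diabetes = p_diabetes, p_prior_stroke = p_prior_stroke,
                 p_hf = p_hf, p_smoker = p_smoker,
                 p_anticoag_afib = p_anticoag_afib,
                 p_anticoag_no_afib = p_anticoag_no_afib,
                 p_antiplatelet = p_antiplatelet,
                 prestroke_mrs_probs = prestroke_mrs_probs),
            class = "case_mix")
}

# NIHSS item maxima (15 items summing to 42)
nihss_item_max <- c(
  loc = 3, loc_questions = 2, loc_commands = 2, best_gaze = 2,
  visual_field = 3, facial_palsy = 3, motor_arm_left = 4, motor_arm_right = 4,
  motor_leg_left = 4, motor_leg_right = 4, limb_ataxia = 2, sensory = 2,
  best_language = 3, dysarthria = 2, extinction_inattention = 2
)

# Draw n rows of clinical features (no pathway fields) from a case mix.
draw_clinical_features <- function(n, cm, age_dist) {
  age <- censor_age(pmax(stats::rnorm(n, age_dist$mean, age_dist$sd), 1))
  sex_male <- stats::rbinom(n, 1, cm$p_male)
  p_item <- stats::plogis(stats::rnorm(n, cm$sev_logit_mean, cm$sev_logit_sd))
  items <- vapply(nihss_item_max, function(mx) stats::rbinom(n, mx, p_item),
                  numeric(n))
  if (n == 1L) items <- matrix(items, nrow = 1, dimnames = list(NULL, names(nihss_item_max)))
  colnames(items) <- paste0("nihss_", names(nihss_item_max))
  afib <- stats::rbinom(n, 1, cm$p_afib)
  feats <- data.frame(
    age = age, sex_male = sex_male,
    nihss_total = rowSums(items), items,
    atrial_fibrillation = afib,
    hypertension = stats::rbinom(n, 1, cm$p_htn),
    diabetes = stats::rbinom(n, 1, cm$p_diabetes),
    prior_stroke = stats::rbinom(n, 1, cm$p_prior_stroke),
    heart_failure = stats::rbinom(n, 1, cm$p_hf),
    smoker = stats::rbinom(n, 1, cm$p_smoker),
    on_anticoagulant = stats::rbinom(n, 1, ifelse(afib == 1, cm$p_anticoag_afib,
                                                  cm$p_anticoag_no_afib)),
    on_antiplatelet = stats::rbinom(n, 1, cm$p_antiplatelet),
    prestroke_mrs = sample(0:5, n, replace = TRUE, prob = cm$prestroke_mrs_probs)
  )
  feats
}

# Solve for the aggressiveness offset so that the mean decision-to-treat
# probability over the hospital's case mix equals p_eligible.
calibrate_aggressiveness <- function(rule, cm, age_dist, p_eligible,
                                     n = 20000L, seed = 1L) {
  if (rule$scale == 0) return(rule)  # deterministic rule is not calibrated
  feats <- with_seed(seed, draw_clinical_features(n, cm, age_dist))
  mean_p <- function(a) {
    r <- rule; r$aggressiveness <- a
    mean(rule_treat_prob(r, feats))
  }
  if (p_eligible <= 1e-8) { rule$aggressiveness <- -Inf; return(rule) }
  if (p_eligible >= 1 - 1e-8) { rule$aggressiveness <- Inf; return(rule) }
  rule$aggressiveness <- stats::uniroot(function(a) mean_p(a) - p_eligible,
                                        lower = -30, upper = 30, tol = 1e-6)$root
  rule
}

# Mean treat probability implied by an explicit rule over a case mix.
implied_p_eligible <- function(rule, cm, age_dist, n = 20000L, seed = 1L) {
  feats <- with_seed(seed, draw_clinical_features(n, cm, age_dist))
  mean(rule_treat_prob(rule, feats))
}

#' Construct a hospital pathway profile
#'
#' A `hospital_profile` parameterises one hospital: the Bernoulli gate
#' probabilities along the pathway (onset time known; arrival within 4 h of
#' onset conditional on known onset; ischaemic stroke; judged clinically
#' eligible among ischaemic patients scanned with at least 30 min left in the
#' treatment window), log-normal process-time distributions, the admitted-age
#' distribution, the case mix of clinical features, and the latent decision
#' rule the cohort synthesizer uses to stamp treatment labels.
#'
#' Unset fields default to a documented reference profile whose values bracket
#' the spread observed across English acute stroke units (onset known
#' 44--73%, arrival-to-scan medians 11--56 min, scan-to-needle medians
#' 21--44 min, eligibility 31--52%).
#'
#' If `p_eligible` is supplied (the usual case) the decision rule's
#' aggressiveness offset is calibrated by Monte-Carlo so the mean
#' decision-to-treat probability over the case mix equals `p_eligible`.
#' If an explicit `decision_rule` with an aggressiveness offset is supplied
#' instead, `p_eligible` is derived from it.
#'
#' @param spec named list of profile fields to override (see fields below).
#' @param seed integer seed for the calibration draw.
#' @return a `hospital_profile` with fields `hospital_id`,
#'   `annual_admissions`, `p_onset_known`, `p_arrive_within_4h`,
#'   `onset_to_arrival_dist`, `arrival_to_scan_dist`, `scan_to_needle_dist`,
#'   `p_ischaemic`, `p_eligible`, `p_not_scanned_within_4h`, `age_dist`,
#'   `case_mix`, `decision_rule`.
#' @export
#' @examples
#' p <- make_hospital_profile(list(p_onset_known = 0.44))
#' p$p_onset_known
make_hospital_profile <- function(spec = list(), seed = 1L) {
  defaults <- list(
    hospital_id = "H1",
    annual_admissions = 560,
    p_onset_known = 0.60,
    p_arrive_within_4h = 0.58,
    onset_to_arrival_dist = time_dist(95, 0.55, truncate_max = 240),
    arrival_to_scan_dist = time_dist(25, 0.50),
    scan_to_needle_dist = time_dist(30, 0.40),
    p_ischaemic = 0.85,
    p_eligible = 0.40,
    p_not_scanned_within_4h = 0,
    age_dist = list(mean = 74, sd = 12),
    case_mix = case_mix(),
    decision_rule = NULL
  )
  unknown <- setdiff(names(spec), names(defaults))
  if (length(unknown))
    stop("unknown profile field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  prof <- utils::modifyList(defaults, spec, keep.null = TRUE)

  for (p in c("p_onset_known", "p_arrive_within_4h", "p_ischaemic",
              "p_eligible", "p_not_scanned_within_4h")) {
    if (!is.null(prof[[p]])) stop_if_not_prob(prof[[p]], p)
  }
  if (!is.numeric(prof$annual_admissions) || prof$annual_admissions < 1)
    stop("annual_admissions must be >= 1", call. = FALSE)
  for (d in c("onset_to_arrival_dist", "arrival_to_scan_dist", "scan_to_needle_dist")) {
    if (!inherits(prof[[d]], "time_dist"))
      prof[[d]] <- do.call(time_dist, as.list(prof[[d]]))
    if (prof[[d]]$median <= 0) stop("time distribution median must be positive", call. = FALSE)
  }
  if (is.null(prof$onset_to_arrival_dist$truncate_max))
    prof$onset_to_arrival_dist$truncate_max <- 240

  if (is.null(prof$decision_rule)) {
    prof$decision_rule <- calibrate_aggressiveness(
      decision_rule(), prof$case_mix, prof$age_dist, prof$p_eligible, seed = seed)
  } else {
    if (!inherits(prof$decision_rule, "decision_rule"))
      prof$decision_rule <- do.call(decision_rule, as.list(prof$decision_rule))
    if (is.null(spec$p_eligible)) {
      prof$p_eligible <- implied_p_eligible(prof$decision_rule, prof$case_mix,
                                            prof$age_dist, seed = seed)
    }
  }
  structure(prof, class = "hospital_profile")
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat("Hospital pathway profile:", x$hospital_id, "\n")
  cat(sprintf("  annual admissions:        %.0f\n", x$annual_admissions))
  cat(sprintf("  P(onset time known):      %.3f\n", x$p_onset_known))
  cat(sprintf("  P(arrive <4h | known):    %.3f\n", x$p_arrive_within_4h))
  cat(sprintf("  P(ischaemic):             %.3f\n", x$p_ischaemic))
  cat(sprintf("  P(judged eligible):       %.3f\n", x$p_eligible))
  cat(sprintf("  onset-to-arrival:  median %.0f min (dispersion %.2f, <=%.0f)\n",
              x$onset_to_arrival_dist$median, x$onset_to_arrival_dist$dispersion,
              x$onset_to_arrival_dist$truncate_max))
  cat(sprintf("  arrival-to-scan:   median %.0f min (dispersion %.2f)\n",
              x$arrival_to_scan_dist$median, x$arrival_to_scan_dist$dispersion))
  cat(sprintf("  scan-to-needle:    median %.0f min (dispersion %.2f)\n",
              x$scan_to_needle_dist$median, x$scan_to_needle_dist$dispersion))
  if (x$p_not_scanned_within_4h > 0)
    cat(sprintf("  P(not scanned <4h of arrival): %.2f\n", x$p_not_scanned_within_4h))
  invisible(x)
}

#' Reference set of seven synthetic hospital profiles
#'
#' Seven profiles spanning the between-hospital variation reported for
#' English acute stroke units: proportion of known onset times 44--73%,
#' arrival-to-scan medians 11--56 min, scan-to-needle medians 21--44 min and
#' clinical-eligibility predisposition 31--52%, with roughly 520--600
#' admissions per hospital per year (about 7870 records over two years in
#' total). These are synthetic profiles, not any real hospital's parameters.
#'
#' @param seed seed for decision-rule calibration.
#' @return named list of seven [make_hospital_profile()] objects.
#' @export
reference_hospital_profiles <- function(seed = 1L) {
  tab <- data.frame(
    hospital_id = paste0("H", 1:7),
    annual_admissions = c(560, 530, 600, 520, 550, 580, 590),
    p_onset_known = c(0.73, 0.55, 0.60, 0.44, 0.48, 0.70, 0.58),
    p_arrive_within_4h = c(0.58, 0.55, 0.55, 0.60, 0.62, 0.60, 0.57),
    ota_median = c(90, 100, 95, 110, 105, 85, 100),
    ota_disp = c(0.55, 0.55, 0.50, 0.60, 0.55, 0.50, 0.55),
    a2s_median = c(14, 30, 26, 40, 56, 11, 22),
    a2s_disp = c(0.45, 0.50, 0.50, 0.55, 0.50, 0.45, 0.50),
    s2n_median = c(24, 28, 36, 30, 21, 29, 44),
    s2n_disp = c(0.40, 0.40, 0.40, 0.40, 0.35, 0.40, 0.40),
    p_eligible = c(0.52, 0.35, 0.48, 0.33, 0.49, 0.44, 0.31),
    sev_logit_mean = c(-1.3, -1.5, -1.2, -1.5, -1.4, -1.4, -1.6)
  )
  profs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    make_hospital_profile(list(
      hospital_id = r$hospital_id,
      annual_admissions = r$annual_admissions,
      p_onset_known = r$p_onset_known,
      p_arrive_within_4h = r$p_arrive_within_4h,
      onset_to_arrival_dist = time_dist(r$ota_median, r$ota_disp, truncate_max = 240),
      arrival_to_scan_dist = time_dist(r$a2s_median, r$a2s_disp),
      scan_to_needle_dist = time_dist(r$s2n_median, r$s2n_disp),
      p_eligible = r$p_eligible,
      case_mix = case_mix(sev_logit_mean = r$sev_logit_mean)
    ), seed = seed)
  })
  names(profs) <- tab$hospital_id
  profs
}

#' Read and write hospital profiles as YAML configuration
#'
#' Profiles are serialised with keys mirroring the `hospital_profile` fields;
#' nested time distributions carry `median`, `dispersion` and (for
#' onset-to-arrival) `truncate_max` keys.
#'
#' @param profiles named list of `hospital_profile` objects.
#' @param path file path.
#' @return `read_hospital_profiles` returns a named list of profiles.
#' @export
write_hospital_profiles <- function(profiles, path) {
  if (inherits(profiles, "hospital_profile")) profiles <- list(profiles)
  plain <- lapply(profiles, function(p) {
    p <- unclass(p)
    p$onset_to_arrival_dist <- unclass(p$onset_to_arrival_dist)
    p$arrival_to_scan_dist <- unclass(p$arrival_to_scan_dist)
    p$scan_to_needle_dist <- unclass(p$scan_to_needle_dist)
    p$case_mix <- unclass(p$case_mix)
    p$decision_rule <- unclass(p$decision_rule)
    p
  })
  names(plain) <- vapply(profiles, function(p) p$hospital_id, character(1))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_hospital_profiles
#' @export
read_hospital_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  profs <- lapply(raw, function(p) {
    p$onset_to_arrival_dist <- do.call(time_dist, p$onset_to_arrival_dist)
    p$arrival_to_scan_dist <- do.call(time_dist, p$arrival_to_scan_dist)
    p$scan_to_needle_dist <- do.call(time_dist, p$scan_to_needle_dist)
    p$case_mix <- do.call(case_mix, p$case_mix)
    dr <- p$decision_rule
    p$decision_rule <- NULL
    prof <- make_hospital_profile(p)
    if (!is.null(dr)) prof$decision_rule <- do.call(decision_rule, dr)
    prof
  })
  names(profs) <- vapply(profs, function(p) p$hospital_id, character(1))
  profs
}
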