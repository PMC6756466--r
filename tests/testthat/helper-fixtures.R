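# Profile with degenerate (zero-variance) process times and a fixed age,
# so pathway outcomes reduce to gate draws plus window arithmetic.
degenerate_profile <- function(ota = 30, a2s = 15, s2n = 15,
                               gates = c(1, 1, 1, 1), age_mean = 70,
                               annual = 1000) {
  make_hospital_profile(list(
    annual_admissions = annual,
    p_onset_known = gates[1],
    p_arrive_within_4h = gates[2],
    p_ischaemic = gates[3],
    p_eligible = gates[4],
    onset_to_arrival_dist = time_dist(ota, 0, truncate_max = 240),
    arrival_to_scan_dist = time_dist(a2s, 0),
    scan_to_needle_dist = time_dist(s2n, 0),
    age_dist = list(mean = age_mean, sd = 0)
  ))
}

# One synthetic patient record with overridable pathway fields, for
# exercising the decision-model inclusion filter.
make_record <- function(age = 75, onset_known = TRUE, ota = 100, a2s = 20,
                        stroke_type = "ischaemic", treated = FALSE) {
  r <- synthesize_cohort(make_hospital_profile(list(annual_admissions = 1)),
                         years = 1, seed = 1)
  r$age <- age
  r$onset_known <- onset_known
  r$onset_to_arrival_min <- if (onset_known) ota else NA_real_
  r$arrival_to_scan_min <- a2s
  r$stroke_type <- stroke_type
  r$thrombolysis_given <- treated
  r
}

# Degenerate classifier spec (predicts the training majority class): cheap
# stand-in for testing fold structure without fitting forests.
majority_classifier <- function() {
  structure(list(
    fit = function(features, labels, seed) as.integer(mean(labels) >= 0.5),
    predict = function(model, features) rep(model, nrow(features))
  ), class = "classifier_spec")
}
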