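#' Outcome-model parameters
#'
#' Converts an onset-to-treatment time (OTT) into the probability that
#' thrombolysis yields an additional good outcome (modified Rankin Scale
#' 0--1, no significant disability). The treatment effect is expressed as an
#' odds ratio for mRS 0--1 that declines with OTT; the default curve has a
#' log odds ratio linear in time, calibrated to the pooled alteplase-trials
#' meta-analysis interval estimates (OR 1.75 for treatment within 3 h and
#' OR 1.26 for 3--4.5 h, anchored at the interval midpoints 90 and 225 min):
#' `log OR(t) = 0.77862 - 0.0024334 t`. Any monotone non-increasing curve
#' may be supplied instead. Benefit is exactly zero at or beyond
#' `max_benefit_min`.
#'
#' @param p_good_untreated baseline probability of mRS 0--1 without
#'   thrombolysis.
#' @param log_or_intercept,log_or_slope coefficients of the default log-OR
#'   line (slope per minute, must be <= 0).
#' @param max_benefit_min minutes at and beyond which additional benefit is 0.
#'   The default 270 matches the strict simulator window, in which treatment
#'   never occurs later.
#' @param effect_curve optional function `f(ott_min) -> odds ratio`,
#'   overriding the log-linear default; must be monotone non-increasing.
#' @return an `outcome_params` object.
#' @export
#' @examples
#' op <- outcome_params()
#' prob_additional_good_outcome(90, op)
outcome_params <- function(p_good_untreated = 0.30,
                           log_or_intercept = 0.77862,
                           log_or_slope = -0.0024334,
                           max_benefit_min = 270,
                           effect_curve = NULL) {
  stop_if_not_prob(p_good_untreated, "p_good_untreated")
  if (is.null(effect_curve)) {
    if (log_or_slope > 0)
      stop("log_or_slope must be <= 0 (benefit cannot grow with time)", call. = FALSE)
    effect_curve <- function(t) exp(log_or_intercept + log_or_slope * t)
  }
  stopifnot(is.function(effect_curve), max_benefit_min > 0)
  structure(list(p_good_untreated = p_good_untreated,
                 effect_curve = effect_curve,
                 max_benefit_min = max_benefit_min),
            class = "outcome_params")
}

#' Probability of an additional good outcome from thrombolysis
#'
#' Applies the treatment odds ratio at the given onset-to-treatment time to
#' the baseline odds of a good outcome and returns the absolute increase in
#' probability: `p_treated(ott) - p_good_untreated`, clamped to zero at and
#' beyond `max_benefit_min`.
#'
#' @param ott_min onset-to-treatment time in minutes (>= 0); vectorised.
#' @param params an [outcome_params()] object.
#' @return probability of an additional disability-free outcome.
#' @export
#' @examples
#' prob_additional_good_outcome(c(60, 180, 270), outcome_params())
prob_additional_good_outcome <- function(ott_min, params = outcome_params()) {
  stopifnot(inherits(params, "outcome_params"))
  if (any(!is.finite(ott_min)) || any(ott_min < 0))
    stop("onset-to-treatment time must be non-negative", call. = FALSE)
  or <- params$effect_curve(ott_min)
  odds0 <- params$p_good_untreated / (1 - params$p_good_untreated)
  p_treated <- (odds0 * or) / (1 + odds0 * or)
  benefit <- p_treated - params$p_good_untreated
  benefit[ott_min >= params$max_benefit_min] <- 0
  pmax(benefit, 0)
}

#' Additional good outcomes per 1000 admissions
#'
#' Sums each treated patient's probability of an additional good outcome and
#' scales to a rate per 1000 admissions.
#'
#' @param treated_otts onset-to-treatment times (minutes) of treated
#'   patients; may be empty.
#' @param n_admissions total admissions in the period (>= 1).
#' @param params an [outcome_params()] object.
#' @return `1000 * sum(prob) / n_admissions`.
#' @export
good_outcomes_per_1000 <- function(treated_otts, n_admissions,
                                   params = outcome_params()) {
  if (!is.numeric(n_admissions) || n_admissions < 1)
    stop("n_admissions must be >= 1", call. = FALSE)
  if (length(treated_otts) > n_admissions)
    stop("more treated patients than admissions", call. = FALSE)
  if (!length(treated_otts)) return(0)
  1000 * sum(prob_additional_good_outcome(treated_otts, params)) / n_admissions
}
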