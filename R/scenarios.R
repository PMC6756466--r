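#' Define a what-if scenario
#'
#' A scenario is a named set of overrides applied to a hospital profile
#' before simulation. Fixed process times become zero-variance distributions;
#' `onset_known_floor` raises the proportion of known onset times only where
#' a hospital currently performs below the floor.
#'
#' The standard scenarios mirror common service-improvement levers:
#' * `A` — arrival-to-scan and scan-to-needle both fixed at 15 min with no
#'   variation,
#' * `B` — 60% of ischaemic patients scanned with 30 min left judged eligible
#'   (the proportion an analysis of ECASS-3/IST-3 suggests is suitable),
#' * `C` — onset time known fixed at 77% (national upper-quartile),
#' * `ABC` — all three combined,
#' * `alternative` — onset-known floored at the national median 67%,
#'   arrival-to-scan and scan-to-needle fixed at 20 min with 10% of patients
#'   not scanned within 4 h of arrival, and eligibility taken from a
#'   benchmark clinical-decision model (see [benchmark_eligibility()]).
#'
#' @param name scenario label.
#' @param fix_arrival_to_scan_min,fix_scan_to_needle_min fixed process times
#'   in minutes, or NULL to leave the profile's distribution untouched.
#' @param fix_p_eligible,fix_p_onset_known fixed gate probabilities or NULL.
#' @param onset_known_floor floor on `p_onset_known`, applied only if above
#'   the profile's current value. At most one of `fix_p_onset_known` /
#'   `onset_known_floor` may be set.
#' @param p_not_scanned_within_4h proportion of patients not scanned within
#'   4 h of arrival, or NULL.
#' @param eligibility_source one of "profile", "fixed", "benchmark".
#' @return a `scenario` object.
#' @export
scenario <- function(name,
                     fix_arrival_to_scan_min = NULL,
                     fix_scan_to_needle_min = NULL,
                     fix_p_eligible = NULL,
                     fix_p_onset_known = NULL,
                     onset_known_floor = NULL,
                     p_not_scanned_within_4h = NULL,
                     eligibility_source = c("profile", "fixed", "benchmark")) {
  eligibility_source <- match.arg(eligibility_source)
  if (!is.null(fix_p_onset_known) && !is.null(onset_known_floor))
    stop("at most one of 'fix_p_onset_known' and 'onset_known_floor' may be set",
         call. = FALSE)
  for (p in list(fix_p_eligible = fix_p_eligible,
                 fix_p_onset_known = fix_p_onset_known,
                 onset_known_floor = onset_known_floor,
                 p_not_scanned_within_4h = p_not_scanned_within_4h)) {
    if (!is.null(p) && !is_prob(p))
      stop("scenario probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(fix_p_eligible) && eligibility_source == "profile")
    eligibility_source <- "fixed"
  structure(list(name = name,
                 fix_arrival_to_scan_min = fix_arrival_to_scan_min,
                 fix_scan_to_needle_min = fix_scan_to_needle_min,
                 fix_p_eligible = fix_p_eligible,
                 fix_p_onset_known = fix_p_onset_known,
                 onset_known_floor = onset_known_floor,
                 p_not_scanned_within_4h = p_not_scanned_within_4h,
                 eligibility_source = eligibility_source),
            class = "scenario")
}

#' @rdname scenario
#' @export
standard_scenarios <- function() {
  list(
    base = scenario("base"),
    A = scenario("A", fix_arrival_to_scan_min = 15, fix_scan_to_needle_min = 15),
    B = scenario("B", fix_p_eligible = 0.60),
    C = scenario("C", fix_p_onset_known = 0.77),
    ABC = scenario("ABC", fix_arrival_to_scan_min = 15,
                   fix_scan_to_needle_min = 15,
                   fix_p_eligible = 0.60, fix_p_onset_known = 0.77)
  )
}

#' @rdname scenario
#' @export
alternative_scenario <- function() {
  scenario("alternative",
           fix_arrival_to_scan_min = 20, fix_scan_to_needle_min = 20,
           onset_known_floor = 0.67, p_not_scanned_within_4h = 0.10,
           eligibility_source = "benchmark")
}

#' Apply a scenario's overrides to a hospital profile
#'
#' @param profile a [make_hospital_profile()] object.
#' @param scen a [scenario()] object (NULL = no change).
#' @param benchmark_p_eligible eligibility probability from a benchmark
#'   decision model; required when the scenario's `eligibility_source` is
#'   "benchmark".
#' @return a new `hospital_profile` with overridden fields.
#' @export
#' @examples
#' p <- make_hospital_profile(list(p_onset_known = 0.44))
#' a <- apply_scenario(p, standard_scenarios()$C)
#' a$p_onset_known  # 0.77
apply_scenario <- function(profile, scen = NULL, benchmark_p_eligible = NULL) {
  stopifnot(inherits(profile, "hospital_profile"))
  if (is.null(scen)) return(profile)
  stopifnot(inherits(scen, "scenario"))
  out <- profile
  if (!is.null(scen$fix_arrival_to_scan_min))
    out$arrival_to_scan_dist <- time_dist(scen$fix_arrival_to_scan_min, 0)
  if (!is.null(scen$fix_scan_to_needle_min))
    out$scan_to_needle_dist <- time_dist(scen$fix_scan_to_needle_min, 0)
  if (!is.null(scen$fix_p_onset_known))
    out$p_onset_known <- scen$fix_p_onset_known
  if (!is.null(scen$onset_known_floor))
    out$p_onset_known <- max(out$p_onset_known, scen$onset_known_floor)
  if (!is.null(scen$p_not_scanned_within_4h))
    out$p_not_scanned_within_4h <- scen$p_not_scanned_within_4h
  if (scen$eligibility_source == "benchmark") {
    if (is.null(benchmark_p_eligible))
      stop("scenario '", scen$name, "' takes its eligibility from a benchmark ",
           "decision model; supply 'benchmark_p_eligible'", call. = FALSE)
    stop_if_not_prob(benchmark_p_eligible, "benchmark_p_eligible")
    out$p_eligible <- benchmark_p_eligible
  } else if (!is.null(scen$fix_p_eligible)) {
    out$p_eligible <- scen$fix_p_eligible
  }
  out
}
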