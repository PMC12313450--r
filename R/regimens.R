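#' Convert benzylpenicillin international units to milligrams
#'
#' Uses the international unit convention for benzylpenicillin sodium,
#' 1 IU = 0.6 ug (1,000,000 IU = 600 mg); the factor is configurable.
#'
#' @param iu Amount in IU (>= 0).
#' @param mg_per_iu Conversion factor, mg per IU.
#' @return Amount in mg.
#' @export
iu_to_mg <- function(iu, mg_per_iu = 6e-4) {
  if (any(iu < 0)) stop("IU amount must be >= 0", call. = FALSE)
  iu * mg_per_iu
}

#' Load a dosing-regimen catalog
#'
#' @param path YAML catalog; defaults to the catalog shipped with the package
#'   (DPF, GA-based and continuous benzylpenicillin regimens fully specified;
#'   other international formularies as untranscribed stubs).
#' @return A named list of regimen definitions, class `regimen_catalog`.
#' @export
regimen_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "regimens.yaml", package = "neopkpd")
  }
  cat <- yaml::read_yaml(path)
  structure(cat, class = "regimen_catalog", path = path)
}

#' Write a regimen catalog back to YAML
#'
#' Catalogs round-trip: `regimen_catalog(write_regimen_catalog(cat, f))`
#' reproduces the same definitions.
#'
#' @param catalog A `regimen_catalog`.
#' @param path Output path.
#' @export
write_regimen_catalog <- function(catalog, path) {
  yaml::write_yaml(unclass(catalog)[names(catalog)], path, precision = 15)
  invisible(path)
}

.rule_matches <- function(rule, subject) {
  ok <- TRUE
  bw <- subject$birth_weight
  ga <- subject$GA
  if (!is.null(rule$birth_weight_min)) ok <- ok && bw >= rule$birth_weight_min
  if (!is.null(rule$birth_weight_max)) ok <- ok && bw < rule$birth_weight_max
  if (!is.null(rule$ga_min)) ok <- ok && ga >= rule$ga_min
  if (!is.null(rule$ga_max)) ok <- ok && ga < rule$ga_max
  ok
}

#' Resolve a dosing regimen into an explicit dose schedule
#'
#' Matches the subject against the regimen's stratification rules (exactly one
#' must match) and expands it over the window:
#' \itemize{
#'   \item intermittent: doses of `dose_per_kg x birth_weight` (IU converted
#'     to mg) at `0, interval, 2*interval, ... < window`, each given as a
#'     5-minute infusion (or the regimen's `infusion_duration`);
#'   \item continuous: a loading dose of `loading_fraction` of the total daily
#'     dose over 5 minutes at `t = 0`, concurrent with a constant-rate
#'     infusion delivering `daily_dose_per_kg x birth_weight` per 24 h for the
#'     whole window.
#' }
#'
#' @param subject List/row with `birth_weight` (kg), `GA` (weeks), optional `id`.
#' @param regimen A single regimen definition from [regimen_catalog()], or a
#'   regimen name looked up in the default catalog.
#' @param window Window length, h (default 48).
#' @param mg_per_iu IU-to-mg conversion factor.
#' @return A [dose_schedule()].
#' @export
resolve_regimen <- function(subject, regimen, window = 48, mg_per_iu = 6e-4) {
  if (is.character(regimen)) {
    cat <- regimen_catalog()
    if (is.null(cat[[regimen]])) {
      stop("unknown regimen '", regimen, "'", call. = FALSE)
    }
    regimen <- cat[[regimen]]
  }
  if (identical(regimen$status, "stub")) {
    stop("regimen is an untranscribed stub; supply its numeric rules in the catalog",
         call. = FALSE)
  }
  subject <- as.list(subject)
  sid <- if (is.null(subject$id)) NA else subject$id
  hits <- which(vapply(regimen$rules, .rule_matches, logical(1), subject = subject))
  if (length(hits) != 1) {
    stop(sprintf("subject %s (bw %.3g kg, GA %.3g w): %d regimen rules match (need exactly 1)",
                 as.character(sid), subject$birth_weight, subject$GA,
                 length(hits)), call. = FALSE)
  }
  rule <- regimen$rules[[hits]]
  in_mg <- function(x) if (identical(regimen$dose_unit, "IU")) iu_to_mg(x, mg_per_iu) else x
  dur <- if (is.null(regimen$infusion_duration)) 0.0833 else regimen$infusion_duration

  if (identical(regimen$mode, "continuous")) {
    daily <- in_mg(rule$daily_dose_per_kg * subject$birth_weight)
    loading <- regimen$loading_fraction * daily
    sched <- dose_schedule(
      start_time = c(0, 0),
      amount = c(loading, daily * window / 24),
      duration = c(dur, window),
      subject_id = sid
    )
  } else {
    starts <- seq(0, by = rule$interval,
                  length.out = ceiling(window / rule$interval))
    starts <- starts[starts < window - 1e-9]
    amt <- in_mg(rule$dose_per_kg * subject$birth_weight)
    sched <- dose_schedule(starts, amt, dur, subject_id = sid)
  }
  sched
}

#' GA-based alternative benzylpenicillin regimen
#'
#' 30,000 IU/kg per dose, every 12 h below GA 28 weeks, every 8 h from 28 to
#' below 36 weeks, every 6 h from 36 weeks (GA exactly 36 assigned to the
#' 6-hourly stratum).
#'
#' @inheritParams resolve_regimen
#' @return A [dose_schedule()].
#' @export
alternative_ga_regimen <- function(subject, window = 48, mg_per_iu = 6e-4) {
  resolve_regimen(subject, "ga_based_benzylpenicillin", window, mg_per_iu)
}

#' Total amount delivered by a schedule
#'
#' @param schedule A [dose_schedule()].
#' @return Total mg across all events.
#' @export
total_dose <- function(schedule) sum(schedule$amount)
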