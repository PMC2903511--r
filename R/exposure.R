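# Exposure inputs: multi-route dosing profiles, unit conversion to the
# internal molar basis (umol, umol/h, h), and intake scaling switches.

#' Split an oral intake into absorbed and unabsorbed-fecal fractions
#'
#' @param intake_rate Oral intake rate (any mass/time unit).
#' @param F_abs Fractional gastrointestinal absorption in `[0, 1]`.
#' @return Named vector `c(absorbed, fecal)` in the units of `intake_rate`.
#' @export
gi_absorption_split <- function(intake_rate, F_abs) {
  if (F_abs < 0 || F_abs > 1) stop("F_abs must lie in [0, 1]")
  c(absorbed = F_abs * intake_rate, fecal = (1 - F_abs) * intake_rate)
}

# molar volume of an ideal gas at 25 C, 1 atm (L/mol)
MOLAR_VOLUME_25C <- 24.45

#' Convert an inhaled gas concentration to an alveolar uptake term
#'
#' Converts ppm (by volume) to a molar air concentration via the ideal-gas
#' molar volume at 25 degrees C (24.45 L/mol), so
#' `C_air (umol/L) = ppm / 24.45`, and returns the continuous alveolar
#' uptake rate `Q_alv * C_air` together with the matching first-order
#' exhalation clearance `Q_alv / P_ba` applied to blood. Together these two
#' terms form the standard steady-inhalation gas-exchange mass balance.
#'
#' @param concentration_ppm Air concentration (ppm v/v).
#' @param alveolar_ventilation Alveolar ventilation rate (L/h).
#' @param blood_air_partition Blood:air partition coefficient.
#' @return List with `c_air_umol_L`, `uptake_umol_h`,
#'   `exhalation_clearance_L_h`.
#' @export
inhalation_intake <- function(concentration_ppm, alveolar_ventilation,
                              blood_air_partition) {
  if (concentration_ppm < 0) stop("air concentration must be >= 0")
  c_air <- concentration_ppm / MOLAR_VOLUME_25C
  list(c_air_umol_L = c_air,
       uptake_umol_h = alveolar_ventilation * c_air,
       exhalation_clearance_L_h = alveolar_ventilation / blood_air_partition)
}

#' Define an exposure profile
#'
#' A time-resolved dosing description for one chemical on one route, in
#' internal units (umol and hours). Use [convert_dose()] to translate from
#' field units (ug/day, ug/kg/day, mg, ppm). Continuous dietary intake is
#' piecewise-constant zero-order input; boluses are instantaneous state
#' jumps applied at solver restarts.
#'
#' @param chemical Chemical name.
#' @param route `"oral_bolus"`, `"oral_continuous"` or `"inhalation"`.
#' @param events List of events. For continuous routes
#'   `list(start=, end=, magnitude=)` with magnitude in umol/h
#'   (umol/L air for inhalation); for boluses `list(time=, amount=)` in
#'   umol. `end = Inf` means "until the end of the simulation".
#' @param F_abs Fractional oral absorption (ignored for inhalation).
#' @param target State receiving the absorbed input: a compartment name or
#'   `c(compartment, sub)`; defaults to `"blood"`.
#' @param alveolar_ventilation Alveolar ventilation (L/h), inhalation only.
#' @param scaling_switches List of `list(time=, factor=)` intake scaling
#'   switch-points; magnitudes are multiplied by `factor` for `t >= time`.
#' @return An `exposure_profile` object.
#' @export
exposure_profile <- function(chemical, route = c("oral_continuous", "oral_bolus", "inhalation"),
                             events, F_abs = 1, target = "blood",
                             alveolar_ventilation = NULL,
                             scaling_switches = list()) {
  route <- match.arg(route)
  if (F_abs < 0 || F_abs > 1) stop("F_abs must lie in [0, 1]")
  for (ev in events) {
    mag <- if (route == "oral_bolus") ev$amount else ev$magnitude
    if (is.null(mag) || mag < 0) stop("exposure event magnitudes must be >= 0")
  }
  if (route != "oral_bolus") {
    starts <- vapply(events, function(e) e$start, numeric(1))
    if (is.unsorted(starts)) stop("exposure events must be time-ordered")
  }
  for (sw in scaling_switches) {
    if (sw$factor <= 0) stop("scaling factors must be > 0")
  }
  if (route == "inhalation" && is.null(alveolar_ventilation))
    stop("inhalation profiles need 'alveolar_ventilation' (L/h)")
  structure(list(chemical = chemical, route = route, events = events,
                 F_abs = F_abs, target = as.character(target),
                 alveolar_ventilation = alveolar_ventilation,
                 scaling_switches = scaling_switches),
            class = "exposure_profile")
}

#' Convert a dosed quantity to internal molar units
#'
#' @param magnitude Numeric dose or rate.
#' @param units One of `"ug/day"`, `"ug/kg/day"`, `"ug/h"`, `"umol/h"`
#'   (rates), `"ug"`, `"mg"`, `"umol"` (amounts), `"ppm"` (air).
#' @param molecular_mass Molar mass (g/mol); needed for mass units.
#' @param body_mass Body mass (kg); needed for per-kg units.
#' @return Value in umol/h (rates), umol (amounts) or umol/L (air).
#' @export
convert_dose <- function(magnitude, units, molecular_mass = NULL, body_mass = NULL) {
  need_mw <- function() {
    if (is.null(molecular_mass)) stop("unit conversion needs molecular_mass")
    molecular_mass
  }
  switch(units,
    "umol/h" = magnitude,
    "umol"   = magnitude,
    "ug/day" = magnitude / 24 / need_mw(),
    "ug/h"   = magnitude / need_mw(),
    "ug/kg/day" = {
      if (is.null(body_mass)) stop("ug/kg/day conversion needs body_mass")
      magnitude * body_mass / 24 / need_mw()
    },
    "ug"  = magnitude / need_mw(),
    "mg"  = magnitude * 1000 / need_mw(),
    "ppm" = magnitude / MOLAR_VOLUME_25C,
    stop(sprintf("unknown units '%s'", units))
  )
}

#' Scale intakes from a switch-point onward
#'
#' Registers a multiplicative scaling switch (e.g. a 40% step means
#' `factor = 1.4`) on the selected profiles, applied to all event
#' magnitudes for `t >= t_switch` and recorded as a solver restart event.
#'
#' @param profiles List of [exposure_profile()] objects.
#' @param factor Multiplicative factor, > 0.
#' @param t_switch Switch time (h).
#' @param chemicals Chemicals to scale; default all.
#' @return The updated list of profiles.
#' @export
scale_intakes <- function(profiles, factor, t_switch, chemicals = NULL) {
  if (factor <= 0) stop("scaling factor must be > 0")
  lapply(profiles, function(p) {
    if (!is.null(chemicals) && !(p$chemical %in% chemicals)) return(p)
    if (factor != 1)
      p$scaling_switches <- c(p$scaling_switches, list(list(time = t_switch, factor = factor)))
    p
  })
}

# product of scaling factors active at time t (switches apply for t >= time)
profile_scale <- function(profile, t) {
  s <- 1
  for (sw in profile$scaling_switches) if (t >= sw$time) s <- s * sw$factor
  s
}

# event breakpoint times a profile contributes to the solver schedule
profile_breakpoints <- function(profile) {
  ts <- numeric()
  for (ev in profile$events) {
    if (profile$route == "oral_bolus") ts <- c(ts, ev$time)
    else ts <- c(ts, ev$start, if (is.finite(ev$end)) ev$end)
  }
  for (sw in profile$scaling_switches) ts <- c(ts, sw$time)
  ts
}

# closed-form cumulative administered amount of a profile up to time t
# (piecewise-constant rates; boluses counted when t >= event time)
profile_administered <- function(profile, t, alveolar_ventilation = NULL) {
  tot <- 0
  if (profile$route == "oral_bolus") {
    for (ev in profile$events) {
      if (t >= ev$time) tot <- tot + ev$amount * profile_scale(profile, ev$time)
    }
    return(tot)
  }
  qa <- if (profile$route == "inhalation") profile$alveolar_ventilation else 1
  for (ev in profile$events) {
    lo <- ev$start; hi <- min(ev$end, t)
    if (hi <= lo) next
    cuts <- sort(unique(c(lo, hi,
                          Filter(function(x) x > lo && x < hi,
                                 vapply(profile$scaling_switches, `[[`, numeric(1), "time")))))
    for (i in seq_len(length(cuts) - 1L)) {
      mid <- (cuts[i] + cuts[i + 1L]) / 2
      tot <- tot + ev$magnitude * qa * profile_scale(profile, mid) * (cuts[i + 1L] - cuts[i])
    }
  }
  tot
}
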