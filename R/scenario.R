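# Scenario configuration files (YAML/JSON), result serialization and the
# command-line entry point.

#' Read and validate a scenario file
#'
#' A scenario bundles a physiology reference, the chemical models to
#' instantiate, exposure events (with mandatory units), intake scaling
#' switches, interaction specs and simulation settings. Validation errors
#' carry the offending field.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` scenario file.
#' @return A validated `pbtk_scenario` object wrapping the parsed
#'   document.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  validate_scenario(raw, origin = path)
}

#' Validate a scenario document
#'
#' @param raw Parsed scenario list.
#' @param origin Label used in error messages.
#' @return A `pbtk_scenario`.
#' @export
validate_scenario <- function(raw, origin = "scenario") {
  fail <- function(field, msg) stop(sprintf("%s: field '%s': %s", origin, field, msg))
  if (is.null(raw$models) || !length(raw$models)) fail("models", "at least one model required")
  known <- c("cadmium", "lead", "chromium", "mehg", "arsenic", "voc")
  for (m in raw$models) {
    if (is.null(m$model)) fail("models", "entry without 'model'")
    if (!m$model %in% known) fail("models", sprintf("unknown model '%s'", m$model))
  }
  for (i in seq_along(raw$exposures)) {
    ex <- raw$exposures[[i]]
    f <- function(x) sprintf("exposures[%d].%s", i, x)
    if (is.null(ex$chemical)) fail(f("chemical"), "missing")
    if (is.null(ex$route)) fail(f("route"), "missing")
    if (!ex$route %in% c("oral_continuous", "oral_bolus", "inhalation"))
      fail(f("route"), sprintf("unknown route '%s'", ex$route))
    if (is.null(ex$magnitude)) fail(f("magnitude"), "missing")
    if (is.null(ex$units)) fail(f("units"), "missing (units are mandatory on every dosed quantity)")
    if (ex$route == "oral_bolus" && is.null(ex$time_h)) fail(f("time_h"), "missing for bolus")
  }
  for (i in seq_along(raw$scaling)) {
    sw <- raw$scaling[[i]]
    if (is.null(sw$time_h) || is.null(sw$factor))
      fail(sprintf("scaling[%d]", i), "needs 'time_h' and 'factor'")
    if (sw$factor <= 0) fail(sprintf("scaling[%d].factor", i), "must be > 0")
  }
  sim <- raw$simulation
  if (is.null(sim) || is.null(sim$t_end_h)) fail("simulation.t_end_h", "missing")
  if (sim$t_end_h <= 0) fail("simulation.t_end_h", "must be > 0")
  structure(list(raw = raw, origin = origin), class = "pbtk_scenario")
}

#' Write a scenario back to a file
#'
#' @param scenario A `pbtk_scenario`.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(scenario$raw, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(scenario$raw, path)
  invisible(path)
}

#' Instantiate the models and exposures of a scenario
#'
#' @param scenario A `pbtk_scenario`.
#' @return List with the combined `model`, `exposures`, `interactions`
#'   and `simulation` settings.
#' @export
build_scenario <- function(scenario) {
  raw <- scenario$raw
  body <- if (is.null(raw$physiology) || identical(raw$physiology, "reference_adult"))
    reference_adult() else load_physiology(raw$physiology)
  models <- lapply(raw$models, function(m) {
    switch(m$model,
      cadmium = build_cadmium_model(sex = if (is.null(m$sex)) "male" else m$sex, body = body),
      lead = build_lead_model(body = body),
      chromium = build_chromium_model(body = body),
      mehg = build_mehg_model(pregnancy = isTRUE(m$pregnancy),
                              lactation = isTRUE(m$lactation), body = body),
      arsenic = build_arsenic_model(body = body),
      voc = build_voc_model(body = body))
  })
  joint <- if (length(models) == 1L) {
    models[[1L]]
  } else combine_models_with_hooks(models, name = if (is.null(raw$name)) "scenario" else raw$name)
  exposures <- lapply(raw$exposures, function(ex) {
    start <- if (is.null(ex$start_h)) 0 else ex$start_h
    end <- if (is.null(ex$end_h)) Inf else ex$end_h
    switch(ex$route,
      oral_continuous = {
        if (ex$units == "ug/kg/day")
          dietary_profile(joint, ex$chemical, ug_per_kg_day = ex$magnitude,
                          start = start, end = end)
        else if (ex$units == "ug/day")
          dietary_profile(joint, ex$chemical, ug_per_day = ex$magnitude,
                          start = start, end = end)
        else stop(sprintf("%s: unsupported continuous-dose units '%s'",
                          scenario$origin, ex$units))
      },
      oral_bolus = {
        if (ex$units == "mg") bolus_profile(joint, ex$chemical, mg = ex$magnitude, time = ex$time_h)
        else if (ex$units == "ug") bolus_profile(joint, ex$chemical, ug = ex$magnitude, time = ex$time_h)
        else stop(sprintf("%s: unsupported bolus units '%s'", scenario$origin, ex$units))
      },
      inhalation = {
        if (ex$units != "ppm")
          stop(sprintf("%s: inhalation units must be 'ppm', got '%s'",
                       scenario$origin, ex$units))
        inhalation_profile(joint, ex$chemical, ex$magnitude, start = start, end = end)
      })
  })
  for (sw in raw$scaling) {
    exposures <- scale_intakes(exposures, sw$factor, sw$time_h,
                               chemicals = if (is.null(sw$chemicals)) NULL else unlist(sw$chemicals))
  }
  interactions <- lapply(raw$interactions, function(ia) {
    switch(ia$kind,
      competitive = interaction_spec("competitive", targets = unlist(ia$targets),
                                     chemical = ia$chemical, I = ia$I, name = ia$name),
      noncompetitive = interaction_spec("noncompetitive", targets = unlist(ia$targets),
                                        chemical = ia$chemical, compartment = ia$compartment,
                                        K_nc = ia$K_nc, name = ia$name),
      induction = interaction_spec("induction", targets = unlist(ia$targets),
                                   factor = ia$factor, name = ia$name),
      metal_vmax_modulation = interaction_spec(
        "metal_vmax_modulation", targets = unlist(ia$targets),
        sources = lapply(ia$sources, function(s)
          list(chemical = s$chemical, compartment = s$compartment, weight = s$weight)),
        tau = if (is.null(ia$tau_h)) 24 else ia$tau_h, name = ia$name),
      stop(sprintf("%s: unknown interaction kind '%s'", scenario$origin, ia$kind)))
  })
  list(model = joint, exposures = exposures, interactions = interactions,
       simulation = raw$simulation)
}

#' Run a scenario end to end
#'
#' @param scenario A `pbtk_scenario` (or path to one).
#' @return A `pbtk_result`.
#' @export
run_scenario <- function(scenario) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  built <- build_scenario(scenario)
  sim <- built$simulation
  sys <- assemble_model(built$model, exposures = built$exposures,
                        interactions = built$interactions)
  grid <- if (!is.null(sim$report_dt_h)) seq(0, sim$t_end_h, by = sim$report_dt_h) else NULL
  simulate_system(sys, sim$t_end_h, report_grid = grid,
                  rtol = if (is.null(sim$rtol)) 1e-8 else sim$rtol,
                  atol = if (is.null(sim$atol)) 1e-12 else sim$atol)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write trajectory and ledger CSV files
#'
#' The trajectory CSV has columns `time_h, chemical, compartment,
#' subcompartment, amount_umol, concentration_umol_per_L`; a ledger CSV
#' (same path with `_ledger` suffix) holds the cumulative
#' administered/excreted/transformed columns. Numbers are written with
#' 17 significant digits so a reload is bit-exact.
#'
#' @param result A `pbtk_result`.
#' @param path Output CSV path.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- as.data.frame(result)
  out <- data.frame(time_h = fmt17(df$time_h), chemical = df$chemical,
                    compartment = df$compartment, subcompartment = df$subcompartment,
                    amount_umol = fmt17(df$amount_umol),
                    concentration_umol_per_L = fmt17(df$concentration_umol_per_L),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  lpath <- sub("(\\.csv)?$", "_ledger.csv", path)
  led <- as.data.frame(result$ledger)
  led <- cbind(time_h = result$time, led)
  led[] <- lapply(led, fmt17)
  utils::write.csv(led, lpath, row.names = FALSE, quote = TRUE)
  invisible(c(trajectory = path, ledger = lpath))
}

#' Read a trajectory CSV back
#'
#' @param path Path written by [write_timeseries()].
#' @return data.frame in the long trajectory format.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(time_h = "numeric", amount_umol = "numeric",
                                       concentration_umol_per_L = "numeric"))
  df$subcompartment[is.na(df$subcompartment)] <- ""
  df
}
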