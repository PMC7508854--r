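#' Read / write temperature-series spectra CSV
#'
#' Dialect: first column `wavenumber_cm-1`; every remaining column header is
#' a temperature in degC. Columns arriving out of temperature order are
#' sorted (with a warning); ragged rows, non-monotone wavenumbers or
#' non-numeric cells raise a parse error naming the offending row/column.
#'
#' @param path CSV file path.
#' @return [read_spectrum_series()]: a [spectrum_series].
#' @export
read_spectrum_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm-1")
    stop("first column must be 'wavenumber_cm-1', got '", names(df)[1], "'")
  temps <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(temps)))
    stop("non-numeric temperature header in column(s): ",
         paste(which(is.na(temps)) + 1, collapse = ", "))
  for (j in seq_along(df))
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop("non-numeric cell at row ", bad, ", column ", j)
    }
  if (is.unsorted(temps, strictly = TRUE)) {
    warning("temperature columns not in ascending order; sorting")
    ord <- order(temps)
    df <- df[, c(1L, ord + 1L)]
    temps <- temps[ord]
  }
  spectrum_series(df[[1]], temps, as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_spectrum_series
#' @param series a [spectrum_series].
#' @export
write_spectrum_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(series$wavenumbers, series$absorbance,
                   check.names = FALSE)
  names(df) <- c("wavenumber_cm-1", format(series$temperatures,
                                           trim = TRUE, digits = 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write melting-curve CSV (`temperature_C, signal`)
#'
#' @param path CSV file path.
#' @param sample optional [sample_spec] attached to the curve.
#' @param observable observable label for the curve.
#' @return A [melting_curve]; temperatures are converted to Kelvin.
#' @export
read_melting_curve <- function(path, sample = NULL, observable = "ir_svd") {
  df <- utils::read.csv(path)
  stopifnot(all(c("temperature_C", "signal") %in% names(df)))
  melting_curve(celsius_to_kelvin(df$temperature_C), df$signal,
                observable = observable, sample = sample)
}

#' @rdname read_melting_curve
#' @param curve a [melting_curve].
#' @export
write_melting_curve <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  utils::write.csv(data.frame(temperature_C =
                                kelvin_to_celsius(curve$temperatures),
                              signal = curve$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write kinetic-trace CSV (`time_s, dSprime`)
#'
#' @param path CSV file path.
#' @param frequency probe wavenumber (cm^-1) for the trace.
#' @param protocol optional [tjump_protocol].
#' @param noise_sigma optional per-point noise sd (estimated when NULL).
#' @return A [kinetic_trace].
#' @export
read_kinetic_trace <- function(path, frequency = NA_real_, protocol = NULL,
                               noise_sigma = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "dSprime") %in% names(df)))
  kinetic_trace(df$time_s, df$dSprime, frequency = frequency,
                protocol = protocol, noise_sigma = noise_sigma)
}

#' @rdname read_kinetic_trace
#' @param trace a [kinetic_trace].
#' @export
write_kinetic_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  utils::write.csv(data.frame(time_s = trace$times, dSprime = trace$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a rate distribution CSV (`rate_per_s, amplitude`)
#'
#' @param dist a [rate_distribution].
#' @param path CSV file path.
#' @export
write_rate_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "rate_distribution"))
  utils::write.csv(data.frame(rate_per_s = dist$rates,
                              amplitude = dist$amplitude),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## deterministic FNV-1a hash of the serialized config, for provenance
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.pipeline_schema <- list(
  required = c("model", "seed"),
  optional = c("C_D", "fluorescence_C_D", "T_i_C", "dT", "noise_sigma",
               "T_f_grid_C", "mem", "stages", "out"))

#' Validate a pipeline configuration
#'
#' Checks the configuration list against the pipeline schema: required keys
#' present, no unknown keys, values of the right type. Called by
#' [run_pipeline()] before any computation.
#'
#' @param config named list.
#' @return The config, with defaults filled in.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  missing <- setdiff(.pipeline_schema$required, names(config))
  if (length(missing))
    stop("config missing required key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(config),
                     c(.pipeline_schema$required, .pipeline_schema$optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!config$model %in% c("complex", "duplex"))
    stop("config$model must be 'complex' or 'duplex'")
  defaults <- list(C_D = 1e-3, fluorescence_C_D = c(2e-6, 2e-7),
                   T_i_C = 70, dT = 15, noise_sigma = 0.01,
                   T_f_grid_C = c(60, 70, 80, 85, 90, 95),
                   mem = list(), stages = c("simulate", "extract",
                                            "fit_melt", "fit_kinetics",
                                            "mem", "report"),
                   out = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  stopifnot(is.numeric(config$seed), config$C_D > 0)
  config
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes the stages in dependency order on synthetic data generated from
#' the configured scenario:
#'
#' 1. `simulate` - build the [tjump_scenario] from the config.
#' 2. `extract` - generate the temperature-series spectra, extract the IR
#'    melting curve by SVD; for the complex model also generate
#'    fluorescence curves at the lower concentrations.
#' 3. `fit_melt` - global two-state fit of all curves.
#' 4. `fit_kinetics` - relaxation rates at the configured final
#'    temperatures, separated into k_a/k_d with the *fitted* melting
#'    thermodynamics, then Eyring regression of both directions.
#' 5. `mem` - generate the T-jump traces at the protocol temperature,
#'    invert with MEM, and compute the amplitude-weighted mean rate.
#' 6. `report` - assemble the result bundle (and write JSON when
#'    `config$out` is set).
#'
#' All randomness derives from `config$seed`; rerunning with the same
#' config reproduces the bundle exactly (modulo the timestamp).
#'
#' @param config named list, see [validate_config()].
#' @return A `result_bundle` list: `provenance` (package version, config
#'   hash, seed, timestamp), `truth` (generating parameters), `melting`,
#'   `kinetics`, `mem` stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  bundle <- list(provenance = list(
    package = "tjumpmelt",
    version = as.character(utils::packageVersion("tjumpmelt")),
    config_hash = .config_hash(config[setdiff(names(config), "out")]),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scenario <- stage("simulate", tjump_scenario(
    model = config$model, C_D = config$C_D, T_i_C = config$T_i_C,
    dT = config$dT, noise_sigma = config$noise_sigma,
    seed = config$seed))
  bundle$truth <- list(dH0 = scenario$thermo$dH0, dS0 = scenario$thermo$dS0,
                       dH_act_a = scenario$eyring_assoc$dH_act,
                       dS_act_a = scenario$eyring_assoc$dS_act,
                       dH_act_d = scenario$eyring_dissoc$dH_act,
                       dS_act_d = scenario$eyring_dissoc$dS_act)

  curves <- stage("extract", {
    # span this sample's transition (the global fit needs complete curves;
    # at 1 mM the complex transition extends past a 5-100 degC ramp)
    Tm <- melting_temperature(scenario$thermo, scenario$sample)
    series <- generate_melting_series(scenario,
      temperatures_C = kelvin_to_celsius(seq(Tm - 45, Tm + 45,
                                             length.out = 33)))
    cv <- svd_melting_curve(series, sample = scenario$sample)
    curves <- list(cv)
    if (config$model == "complex")
      for (i in seq_along(config$fluorescence_C_D)) {
        sc_i <- tjump_scenario(model = "complex",
                               C_D = config$fluorescence_C_D[i],
                               T_i_C = config$T_i_C, dT = config$dT,
                               noise_sigma = config$noise_sigma,
                               seed = config$seed + i)
        Tm_i <- melting_temperature(sc_i$thermo, sc_i$sample)
        grid <- seq(Tm_i - 45, Tm_i + 45, length.out = 40)
        curves <- c(curves, list(generate_fluorescence_curve(sc_i, grid)))
      }
    curves
  })

  fit <- stage("fit_melt", fit_two_state(curves, model = config$model))
  bundle$melting <- list(
    dH0 = fit$dH0, dS0 = fit$dS0, se_dH0 = fit$se_dH0, se_dS0 = fit$se_dS0,
    residual_rms = fit$residual_rms, n_points = fit$n_points,
    T0_K = reference_temperature(fit),
    T0_C = kelvin_to_celsius(reference_temperature(fit)))

  bundle$kinetics <- stage("fit_kinetics", {
    T_f <- celsius_to_kelvin(config$T_f_grid_C)
    lam <- vapply(T_f, function(Tf)
      predicted_relaxation_rate(scenario$eyring_assoc, scenario$thermo,
                                scenario$sample, Tf)$lambda_obs, numeric(1))
    rcs <- lapply(seq_along(T_f), function(i)
      rate_constants_from_relaxation(lam[i], fit, scenario$sample, T_f[i]))
    ka <- vapply(rcs, `[[`, numeric(1), "k_a")
    kd <- vapply(rcs, `[[`, numeric(1), "k_d")
    ea <- fit_eyring(T_f, ka, direction = "association",
                     model = config$model)
    ed <- fit_eyring(T_f, kd, direction = "dissociation",
                     model = config$model)
    list(T_f_C = config$T_f_grid_C, lambda_obs = lam, k_a = ka, k_d = kd,
         assoc = list(dH_act = ea$dH_act, dS_act = ea$dS_act,
                      se_dH_act = ea$se_dH_act),
         dissoc = list(dH_act = ed$dH_act, dS_act = ed$dS_act,
                       se_dH_act = ed$se_dH_act))
  })

  bundle$mem <- stage("mem", {
    traces <- generate_tjump_traces(scenario)
    settings <- do.call(mem_settings, config$mem)
    dists <- lapply(traces, mem_invert, settings = settings)
    wm <- weighted_mean_rate(dists)
    # summarize the slow dissociation phase apart from the fast (~3e7 s^-1)
    # terminal response; 3e6 s^-1 sits in the gap between the two classes
    slow <- tryCatch(weighted_mean_rate(dists, exclude_above = 3e6),
                     error = function(e) list(mean_rate = NA_real_,
                                              sd_rate = NA_real_))
    list(mean_rate = wm$mean_rate, sd_rate = wm$sd_rate,
         mean_rate_dissociation = slow$mean_rate,
         sd_rate_dissociation = slow$sd_rate,
         per_frequency = wm$per_frequency,
         chi2_per_point = vapply(dists, `[[`, numeric(1), "chi2_per_point"),
         lambda_obs_true = attr(traces, "truth")$lambda_obs)
  })

  class(bundle) <- "result_bundle"
  if (!is.null(config$out)) write_result_bundle(bundle, config$out)
  bundle
}

#' Serialize / read back a result bundle as JSON
#'
#' The JSON layout is documented in the schema shipped at
#' `system.file("extdata", "result-bundle-schema.json", package =
#' "tjumpmelt")`; [validate_result_bundle()] checks conformance.
#'
#' @param bundle a `result_bundle` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_result_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_result_bundle
#' @export
read_result_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(b) <- "result_bundle"
  b
}

#' @rdname write_result_bundle
#' @export
validate_result_bundle <- function(bundle) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "result-bundle-schema.json",
                                            package = "tjumpmelt"))
  need <- names(schema$properties)
  missing <- setdiff(unlist(schema$required), names(bundle))
  if (length(missing))
    stop("result bundle missing section(s): ",
         paste(missing, collapse = ", "))
  for (sec in intersect(need, names(bundle))) {
    sub <- schema$properties[[sec]]$required
    miss <- setdiff(unlist(sub), names(bundle[[sec]]))
    if (length(miss))
      stop("result bundle section '", sec, "' missing field(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
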