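## Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gaussian peak in a synthetic basis spectrum
#'
#' @param center peak center (cm^-1).
#' @param width Gaussian sigma (cm^-1), > 0.
#' @param amplitude peak amplitude (OD); signed values are allowed when
#'   building difference spectra.
#' @param state which basis the peak belongs to: `"ds"` (intact duplex),
#'   `"ss"` (single strands) or `"ligand_bound"` (extra features of the
#'   ligand-bound duplex, e.g. the shifted thymine carbonyl).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width, amplitude,
                      state = c("ds", "ss", "ligand_bound")) {
  state <- match.arg(state)
  stopifnot(width > 0, is.finite(amplitude))
  structure(list(center = center, width = width, amplitude = amplitude,
                 state = state), class = "peak_spec")
}

#' Default basis peak set
#'
#' Emulates the marker structure of duplex melting in the base ring/carbonyl
#' region: the adenine ring mode at 1622 cm^-1 and guanine ring modes at
#' 1564/1575 cm^-1 are suppressed in the stacked, hydrogen-bonded duplex and
#' gain intensity in the single strands; the carbonyl envelope near
#' 1668 cm^-1 and the guanine ring mode at 1546 cm^-1 dominate the duplex
#' basis; the thymine carbonyl sits at 1698 cm^-1 and acquires a 1702 cm^-1
#' shoulder when the minor-groove ligand is bound. Amplitudes give a peak
#' OD near 1 so the default noise level (0.01) corresponds to SNR ~ 100.
#'
#' @param model `"duplex"` (no ligand features) or `"complex"` (adds the
#'   1702 cm^-1 bound-thymine shoulder to the duplex basis).
#' @return List of [peak_spec]s.
#' @export
default_peak_set <- function(model = c("complex", "duplex")) {
  model <- match.arg(model)
  peaks <- list(
    peak_spec(1668, 14, 1.00, "ds"),
    peak_spec(1546,  8, 0.45, "ds"),
    peak_spec(1698,  6, 0.30, "ds"),
    peak_spec(1622, 10, 0.10, "ds"),   # residual A-ring intensity in duplex
    peak_spec(1622, 10, 0.85, "ss"),
    peak_spec(1564,  8, 0.40, "ss"),
    peak_spec(1575,  8, 0.40, "ss"),
    peak_spec(1668, 14, 0.55, "ss"),
    peak_spec(1546,  8, 0.15, "ss"),
    peak_spec(1698,  6, 0.25, "ss"))
  if (model == "complex")
    peaks <- c(peaks, list(peak_spec(1702, 6, 0.25, "ligand_bound")))
  peaks
}

## Evaluate the summed Gaussian basis for one state on a wavenumber grid.
.basis_spectrum <- function(peaks, wavenumbers, states) {
  y <- numeric(length(wavenumbers))
  for (p in peaks)
    if (p$state %in% states)
      y <- y + p$amplitude * exp(-(wavenumbers - p$center)^2 / (2 * p$width^2))
  y
}

#' Synthetic study scenario
#'
#' Bundles the ground-truth parameters from which all synthetic inputs are
#' generated. The defaults are the study conditions of the modeled
#' experiments: 1 mM duplex-equivalent concentration, a 15 K jump from
#' 70 degC, melting thermodynamics of 415 kJ/mol and 1000 J/mol/K for the
#' concerted ligand-bound complex (403 kJ/mol and 1088 J/mol/K for the
#' native duplex), the corresponding association activation parameters, a
#' fast terminal G:C response at 3e7 s^-1, and thermal re-equilibration at
#' 2e2 s^-1 (below the 4e2 s^-1 analysis cutoff).
#'
#' @param model `"complex"` (ligand-bound) or `"duplex"` (native).
#' @param thermo melting [thermo_params]; default per `model` as above.
#' @param eyring_assoc association [eyring_params]; default per `model`.
#' @param C_D duplex-equivalent concentration (M).
#' @param T_i_C initial temperature (degC); the protocol jumps by `dT` K.
#' @param dT jump magnitude (K).
#' @param peaks list of [peak_spec]s; default [default_peak_set()].
#' @param fast_phase_rate fast-phase rate (s^-1), within the MEM grid.
#' @param thermal_rate thermal re-equilibration rate (s^-1), < 4e2.
#' @param thermal_amplitude amplitude of the (negative) thermal component.
#' @param amplitudes named list of per-marker phase amplitudes, each a
#'   `c(fast =, slow =)` pair; defaults depend on `model` (see
#'   [generate_tjump_traces()]).
#' @param noise_sigma additive Gaussian noise sd for all generators.
#' @param seed integer seed; every generator is a pure function of
#'   (scenario, seed).
#' @return An object of class `tjump_scenario`.
#' @export
tjump_scenario <- function(model = c("complex", "duplex"),
                           thermo = NULL, eyring_assoc = NULL,
                           C_D = 1e-3, T_i_C = 70, dT = 15,
                           peaks = default_peak_set(model),
                           fast_phase_rate = 3e7,
                           thermal_rate = 2e2,
                           thermal_amplitude = 0.2,
                           amplitudes = NULL,
                           noise_sigma = 0.01, seed = 1L) {
  model <- match.arg(model)
  if (is.null(thermo))
    thermo <- if (model == "complex") thermo_params(415e3, 1000, "complex")
              else thermo_params(403e3, 1088, "duplex")
  if (is.null(eyring_assoc))
    eyring_assoc <- if (model == "complex")
      eyring_params(-2.48e5, -754, "association", "complex")
    else eyring_params(-2.63e4, -187, "association", "duplex")
  stopifnot(thermo$model == model, eyring_assoc$model == model,
            thermal_rate < 4e2, fast_phase_rate >= 1e1,
            fast_phase_rate <= 1e8, noise_sigma >= 0)
  if (is.null(amplitudes))
    amplitudes <- if (model == "complex")
      list(A = c(fast = 0.00, slow = 0.40),
           G = c(fast = 0.66, slow = 0.34),
           R = c(fast = 0.33, slow = 0.33))
    else
      list(A = c(fast = 0.50, slow = 0.50),
           G = c(fast = 0.50, slow = 0.50),
           R = c(fast = 0.50, slow = 0.50))
  structure(list(
    model = model, thermo = thermo, eyring_assoc = eyring_assoc,
    eyring_dissoc = dissociation_eyring_from_association(eyring_assoc, thermo),
    sample = sample_spec(C_D),
    protocol = tjump_protocol(celsius_to_kelvin(T_i_C), dT),
    peaks = peaks, fast_phase_rate = fast_phase_rate,
    thermal_rate = thermal_rate, thermal_amplitude = thermal_amplitude,
    amplitudes = amplitudes, noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "tjump_scenario")
}

#' Generate a temperature-series spectrum matrix
#'
#' Builds \eqn{A(\nu, T) = \theta(T) B_{ds}(\nu) + (1-\theta(T))
#' B_{ss}(\nu) + \varepsilon} with the intact fraction \eqn{\theta(T)} from
#' the scenario's melting model, Gaussian basis spectra from the scenario's
#' peaks (ligand-bound peaks join the duplex basis in the complex model),
#' and iid Gaussian noise of sd `noise_sigma`. Noise-free output has exact
#' rank 2. Reproducible from the scenario seed.
#'
#' @param scenario a [tjump_scenario].
#' @param temperatures_C temperature grid (degC), ascending; the default
#'   emulates a 5-100 degC ramp in 3 degC steps.
#' @param wavenumbers probe grid (cm^-1).
#' @return A [spectrum_series]; attribute `theta_true` carries the
#'   generating intact fraction.
#' @export
generate_melting_series <- function(scenario,
                                    temperatures_C = seq(5, 98, by = 3),
                                    wavenumbers = seq(1500, 1750, by = 2)) {
  stopifnot(inherits(scenario, "tjump_scenario"))
  theta <- vapply(celsius_to_kelvin(temperatures_C), function(T)
    solve_equilibrium(scenario$thermo, scenario$sample, T)$theta, numeric(1))
  ds_states <- if (scenario$model == "complex") c("ds", "ligand_bound") else "ds"
  B_ds <- .basis_spectrum(scenario$peaks, wavenumbers, ds_states)
  B_ss <- .basis_spectrum(scenario$peaks, wavenumbers, "ss")
  A <- outer(B_ds, theta) + outer(B_ss, 1 - theta)
  if (scenario$noise_sigma > 0)
    A <- A + .with_seed(scenario$seed,
      matrix(stats::rnorm(length(A), 0, scenario$noise_sigma),
             nrow = nrow(A)))
  out <- spectrum_series(wavenumbers, temperatures_C, A)
  attr(out, "theta_true") <- theta
  out
}

#' Generate a fluorescence melting curve
#'
#' Fluorescence of the bound ligand is modeled as proportional to the
#' complex fraction \eqn{[DH](T)/C_D} (the ligand fluoresces when held
#' rigid in the minor groove), plus Gaussian noise. The returned
#' [melting_curve] stores dissociation progress in `signal` (so all fitting
#' code sees one convention) and the normalized intensity, 1 at low
#' temperature, in `intensity`.
#'
#' @param scenario a [tjump_scenario] with `model = "complex"`.
#' @param T_grid_K temperatures (K), ascending.
#' @return A [melting_curve] (observable `"fluorescence"`).
#' @export
generate_fluorescence_curve <- function(scenario, T_grid_K) {
  stopifnot(inherits(scenario, "tjump_scenario"),
            scenario$model == "complex")
  f_DH <- vapply(T_grid_K, function(T)
    predicted_complex_fraction(scenario$thermo, scenario$sample, T),
    numeric(1))
  noise <- if (scenario$noise_sigma > 0)
    .with_seed(scenario$seed + 1L,
               stats::rnorm(length(f_DH), 0, scenario$noise_sigma))
  else 0
  # as-measured affine normalization; the map flips the decreasing
  # intensity into dissociation progress (0 at low T, 1 at high T)
  signal <- .normalize_curve(f_DH + noise)
  intensity <- 1 - signal
  cv <- melting_curve(T_grid_K, signal, observable = "fluorescence",
                      sample = scenario$sample, theta = intensity)
  cv$intensity <- intensity
  cv
}

#' Generate T-jump kinetic traces at the marker frequencies
#'
#' Per marker frequency, the fractional signal is a bimodal rise plus a
#' slow negative thermal-recovery component:
#' \deqn{\Delta S'(t) = a_{fast}(1 - e^{-\lambda_{fast} t}) +
#'   a_{slow}(1 - e^{-\lambda_{obs} t}) -
#'   a_{th}(1 - e^{-\lambda_{th} t}) + \varepsilon}
#' with \eqn{\lambda_{obs}} computed from the scenario thermodynamics and
#' association activation parameters at `T_f`
#' ([predicted_relaxation_rate()]), \eqn{\lambda_{fast}} the fast terminal
#' G:C phase and \eqn{\lambda_{th}} the thermal re-equilibration rate. The
#' amplitude split follows the scenario: for the ligand-bound complex the
#' G marker carries both phases, the A marker only the slow dissociation
#' phase (ligand binding suppresses the early A:T response), and for the
#' native duplex both phases are comparable at every marker.
#'
#' @param scenario a [tjump_scenario].
#' @param frequencies subset of `c("A", "G", "R")` (1607, 1546, 1668 cm^-1).
#' @param times observation delays (s); default 64 log-spaced points from
#'   1e-8 to 5e-2 s.
#' @param thermal logical; include the thermal component (default TRUE).
#' @return Named list of [kinetic_trace]s; attribute `truth` records
#'   `lambda_obs`, the planted rates and per-marker amplitudes.
#' @export
generate_tjump_traces <- function(scenario, frequencies = c("A", "G", "R"),
                                  times = 10^seq(log10(1e-8), log10(5e-2),
                                                 length.out = 64),
                                  thermal = TRUE) {
  stopifnot(inherits(scenario, "tjump_scenario"),
            all(frequencies %in% c("A", "G", "R")))
  marker_wn <- c(A = 1607, G = 1546, R = 1668)
  pred <- predicted_relaxation_rate(scenario$eyring_assoc, scenario$thermo,
                                    scenario$sample, scenario$protocol$T_f)
  traces <- list()
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    a <- scenario$amplitudes[[f]]
    y <- a[["fast"]] * (1 - exp(-scenario$fast_phase_rate * times)) +
         a[["slow"]] * (1 - exp(-pred$lambda_obs * times))
    if (thermal)
      y <- y - scenario$thermal_amplitude *
        (1 - exp(-scenario$thermal_rate * times))
    if (scenario$noise_sigma > 0)
      y <- y + .with_seed(scenario$seed + 10L + i,
                          stats::rnorm(length(times), 0,
                                       scenario$noise_sigma))
    traces[[f]] <- kinetic_trace(times, y, frequency = marker_wn[[f]],
                                 protocol = scenario$protocol,
                                 noise_sigma = max(scenario$noise_sigma,
                                                   1e-6))
  }
  attr(traces, "truth") <- list(
    lambda_obs = pred$lambda_obs, k_a = pred$k_a, k_d = pred$k_d,
    fast_phase_rate = scenario$fast_phase_rate,
    thermal_rate = scenario$thermal_rate,
    amplitudes = scenario$amplitudes[frequencies])
  traces
}
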