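#' Temperature-series absorption spectra
#'
#' @param wavenumbers strictly increasing probe axis (cm^-1).
#' @param temperatures strictly increasing temperatures (degC; instrument
#'   files use Celsius, conversion to Kelvin happens when fitting).
#' @param absorbance matrix of optical density, wavenumber x temperature.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(wavenumbers, temperatures, absorbance) {
  absorbance <- as.matrix(absorbance)
  stopifnot(!is.unsorted(wavenumbers, strictly = TRUE),
            !is.unsorted(temperatures, strictly = TRUE),
            nrow(absorbance) == length(wavenumbers),
            ncol(absorbance) == length(temperatures),
            all(is.finite(absorbance)))
  structure(list(wavenumbers = wavenumbers, temperatures = temperatures,
                 absorbance = absorbance), class = "spectrum_series")
}

#' Normalized melting curve
#'
#' @param temperatures temperatures (K), ascending.
#' @param signal normalized dissociation progress, nominally in \[0, 1\]
#'   (small noise excursions to \[-0.05, 1.05\] are allowed).
#' @param observable `"ir_svd"` or `"fluorescence"`.
#' @param sample the [sample_spec] the curve was measured at.
#' @param theta optional companion intact-fraction curve (`1 - signal`).
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperatures, signal,
                          observable = c("ir_svd", "fluorescence"),
                          sample = NULL, theta = 1 - signal) {
  observable <- match.arg(observable)
  stopifnot(length(temperatures) == length(signal),
            !is.unsorted(temperatures), all(is.finite(signal)))
  if (any(signal < -0.05 - 1e-9) || any(signal > 1.05 + 1e-9))
    warning("normalized signal outside [-0.05, 1.05]")
  structure(list(temperatures = temperatures, signal = signal, theta = theta,
                 observable = observable, sample = sample),
            class = "melting_curve")
}

## Affine normalization using the mean of the 3 lowest-T and 3 highest-T
## points as the folded/unfolded baselines. No sloping-baseline term.
.normalize_curve <- function(y) {
  n <- length(y)
  k <- min(3L, n)
  lo <- mean(y[seq_len(k)])
  hi <- mean(y[seq.int(n - k + 1L, n)])
  if (abs(hi - lo) < .Machine$double.eps * 10)
    stop("curve has no amplitude to normalize")
  (y - lo) / (hi - lo)
}

#' Extract a melting curve from temperature-series spectra by SVD
#'
#' The spectra matrix is decomposed as \eqn{A = U \Sigma V^T}. For a
#' two-state transition the matrix is rank 2 (folded and unfolded basis
#' spectra mixed by \eqn{\theta(T)}), and the second right-singular vector
#' carries the temperature dependence of the transition. Its amplitude
#' \eqn{\sigma_2 v_2(T)} is sign-fixed to increase with temperature
#' (singular-vector signs are arbitrary) and affinely normalized to \[0, 1\]
#' using the mean of the 3 lowest- and highest-temperature points. The
#' returned `signal` is the dissociation progress \eqn{1 - \theta};
#' the companion `theta` field holds the intact fraction.
#'
#' The extraction is invariant to positive rescaling of the spectra and to
#' adding any temperature-independent background spectrum (a background only
#' feeds the first component).
#'
#' @param series a [spectrum_series] with >= 3 temperatures and >= 2
#'   wavenumbers.
#' @param sample optional [sample_spec] attached to the curve.
#' @return A [melting_curve] (observable `"ir_svd"`) with extra fields
#'   `singular_values` and `rank2_fraction` (variance captured by the first
#'   two components).
#' @export
svd_melting_curve <- function(series, sample = NULL) {
  stopifnot(inherits(series, "spectrum_series"))
  A <- series$absorbance
  if (ncol(A) < 3 || nrow(A) < 2)
    stop("need at least 3 temperatures and 2 wavenumbers")
  sv <- svd(A)
  if (sv$d[2] / sv$d[1] < 1e-6)
    stop("degenerate series: second singular value at noise floor ",
         "(sigma2/sigma1 = ", signif(sv$d[2] / sv$d[1], 3), ")")
  comp <- sv$d[2] * sv$v[, 2]
  T_C <- series$temperatures
  if (stats::cor(comp, T_C) < 0) comp <- -comp
  signal <- .normalize_curve(comp)
  out <- melting_curve(celsius_to_kelvin(T_C), signal,
                       observable = "ir_svd", sample = sample)
  out$singular_values <- sv$d
  out$rank2_fraction <- sum(sv$d[1:2]^2) / sum(sv$d^2)
  out
}

## Deterministic initializer: temperatures where the normalized signal
## crosses 25% and 75% dissociation give two (T, K_d) points via the
## mass-action polynomial; a two-point van't Hoff line yields (dH0, dS0).
.init_two_state <- function(curves, model) {
  cross_T <- function(cv, level) {
    s <- cv$signal; T <- cv$temperatures
    i <- which(s >= level)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    # linear interpolation between bracketing points
    T[i - 1] + (level - s[i - 1]) / (s[i] - s[i - 1]) * (T[i] - T[i - 1])
  }
  kd_at <- function(x, C_D)
    if (model == "duplex") 4 * x^2 * C_D / (1 - x) else 4 * x^3 * C_D^2 / (1 - x)
  cv <- curves[[1]]
  C_D <- cv$sample$C_D
  T1 <- cross_T(cv, 0.25); T2 <- cross_T(cv, 0.75)
  if (!is.finite(T1) || !is.finite(T2) || T2 <= T1)
    stop("curve does not span its transition; cannot initialize fit")
  lnK1 <- log(kd_at(0.25, C_D)); lnK2 <- log(kd_at(0.75, C_D))
  R <- phys_const$R
  dH <- -R * (lnK2 - lnK1) / (1 / T2 - 1 / T1)
  dS <- (dH + R * T1 * lnK1) / T1
  c(dH, dS)
}

#' Global two-state fit of melting curves
#'
#' Least-squares estimate of a single (dH0, dS0) pair shared across one or
#' more normalized melting curves measured at different concentrations; each
#' curve is predicted through the mass-action solver with its own `C_D`.
#' The objective is unweighted residual sum of squares over all points
#' (per-point uncertainties are not generally available). Optimization uses
#' Levenberg-Marquardt on the residual vector, started from a deterministic
#' two-point van't Hoff initializer (25%/75% crossing temperatures), so no
#' random restarts are involved.
#'
#' @param curves a [melting_curve] or list of them; each must carry its
#'   [sample_spec] and span its transition (min signal < 0.3, max > 0.7).
#' @param model `"duplex"` or `"complex"`.
#' @return A [thermo_params] with extra fields `se_dH0`, `se_dS0` (standard
#'   errors), `residual_rms`, `n_points`, `covariance` and `fit` (the
#'   `nls.lm` object).
#' @export
fit_two_state <- function(curves, model = c("duplex", "complex")) {
  model <- match.arg(model)
  if (inherits(curves, "melting_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "melting_curve")),
            all(vapply(curves, function(cv) !is.null(cv$sample), logical(1))))
  for (cv in curves)
    if (min(cv$signal) > 0.3 || max(cv$signal) < 0.7)
      stop("each curve must span its transition ",
           "(min signal < 0.3 and max > 0.7 after normalization)")

  start <- .init_two_state(curves, model)
  # scaled parameters keep LM steps comparable: dH in 1e5 J, dS in 1e3 J/K.
  # The model curve passes through the same 3-point affine normalization as
  # the data, so the objective is invariant to the curves' normalization.
  resid_fun <- function(par) {
    p <- thermo_params(par[1] * 1e5, par[2] * 1e3, model)
    unlist(lapply(curves, function(cv) {
      x <- vapply(cv$temperatures,
                  function(T) solve_equilibrium(p, cv$sample, T)$x, numeric(1))
      if (diff(range(x)) > 1e-8) x <- .normalize_curve(x)
      x - cv$signal
    }))
  }
  fit <- minpack.lm::nls.lm(par = start / c(1e5, 1e3), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5)
    stop("two-state fit did not converge: ", fit$message,
         " (final deviance ", signif(fit$deviance, 4), ")")
  par <- fit$par * c(1e5, 1e3)
  out <- thermo_params(par[1], par[2], model)
  # an effectively step-like curve drives the cooperativity out of the
  # physically sensible range; flag rather than report silently
  out$boundary_flag <- abs(par[1]) > 2e6
  if (out$boundary_flag)
    warning("fitted enthalpy exceeds 2e6 J/mol; ",
            "curve is near the infinitely cooperative limit")
  n <- length(fit$fvec)
  covm <- tryCatch({
    s2 <- fit$deviance / max(n - 2, 1)
    s2 * solve(fit$hessian) * outer(c(1e5, 1e3), c(1e5, 1e3))
  }, error = function(e) matrix(NA_real_, 2, 2))
  out$se_dH0 <- sqrt(covm[1, 1])
  out$se_dS0 <- sqrt(covm[2, 2])
  out$covariance <- covm
  out$residual_rms <- sqrt(fit$deviance / n)
  out$n_points <- n
  out$fit <- fit
  out
}

#' Fit the stepwise three-state binding constant to a melting curve
#'
#' Diagnostic for the stepwise scheme 2S = D, D + H = DH: holding the
#' ligand-free duplex thermodynamics fixed, a single temperature-independent
#' binding constant `K_b` is fit by least squares of the three-state bound
#' fraction \eqn{[DH](T)/C_D} (normalized like the data) against the curve.
#' The optimum is found on \eqn{\log_{10} K_b} by golden-section search.
#'
#' Applied to data that truly follow the stepwise scheme, the fitted `K_b`
#' is independent of concentration; applied to data generated by concerted
#' dissociation (DH = H + 2S) it drifts by orders of magnitude across
#' concentrations, which is the model-rejection signature this function
#' exposes.
#'
#' @param curve a [melting_curve] with its [sample_spec] (signal read as
#'   dissociation progress of the complex).
#' @param duplex_params [thermo_params] of the ligand-free duplex.
#' @param T_eval temperature (K) at which the fitted constant is reported
#'   (the constant itself is temperature-independent in this scheme).
#' @param log10_bounds search interval for log10(K_b / M^-1).
#' @return A list with `K_b` (M^-1), `log10_K_b`, `T_eval`, `rss`, and
#'   `at_boundary` (TRUE when the optimum hit the search bounds).
#' @export
fit_three_state_Kb <- function(curve, duplex_params,
                               T_eval = celsius_to_kelvin(25),
                               log10_bounds = c(-2, 14)) {
  stopifnot(inherits(curve, "melting_curve"), !is.null(curve$sample),
            inherits(duplex_params, "thermo_params"),
            duplex_params$model == "duplex")
  sample <- curve$sample
  bound_frac <- function(lKb) {
    p3 <- three_state_params(duplex_params, 10^lKb)
    vapply(curve$temperatures,
           function(T) solve_three_state(p3, T, sample)$f_DH, numeric(1))
  }
  obj <- function(lKb) sum((1 - bound_frac(lKb) - curve$signal)^2)
  opt <- stats::optimize(obj, interval = log10_bounds, tol = 1e-6)
  at_boundary <- min(opt$minimum - log10_bounds[1],
                     log10_bounds[2] - opt$minimum) < 0.05
  list(K_b = 10^opt$minimum, log10_K_b = opt$minimum, T_eval = T_eval,
       rss = opt$objective, at_boundary = at_boundary)
}

#' Bound-complex fraction predicted by a melting model
#'
#' \eqn{[DH]/C_D} at temperature `T` under either the concerted two-state
#' description ([thermo_params] with `model = "complex"`) or the stepwise
#' three-state description ([three_state_params]). Fluorescence intensity of
#' the bound ligand is modeled as proportional to this fraction, so the
#' linearity of predicted fraction versus measured fluorescence across
#' concentrations discriminates the two schemes.
#'
#' @param params [thermo_params] (complex model) or [three_state_params].
#' @param sample a [sample_spec].
#' @param T temperature (K).
#' @return Bound fraction in \[0, 1\].
#' @export
predicted_complex_fraction <- function(params, sample, T) {
  if (inherits(params, "thermo_params")) {
    if (params$model != "complex")
      stop("two-state bound fraction requires complex-model parameters")
    solve_equilibrium(params, sample, T)$theta
  } else if (inherits(params, "three_state_params")) {
    solve_three_state(params, T, sample)$f_DH
  } else stop("params must be thermo_params or three_state_params")
}
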