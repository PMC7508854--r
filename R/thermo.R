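#' Standard dissociation thermodynamics for a melting transition
#'
#' Bundles the standard dissociation enthalpy and entropy that define
#' \eqn{\Delta G_d^0(T) = \Delta H_d^0 - T \Delta S_d^0 = -RT \ln K_d} for one
#' of the two dissociation reactions handled by the package:
#'
#' * `model = "duplex"`: D = 2S, the native duplex separating into two single
#'   strands. K_d carries units of M (`kd_units_power = 1`).
#' * `model = "complex"`: DH = H + 2S, concerted dissociation of the
#'   ligand-bound duplex into ligand plus two single strands. K_d carries
#'   units of M^2 (`kd_units_power = 2`).
#'
#' The unit power is stored with the parameters so that duplex and complex
#' equilibrium constants cannot be mixed silently in one expression.
#'
#' @param dH0 standard dissociation enthalpy (J mol^-1).
#' @param dS0 standard dissociation entropy (J mol^-1 K^-1).
#' @param model `"duplex"` or `"complex"`.
#' @return An object of class `thermo_params`.
#' @export
#' @examples
#' # native duplex: 403 kJ/mol, 1088 J/mol/K
#' thermo_params(403e3, 1088, "duplex")
thermo_params <- function(dH0, dS0, model = c("duplex", "complex")) {
  model <- match.arg(model)
  stopifnot(is.finite(dH0), is.finite(dS0))
  structure(
    list(dH0 = dH0, dS0 = dS0, model = model,
         kd_units_power = if (model == "duplex") 1L else 2L),
    class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Dissociation thermodynamics (%s model)\n", x$model))
  cat(sprintf("  dH0 = %.4g kJ/mol, dS0 = %.4g J/mol/K\n",
              x$dH0 / 1e3, x$dS0))
  cat(sprintf("  K_d in M^%d; T0 = dH0/dS0 = %.2f K (%.1f degC)\n",
              x$kd_units_power, x$dH0 / x$dS0,
              kelvin_to_celsius(x$dH0 / x$dS0)))
  invisible(x)
}

#' Sample composition for a melting experiment
#'
#' `C_D` is the duplex-equivalent total strand concentration: the total
#' concentration of native plus ligand-bound duplex counted as duplex, so a
#' fully dissociated sample has single-strand concentration `2 * C_D`. The
#' ligand, when present, is mixed 1:1 with the duplex.
#'
#' @param C_D duplex-equivalent concentration (M), > 0.
#' @param stoichiometry ligand:duplex mole ratio; only 1 is supported.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(C_D, stoichiometry = 1) {
  stopifnot(is.finite(C_D), C_D > 0, stoichiometry == 1)
  structure(list(C_D = C_D, stoichiometry = stoichiometry),
            class = "sample_spec")
}

#' Standard Gibbs free energy of dissociation
#'
#' \eqn{\Delta G_d^0(T) = \Delta H_d^0 - T \Delta S_d^0}.
#'
#' @param params a [thermo_params] object.
#' @param T temperature (K), > 0. Vectorized.
#' @return Free energy change (J mol^-1).
#' @export
#' @examples
#' gibbs_free_energy(thermo_params(403e3, 1088, "duplex"), 298.15)
gibbs_free_energy <- function(params, T) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive and finite (Kelvin)")
  params$dH0 - T * params$dS0
}

#' Equilibrium dissociation constant from van't Hoff parameters
#'
#' \eqn{K_d(T) = \exp(-\Delta G_d^0 / RT)}. Because \eqn{\Delta G^0/RT}
#' spans roughly -50 to +50 over the studied temperature range, the constant
#' is computed in log space and returned together with `log_Kd`; downstream
#' solvers consume the log form.
#'
#' @inheritParams gibbs_free_energy
#' @return A list with `Kd` (M or M^2 per `params$model`), `log_Kd`
#'   (natural log, dimensionless in the model's concentration units) and
#'   `kd_units_power`.
#' @export
#' @examples
#' dissociation_constant(thermo_params(415e3, 1000, "complex"), 343.15)
dissociation_constant <- function(params, T) {
  dG <- gibbs_free_energy(params, T)
  log_Kd <- -dG / (phys_const$R * T)
  list(Kd = exp(log_Kd), log_Kd = log_Kd,
       kd_units_power = params$kd_units_power)
}

## Monotone-residual bisection for the mass-action polynomials, followed by
## a few Newton steps so the relative residual reaches machine precision
## even when the root is many orders of magnitude below 1.
.bisect_fraction <- function(residual, dresidual = NULL, xtol = 1e-15) {
  lo <- 0; hi <- 1 - 1e-15
  if (residual(lo) >= 0) return(0)
  if (residual(hi) <= 0) return(hi)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (residual(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < xtol) break
  }
  x <- 0.5 * (lo + hi)
  if (!is.null(dresidual))
    for (i in 1:4) {
      step <- residual(x) / dresidual(x)
      if (!is.finite(step)) break
      x <- min(max(x - step, 0), 1 - 1e-15)
    }
  x
}

.equilibrium_state <- function(T, x, K_d, sample, model) {
  C_D <- sample$C_D
  structure(list(
    T = T, x = x, theta = 1 - x, K_d = K_d,
    conc_S = 2 * x * C_D,
    conc_D_or_DH = (1 - x) * C_D,
    conc_H = if (model == "complex") x * C_D else 0,
    model = model, C_D = C_D), class = "equilibrium_state")
}

#' Two-state duplex melting equilibrium D = 2S
#'
#' Solves the mass-action condition for the dissociated fraction `x`:
#' with \eqn{[S] = 2 x C_D} and \eqn{[D] = (1-x) C_D},
#' \deqn{K_d = [S]^2/[D] = 4 x^2 C_D / (1 - x).}
#' The left side of \eqn{4x^2 C_D - K_d (1-x) = 0} is strictly increasing on
#' \[0, 1), so the unique physical root is found by bisection; no closed-form
#' quadratic root selection is used, which stays robust when `K_d` is many
#' orders of magnitude above or below `C_D`.
#'
#' @param K_d dissociation constant (M), >= 0; alternatively pass the list
#'   returned by [dissociation_constant()].
#' @param sample a [sample_spec].
#' @param T temperature (K) recorded in the returned state (metadata only).
#' @return An `equilibrium_state`: fields `x`, `theta = 1 - x`, `conc_S`,
#'   `conc_D_or_DH`, `conc_H` (zero here), `K_d`.
#' @export
#' @examples
#' s <- sample_spec(1e-3)
#' solve_duplex_equilibrium(2e-3, s)$x  # K_d = 2 C_D gives x = 0.5
solve_duplex_equilibrium <- function(K_d, sample, T = NA_real_) {
  if (is.list(K_d)) K_d <- K_d$Kd
  stopifnot(inherits(sample, "sample_spec"))
  if (K_d < 0) stop("K_d must be non-negative")
  C_D <- sample$C_D
  x <- .bisect_fraction(function(x) 4 * x^2 * C_D - K_d * (1 - x),
                        function(x) 8 * x * C_D + K_d)
  .equilibrium_state(T, x, K_d, sample, "duplex")
}

#' Two-state concerted complex equilibrium DH = H + 2S
#'
#' With 1:1 ligand:duplex stoichiometry, a dissociated fraction `x` gives
#' \eqn{[H] = x C_D}, \eqn{[S] = 2 x C_D}, \eqn{[DH] = (1-x) C_D}, so
#' \deqn{K_d = [H][S]^2/[DH] = 4 x^3 C_D^2 / (1 - x),}
#' solved for the unique root in \[0, 1) by monotone bisection.
#'
#' @param K_d dissociation constant (M^2), >= 0, or the result of
#'   [dissociation_constant()].
#' @inheritParams solve_duplex_equilibrium
#' @return An `equilibrium_state` with `conc_H = x * C_D`.
#' @export
#' @examples
#' s <- sample_spec(1e-3)
#' solve_complex_equilibrium(1e-6, s)$x  # K_d = C_D^2 gives x = 0.5
solve_complex_equilibrium <- function(K_d, sample, T = NA_real_) {
  if (is.list(K_d)) K_d <- K_d$Kd
  stopifnot(inherits(sample, "sample_spec"))
  if (K_d < 0) stop("K_d must be non-negative")
  C_D <- sample$C_D
  x <- .bisect_fraction(function(x) 4 * x^3 * C_D^2 - K_d * (1 - x),
                        function(x) 12 * x^2 * C_D^2 + K_d)
  .equilibrium_state(T, x, K_d, sample, "complex")
}

#' Dissociated fraction under the model carried by the parameters
#'
#' Convenience dispatcher: evaluates K_d(T) and solves the matching
#' mass-action polynomial.
#'
#' @inheritParams gibbs_free_energy
#' @param sample a [sample_spec].
#' @return An `equilibrium_state`.
#' @export
solve_equilibrium <- function(params, sample, T) {
  K <- dissociation_constant(params, T)
  if (params$model == "duplex") solve_duplex_equilibrium(K$Kd, sample, T)
  else solve_complex_equilibrium(K$Kd, sample, T)
}

#' Parameters of the stepwise three-state scheme 2S = D, D + H = DH
#'
#' The hybridization step is described by dissociation thermodynamics of the
#' ligand-free duplex (`duplex_params`, D -> 2S sense) and the binding step
#' by a single binding constant `K_b = [DH]/([D][H])` (M^-1) evaluated at a
#' stated temperature.
#'
#' @param duplex_params [thermo_params] with `model = "duplex"`.
#' @param K_b binding constant of ligand with duplex (M^-1), > 0.
#' @return An object of class `three_state_params`.
#' @export
three_state_params <- function(duplex_params, K_b) {
  stopifnot(inherits(duplex_params, "thermo_params"),
            duplex_params$model == "duplex", is.finite(K_b), K_b > 0)
  structure(list(duplex_params = duplex_params, K_b = K_b),
            class = "three_state_params")
}

#' Solve the coupled three-state equilibrium
#'
#' Species S, D, H, DH satisfy
#' \deqn{K_d = [S]^2/[D], \quad K_b = [DH]/([D][H]),}
#' strand balance \eqn{2[D] + 2[DH] + [S] = 2 C_D} and ligand balance
#' \eqn{[H] + [DH] = C_D}. Parameterizing by \eqn{[D]} eliminates the other
#' species analytically: \eqn{[S] = \sqrt{K_d [D]}},
#' \eqn{[DH] = C_D - [D] - [S]/2}, \eqn{[H] = C_D - [DH]}. The remaining
#' scalar residual \eqn{K_b [D][H] - [DH]} is strictly increasing in
#' \eqn{[D]} on the physical interval, so a single 1-D bisection suffices;
#' no multidimensional root finding is involved.
#'
#' @param params a [three_state_params] (or `K_d` may be given directly via
#'   `K_d_duplex` when the duplex constant at `T` is already known).
#' @param T temperature (K) at which the duplex K_d is evaluated.
#' @param sample a [sample_spec].
#' @param K_d_duplex optional duplex dissociation constant (M) overriding the
#'   van't Hoff evaluation at `T`.
#' @return A list of concentrations `S`, `D`, `H`, `DH` (M) plus the bound
#'   fraction `f_DH = [DH]/C_D` and inputs `K_d`, `K_b`.
#' @export
solve_three_state <- function(params, T, sample, K_d_duplex = NULL) {
  stopifnot(inherits(params, "three_state_params"),
            inherits(sample, "sample_spec"))
  K_d <- if (is.null(K_d_duplex))
    dissociation_constant(params$duplex_params, T)$Kd else K_d_duplex
  K_b <- params$K_b
  C_D <- sample$C_D
  stopifnot(K_d >= 0, K_b > 0)

  species <- function(D) {
    S <- sqrt(K_d * D)
    DH <- C_D - D - S / 2
    H <- C_D - DH
    list(S = S, D = D, H = H, DH = DH)
  }
  # D_max: ligand-free limit where [DH] = 0, i.e. D + sqrt(K_d D)/2 = C_D
  D_max <- stats::uniroot(function(D) D + sqrt(K_d * D) / 2 - C_D,
                          c(0, C_D), tol = 1e-18 * C_D)$root
  resid <- function(D) {
    sp <- species(D)
    K_b * sp$D * sp$H - sp$DH
  }
  if (resid(D_max) <= 0) {
    D <- D_max                      # binding negligible at this K_b
  } else {
    lo <- 0; hi <- D_max
    for (i in 1:200) {
      mid <- 0.5 * (lo + hi)
      if (resid(mid) > 0) hi <- mid else lo <- mid
    }
    D <- 0.5 * (lo + hi)
  }
  sp <- species(D)
  sp$DH <- max(sp$DH, 0)
  # relative residual diagnostics
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  checks <- c(
    mass_action = if (sp$D > 0) rel(sp$S^2 / sp$D, K_d) else 0,
    strand = abs(2 * sp$D + 2 * sp$DH + sp$S - 2 * C_D) / (2 * C_D),
    ligand = abs(sp$H + sp$DH - C_D) / C_D)
  if (any(!is.finite(unlist(sp))) || any(unlist(sp) < -1e-12 * C_D))
    stop("three-state solver failed: ", paste(names(checks), signif(checks, 3),
         collapse = ", "))
  c(sp, list(f_DH = sp$DH / C_D, K_d = K_d, K_b = K_b,
             residuals = checks))
}

#' Concentration-dependent melting temperature
#'
#' T_m is the temperature at which the duplex (or complex) fraction is 0.5.
#' At `x = 0.5` the mass-action polynomial fixes the dissociation constant:
#' `K_d(T_m) = 2 C_D` for the duplex model and `K_d(T_m) = C_D^2` for the
#' concerted complex model, giving the closed form
#' \deqn{T_m = \Delta H^0 / (\Delta S^0 - R \ln K_d^*).}
#' The root of `x(T) = 0.5` is located by bisection on \[250, 500\] K to
#' 1e-4 K and cross-checked against this closed form.
#'
#' @inheritParams solve_equilibrium
#' @return T_m in K.
#' @export
#' @examples
#' melting_temperature(thermo_params(403e3, 1088, "duplex"), sample_spec(1e-3))
melting_temperature <- function(params, sample) {
  stopifnot(inherits(params, "thermo_params"), inherits(sample, "sample_spec"))
  Kd_star <- if (params$model == "duplex") 2 * sample$C_D else sample$C_D^2
  f <- function(T) solve_equilibrium(params, sample, T)$x - 0.5
  lo <- 250; hi <- 500
  if (f(lo) > 0 || f(hi) < 0)
    stop("no melting transition bracketed in [250, 500] K")
  while (hi - lo > 1e-4) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  Tm <- 0.5 * (lo + hi)
  Tm_closed <- params$dH0 / (params$dS0 - phys_const$R * log(Kd_star))
  if (abs(Tm - Tm_closed) > 1e-2)
    warning("bisection and closed-form T_m disagree by more than 0.01 K")
  Tm
}

#' Concentration-independent reference temperature T_0
#'
#' The temperature at which \eqn{\Delta G_d^0 = 0} and \eqn{K_d = 1} (in the
#' model's concentration units): \eqn{T_0 = \Delta H_d^0 / \Delta S_d^0}.
#' Unlike T_m it does not depend on `C_D`, which makes it the natural
#' reference for comparing ligand-free and ligand-bound stability.
#'
#' @inheritParams gibbs_free_energy
#' @return T_0 in K.
#' @export
#' @examples
#' kelvin_to_celsius(reference_temperature(thermo_params(415e3, 1000, "complex")))
reference_temperature <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  if (params$dS0 <= 0)
    stop("T_0 requires a positive dissociation entropy")
  params$dH0 / params$dS0
}

#' Model melting curve theta(T)
#'
#' Fraction of intact duplex/complex `theta = 1 - x` on a temperature grid,
#' each point from the mass-action solver for the model carried by `params`.
#'
#' @inheritParams solve_equilibrium
#' @param T_grid ascending temperatures (K).
#' @return A data.frame with columns `T` (K), `theta`, `x`.
#' @export
melting_curve_model <- function(params, sample, T_grid) {
  stopifnot(!is.unsorted(T_grid, strictly = TRUE))
  x <- vapply(T_grid, function(T) solve_equilibrium(params, sample, T)$x,
              numeric(1))
  data.frame(T = T_grid, theta = 1 - x, x = x)
}
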