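#' Eyring activation parameters for one elementary direction
#'
#' Activation enthalpy and entropy entering the transition-state rate
#' expression \eqn{k = (k_B T / h)\exp(\Delta S^\ddagger/R -
#' \Delta H^\ddagger/RT)}. The direction (`association` or `dissociation`)
#' and the melting model are recorded so that rate-constant units can be
#' interpreted: dissociation rates are s^-1 in both models; association
#' rates are M^-1 s^-1 for the duplex model and M^-2 s^-1 for the concerted
#' complex model.
#'
#' Note the attempt frequency \eqn{k_0 = k_B T/h} is applied to both the
#' unimolecular and the multimolecular direction. For the multimolecular
#' association this leaves the concentration units implicitly absorbed into
#' \eqn{\Delta S^\ddagger} (a 1 M, resp. 1 M^2, standard state); the
#' activation entropies for association are therefore standard-state
#' dependent quantities.
#'
#' @param dH_act activation enthalpy (J mol^-1).
#' @param dS_act activation entropy (J mol^-1 K^-1).
#' @param direction `"association"` or `"dissociation"`.
#' @param model `"duplex"` or `"complex"`.
#' @return An object of class `eyring_params`.
#' @export
eyring_params <- function(dH_act, dS_act,
                          direction = c("association", "dissociation"),
                          model = c("duplex", "complex")) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  stopifnot(is.finite(dH_act), is.finite(dS_act))
  structure(list(dH_act = dH_act, dS_act = dS_act,
                 direction = direction, model = model),
            class = "eyring_params")
}

#' Eyring rate constant
#'
#' \eqn{k(T) = (k_B T / h) \exp(\Delta S^\ddagger/R - \Delta H^\ddagger/RT)},
#' computed in log space. Both the rate constant and its natural log are
#' returned: over the studied parameter range ln k spans roughly -60 to +40
#' and direct exponentiation of intermediate terms would overflow.
#'
#' @param p an [eyring_params] object.
#' @param T temperature (K), > 0. Vectorized.
#' @return A list with `k` (rate constant) and `log_k` (natural log).
#' @export
#' @examples
#' # zero barriers give the bare attempt frequency k_B T / h
#' eyring_rate(eyring_params(0, 0, "dissociation", "duplex"), 300)$k
eyring_rate <- function(p, T) {
  stopifnot(inherits(p, "eyring_params"))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive and finite (Kelvin)")
  R <- phys_const$R
  log_k <- log(phys_const$k_B * T / phys_const$h) +
    p$dS_act / R - p$dH_act / (R * T)
  list(k = exp(log_k), log_k = log_k)
}

#' Activation free energy
#'
#' \eqn{\Delta G^\ddagger(T) = \Delta H^\ddagger - T \Delta S^\ddagger}.
#' For a self-consistent (association, dissociation) pair derived from one
#' set of melting thermodynamics, the difference of barriers recovers the
#' standard free energy of dissociation:
#' \eqn{\Delta G_d^0 = \Delta G_d^\ddagger - \Delta G_a^\ddagger}.
#'
#' @inheritParams eyring_rate
#' @return Barrier height (J mol^-1).
#' @export
free_energy_barrier <- function(p, T) {
  stopifnot(inherits(p, "eyring_params"), all(T > 0))
  p$dH_act - T * p$dS_act
}

## [S]_eq at T from the melting model; shared by the relaxation expressions.
.S_eq <- function(thermo, sample, T) {
  eq <- solve_equilibrium(thermo, sample, T)
  eq$conc_S
}

#' Predicted relaxation rate after a small temperature jump
#'
#' Linearizing the mass-action kinetics about the equilibrium at the final
#' temperature `T_f` gives a single observable relaxation rate:
#' \deqn{\lambda_{obs} = 3 [S]_{eq}^2 k_a + k_d \quad \textrm{(complex, DH = H + 2S)}}
#' \deqn{\lambda_{obs} = 4 [S]_{eq} k_a + k_d \quad \textrm{(duplex, D = 2S)}}
#' with \eqn{[S]_{eq}} evaluated at `T_f` from the melting thermodynamics and
#' \eqn{k_d = K_d(T_f)\, k_a} enforced by detailed balance. The final
#' temperature of the jump is taken as the operational temperature for the
#' kinetics, since relaxation proceeds toward the `T_f` equilibrium.
#'
#' @param assoc [eyring_params] for the association direction; its `model`
#'   must match `thermo$model`.
#' @param thermo [thermo_params] for the melting equilibrium.
#' @param sample a [sample_spec].
#' @param T_f final temperature of the jump (K).
#' @param dissoc optional [eyring_params] for the dissociation direction.
#'   When supplied, `k_d` is evaluated from it directly instead of via
#'   detailed balance; with independently rounded activation parameters the
#'   two routes can differ by a few percent.
#' @return A list with `lambda_obs` (s^-1), `k_a`, `k_d`, `S_eq` (M) and
#'   `K_d` at `T_f`.
#' @export
#' @examples
#' th <- thermo_params(415e3, 1000, "complex")
#' ey <- eyring_params(-2.48e5, -754, "association", "complex")
#' predicted_relaxation_rate(ey, th, sample_spec(1e-3), 343.15)$lambda_obs
predicted_relaxation_rate <- function(assoc, thermo, sample, T_f,
                                      dissoc = NULL) {
  stopifnot(inherits(assoc, "eyring_params"), inherits(thermo, "thermo_params"))
  if (assoc$direction != "association")
    stop("`assoc` must carry association-direction activation parameters")
  if (assoc$model != thermo$model)
    stop("association parameters are for the ", assoc$model,
         " model but the thermodynamics are for the ", thermo$model, " model")
  K <- dissociation_constant(thermo, T_f)
  ka <- eyring_rate(assoc, T_f)
  log_kd <- if (is.null(dissoc)) {
    K$log_Kd + ka$log_k                  # detailed balance in log space
  } else {
    stopifnot(inherits(dissoc, "eyring_params"),
              dissoc$direction == "dissociation",
              dissoc$model == thermo$model)
    eyring_rate(dissoc, T_f)$log_k
  }
  S_eq <- .S_eq(thermo, sample, T_f)
  lambda <- if (thermo$model == "complex")
    3 * S_eq^2 * ka$k + exp(log_kd)
  else
    4 * S_eq * ka$k + exp(log_kd)
  list(lambda_obs = lambda, k_a = ka$k, k_d = exp(log_kd),
       log_k_a = ka$log_k, log_k_d = log_kd, S_eq = S_eq, K_d = K$Kd)
}

#' Separate association and dissociation rate constants from lambda_obs
#'
#' Inverts the linearized relaxation expression using the equilibrium
#' constant \eqn{K_d = k_d/k_a}:
#' \eqn{k_a = \lambda_{obs}/(3[S]_{eq}^2 + K_d)} for the complex model and
#' \eqn{k_a = \lambda_{obs}/(4[S]_{eq} + K_d)} for the duplex model, with
#' \eqn{k_d = K_d k_a}. This is the exact algebraic inverse of
#' [predicted_relaxation_rate()].
#'
#' @param lambda_obs observed relaxation rate (s^-1), > 0.
#' @inheritParams predicted_relaxation_rate
#' @return An object of class `rate_constants`: `k_a`, `k_d`, `T`, `model`,
#'   plus log forms.
#' @export
rate_constants_from_relaxation <- function(lambda_obs, thermo, sample, T_f) {
  stopifnot(inherits(thermo, "thermo_params"), lambda_obs > 0)
  K <- dissociation_constant(thermo, T_f)
  S_eq <- .S_eq(thermo, sample, T_f)
  denom <- if (thermo$model == "complex") 3 * S_eq^2 + K$Kd else 4 * S_eq + K$Kd
  k_a <- lambda_obs / denom
  structure(list(k_a = k_a, k_d = K$Kd * k_a,
                 log_k_a = log(k_a), log_k_d = log(K$Kd * k_a),
                 T = T_f, model = thermo$model), class = "rate_constants")
}

#' Fit Eyring activation parameters to temperature-dependent rate constants
#'
#' Linear regression of \eqn{\ln(k h / k_B T)} on \eqn{1/T}:
#' slope \eqn{= -\Delta H^\ddagger / R}, intercept
#' \eqn{= \Delta S^\ddagger / R}. Standard errors come from the ordinary
#' least-squares fit.
#'
#' @param T temperatures (K), at least 3 distinct values.
#' @param k rate constants at those temperatures (same length), or supply
#'   `log_k` directly to avoid exp/log roundoff for extreme rates.
#' @param log_k optional natural-log rates (overrides `k`).
#' @param direction,model recorded on the returned [eyring_params].
#' @return An [eyring_params] with extra fields `se_dH_act`, `se_dS_act`
#'   (standard errors, J mol^-1 and J mol^-1 K^-1) and `fit` (the `lm`).
#' @export
#' @examples
#' p <- eyring_params(3.77e5, 902, "dissociation", "duplex")
#' Ts <- c(333.15, 343.15, 353.15, 358.15, 368.15)
#' fit_eyring(Ts, eyring_rate(p, Ts)$k, direction = "dissociation")$dH_act
fit_eyring <- function(T, k = NULL, log_k = NULL,
                       direction = c("association", "dissociation"),
                       model = c("duplex", "complex")) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  if (is.null(log_k)) {
    stopifnot(!is.null(k), length(k) == length(T), all(k > 0))
    log_k <- log(k)
  }
  stopifnot(length(log_k) == length(T))
  if (length(unique(T)) < 3)
    stop("Eyring regression needs rate constants at >= 3 distinct temperatures")
  y <- log_k - log(phys_const$k_B * T / phys_const$h)
  fit <- stats::lm(y ~ I(1 / T))
  # noise-free rate sets give an essentially perfect regression; the
  # summary warning about it is expected and unhelpful here
  co <- suppressWarnings(summary(fit)$coefficients)
  R <- phys_const$R
  out <- eyring_params(dH_act = -co[2, 1] * R, dS_act = co[1, 1] * R,
                       direction = direction, model = model)
  out$se_dH_act <- co[2, 2] * R
  out$se_dS_act <- co[1, 2] * R
  out$fit <- fit
  out
}

#' Derive a self-consistent dissociation Eyring pair
#'
#' Given association activation parameters and the melting thermodynamics,
#' detailed balance (\eqn{K_d = k_d/k_a}) fixes the dissociation barrier:
#' \eqn{\Delta H_d^\ddagger = \Delta H_a^\ddagger + \Delta H_d^0},
#' \eqn{\Delta S_d^\ddagger = \Delta S_a^\ddagger + \Delta S_d^0}.
#'
#' @inheritParams predicted_relaxation_rate
#' @return An [eyring_params] for the dissociation direction.
#' @export
dissociation_eyring_from_association <- function(assoc, thermo) {
  stopifnot(inherits(assoc, "eyring_params"), assoc$direction == "association",
            inherits(thermo, "thermo_params"), assoc$model == thermo$model)
  eyring_params(assoc$dH_act + thermo$dH0, assoc$dS_act + thermo$dS0,
                "dissociation", thermo$model)
}
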