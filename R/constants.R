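#' Physical constants used throughout the package
#'
#' Gas constant `R` (J mol^-1 K^-1), Boltzmann constant `k_B` (J K^-1) and
#' Planck constant `h` (J s). These enter the van't Hoff relation
#' \eqn{\Delta G_d^0 = -RT \ln K_d} and the Eyring attempt frequency
#' \eqn{k_0 = k_B T / h}.
#'
#' @format A named list with elements `R`, `k_B`, `h`.
#' @export
#' @examples
#' phys_const$R
phys_const <- list(
  R   = 8.314,
  k_B = 1.380649e-23,
  h   = 6.62607015e-34
)

#' Convert between Celsius and Kelvin
#'
#' All internal computation uses absolute temperature; Celsius appears only
#' at I/O boundaries (instrument files and printed tables use degC).
#'
#' @param T_C,T_K temperature in degrees Celsius / Kelvin.
#' @return numeric temperature in the other unit.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15
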