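#' Spectral band definition
#'
#' Integration window for one marker band. Default windows follow the
#' diagnostic markers of duplex melting in the base-carbonyl/ring-mode
#' region: the adenine ring mode near 1607-1622 cm^-1 (A:T pairs), the
#' guanine ring modes at 1540-1580 cm^-1 (G:C pairs), the all-base-pair
#' carbonyl region near 1668 cm^-1, and the bound-thymine carbonyl marker
#' around the 1698 to 1702 cm^-1 shift upon ligand binding.
#'
#' @param name marker label.
#' @param lo,hi window edges (cm^-1), `lo < hi`.
#' @param assignment one of `"A_ring"`, `"G_ring"`, `"carbonyl_all"`,
#'   `"T_carbonyl_bound"`.
#' @return An object of class `band_definition`.
#' @export
#' @examples
#' band_definition("G", 1540, 1580, "G_ring")
band_definition <- function(name, lo, hi,
                            assignment = c("A_ring", "G_ring",
                                           "carbonyl_all",
                                           "T_carbonyl_bound")) {
  assignment <- match.arg(assignment)
  stopifnot(lo < hi)
  structure(list(name = name, lo = lo, hi = hi, assignment = assignment),
            class = "band_definition")
}

#' Default marker bands
#'
#' @return Named list of [band_definition]s: `A` (1600-1650 cm^-1 around the
#'   1607/1622 cm^-1 adenine ring markers), `G` (1540-1580 cm^-1 guanine
#'   ring modes), `R` (1650-1690 cm^-1 around the 1668 cm^-1 all-base-pair
#'   carbonyl), `T_bound` (1695-1706 cm^-1 bound thymine carbonyl).
#' @export
default_bands <- function() {
  list(A = band_definition("A", 1600, 1650, "A_ring"),
       G = band_definition("G", 1540, 1580, "G_ring"),
       R = band_definition("R", 1650, 1690, "carbonyl_all"),
       T_bound = band_definition("T_bound", 1695, 1706, "T_carbonyl_bound"))
}

#' Transient difference spectrum at one delay
#'
#' @param wavenumbers probe axis (cm^-1), ascending.
#' @param delta_signal signal change versus the pre-jump spectrum.
#' @param delay delay after the jump (s), within 5e-9 to 5e-2.
#' @param protocol a [tjump_protocol] (optional).
#' @return An object of class `transient_spectrum`.
#' @export
transient_spectrum <- function(wavenumbers, delta_signal, delay,
                               protocol = NULL) {
  stopifnot(length(wavenumbers) == length(delta_signal),
            !is.unsorted(wavenumbers, strictly = TRUE),
            delay >= 5e-9, delay <= 5e-2)
  structure(list(wavenumbers = wavenumbers, delta_signal = delta_signal,
                 delay = delay, protocol = protocol),
            class = "transient_spectrum")
}

#' Rescale a raw T-jump signal to a fractional change
#'
#' \eqn{\Delta S'(t) = \Delta S(t) / \max(S_{eq}(T_i))}: the raw signal
#' change is divided by the maximum spectral intensity of the equilibrium
#' spectrum at the initial temperature, making traces comparable across
#' frequencies and samples.
#'
#' @param raw raw signal changes \eqn{\Delta S(t)}.
#' @param S_eq_Ti_max maximum equilibrium spectral intensity at `T_i`, > 0.
#' @return \eqn{\Delta S'(t)}, same length as `raw`.
#' @export
fractional_signal_change <- function(raw, S_eq_Ti_max) {
  if (!is.finite(S_eq_Ti_max) || S_eq_Ti_max <= 0)
    stop("normalizer max(S_eq(T_i)) must be positive")
  raw / S_eq_Ti_max
}

#' Integrate a transient spectrum over a band
#'
#' Trapezoidal quadrature of `delta_signal` over the grid points falling in
#' \[`lo`, `hi`\]; the spectrum's native wavenumber grid is used without
#' interpolation.
#'
#' @param spec a [transient_spectrum].
#' @param band a [band_definition]; must lie within the spectrum range.
#' @return Integrated intensity (signal units times cm^-1).
#' @export
integrate_band <- function(spec, band) {
  stopifnot(inherits(spec, "transient_spectrum"),
            inherits(band, "band_definition"))
  wn <- spec$wavenumbers
  if (band$lo < min(wn) || band$hi > max(wn))
    stop("band [", band$lo, ", ", band$hi, "] outside spectrum range [",
         min(wn), ", ", max(wn), "]")
  sel <- wn >= band$lo & wn <= band$hi
  if (sum(sel) < 2) stop("fewer than 2 grid points inside the band")
  pracma::trapz(wn[sel], spec$delta_signal[sel])
}

#' Fraction of base pairs broken at a delay
#'
#' Ratio of a transient band integral at one delay to the corresponding
#' full equilibrium difference integral (spectrum at `T_f` minus spectrum at
#' `T_i`): the fraction of the pairs that will eventually break which have
#' already broken. Any overall normalization applied consistently to both
#' integrals (e.g. [fractional_signal_change()]) cancels in the ratio.
#'
#' @param transient_integral band integral of the transient spectrum.
#' @param equilibrium_difference_integral band integral of the full
#'   equilibrium T_i to T_f difference; must be nonzero.
#' @return A list with `fraction` and `clipped` (TRUE when the raw ratio
#'   fell outside \[0, 1.05\] and was reported as-is with a flag).
#' @export
fraction_broken <- function(transient_integral,
                            equilibrium_difference_integral) {
  if (equilibrium_difference_integral == 0)
    stop("equilibrium difference integral is zero")
  f <- transient_integral / equilibrium_difference_integral
  list(fraction = f, clipped = f < 0 || f > 1.05)
}
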