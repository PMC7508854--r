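# Printed melting/activation parameters used across tests (J, mol, K units)
params_native <- function() thermo_params(403e3, 1088, "duplex")
params_bound  <- function() thermo_params(415e3, 1000, "complex")

eyring_native_a <- function() eyring_params(-2.63e4, -187, "association", "duplex")
eyring_native_d <- function() eyring_params(3.77e5, 902, "dissociation", "duplex")
eyring_bound_a  <- function() eyring_params(-2.48e5, -754, "association", "complex")
eyring_bound_d  <- function() eyring_params(1.67e5, 246, "dissociation", "complex")

# Independent root oracle for the mass-action polynomials (stats::uniroot,
# a different algorithm and code path than the package's bisection).
oracle_x <- function(K_d, C_D, power) {
  if (K_d == 0) return(0)
  f <- function(x) 4 * x^(power + 1) * C_D^power - K_d * (1 - x)
  if (f(1 - 1e-12) <= 0) return(1 - 1e-12)
  stats::uniroot(f, c(0, 1 - 1e-12), tol = 1e-15)$root
}

# Melting curve spanning the model transition, generated noise-free or with
# seeded noise, extracted through the SVD path.
spanning_ir_curve <- function(model, C_D, noise_sigma = 0, seed = 1) {
  sc <- tjump_scenario(model, C_D = C_D, noise_sigma = noise_sigma,
                       seed = seed)
  Tm <- melting_temperature(sc$thermo, sc$sample)
  ser <- generate_melting_series(
    sc, temperatures_C = kelvin_to_celsius(seq(Tm - 45, Tm + 45,
                                               length.out = 33)))
  svd_melting_curve(ser, sample = sc$sample)
}

# Default log time grid of the T-jump experiments
tjump_times <- function(n = 64) 10^seq(log10(1e-8), log10(5e-2),
                                       length.out = n)

# number of contiguous half-maximum features in a rate distribution
n_halfmax_features <- function(d) {
  a <- abs(d$amplitude)
  sel <- a >= 0.5 * max(a)
  sum(diff(c(FALSE, sel)) == 1)
}
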