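---
title: "Melting thermodynamics and T-jump kinetics of a ligand-bound DNA duplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting thermodynamics and T-jump kinetics of a ligand-bound DNA duplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjumpmelt)
```

## The system and the models

`tjumpmelt` models the thermal dissociation of a short DNA duplex with and
without a minor-groove ligand (a bis-benzimidazole dye such as Hoechst
33258) bound 1:1, and the relaxation kinetics observed after a nanosecond
temperature jump. Three mass-action schemes are implemented:

* **Two-state duplex**: D &#8652; 2S, with
  `K_d = [S]^2/[D]` in M. With the duplex-equivalent concentration `C_D`
  and dissociated fraction `x`, `[S] = 2 x C_D`, `[D] = (1 - x) C_D`, and
  `K_d = 4 x^2 C_D / (1 - x)`.
* **Two-state concerted complex**: DH &#8652; H + 2S, with
  `K_d = [H][S]^2/[DH]` in M&sup2; and `K_d = 4 x^3 C_D^2 / (1 - x)` at 1:1
  stoichiometry. The complex forms directly from its three constituents —
  no ligand-free duplex intermediate.
* **Stepwise three-state**: 2S &#8652; D, D + H &#8652; DH, combining the
  duplex thermodynamics with a binding constant
  `K_b = [DH]/([D][H])` in M&#8315;&sup1;. This scheme is retained as a
  *diagnostic*: fitted to data that actually follow concerted dissociation
  it produces a concentration-dependent `K_b`, which is the signature used
  to reject it.

Temperature enters through the van't Hoff layer,
`dG_d0(T) = dH0 - T*dS0 = -R T ln K_d`, with a single enthalpy/entropy pair
per reaction. Two characteristic temperatures summarize a parameter set:
the concentration-dependent melting temperature `T_m` (duplex fraction 0.5,
closed form `T_m = dH0 / (dS0 - R ln K_d*)` with `K_d* = 2 C_D` or `C_D^2`)
and the concentration-independent reference temperature `T_0 = dH0/dS0`
where `K_d = 1` and `dG_d0 = 0`. `T_0` is the quantity used to compare
ligand-free and ligand-bound stability:

```{r t0}
kelvin_to_celsius(reference_temperature(thermo_params(403e3, 1088, "duplex")))
kelvin_to_celsius(reference_temperature(thermo_params(415e3, 1000, "complex")))
```

A note on the default parameter values: the bundled defaults (403 kJ/mol,
1088 J/mol/K for the native duplex; 415 kJ/mol, 1000 J/mol/K for the
complex; the activation parameters in the kinetics section) are rounded to
3–4 significant figures, and they sit inside exponentials. The model-implied
`T_m` at 1 mM (80.5 °C native, 99.1 °C complex) is therefore 3–6 K above
the corresponding experimental midpoints such parameter sets are usually
quoted with; the package makes no attempt to absorb that rounding, and all
printed-value checks in the test suite use `T_0` or carry tolerances
consistent with it.

## Melting-curve extraction and fitting

Temperature-series IR spectra are decomposed by SVD. For a two-state
transition the spectra matrix is rank 2 — folded and unfolded basis spectra
mixed by the intact fraction &theta;(T) — so the second right-singular
vector carries the transition. Its sign is arbitrary and is fixed so the
curve increases with temperature; the amplitude is then normalized
affinely using the mean of the 3 lowest- and 3 highest-temperature points
as baselines. No sloping-baseline term is used. Raw (not mean-centered)
spectra are decomposed; the extraction is invariant to positive rescaling
and to any temperature-independent background, both of which only feed the
first component, and both invariances are tested.

`fit_two_state()` estimates a single (dH0, dS0) pair across one or more
curves, each predicted through the mass-action solver with its own `C_D`.
Two choices matter here:

* **The model is normalized like the data.** Model curves pass through the
  same 3-point affine normalization before entering the unweighted
  least-squares objective, making the fit invariant to the curves'
  normalization convention; for noise-free spanning curves recovery is
  exact to machine precision.
* **Deterministic initialization.** The 25%/75% crossing temperatures of
  the first curve give two (T, K_d) points through the mass-action
  polynomial; a two-point van't Hoff line yields the starting (dH0, dS0).
  No random restarts. Optimization is Levenberg–Marquardt
  (`minpack.lm::nls.lm`) on scaled parameters (1e5 J, 1e3 J/K units).

Each curve must span its transition (min signal < 0.3, max > 0.7): a
partial curve under-determines the pair. Step-like curves (the infinitely
cooperative limit) either fail initialization or are reported with a
`boundary_flag` when the fitted enthalpy exceeds 2 MJ/mol.

Fluorescence curves are modeled as intensity proportional to the bound
fraction `[DH]/C_D` — the ligand fluoresces when held rigid in the minor
groove — normalized the same way as IR curves.

### The three-state diagnostic

`fit_three_state_Kb()` holds the ligand-free duplex thermodynamics fixed
and fits a single temperature-independent `K_b` to a melting curve by 1-D
search on `log10 K_b`. The convention adopted for this diagnostic is to
supply curves *as the instrument provides them*: observed over a 5–98 °C
ramp and affinely normalized. That matters at high concentration, where the
complex transition extends beyond the ramp and the normalized curve is
stretched — exactly the situation in the experiments this package models.
Under that convention, concerted-model data at 1 mM versus 200 nM yield
fitted `K_b` values more than two orders of magnitude apart, while data
generated from the three-state scheme itself return a concentration-stable
`K_b` (spread below 10%). On idealized curves that fully span each
transition the concerted-data spread shrinks to roughly 1.7 decades; the
qualitative rejection signature survives, but the instrument-window
convention is the one the test suite pins down.

## T-jump kinetics

Linearizing the kinetics about the equilibrium at the final temperature of
the jump gives one observable relaxation rate per scheme:

* complex: `lambda_obs = 3 [S]_eq^2 k_a + k_d`
* duplex: `lambda_obs = 4 [S]_eq k_a + k_d`

`[S]_eq` is evaluated at `T_f` (relaxation proceeds toward the `T_f`
equilibrium; `T_f` is the operational temperature throughout). The duplex
expression is the standard linearized dimerization result, consistent with
M&#8315;&sup1;s&#8315;&sup1; association units; the complex expression is
its three-body analogue. Rate constants follow the Eyring form
`k = (k_B T / h) exp(dS_act/R - dH_act/(R T))`, computed in log space. The
attempt frequency `k_B T / h` is applied to the multimolecular association
direction as well, so association activation entropies are standard-state
(1 M or 1 M&sup2;) dependent quantities.

By default `k_d` is derived from detailed balance, `k_d = K_d(T_f) k_a`,
which guarantees `dG_d0 = dG_d_barrier - dG_a_barrier` exactly. An
independently tabulated dissociation pair can be passed instead
(`dissoc =`); with rounded published pairs the two routes can differ by a
few percent, and the forward predictions quoted below use the tabulated
route for both directions:

```{r lambda}
s <- sample_spec(1e-3)
predicted_relaxation_rate(
  eyring_params(-2.48e5, -754, "association", "complex"),
  thermo_params(415e3, 1000, "complex"), s, celsius_to_kelvin(70),
  dissoc = eyring_params(1.67e5, 246, "dissociation", "complex"))$lambda_obs
```

`rate_constants_from_relaxation()` is the exact algebraic inverse
(`k_a = lambda / (3 [S]_eq^2 + K_d)` or `/(4 [S]_eq + K_d)`), and
`fit_eyring()` regresses `ln(k h / k_B T)` on `1/T` (slope `-dH_act/R`,
intercept `dS_act/R`), needing at least three distinct temperatures.

## Maximum-entropy rate distributions

`mem_invert()` converts a log-time trace into a signed distribution of
relaxation rates on a log-spaced grid (20 points/decade over
10&sup1;–10&#8312; s&#8315;&sup1;, 141 points). The forward model is a
superposition of saturating exponentials
`S(t) = sum_j g_j (1 - exp(-lambda_j t))` — T-jump signals rise toward the
new equilibrium, and negative `g_j` carry decaying or recovering
components such as thermal re-equilibration.

Because plain maximum entropy requires positivity, the signed amplitude is
decomposed as `g = g+ - g-` with Shannon–Jaynes entropy
`sum(g - m - g ln(g/m))` summed over both branches against a flat prior
level `m` (default 1e-4 of the trace maximum). The constrained problem —
maximize entropy subject to `chi^2 = N` — is solved as a sequence of
unconstrained minimizations of `chi^2/2 - alpha S` (log-parameterized, with
analytic gradients, L-BFGS-B), stepping the multiplier down by decades
from a heavily regularized start and then bisecting on `log alpha` until
`chi^2` is within 2% of target. The procedure is deterministic; a
pure-noise trace simply returns the heavily smoothed solution whose
`chi^2` already meets the target, and failure to get within 1.2&times;N
raises an error. Per-point noise is taken from the trace or estimated as
the standard deviation of the first five (pre-rise) points.

Resolution is what MEM gives, not better: two planted rates 1.5 decades
apart at SNR 50 separate into distinct half-maximum features; rates 0.2
decades apart merge into one. These limits are asserted, not hidden, in
the test suite.

`weighted_mean_rate()` reduces distributions to the amplitude-weighted
mean `sum(|g| lambda)/sum(|g|)`, masking grid points per frequency below
half of that frequency's maximum amplitude and below a thermal cutoff
(4e2 s&#8315;&sup1;; slower features reflect sample cooling, not
chemistry). Masking is applied per frequency and surviving points are then
pooled; the standard deviation of per-frequency means is the error bar. An
upper cutoff (`exclude_above`) lets the slow dissociation phase be
summarized separately from the fast (~3e7 s&#8315;&sup1;) terminal
base-pair response; the pipeline uses 3e6 s&#8315;&sup1; as the split,
one decade below the fast phase. Note the slow complex phase (hundreds of
s&#8315;&sup1;) sits within a decade of the thermal cutoff, so when a
thermal component is present the slow-phase mean is biased upward by
overlap — visible in the pipeline's diagnostics and left as a documented
limitation rather than compensated.

## The synthetic-data generator

Every input the pipeline consumes can be generated from a
`tjump_scenario`, a pure function of its parameters and a seed. Defaults
are the study conditions: 1 mM duplex-equivalent concentration, 70 °C
initial temperature, a 15 K jump, the melting and activation parameters
quoted above, a fast terminal-G:C phase at 3e7 s&#8315;&sup1;, thermal
re-equilibration at 2e2 s&#8315;&sup1;, and 1% additive Gaussian noise
(SNR ~ 100 against unit-scale basis spectra).

* `generate_melting_series()` builds
  `A(nu, T) = theta(T) B_ds(nu) + (1 - theta(T)) B_ss(nu) + noise` from
  Gaussian basis peaks carrying the melting markers: the adenine ring mode
  (1622 cm&#8315;&sup1;) and guanine ring modes (1564/1575
  cm&#8315;&sup1;) suppressed in the duplex and gained in single strands,
  the carbonyl envelope at 1668 cm&#8315;&sup1;, the guanine 1546
  cm&#8315;&sup1; mode, and a 1702 cm&#8315;&sup1; bound-thymine shoulder
  in the ligand-bound duplex basis. Noise-free output is exactly rank 2.
  Lineshapes are Gaussian only — lineshape physics is not a test target.
* `generate_fluorescence_curve()` emits the normalized bound-fraction
  observable at any concentration.
* `generate_tjump_traces()` builds bimodal log-time traces (64 points,
  10 ns–50 ms): for the complex, the G marker carries fast and slow phases
  (amplitudes 0.66/0.34), the A marker only the slow dissociation phase
  (amplitude 0.4, keeping its deterministic signal below 3&sigma; of the
  default noise out to 100 &micro;s — ligand binding suppresses the early
  A:T response), and for the native duplex both phases are comparable at
  every marker.

What the generator does **not** emulate: baseline drift, sloping
backgrounds, correlated (non-white) noise, instrument-response convolution
of the fast phase, solvent background spectra, or any sequence-dependent
fine structure. Passing tests therefore demonstrate correctness of the
analysis pipeline under its own statistical assumptions, not robustness to
every artifact of real spectrometers.

## Pipeline, problem sizes, and reproducibility

`run_pipeline()` chains simulate &rarr; extract &rarr; fit-melt &rarr;
fit-kinetics &rarr; mem &rarr; report, validating its configuration
against a schema first and deriving all randomness from one seed recorded
in the result bundle (serializable to JSON; a structural schema ships in
`inst/extdata/`). The melting series for fitting is generated on a
33-point grid spanning the sample's transition (T_m &plusmn; 45 K) — at
1 mM the complex transition extends past a 5–100 °C ramp, and the global
fit needs complete curves. Kinetic refits use six final temperatures
between 60 and 95 °C; MEM inversion runs on the three marker traces at 64
time points. These sizes keep a full pipeline run around five seconds
while leaving every stage statistically meaningful; the integration test
at 1% noise recovers the melting enthalpy and entropy within 2% and the
activation enthalpies within 5%.

## Known limitations

* With published parameters rounded to 3–4 figures inside exponentials,
  forward-predicted relaxation rates carry a few percent of irreducible
  slack (about 2% at 70 °C for the complex), and printed `T_m` values are
  not reproduced exactly — `T_0` comparisons are the stable ones.
* The temperature-independent `K_b` in the three-state diagnostic is a
  deliberate simplification; it is a model-rejection tool, not an estimate
  of binding thermodynamics.
* MEM feature positions are reliable to about one grid spacing; amplitudes
  of features within a decade of the thermal cutoff are biased by overlap.
* The fluorescence observable is assumed strictly proportional to the
  bound fraction; quenching and inner-filter effects are out of scope.
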