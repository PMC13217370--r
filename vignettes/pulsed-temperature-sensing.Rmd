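---
title: "Modelling pulsed-temperature ion sensing: from free-energy profiles to limits of detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pulsed-temperature ion sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsefet)
```

## The problem

Trace detection of Pb²⁺ with a surface-bound molecular probe (a
tetra-carboxyphenyl porphyrin whose central N₄ cavity coordinates the ion)
faces a kinetic paradox. Binding is strongly downhill at room temperature
(ΔG° ≈ −43.8 kJ/mol) but guarded by a large activation barrier
(Eₐ ≈ 76.3 kJ/mol), so complexation is slow. Heating accelerates the
forward reaction, but a sensor held hot also dissociates quickly: at 60 °C
the dissociation rate constant rises by more than two orders of magnitude,
and the equilibrium occupancy of the probe sites is *lower* than at room
temperature. A pulsed protocol — inject a small hot aliquot, let the
chamber quench back — buys the fast forward kinetics of the hot state while
keeping the slow reverse kinetics of the cold state.

`pulsefet` implements this reasoning end to end as a desk-scale modelling
chain:

1. **free energy** — tabulated profiles G(r) along the probe–ion
   separation coordinate, and the scalars read off them;
2. **kinetics** — diffusion-limited association rates over G(r)
   (Smoluchowski), Arrhenius laws, and detailed-balance reverse rates;
3. **pulse simulation** — two-state occupancy kinetics under arbitrary
   temperature protocols;
4. **EDL/FET transduction** — Gouy–Chapman–Stern capacitances turning bound
   interfacial charge into a gate-voltage shift, amplified by the
   transistor's transconductance;
5. **calibration** — serial-dilution bookkeeping, the log-concentration
   calibration line, the 3σ/S limit of detection, and real-sample
   back-calculation;
6. **synthetic data** — seeded sensing-run traces with the noise structure
   the analysis assumes, so the entire pipeline is testable without
   instrument data.

## Free-energy profiles

A `free_energy_profile` is a tabulated curve G(r) in kJ/mol on a strictly
increasing separation grid in Å, referenced to G = 0 at the separated
state (largest r), with a temperature tag and a minimum binding distance
`a`. Only two scalar features of the curve enter any downstream number:
the well depth ΔG° (minimum of G) and the barrier height Eₐ (maximum of G
beyond the well, measured from the separated state). `build_profile()`
therefore synthesises a profile from exactly those scalars, as two narrow
Gaussian features centred at the well and barrier positions:

```{r profile}
p <- build_profile(dG0 = -43.84, Ea = 76.32, r_well = 2.2, r_barrier = 6,
                   r_max = 40, a = 1)
extract_thermo(p)
```

The feature width is one eighth of the well–barrier separation, which
keeps cross-contamination of the two extrema below 10⁻⁹ kJ/mol, so
`build_profile()` → `extract_thermo()` round-trips (ΔG°, Eₐ) to better
than 10⁻⁶. The barrier position itself is a free synthetic parameter: the
underlying electronic-structure scan is specified only by its 0–40 Å
range, and no downstream quantity depends on where the barrier sits.
Profiles can also be read from two-column text files
(`read_profile()`/`write_profile()`); the electronic-structure
calculations that would produce a real profile are deliberately out of
scope — profiles are inputs here.

Two helpers support the thermodynamic bookkeeping around such profiles:
`gibbs_from_components()` composes G = E + ZPE + H_th − TS, and
`sackur_tetrode_entropy()` gives the translational entropy of the ion at a
standard-state concentration, the correction used when a gas-phase
electronic-structure energy is referred to solution.

The solvent dielectric constant enters through `water_dielectric()`,
a linear interpolation between the two anchors used in the binding
calculations (78.36 at 298 K, 66.77 at 333 K); with only two anchors
stated, a linear form is the only defensible choice.

## From profiles to rate constants

`smoluchowski_rate()` evaluates the diffusion-limited association rate

k_f = 4π D N_A / ∫ₐ^∞ exp(G(r)/RT) / r² dr,

where D is the sum of the partners' diffusion coefficients and `a` the
minimum binding distance. The integral is evaluated piecewise between the
profile's grid knots with adaptive quadrature (per-panel relative
tolerance 10⁻¹⁰), so kinks in a tabulated profile never cross a quadrature
panel; beyond the grid G = 0 and the tail ∫ r⁻² dr = 1/r_max is added
analytically. Everything is computed in SI and converted to M⁻¹s⁻¹ in a
single centralized factor. Two closed forms anchor the implementation: a
flat profile collapses to the classic Smoluchowski limit 4π D N_A a, and a
square barrier has an elementary integral; the test suite holds the
quadrature to 10⁻⁶ of both.

The equilibrium side is fixed by detailed balance against the 1 M standard
state: `dissociation_constant()` computes K_d = exp(+ΔG°_binding/RT) and
`reverse_rate()` gives k_r = k_f · K_d. The sign convention is the one
that makes K_d small for a strongly bound complex and reproduces the known
reverse rates of this system (k_r ≈ 1.1 × 10⁻³ s⁻¹ at 298 K and
≈ 3 × 10⁻¹ s⁻¹ at 333 K from the printed forward rates and binding free
energies); the opposite sign would be inconsistent with k_r/k_f by fifteen
orders of magnitude.

```{r rates}
reverse_rate(kf = 5.33e4, dG0 = -43.84, T_K = 298)
reverse_rate(kf = 1.22e5, dG0 = -35.65, T_K = 333)
```

`rate_ratio_ordering()` forms the three forward/reverse ratios that rank
the operating modes — pulsed (hot k_f against cold k_r), isothermal room
temperature, and sustained heating — and checks the strict ordering
k_f2/k_r1 > k_f1/k_r1 > k_f2/k_r2 that motivates the pulsed protocol.

Between the two anchor temperatures, rates are interpolated by an
effective Arrhenius law (`rate_interpolator()`): with exactly two
measured anchors, fitting A and Eₐ through them is the minimal model
consistent with Arrhenius behaviour. Temperatures outside [298, 333] K are
clamped with a warning rather than extrapolated — hot-side behaviour
(e.g. 95 °C operation) is dominated by effects the two-anchor model cannot
see.

## Pulsed-temperature binding simulation

A `temperature_protocol` is a contiguous list of segments, each constant
or an exponential relaxation. `protocol_from_injection()` models the
hot-aliquot pulse: injecting a volume fraction f of sample at T_sample
into a chamber at T_base mixes enthalpies of ideal dilute solutions,
T_mix = (1−f) T_base + f T_sample, then relaxes back exponentially. A 10 %
injection of a 60 °C aliquot into a 21 °C chamber gives the observed ~4 K
spike. The relaxation constant is not a measured quantity; the default
τ = 15 s lets a spike decay within about a minute, the visual timescale of
the recorded temperature transients, and it is an exposed parameter.

`simulate_binding()` integrates the two-state site-occupancy kinetics

dθ/dt = k_f(T(t)) · C_free · (1−θ) − k_r(T(t)) · θ,  C_free = C0 − ρ_site θ,

with `deSolve`'s lsoda at rtol 10⁻¹⁰ (the constant-temperature case is
held to its closed-form pseudo-first-order solution in the tests). The
probe site density is never stated for the real device; the trace-site
default (10⁻¹² M) keeps C_free ≈ C0, which is also the regime where the
analytic checks are exact. Integration is deterministic — all stochasticity
lives in the synthetic-data module.

```{r pulse}
fn <- default_rates_fn()
prots <- list(
  pulsed     = protocol_from_injection(298, 333, 0.1, duration = 300),
  isothermal = isothermal_protocol(298, 300)
)
compare_protocols(prots, fn, C0 = 1e-8, n_out = 101)
```

The pulsed protocol ends with strictly higher occupancy than isothermal
room-temperature operation at every concentration in the assay range,
while the *equilibrium* occupancy at sustained 60 °C
(`langmuir_occupancy()` with the hot K_d) is lower than at room
temperature — the quantitative form of the spike-and-quench rationale.
The margin of the pulsed gain is modest under the clamped two-anchor rate
model (~0.3 % at a 300 s horizon) because the mixing spike only reaches
~3.5 K above the room-temperature anchor; the ordering, not the
magnitude, is the claim this model can support.

## Electric-double-layer transduction

The interfacial model is classical Gouy–Chapman–Stern: a compact Stern
layer (C_St = ε₀ε_r,St A/l_St) in series with a diffuse layer whose
thickness is the Debye screening length
(`debye_length()`, λ_D ∝ c₀^(−1/2)), combined by
1/C_EDL = 1/C_St + 1/C_diff. Bound charge Δσ shifts the gate voltage by
ΔV_g = Δσ·A/C_EDL (`gate_shift_from_binding()`), and the transistor
converts it to current through its transconductance, ΔI_d = g_m ΔV_g, with
g_m = 128.3 mS at the operating point. `grahame_charge()` provides the
nonlinear charge–potential relation of the diffuse layer in its standard
form σ = √(8 c₀ N_A ε ε₀ k_B T) · sinh(eφ_St/2k_BT); the dimensionally
inconsistent prefactor-only variant sometimes quoted is available as
`form = "literal"` strictly for comparison, and the small-potential
Debye-capacitor limit as `form = "linearized"`.

Stern-layer constants (ε_r,St = 6, l_St = 0.5 nm) are not printed for this
device; the defaults are the common textbook magnitudes for a
strongly ordered compact water layer and are fully configurable. The
charge per bound ion at the surface is likewise unknown, so the
full-occupancy charge density `sigma_site` is a ground-truth scenario
parameter (default 6 × 10⁻⁴ C/m², giving ~10 mV full-scale gate shift and
~1.3 mA full-scale current — mA-scale signals consistent with a blank SD
of 0.067 mA).

`salt_response_factor()` captures the ionic-strength dependence as a
product of two terms: the physical capacitive-division factor
C_St/C_EDL(c₀), which falls as salt rises (diffuse-layer compression
screens the bound charge), and a phenomenological hydration attenuation —
a logistic roll-off in log₁₀ c₀ below 3 × 10⁻⁴ M (≈ 0.002X PBS, width 0.4
decades) representing the thick hydration shells that impede direct
coordination at very low ionic strength. No governing equation exists for
the hydration effect, so only orderings are asserted: the factor is
unimodal, attenuated at 0.1X PBS relative to 0.01X and attenuated again at
0.0001X, with the optimum at moderate ionic strength. PBS dilutions map to
ionic strength via `pbs_ionic_strength()` (1X ≡ 162.7 mM 1:1-equivalent,
linear in dilution — a documented, overridable constant).

## Calibration, LOD, and real samples

`dilution_series()` does exact mole/volume bookkeeping for incremental
additions. The standard six-step schedule (5.55, 6.17, 6.85, 7.62, 8.40,
9.40 µL of 10⁻¹⁰…10⁻⁵ M stocks into 50 µL) steps the chamber through
10⁻¹¹…10⁻⁶ M within 10 % of each decade; the first addition gives
9.991 × 10⁻¹² M, i.e. "10⁻¹¹ M" to 0.1 %.

`fit_calibration()` is ordinary least squares of signal (mA) on log₁₀
concentration; `lod()` converts blank noise and slope to a limit of
detection, LOD = 3σ/S decades, and to molarity through the calibration
reference concentration C_ref:

```{r lod}
res <- lod(sigma_blank = 0.067, slope = 0.307, C_ref = 2.43e-13)
unlist(res)
```

C_ref = 2.43 × 10⁻¹³ M is taken verbatim as an input constant — its
provenance (extrapolated intercept vs blank-equivalent concentration) is
not documented for this system. Note the package reports the exact
quotient 3 × 0.067/0.307 = 0.6547 decades (1.097 × 10⁻¹² M); quoting the
same quantities from pre-rounded intermediates gives 0.656 and
1.101 × 10⁻¹² M.

`quantify()` inverts the calibration line, multiplies back the sample
dilution (the certified-river-water workflow — pH adjustment, 4-fold
dilution, 1-in-10 introduction — is the ×40 preset
`slrs_dilution_factor()`), and converts to ppb via the molar mass
(Pb: 207.2 g/mol). `relative_deviation(0.182, 0.170)` reproduces the ~7 %
agreement with the certified value.

## Synthetic sensing runs

`generate_trace()` emulates a recorded run:

I_d(t) = baseline + g_m ΔV_g(θ(t)) + drift·t + ε(t) + injection spikes,

with θ(t) from the binding simulation under the per-addition injection
protocol, ΔV_g from the EDL chain, Gaussian noise of SD
σ_ref (T(t)/T_ref)^η — the default η = 0.5 is the Johnson-noise
square-root law, the exponent being exposed since only "scales with
temperature" is known — plus brief exponentially decaying artifacts at
addition times mirroring the temperature transients. Traces are
bit-reproducible given (scenario, seed), and generation does not disturb
the caller's RNG stream. The default sampling interval is 0.1 s (the
instrument's 100 ms idle interval); the tests and the acceptance script
use 0.5 s, which leaves the 30 s settle-window statistics unchanged at a
quarter of the cost.

`extract_step_heights()` operationalizes "recorded after signal
stabilization": per addition, the mean current over the settle window
before the next addition minus the mean over the window before this one.

What the generator emulates: stepwise responses at timed additions,
baseline drift, temperature-dependent noise, injection artifacts, and the
pulsed-vs-isothermal signal ordering. What it does not: the log-linear
calibration shape of the real device (a two-state Langmuir model cannot
produce it — real-surface heterogeneity presumably does), electrode-to-
electrode variability, hot-side instability, or fouling drift
nonlinearity. Parameter-recovery tests on synthetic runs therefore
demonstrate that the *analysis pipeline* is unbiased at realistic noise,
not that the mechanistic forward model matches a real calibration curve:
the recovered slope is compared against the same scenario's noiseless
ground truth, never against the instrument's printed slope.

## Numerical choices and problem sizes

* Quadrature: adaptive per-panel integration at relative tolerance 10⁻¹⁰,
  panels split at profile knots; square-barrier and flat closed forms are
  the accuracy oracles (10⁻⁶).
* ODE: lsoda, rtol 10⁻¹⁰/atol 10⁻¹⁴; rates pre-tabulated on a 200-point
  temperature grid per protocol segment so the right-hand side stays cheap
  and smooth; occupancy clipped to [0,1] after integration (excursions are
  at integrator tolerance).
* Degenerate inputs: profiles without an interior minimum are flagged
  unbound (ΔG° = 0); monotone profiles have Eₐ = 0; zero injected fraction,
  zero noise, and two-point calibrations are all exact limiting cases.
* Tie-breaks: `extract_thermo` reads extrema off the grid (no
  super-linear interpolation), so feature positions are snapped onto the
  grid by construction in `build_profile`.
* Problem sizes: simulations in the tests and acceptance script use 300 s
  protocol horizons (76–151 output points), 840 s six-addition runs
  sampled at 0.5 s, and 100-seed recovery ensembles — sizes chosen so the
  whole suite runs in about a minute on a laptop while keeping every
  statistical check well-powered.

## Known limitations

* The forward rates are treated as printed inputs; reproducing them from
  first principles would require the unpublished diffusion coefficients,
  binding distance, and full profile shape.
* The two-anchor Arrhenius interpolation is clamped outside [298, 333] K;
  the model is silent about 95 °C operation.
* The hydration attenuation is phenomenological; only orderings across
  PBS dilutions are meaningful, not its functional form.
* Selectivity (the response of other metal ions) involves no stated
  computation and is out of scope.
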