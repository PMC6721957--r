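---
title: "Modelling the stability landscape of an aggregation-prone dimeric enzyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the stability landscape of an aggregation-prone dimeric enzyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscape)
```

## The model

`dimerscape` analyses homodimeric enzymes — fumarylacetoacetate
hydrolase (FAH), the enzyme deficient in hereditary tyrosinemia type I,
is the motivating case — whose behaviour is governed by a coupled
thermodynamic–kinetic scheme:

$$\mathrm{D} \rightleftharpoons 2\,\mathrm{M} \rightleftharpoons 2\,\mathrm{U},
\qquad \mathrm{M} \xrightarrow{k_{Ag}} \mathrm{Ag}$$

The catalytically active dimer D dissociates into an inactive folded
monomer M with dissociation constant $K_D = [\mathrm{M}]^2/[\mathrm{D}]$;
the monomer unfolds reversibly (free energy $\Delta G_{MU}$) and, in
competition, aggregates irreversibly with first-order rate $k_{Ag}$.
Each species and transition is constrained by a different experiment,
and the package provides one fitting operation per data class plus the
assembly step that combines them into a per-variant energy landscape.

Units throughout: concentrations in µM (subunit units unless a quantity
is explicitly "per dimer"), energies in kcal/mol with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹, temperatures in Kelvin
internally (Celsius is accepted at the I/O boundary), rates in s⁻¹.

### Monomer–dimer partitioning and dimer-only activity

Mass balance $C_T = [\mathrm{M}] + 2[\mathrm{D}]$ with
$K_D = [\mathrm{M}]^2/[\mathrm{D}]$ gives the closed-form root

$$[\mathrm{M}] = \frac{K_D}{4}\left(\sqrt{1 + 8C_T/K_D} - 1\right),$$

implemented in `monomer_dimer_partition()`. The paper-scale convention
matters: $K_D$ is defined on subunit concentrations, which matches the
sub-µM dissociation constants reported for FAH-family dimers. The
standard-state dissociation free energy is
$\Delta G_{DM} = -RT\ln(K_D/C^\circ)$ with $C^\circ = 1$ M.

Because the crystal structures place the complete active site across
the dimer interface, only subunits in dimers turn over substrate:
$v = k_{cat}\,2[\mathrm{D}]\,S/(K_m+S)$ (`dimer_activity_rate()`).
$k_{cat}$ is normalized per subunit within the dimer; when the enzyme
concentration and $K_D$ are supplied, `fit_michaelis_menten()` applies
this correction ($k_{cat} = V_{max}/2[\mathrm{D}]$), and the
uncorrected per-total-subunit number is available by omitting $K_D$ —
whether published assays corrected for residual monomer is often
unstated, so both conventions are exposed.

`fit_activity_vs_concentration()` inverts the activity-versus-$C_T$
curve for $K_D$. Both rate fitters minimize *relative* residuals by
default (`relative = TRUE`): initial-rate errors are proportional to
the rate, and weighting by the model prediction is the corresponding
maximum-likelihood objective. On simulated scans at 10% proportional
noise this choice is what makes single replicates land within a factor
of two of the true $K_D$ essentially always; absolute residuals let the
saturated high-concentration points dominate and roughly triple the
spread. Set `relative = FALSE` for homoscedastic data.

### Thermal and chemical denaturation (linear extrapolation model)

A two-state melt is fitted as
$\theta(T) = \theta_F(T)(1-p_U) + \theta_U(T)\,p_U$ with linear
baselines $\theta_F,\theta_U$, unfolded population
$p_U = K/(1+K)$, $K = \exp(-\Delta G(T)/RT)$ and the pure van't Hoff
form $\Delta G(T) = \Delta H(1 - T/T_m)$. $\Delta C_p$ is fixed at zero:
the melts being modelled are characterized by a single enthalpy, and a
heat-capacity term is not identifiable from one irreversible scan. By
construction $\Delta G(T_m) = 0$ exactly.

Dimer-regime melts of aggregation-prone dimers are bimodal: a first
apparent event near the temperature where the dimer dissociates and
aggregation sets in, then the monomer unfolding. `fit_bimodal_melts()`
fits a family of melts at several concentrations globally as a convex
combination of two van't Hoff transitions,

$$p_U(T) = \chi_A\,p_1(T; T_{m1}, \Delta H_1) +
  (1-\chi_A)\,p_2(T; T_{m2}, \Delta H_2),$$

with $T_{m1}$, $T_{m2}$, both enthalpies and both baselines shared
across the family and one aggregate fraction $\chi_A \in [0,1]$ per
curve (logistic-transformed, so the bound is enforced smoothly). Three
sharing choices were genuinely open and are resolved as follows:
baselines are shared between the two transitions (the two events report
on the same chromophore, and per-transition baselines are not
identifiable when the transitions overlap); both $T_m$s are shared
across concentrations (the first event's apparent position is
concentration-independent in the data this models, only its weight
grows); and the enthalpies are likewise global. With $\chi_A = 0$ the
model collapses *exactly* to the two-state fit — a property the test
suite checks to 10⁻⁶.

Chemical denaturation uses the same machinery with
$\Delta G(c) = \Delta G_0 - m\,c$ (`fit_chemical_denaturation()`); fits
are sign-agnostic in the ellipticity direction, and the midpoint
satisfies $C_m = \Delta G_0/m$ identically.

`ddg_from_tm_shift()` converts a variant's melting-temperature shift
into a destabilization energy,
$\Delta\Delta G \approx \Delta H^{T_m}(T_m^{wt}-T_m^{mut})/T_m^{wt}$,
the first-order expansion that lets thermal screens stand in for full
chemical denaturation when a single reference enthalpy is justified.

The aggregate fractions feed `phase_diagram()`: the soluble monomer
line $[\mathrm{M}] = (1-\chi_A)C_T$ against the diagonal
$[\mathrm{M}] = C_T$ of a hypothetical aggregation-free species, with
the phenomenological exponential $1-\chi_A = \exp(-C_T/C^\ast)$
supplying a one-parameter scale $C^\ast$ for aggregation propensity.
The exponential is a phenomenological choice; nothing in the model
excludes, say, Hill-like forms, but one parameter is all the 3–6 point
data sets this summarizes can support.

### Aggregation kinetics and the Eyring barrier

Isothermal loss of CD signal is fitted as a single exponential
(`fit_decay()`); the model deliberately excludes stretched exponentials
and nucleation lags because monomer loss in this regime is first-order.
The rate estimate is invariant to affine transforms of the signal, and
traces shorter than $3/k_{Ag}$ are flagged rather than rejected.
`fit_arrhenius()` regresses $\ln k$ on $1/T$ (unweighted by default;
inverse-variance weights from the per-trace errors are available),
yielding $E_a$ and $\ln A$. `barrier_free_energy()` converts any rate
to a transition-state free energy
$\Delta G^\ddagger = RT[\ln(k_BT/h) - \ln k]$ with transmission
coefficient 1. Note that $\ln(k_BT/h) \approx 29.5$ near physiological
temperature; published prefactor comparisons sometimes quote slightly
smaller values whose convention (e.g. $\kappa < 1$) is not always
recoverable, so the package reports the exact Eyring value and leaves
any transmission correction to the user.

### Diffusion and populations

`fit_stejskal_tanner()` fits DOSY gradient attenuation
$I(g) = I_0\exp(-D\gamma^2g^2\delta^2(\Delta-\delta/3))$, seeded by the
log-linear solution and refined on the natural intensity scale so weak,
noisy points are not over-weighted. `stokes_einstein_diameter()`
applies $d = k_BT/(3\pi\eta D)$; water viscosities at 20/25/37 °C are
built in and overridable for buffers. Under fast monomer–dimer exchange
the observed $D$ is the population average, and
`two_species_population()` inverts it for the dimer fraction — the
reference $D$ values of the pure species must be supplied (measured or
structure-derived), since apparent diffusion alone cannot fix both
endpoints.

### Landscape assembly and mechanism classification

`assemble_landscape()` merges, per variant, whatever observables are
available — $K_D$, $k_{Ag}$, $\Delta G_{MU}$, activity — into
WT-referenced ratios and absolute energies ($\Delta G_{DM}$,
$\Delta G_{MU}$, $\Delta G^\ddagger$ at 310.15 K). Missing quantities
stay `NA`; nothing is imputed. `classify_mechanism()` then applies an
ordered rule with three configurable thresholds (defaults printed in
every report):

1. $\Delta G_{MU} < 3$ kcal/mol → `unfolding-destabilized` (a protein
   with a substantially populated unfolded state is a different problem
   regardless of its quaternary behaviour);
2. relative dimer fraction $< 0.7$ *and* relative $k_{Ag} > 2$ →
   `indeterminate`, flagged with both mechanisms;
3. relative dimer fraction $< 0.7$ → `Gr1` (dimer-interface
   destabilization);
4. relative $k_{Ag} > 2$ → `Gr2` (monomer kinetic destabilization);
5. otherwise `WT-like`.

The field's grouping of pathogenic variants into interface versus
kinetic destabilizers is qualitative; no numeric cutoffs exist in the
literature, so these defaults were placed in the gaps between the two
phenotype clusters the synthetic panel emulates and are deliberately
conservative. They are parameters, not facts — classification by
structural location is intentionally *not* used, because interface
variants with normal dimer content exist and the data should decide.

## The synthetic-data generator

Every fitting operation has a paired generator
(`simulate_melt_curve()`, `simulate_melt_family()`,
`simulate_chem_denat()`, `simulate_decay_trace()`,
`simulate_arrhenius_series()`, `simulate_mm_titration()`,
`simulate_ctotal_scan()`, `simulate_dosy_decay()`, orchestrated by
`simulation_design()`/`generate()` and `mutant_panel()`). The defaults
in `wt_defaults()` are the study conditions of the wild-type FAH
system: $T_m = 68.3$ °C and $\Delta H = 75$ kcal/mol for the monomer
melt, $T_{m1} = 48$ °C / $T_{m2} = 70$ °C for the dimer-regime family
with $\chi_A = 1-\exp(-C_T/5\,\mu M)$, $\Delta G_0 = 9.5$ kcal/mol and
$m = 3$ kcal mol⁻¹ M⁻¹, $K_m = 25.2$ µM and $k_{cat} = 0.10$ s⁻¹ at
5 µM enzyme, $K_D = 0.5$ µM, and $E_a = 20.9$ kcal/mol with
$\ln A = 26$ (implying $k_{Ag} \approx 3.7\times10^{-4}$ s⁻¹ at 37 °C,
which is also the decay-trace default — the rate is derived from the
Arrhenius parameters because no directly usable isothermal rate with
units is available). $\Delta H_1 = 60$ kcal/mol for the
aggregation-coupled transition is the one generator default with no
literature anchor; it was chosen once as a plausibly broader-than-
unfolding transition and left alone.

Grids follow the experimental protocols being emulated: melts 25–90 °C
in 0.5 K steps, denaturant 0–7 M in 0.1 M steps, five Arrhenius
temperatures over 302–318 K, ten log-spaced substrate concentrations
from 5 to 500 µM, $C_T \in \{0.1, 0.25, 0.5, 1, 2.5, 5, 10\}$ µM, and
32 gradient steps over 2–95%. Noise models preserve positivity where
physics requires it: additive Gaussian (scaled to the signal span) for
ellipticities, proportional Gaussian for rates, lognormal for rate
constants. Every generator takes a seed, restores the caller's RNG
state, and `generate()` writes a machine-readable `truth.json` that the
parameter-recovery tests treat as the contract.

What the generator does *not* emulate — and therefore what passing
recovery tests do not demonstrate about real data: instrument drift and
1/f noise in CD baselines, partial refolding on cooling, deviations
from single-exponential aggregation (nucleation lags, secondary
processes), convection artefacts in diffusion data, and day-to-day
concentration errors. Recovery medians over 200 replicates measure the
bias of the estimator chain under the assumed noise, not the accuracy
of any particular laboratory measurement.

## Numerical choices

All nonlinear fits run Levenberg–Marquardt (`minpack.lm`) from
data-driven starts — baselines from the outer 15% of each scan,
transition positions from derivative extrema of a smoothing spline —
plus jittered restarts under a fixed seed, keeping the best deviance;
convergence tolerances are 10⁻¹². Positive parameters ($\Delta H$, $m$,
$k$, $K_m$, $V_{max}$, $K_D$, $C^\ast$) are fitted on the log scale and
$\chi_A$ through a logistic transform, which enforces bounds without
constrained optimization; standard errors are mapped back by the delta
method and reported as 1σ from the fit covariance (no bootstrap by
default). Degenerate inputs fail loudly with classed errors: flat melts
and non-decaying traces are rejected against a 3σ amplitude test,
midpoints outside the sampled range are fit failures, and
unidentifiable designs (all $C_T \gg K_D$) attach warning flags rather
than returning silently useless numbers. The ordering
$T_{m1} < T_{m2}$ is enforced by parameterizing the gap on the log
scale. `simulate_scheme1_timecourse()` integrates the aggregation flux
with `deSolve::lsoda` under the rapid pre-equilibrium assumption
(dimer–monomer exchange fast relative to aggregation, which is how the
scheme is defined) at tolerances that hold mass conservation to 10⁻⁶
relative.

Problem sizes in the validation suite — 200 replicates per
single-curve recovery study and 50 replicate families for the global
bimodal fit — were chosen so that the Monte-Carlo error of a reported
median is well below the experimental uncertainty of the corresponding
published parameter.

## Known limitations

* Aggregation is strictly first-order in monomer; nucleation–elongation
  or higher-order mechanisms require a different kinetic module.
* The bimodal melt model treats $\chi_A$ as temperature-independent
  within one scan — it is the $t \to 0$, $T \approx T_{m1}$ snapshot of
  a process that in reality keeps running during the scan.
* $\Delta C_p = 0$ means extrapolated $\Delta G(T)$ values far from
  $T_m$ are upper bounds rather than estimates.
* The two-species diffusion inversion assumes fast exchange; slow
  exchange would show two resolved diffusion components instead, and
  the population formula does not apply.
* Classification thresholds are tunable conventions; borderline
  variants should be reported with their flags, not just their group.
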