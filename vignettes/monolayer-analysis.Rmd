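---
title: "Monolayer thermodynamics with langmuir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer thermodynamics with langmuir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmuir)
```

## The experimental system

A Langmuir film balance records the surface pressure $\Pi$ (mN/m) of an
insoluble film spread at the air–water interface as a function of the
area available per molecule $A$ (Å²). This package analyses three kinds
of records from such experiments on lipid–polymer films:

* **compression isotherms** $\Pi(A)$ of pure lipids, pure polymers and
  co-spread mixtures;
* **adsorption traces** $\Pi(t)$ after injecting polymer underneath a
  preformed lipid monolayer held at an initial pressure $\Pi_{ini}$;
* **epifluorescence micrographs** of the coexisting liquid-expanded (LE)
  and liquid-condensed (LC) phases.

The motivating system is a monofluorinated DPPC analogue mixed with an
amphiphilic triblock copolymer, with and without perfluoroalkyl end
caps; the polymer with fluorous anchors resists expulsion from the film
up to markedly higher pressures. None of the analyses are specific to
that chemistry.

Units are fixed package-wide: Å² (per molecule or per lipid), mN/m,
seconds, °C. Compression order is decreasing area.

## Isotherm features

`monotonize()` makes $A(\Pi)$ single-valued by replacing pressure with
its running maximum along compression and collapsing pressure ties to
the largest-area sample. The tie rule means a coexistence plateau is
read at its *onset* (first attainment), not its completion — relevant
when interpolating inside the LE–LC plateau, where $A(\Pi)$ is nearly
multivalued.

Three features are extracted:

* **Lift-off area** — where $\Pi$ first deviates from zero, read at a
  0.5 mN/m threshold (the usual Wilhelmy-plate uncertainty).
* **Compressibility modulus** $C_s^{-1} = -A\,\partial\Pi/\partial A$,
  estimated by a symmetric local quadratic fit (default window
  11 samples). The window is exposed because smoothing conventions are
  not standardized.
* **LE–LC transition onset** — the first point, past lift-off, where
  $C_s^{-1}$ drops below a fraction (default 0.25) of the running median
  of the preceding LE branch, sustained for 2 samples. How kink points
  are read off an isotherm is nowhere standardized; this criterion is
  this package's documented choice, and plateaus in practice drop
  $C_s^{-1}$ by a factor of 10–30 so the 0.25 fraction is not delicate.

**A deliberate deviation.** `lift_off_area()` and `transition_onset()`
accept *raw* (non-monotonized) curves and work on the samples as given.
Running-maximum monotonization clips negative noise excursions only:
under $\sigma_\Pi = 0.1$ mN/m it biases a naive threshold crossing by
about +1 Å² and decimates the near-flat plateau (pressure increments on
the plateau are smaller than the noise, so most samples land in tie
runs). Raw pressure noise is zero-mean, so local least-squares fits on
the raw samples are unbiased; for noiseless input both routes agree
exactly. `area_at_pressure()` keeps the strict monotonized precondition
and never extrapolates — downstream analyses restrict themselves to
overlapping pressure ranges instead.

The lift-off estimate is refined by a straight-line fit of the raw
samples within ±4 Å² of the smoothed crossing. The half-width is a
bias–variance compromise: ±3 gives 0.24 Å² estimator SD, ±4 gives
0.21 Å² with a +0.09 Å² curvature bias, ±5 lets the LE-branch curvature
through (bias +0.16 Å²).

## Ideal mixing and excess area

For a binary film the additivity rule predicts, at each pressure,

$$A_{calc}(\Pi) = x_{polymer} A_{polymer}(\Pi) + x_{lipid} A_{lipid}(\Pi),$$

valid both for ideal mixing and for complete demixing. The rule is
evaluated per total molecule (`ideal_additive_isotherm()`) and only then
converted per lipid (`to_per_lipid()`), matching the convention of
plotting mixed-film isotherms against the pure lipid "based on lipid
content only". Mixing the two conventions raises an error rather than a
silently wrong area.

Two difference series are provided, both per lipid:
`area_shift_vs_lipid()` ($\Delta A$ vs the pure lipid — how much space
the polymer occupies) and `excess_area_of_mixing()` ($\Delta A$ vs the
calculated ideal curve — the non-ideality proper; positive values mean
the film occupies more area than additivity predicts).

`convergence_pressure()` reports the smallest pressure above which
$|\Delta A|$ *stays* within 2 Å² (the molecular-area uncertainty) of the
pure lipid through the end of the shared range: sustained coincidence
signals complete squeeze-out of the polymer into the subphase. A single
crossing is not accepted, for noise robustness; "never converges" is a
valid `NA` outcome, not an error.

`excess_peak()` smooths the $\Delta A$ series (11-sample running mean)
before taking its maximum. The raw pointwise maximum is biased high
wherever $A(\Pi)$ is near-flat: inverting a noisy, almost horizontal
isotherm turns $\sigma_\Pi = 0.1$ mN/m into area spikes of several Å²
(the plateau's $|dA/d\Pi| \approx 50$ Å² per mN/m). With smoothing, a
programmed 15 Å² Gaussian excess is recovered within ±2 Å² in 100 % of
200 seeded runs; without, in 64 %.

## Insertion kinetics and the maximum insertion pressure

Injected polymer raises the surface pressure by
$\Delta\Pi = \Pi_{max} - \Pi_{ini}$ (mode `"max"`, the conventional
definition, floored at zero) or by $\pi_{eq} - \Pi_{ini}$ from a
kinetics fit (mode `"fitted_eq"`, less biased when the trace has not
equilibrated — both are reported because which one a given study used is
rarely stated).

`fit_adsorption_kinetics()` fits
$\Pi(t) = \pi_{eq} - \sum_i a_i e^{-t/\tau_i}$ for one and two
components by bounded least squares ($a_i \ge 0$: adsorption only raises
$\Pi$ here) from deterministic log-spaced $\tau$ starts — no random
initialization, so fits are reproducible without seeds. Order selection
uses AICc with a tie margin of 2 in favour of order 1, *plus*
identifiability guards before a second component is reported:
$\tau_{slow}/\tau_{fast} \ge 4$, both amplitudes ≥ 10 % of the total
rise, and $\tau_{fast}$ at least half the sampling interval. The guards
exist because the AICc margin alone admits noise-chasing second
components at a ~2–5 % rate (the SSE gain from two spurious parameters
has a $\chi^2_2$ tail); components inside the guard limits are not
resolvable at film-balance noise levels, while genuinely distinct
fast/slow adsorption regimes (τ ratio ~20, comparable amplitudes) are
far outside them. The cost is deliberate: a true but barely separated
second process (τ ratio < 4) is reported as order 1.

`mip_from_series()` fits an ordinary least-squares line through
$(\Pi_{ini}, \Delta\Pi)$ points with $\Delta\Pi > 0$; its x-intercept is
the **maximum insertion pressure** (exclusion pressure $\Pi_e$), the
initial pressure at which the polymer no longer inserts. The
extrapolation method in the literature is usually unstated; OLS on all
positive points is the field convention, and the slope/intercept
covariance is propagated to a standard error so alternative weightings
can be compared against it.

## Domain imaging

`segment_dark_domains()` thresholds a micrograph (Otsu or fixed level);
the dark-phase convention follows probes excluded from the condensed
phase (LC domains dark), with `invert = TRUE` for probes that accumulate
in the LC phase. `domain_stats()` reports the exact pixel area fraction
and 8-connected component count, border-touching components included —
the simplest defensible convention, recorded in the CLI output.
Domain-shape taxonomy (bean / propeller / seaweed shapes) is
deliberately not quantified.

The isotherm cross-check `predicted_lc_coverage()` uses the relation
$\phi_{pred} = A_{lipid}(\Pi) / A_{mix,per\,lipid}(\Pi)$: once the LE–LC
transition is essentially complete, condensed lipid occupies the
pure-lipid area while the mixed film's per-lipid area also carries the
polymer's share — a mixed film at twice the pure-lipid area predicts
50 % dark coverage. Whether the transition is complete at the chosen
pressure is the caller's responsibility and is recorded as a flag.

Images travel as plain ASCII PGM (P2): no PNG/TIFF codec is available in
the dependency budget, and a text dialect keeps the artifacts diffable.

## The synthetic stated world

The generators emulate the phenomenology of the motivating experiments;
their defaults *are* the stated world of the test suite and are never
tuned against test outcomes.

* **Lipid isotherm** (`simulate_lipid_isotherm()`): piecewise — a
  "zero-pressure" gas tail, a Volmer LE branch
  $\Pi = kT/(A-\omega) - \Pi_{coh}$ (with $kT = 404.7$ Å² mN/m at
  20 °C), a plateau of slope 0.02 mN/m/Å² from $\Pi_t = 9$ mN/m, and an
  LC branch of slope 3 mN/m/Å² up to collapse at 55 mN/m. With
  $\omega = 50$ Å², $\Pi_{coh}$ is solved so the 0.5 mN/m lift-off falls
  exactly at 110 Å². The Volmer form is a modelling choice of this
  package — the motivating study fits no equation of state.
* **Polymer isotherm** (`simulate_polymer_isotherm()`): pancake area
  2500 Å² decaying as $(1+\Pi/8)^{-2}$ toward a brush regime, multiplied
  by a logistic squeeze-out retention centred at 32.5 (`gp_like`) or
  42.4 mN/m (`fgp_like`) with width 0.5 mN/m. The width is set so
  squeeze-out completes within ~2 mN/m, consistent with the sharp
  coincidence of mixed and pure isotherms; it also fixes the intrinsic
  +0.8 mN/m offset between the programmed sigmoid centre and the
  detected convergence pressure (inside the ±1 mN/m acceptance band).
* **Mixed film** (`simulate_mixed_isotherm()`):
  $A_{mix} = A_{lipid} + (x_p/x_l) A_{polymer} + E(\Pi)$ per lipid, with
  a prescribed excess profile $E$ (zero allowed; `gaussian_excess()`
  provides the 15 Å² / 12 mN/m / 5 mN/m default bump).
* **Adsorption trace** (`simulate_adsorption_trace()`): equilibrium rise
  $\Delta\Pi_{eq} = \max(0, s\,(\Pi_e - \Pi_{ini}))$ approached
  biexponentially ($\tau$ 30 s and 600 s, 60 % fast share, 3600 s
  duration). The slopes are anchored to printed physics: the
  zero-coverage intercept equals the equilibrium adsorption pressure at
  the bare surface (13 / 24 mN/m at 200 nM), so $s = 13/32.5 = 0.40$ and
  $24/42.4 = 0.566$.
* **Micrograph** (`simulate_micrograph()`): harmonically perturbed dark
  ellipses on a jittered grid (one per cell, so coverage up to dense
  packing is reachable without overlap), radii bisected until the
  realized fraction is within 0.005 of target; background 200, contrast
  160, Gaussian intensity noise.

Noise is Gaussian on *pressure* only (σ default 0.1 mN/m, well under
the ±0.5 instrument uncertainty): on a real trough the barrier program
sets the area and pressure is the measured quantity. All randomness
flows from one explicit seed per call through an RNG-state-preserving
wrapper; generators are pure functions of (parameters, seed).

Two small departures from idealized forms keep every noiseless curve
strictly monotone (and hence invariant under `monotonize()`): the gas
tail decays exponentially below 0.01 mN/m instead of being exactly
zero, and the squeezed-out polymer branch retains a residual
compressibility of 0.002 Å² per mN/m.

**What a green test does not establish.** The generators reproduce
landmark values and qualitative shapes, not real-trough artifacts:
no drift, no leakage, no barrier-speed hysteresis, no multivalued
plateaus from domain nucleation kinetics, no uneven illumination or
vignetting in images. Parameter-recovery results bound estimator error
under the stated noise model only.

## Numerical choices and degenerate inputs

* Interpolation is piecewise linear; out-of-range queries are errors,
  never extrapolations.
* Pressure ties collapse to the largest-area sample; curves with fewer
  than 2 surviving samples raise a degenerate-curve error.
* The AICc comparison is skipped (order 1 wins) when residuals reach
  numerical precision, where the log-SSE ratio is meaningless.
* Constant images make Otsu's threshold undefined → a
  degenerate-threshold error; constant adsorption traces fit as order 1
  with zero amplitude.
* A convergence pressure is only reported if the tolerance band holds
  through the end of the shared range (all remaining samples).

## Limitations

* Per-lipid vs per-molecule axes of experimental mixed-film files must
  be declared in the file metadata; the package enforces convention
  consistency but cannot detect a mislabelled file.
* The LE–LC onset criterion presumes the plateau depresses $C_s^{-1}$ by
  more than the configured fraction relative to the LE branch; gentle
  second-order-like transitions will return the no-transition flag.
* Kinetics fits report at most two exponential components, and only
  when well separated (see guards above).
* No free-energy-of-mixing integration, no three-component mixtures, no
  diffusion-limited (Ward–Tordai) adsorption modelling, no
  fractal-dimension or domain-shape analysis.
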