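---
title: "Growth-rate-guided boost scheduling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate-guided boost scheduling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftgr)
```

This vignette documents the models behind `ftgr`, the choices made where the
underlying methodology leaves room, and what the package's synthetic-data
tests do and do not establish about real data.

## The measurement model

Subcutaneous tumors are measured with a digital caliper along two axes and
volumes computed as $V = 0.5\,w^2 l$ (mm³), the standard prolate-ellipsoid
approximation with the width as the doubly counted short axis. The package
enforces the convention $l \ge w$ by swapping transposed pairs with a warning
rather than erroring: transposed columns are among the most common artefacts
in hand-recorded caliper sheets, and the volume formula is *not* symmetric in
its arguments, so silent acceptance would bias volumes.

Cohort summaries use the arithmetic group mean of per-animal volumes at each
grid day, which is the quantity the downstream indicator is defined on.
Animals are censored from the mean from their first non-alive record onward,
and the per-day animal count is carried in the series so composition changes
remain visible. Missing interior days are a hard error by default; optional
repair interpolates linearly in log-volume (growth is multiplicative), but is
off by default because an interpolated point could fabricate a boost trigger.

## FTGR and its day-label convention

On a uniform grid with step $h$ (2 days by default), the fluctuation of
tumor growth rate at the triplet $(t_{n-1}, t_n, t_{n+1})$ is

$$\mathrm{FTGR} \;=\; \frac{V(t_{n+1})-V(t_n)}{V(t_n)}\cdot 100\%
\;-\; \frac{V(t_n)-V(t_{n-1})}{V(t_{n-1})}\cdot 100\%,$$

a discrete second-difference of log-like growth: zero for any exact
exponential (constant fold-change), negative while growth decelerates,
positive when it accelerates. Values are carried in percent throughout
(−13.2 means −13.2%).

A triplet value can be indexed by any of its three days. `ftgr` defaults to
the **latest** day ($t_{n+1}$): a value is reported at the last day whose
measurement it requires, so every value is computable on its label day and a
same-day boost decision never peeks at the future. The **middle** convention
($t_n$) is offered for plotting and retrospective analysis; the two are the
same values shifted by one grid step, and `detect_triggers()` refuses
middle-labelled traces outright rather than risking a non-causal decision.

FTGR is computed on the group-mean series, not averaged over per-animal FTGR
values: the indicator is defined on mean tumor volume, and the ratio of means
is not the mean of ratios. Per-animal traces can still be formed by passing
single-animal series.

## The trigger rule

A booster irradiation is called on the first measurement day whose FTGR value
is **strictly** greater than the threshold (default 0): an exact zero means
the growth rate is not yet accelerating and waits. The decision executes the
same day the crossing is observed — no lookahead, no lag parameter. Two
guards are available: a cap on the number of boosts and a minimum gap between
events (a crossing inside the gap is suppressed and logged). By default the
number of boosts is uncapped: the engine stops adaptively when the trace
stays below threshold, which is the behaviour the indicator is designed for —
tumors of different aggressiveness earn different numbers of boosts.

## TGI

Arms are scored by tumor growth inhibition at an evaluation day $t$,
$\mathrm{TGI} = [1 - (T_t/T_0)/(C_t/C_0)]\cdot 100\%$, the fold-change of the
treated arm relative to the control's, both from the post-randomization
baseline. TGI is invariant to per-arm unit rescaling, equals 0 for equal
fold-changes, and is bounded above by 100% for positive volumes.

## The synthetic cohort generator

The generator exists so the full pipeline — volumetry, FTGR, triggering,
regimen scoring — can be exercised end to end with known ground truth. The
latent trajectory follows Gompertz growth with treatment-induced kill:

$$\frac{dV}{dt} = a\,V \ln\!\frac{K}{V} \;-\; k(t)\,V, \qquad
k(t) = \sum_i A_i\, e^{-(t - t_i - L)/\tau_\mathrm{eff}}
\;\; \text{for } t \ge t_i + L.$$

Gompertz was chosen over pure exponential growth so that untreated FTGR is
slightly negative late in the study (decelerating growth), making the
treatment-induced dip the dominant signal rather than the only one; exact
exponential series remain available analytically for invariance tests.

Each irradiation event $i$ at day $t_i$ contributes a death-rate pulse with
onset lag $L$ (adaptive immune responses need days to expand) and decay time
$\tau_\mathrm{eff}$. The first (vaccination-day) event has amplitude
$A_1 = k_0$. Booster amplitudes are attenuated by two factors:

$$A_i = k_0 \cdot e^{-(t_i - t_1)/\tau_\mathrm{vax}}
\cdot \big(1 - e^{-(t_i - t_{i-1})/\tau_\mathrm{refract}}\big).$$

The first factor models decay of the injected vaccine depot — later
irradiations re-heat less antigen; the second models refractoriness — a
boost delivered while the previous response is still expanding adds little.
This extension is deliberate: with a time-invariant pulse, the log-volume
dynamics are linear and a later boost *always* yields more inhibition at a
fixed evaluation day, so no timing rule could ever be optimal and the
scheduling problem the indicator addresses would not exist in the simulator.
The two attenuation terms are the minimal phenomenology that gives boosting
an interior optimum in time. No mechanistic fidelity is claimed for either
term, and irradiation physics (temperature, heat-shock-protein induction)
are not modelled — an event maps directly to a kill pulse.

### Default parameters

The defaults define the package's reference study: cohorts of 6 animals
enrolled at $V_0 = 60$ mm³, measured every 2 days to day 20.

| parameter | default | units | role |
|---|---|---|---|
| `a` | 0.03 | day⁻¹ | Gompertz rate |
| `K` | 4000 | mm³ | carrying capacity |
| `noise_cv` | 0.05 | — | lognormal CV of a measured volume |
| `k0` | 0.25 | day⁻¹ | peak kill of the first event |
| `tau_eff` | 6 | days | kill-pulse decay |
| `onset_lag` | 3 | days | irradiation-to-effect delay |
| `vax_decay` | 15 | days | depot decay for boosters |
| `refractory` | 5 | days | booster blunting time constant |

`a` and `K` give untreated growth of roughly 60 → 2000 mm³ over 20 days, a
typical aggressive syngeneic-model pace; `noise_cv` of 5% reflects careful
caliper work on small tumors. The treatment constants were then fixed, once, by a coarse search so that the
reference single-irradiation cohort at seed 1 shows the qualitative
signature the indicator is designed around: the mean-trace FTGR dips below
−10% and re-crosses 0 exactly once within days 6–12 (at day 8 under the
causal convention). They are the package's own fixture values, not estimates
of any real tumor model. With these defaults a noiseless booster-day sweep
(4 days before the trigger, on the trigger day, 6 days after) is maximised
at the trigger day when scored by TGI at day 20 — the behaviour that makes
on-demand scheduling worth doing — with modest margins between the arms.

Measurement noise is multiplicative lognormal with mean 1 (caliper error
scales with tumor size), applied at measurement only: the latent trajectory
is shared by all animals of an arm, so inter-animal variation in the
generator is purely observational. Caliper width/length are back-solved from
the noisy volume under a fixed aspect ratio $w = 0.8\,l$; any ratio yields
identical volumes by construction, which is verified by test.

### What the generator does not emulate

Real cohorts have inter-animal heterogeneity in growth rate and treatment
response, non-lognormal measurement artefacts (digit preference, transposed
axes), occasional deaths and dropouts, and randomization splits that shrink
the measured group over time. The generator reproduces none of these (beyond
optional `alive` flags handled by the aggregation layer), so a green test
suite demonstrates the *algorithms* — causality, determinism, thresholding,
scoring — not robustness of the indicator to real-world noise regimes.
Sensitivity of trigger days to `noise_cv` is easy to explore but is not part
of the default test conditions.

## Numerical choices

- **Integrator.** Fixed-step classical Runge–Kutta (RK4) at 0.01 day on the
  volume scale, floored at $10^{-6}$ mm³ with a warning. A fixed step keeps
  trajectories bit-identical across platforms (an adaptive integrator's step
  history may not be); at this step the untreated trajectory agrees with the
  Gompertz closed form to better than $10^{-6}$ relative, verified by test.
- **Seeding.** Every stochastic function takes an explicit seed and restores
  the caller's RNG state; noise is pre-drawn in one block per arm so that an
  adaptive schedule cannot perturb the noise stream (decisions change events,
  never measurements).
- **Trigger comparisons.** Strict `>` at the threshold; grid days are
  integers so no floating-point day arithmetic occurs.

## Photothermal efficiency estimation

Heating–cooling traces are analysed by the single-compartment energy
balance. With sample mass $m$, specific heat $C_p$, laser power $I$,
absorbance $A$ at the laser wavelength and ambient temperature
$T_\mathrm{surr}$:

$$ m C_p \frac{dT}{dt} = \eta I (1 - 10^{-A}) + Q_\mathrm{dis}
 - hS\,(T - T_\mathrm{surr}), $$

so the plateau satisfies $hS\,\Delta T_\mathrm{max} =
\eta I(1-10^{-A}) + Q_\mathrm{dis}$ and free cooling is exponential with
$\tau_s = m C_p / hS$. The estimator:

- **Plateau**: mean of the final 10% of the hottest heating phase. This is
  robust to sensor noise without curve fitting, but biased low if heating is
  truncated before steady state — traces should heat for ≥ ~6 τ (documented
  on `estimate_eta()`; at 8 τ the residual bias is below 0.1% of η).
- **Cooling fit**: $\tau_s$ is the least-squares slope of elapsed time
  against $-\ln\theta$, $\theta = (T - T_\mathrm{surr})/(T_\mathrm{max} -
  T_\mathrm{surr})$, restricted to $\theta \in [0.1, 0.9]$: the window
  excludes the logarithm's blow-up near ambient and transients near the
  plateau. An $R^2$ below 0.995 raises a poor-fit warning (a biexponential
  decay — e.g. a sample exchanging heat with its holder on two scales —
  lands well below it, while Gaussian sensor noise of 0.05 K does not).
- **$Q_\mathrm{dis}$** (solvent/container baseline) defaults to 0 with a
  warning when unspecified, since omitting a measured blank inflates η.
- **Identities**: $hS\,\tau_s = m C_p$ holds exactly in returned objects;
  estimates are invariant to time shifts and to whole-trace temperature
  offsets when ambient is taken from the trace.
- Laser power is `power_density × area_cm2`; the spot area has no default
  because it is rig-specific.

The thermal forward model (`predict_heating_curve()`,
`simulate_thermal_trace()`) is the analytic solution of the same ODE, which
makes estimator validation a true round trip: tests recover η within 0.5%
absolute noiselessly and within 3% under 0.05 K Gaussian noise across 100
seeds.

## Problem sizes

The test suite and the acceptance script run cohorts of 6 animals over 20
days (11 grid points), FTGR property checks over 1000 random series, and
photothermal Monte Carlo over 100 traces of ~4000 samples — sizes chosen to
match the reference study design while keeping the whole suite fast on a
single CPU.

## Known limitations

- FTGR on group means is sensitive to cohort composition changes; the
  package reports `n_animals` per day but does not adjust for informative
  censoring.
- The trigger rule reacts to measurement noise like any threshold rule;
  with noisy small cohorts, crossings can shift by one grid step (the
  acceptance outputs expose this honestly across seeds).
- The treatment model is phenomenological; its attenuation constants shape
  *when* boosting is optimal and should not be interpreted biologically.
- The plateau estimator assumes heating reaches steady state; for truncated
  heating phases, fit-based plateau extrapolation would be needed.
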