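---
title: "Modeling a genetic delay circuit: gate kinetics, plate-reader analytics, and the turn-on-rate trend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a genetic delay circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaygate)
```

## The system and the model

`delaygate` models a two-input transcriptional delay circuit: a bacterial
strain that produces a fluorescent reporter only when both of its inducers
(arabinose and a homoserine lactone, HSL) are present, with a built-in
delay set by the relaxation kinetics of the gate cascade.  The package
covers the full test-and-learn loop around such a circuit: steady-state and
dynamic gate models, plate-reader trace analytics, staged parameter
estimation across bacterial growth phases, and a trend model that predicts
circuit behavior for induction times that were never measured.

### Steady state

Each internal gate is a Hill-type response function of its input RNAP flux
$x$, in relative promoter units (RPU):

$$y_\mathrm{rep}(x) = y_{\min} + (y_{\max}-y_{\min})
  \frac{\kappa^n}{\kappa^n + x^n}, \qquad
  y_\mathrm{act}(x) = y_{\min} + (y_{\max}-y_{\min})
  \frac{x^n}{\kappa^n + x^n}.$$

Sensor gates are digital: output $x_{\max}$ when their inducer is present
($q=1$) and $x_{\min}$ when absent — there is no dose-response curve in the
base model.  A sensor re-used downstream of other gates is promoted to a
graded Hill gate with `as_gate_params()`.  Where several wires meet at one
gate, the input RNAP fluxes are summed before the Hill function is applied:
fluxes converging on a shared promoter region are additive in this
framework.  `circuit_steady_state()` propagates these rules over the
acyclic wiring in topological order; a property test checks the result
against damped fixed-point iteration on random DAGs to $10^{-12}$
relative.

### Dynamics

Between steady states each gate relaxes with a first-order law

$$\frac{dy_i}{dt} = \tau\,\bigl(y_i^{SS}(t) - y_i\bigr), \qquad
  \tau = \begin{cases}\tau^{ON} & y_i^{SS} > y_i\\
                       \tau^{OFF} & \text{otherwise,}\end{cases}$$

where $y_i^{SS}$ is the Hill steady state evaluated at the *current*
upstream fluxes.  The two rates bundle every underlying production,
degradation, and dilution process into the phenomenological response times
a plate reader actually sees.  The reporter obeys the same law toward
`rpu_to_au * input_flux`.  Two conventions exist in the literature for
"$\tau$": a first-order **rate** (1/min) and a **time constant** (min).
The package treats $\tau$ as a rate — fitted magnitudes of
$10^{-2}$–$10^{-1}\,$min$^{-1}$ then imply 10–100 min relaxation
timescales, consistent with the observed 180–240 min circuit delays — and
isolates the alternative reading behind
`solver_config(tau_convention = "time_constant")`.

Integration uses the adaptive embedded Dormand–Prince 4(5) pair from
**deSolve** (default `rtol = 1e-6`, `atol = 1e-9`), piecewise between
induction events: only the digital sensor states switch at an event, the
continuous state carries over.  The dense solution is resampled on a
uniform 1-min grid because every downstream analytic assumes uniform
spacing.  Negative undershoots are clamped at zero, and anything below
$-10\,\cdot$`atol` is reported rather than silently absorbed.

**Initial condition.**  "Steady state at $t=0$" means the steady state of
the *pre-event* baseline (all inducers absent); events scheduled at $t=0$
are then applied as switches.  The alternative — initializing at the
post-event steady state — would make every induction-at-zero experiment
start already ON, which contradicts what such an experiment measures.  An
`all_zero` init is provided for exploring setup transients.

### The delay circuit fixture

`delay_circuit()` is a NOR-based AND stage: each sensor drives a NOT gate
and the two NOT outputs sum into a final repressor, so the output is high
only when both inducers are present.  With HSL alone from $t=0$, the
simulated reporter stays below 1% of its eventual plateau until arabinose
arrives — the failure-free delay behavior the circuit is designed for.
Gate parameter magnitudes (fluxes of order 0.01–3 RPU, Hill $n$ of 4–5,
$\tau$ of 0.008–0.03 min$^{-1}$) bracket the range reported for
standardized gate libraries; they are a committed fixture, not estimates
of any particular strain.

## Plate-reader analytics

All metrics follow the assay conventions of kinetic plate-reader
experiments sampled every 10 min:

* **Normalization**: per time point, $(\bar F - \bar F_\mathrm{blank}) /
  \overline{OD}$, replicate-averaged *before* the metric is formed.  The
  OD denominator is blank-corrected by default (media turbidity otherwise
  biases the per-cell signal), with `od_blank_correct = FALSE` restoring
  the literal uncorrected rule.
* **Detection time**: first grid time the sample's normalized trace
  strictly exceeds the negative control's and stays above for a debounce
  window (default 2 grid points; `debounce = 1` is the literal single-point
  rule, which replicate noise makes unstable).  Crossing times are reported
  at grid resolution — the measurement's own resolution — not interpolated.
* **Doubling time** is the exception: the 0.2→0.4 OD threshold rule uses
  linearly interpolated crossings, since it estimates a continuous quantity.
* **Lysis / rescue**: first debounced OD decline while the control keeps
  growing, and the first debounced post-lysis increase.
* **Accumulated fluorescence**: left-closed 60-min bins from the detection
  time; the bins partition the trace, so their sum equals the total — a
  property every fixture asserts.
* **Growth phases** (EL, LL, EE, ME, LE, S) are called from the fraction of
  the OD rise completed, with configurable boundaries
  (`growth_phase_config()`).  The boundary values are a documented
  convention: the field reports no standard thresholds, so these defaults
  are configuration, not claims.

## Parameter estimation

All fits minimize the sum of squared *relative* errors (normalized least
squares) with bounded Levenberg–Marquardt (**minpack.lm**), restarted from
`n_starts` log-uniform draws within the bounds (default 100, fixed seed):
relaxation rates and flux parameters span orders of magnitude, so uniform
draws would oversample the top decade.  Default bounds are
$\tau \in [10^{-4}, 10]$ min$^{-1}$, fluxes $\in [10^{-6}, 100]$ RPU,
$n \in [0.5, 8]$.  A start counts as converged when the optimizer reports
success; the winner is the converged start with the smallest chi-squared.
Converged starts that tie the winner but scatter widely in a parameter mark
that parameter *unidentifiable* — flat dose-response data flags $\kappa$
and $n$ this way, and a trace already at its plateau flags the rates.

The OFF-to-ON model is a two-stage cascade: a sensor stage rising as
$x(t) = x_{SS}(1 - e^{-\tau_x^{ON} t})$ feeding
$dy/dt = \tau_y^{ON}(x - y)$, fitted in closed form.  At a near-zero
initial level the two rates enter the solution symmetrically, so
unconstrained fits are reported under the convention
$\tau_x^{ON} \ge \tau_y^{ON}$ (the sensor stage is no slower than the
reporter stage); once either rate is fixed the ambiguity disappears.  The
ON-to-OFF model is single-exponential decay.

### Staged refitting

Fitting every phase with all parameters free lets the optimizer trade
parameters off against each other, which buries any growth-phase trend in
compensation noise.  The staged workflow pins the shared parameters one at
a time:

1. fit $\tau_y^{OFF}$ to each phase's decay experiment and fix its
   cross-phase mean;
2. fit the rise model everywhere, fix $x_{SS}$ at its cross-phase mean;
3. refit, fix $\tau_x^{ON}$ likewise;
4. final refit with only $\tau_y^{ON}$ free — one turn-on rate per phase.

Cross-phase averages are unweighted arithmetic means of the converged
estimates (no fit-quality weighting is attempted).  The full per-iteration
ledger is returned for audit.  On noiseless synthetic phases generated with
a common $(x_{SS}, \tau_x^{ON}, \tau_y^{OFF})$ and per-phase
$\tau_y^{ON} \in \{0.12, 0.08, 0.05, 0.03\}$, the workflow recovers each
rate within 2% and preserves the decreasing order; under replicate noise
the unconstrained workflow spreads the shared parameters across phases
while the staged one pins them — the compensation effect the staging
exists to remove.

## The turn-on-rate trend

Later induction turns gates on more slowly.  The Learn step condenses this
into a four-parameter logistic in the induction time $x$:

$$\tau_y^{ON}(x) = \frac{L}{1 + e^{k (x - x_0)}} + b.$$

The generic four-parameter logistic admits rising and falling orientations;
the falling form is adopted because the fitted $\tau_y^{ON}$ values
decrease with later induction while the reported steepness is positive.
The rising form stays available via `orientation = "rising"` for
sensitivity analysis.  `tau_trend_defaults()` carries the published
reference constants ($L = 1.02423886\times10^{-1}$,
$x_0 = 3.13060089\times10^{2}$ min, $k = 1.80082383\times10^{-2}$
min$^{-1}$, $b = 1.95602872\times10^{-2}$); fitting noiseless points drawn
from them at six induction times recovers all four to $10^{-4}$ relative —
the package's round-trip consistency anchor.

`predict_untested()` composes the pipeline: predict $\tau_y^{ON}$ at an
untested induction time, substitute it into the reporter stage, and
simulate with the second inducer added at that time.  Because the
substituted $\tau$ only sets the relaxation *rate*, its steady state is
unchanged — but over a finite assay window a slower rise also lowers the
maximum attained signal, which is how a rate-only parameter reproduces the
observed intensity differences.  Predictions beyond 1.5× the largest
fitted induction time warn: the trend is interpolative, and nothing
constrains the logistic tails outside the fitted range.

## The synthetic generator

No raw plate-reader data ship with the package, so every recovery test
runs against `generate_*` output with recorded ground truth.  The
observation model is the minimal one under which the normalization formula
above is the exact inverse:

$$F = F_\mathrm{blank} + OD_\mathrm{true}\cdot s(t)\cdot(1+\varepsilon_m)
      + \varepsilon_a, \qquad
  OD_\mathrm{read} = OD_\mathrm{true} + OD_\mathrm{media} + \varepsilon_o,$$

with $s(t)$ the simulated per-cell reporter signal, multiplicative CV and
additive SD noise per point, and fluorescence **quantized to whole au
counts** — plate readers report integer counts, and this resolution floor
is what makes a noise-free detection time meaningful at all (without it an
induced trace exceeds the control at the first grid step).  Growth is
logistic with a lag; lysis experiments switch to exponential OD decline at
the configured delay and regrow from the rescue time.

Two calibrations are committed as fixtures, tuned once and never revisited:
the optimal-lab-condition preset (`olc_preset()`, reporter scale
`rpu_to_au = 4`) places the noise-free control-condition detection time at
180 min — the optimal detection time — and the early-lag lysis preset
(`lysis_preset()`) places the lysis call at 240 min and rescue at 650 min.
Replicate counts default to 5, sampling to 10-min over 800 min, and
ON/OFF characterization series to 650 min, matching the standard assay
design.  Named condition presets (temperature, inducer ratio, soil) scale
amplitude, rates, and noise in the observed trend direction only; their
magnitudes are fixtures.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* show about real data: resource competition between circuit
and host, cell-to-cell heterogeneity (every well shares one deterministic
per-cell trajectory), instrument drift and edge effects, inducer
degradation, and the mechanistic biology of temperature or soil exposure.
The replicate-noise magnitudes are plausible fixtures; no published value
constrains them.

## Numerical choices and problem sizes

* Solver tolerances `rtol = 1e-6 / atol = 1e-9`; halving them moves a
  400-min delay-circuit endpoint by less than the coarser tolerance.
* Relative-error residuals guard their denominator at $10^{-8}$ of the
  data scale, so exact zeros cannot produce infinite weights.
* Degenerate inputs fail loudly: cyclic wiring, missing inducers or well
  roles, nonpositive corrected OD (excluded with a warning), fewer points
  than parameters, and decay fits on rising series (warned, then fitted).
* The test suite runs on deliberately small problems — circuits of ≤ 6
  gates, 10-min grids over ≤ 800 min, 12–100 multi-start draws, 25–50
  Monte-Carlo repeats — sizes at which every oracle (closed forms,
  fixed-point iteration, fine-grid scans, log-linear regression) is cheap
  and exact.

## Known limitations

Single-cell-equivalent deterministic dynamics only (no stochastic
simulation); no confidence intervals beyond the multi-start spread flag;
the digital sensor model ignores inducer dose-response, so inducer-ratio
effects enter only through the synthetic presets; and the trend model is a
phenomenological summary — it predicts *that* later induction slows the
gate, not *why*.
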