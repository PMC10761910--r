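---
title: "Methods: droplet performance prediction and design automation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet performance prediction and design automation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletdesign)
```

## The problem

Flow-focusing microfluidic junctions pinch a dispersed liquid into
monodisperse droplets inside an immiscible carrier. Droplet diameter and
generation rate set the performance of every downstream droplet assay —
encapsulation statistics, effective concentration, sorting throughput — yet
they depend on device geometry, fluid properties and flow rates through
strongly nonlinear multiphase dynamics that have resisted a general
analytical solution. In practice devices are designed by iterating
fabrication and testing. `dropletdesign` replaces that loop with surrogate
models trained on droplet-generation data and a search layer that inverts
them: given a target diameter and/or rate, it returns a geometry and flow
rates predicted to deliver it, for both single emulsions (SE) and
core–shell double emulsions (DE) produced at two junctions (FF1, FF2) in
series.

## Dimensionless formulation

All models work in dimensionless coordinates to generalize across size
scales and fluids:

* capillary number $\mathrm{Ca} = \mu_c U_c / \sigma_{c,d}$, with $U_c$ the
  continuous-phase flow divided by the orifice cross-section $W_{or} H$;
* flow-rate ratio $\Phi = Q_c / Q_d$ and viscosity ratio
  $\lambda = \mu_c / \mu_d$;
* geometric parameters normalized by the orifice width
  ($\bar{X} = X / W_{or}$), with the orifice width itself the single
  dimensional input;
* the regression target is the droplet diameter normalized by the orifice
  hydraulic diameter $D_h = 2 W_{or} H / (W_{or} + H)$.

Generation rate is never modeled directly: assuming stable monodisperse
generation, conservation of mass fixes it from the predicted diameter,
$F = 6 Q_d / (\pi D^3)$. Because $F \propto D^{-3}$, a small relative
diameter error $\varepsilon$ produces a rate error of about $3\varepsilon$
(first-order Taylor expansion), so rate percentage errors run about three
times the diameter ones — a property the test suite checks explicitly.

Canonical units are µm (lengths), mPa·s (viscosity), mN/m (tension), µL/h
(flow), Hz (rate) and cm³/mol (molar volume); every operation converts to SI
internally and none applies smoothing, clamping or silent unit inference.
When the interfacial tension of a pair has not been measured, the
Good–Girifalco approximation
$\sigma_{c,d} = \sigma_c + \sigma_d - 2\Phi_{gg}\sqrt{\sigma_c \sigma_d}$
is available. The interaction coefficient is implemented in its standard
dimensionless form $\Phi_{gg} = 4\sqrt{V_c V_d} / (\sqrt{V_c}+\sqrt{V_d})^2$,
which equals one at equal molar volumes; a legacy variant with the unsquared
denominator is kept behind `squared_denominator = FALSE` for comparison with
older write-ups, but it is not dimensionless and can push the model outside
its validity range (negative tensions raise an error rather than being
clamped, since they signal misuse).

## The diameter models

Four interchangeable surrogates predict the normalized diameter:

* **Literature power law** $\bar{D} = a\,\Phi^b\,\mathrm{Ca}^c\,\lambda^d$,
  fit by least squares in log space. Published exponent sets vary by fluid
  system, so coefficients are always refit to the data at hand.
* **Interaction law**
  $\bar{D} = a\,\Phi^{\,b + c\ln \mathrm{Ca}}\,\mathrm{Ca}^d\,\lambda^e$,
  which lets the influence of the flow-rate ratio vary between low and high
  capillary numbers — the empirical behavior that motivates going beyond
  independent power laws. The form is selected by `form_id` and is
  deliberately pluggable.
* **Neural network**: two ReLU hidden layers of 512 and 16 units (wide and
  shallow suits a ~10³-record dataset better than deep and narrow), linear
  output, mean-squared-error loss with an L2 weight penalty of 0.001,
  minibatch Adam (learning rate 3·10⁻⁴, batches of 32). It takes the
  7-feature set (orifice width, Ca, Φ and the four normalized geometric
  parameters); the viscosity ratio is excluded by default because it tends
  to hurt generalization to unseen fluids even when it helps in-distribution
  accuracy. The network is implemented directly in R with matrix algebra,
  which keeps training single-threaded and exactly reproducible under a
  seed. Unstated details were fixed as follows: features are z-scored on
  training statistics, the target stays untransformed, initialization is
  He-normal, and training runs at most 1000 epochs with early stopping
  (patience 50) on a 10% validation slice, restoring the best-validation
  weights.
* **Boosted trees** (via xgboost): 100 trees, learning rate 0.3, L2 penalty
  1, depth ≤ 6, leaf splitting halted below a child weight of 1, on the
  8-feature set (with viscosity ratio). Single-threaded training is
  bit-reproducible.

The **consensus model** averages the neural-network and boosted-tree
normalized diameters. By convexity its pointwise absolute error never
exceeds the worse member's, and it combines the trees' accuracy on rates
with the network's better-calibrated DE stability predictions, so it is the
default engine for design automation.

Model assessment uses randomized 80/20 train/test sessions (15 by default,
seeds 0–14; the split is simple random, not stratified by emulsion class)
and reports MAPE, MAE, RMSE and $R^2$, with observed values as MAPE
denominators. Parameter importance for the trees is the per-feature share
of total split gain, averaged across sessions with a two-standard-deviation
dispersion; a feature the ensemble never splits on receives share zero.

## Double emulsions

DE generation at two junctions in series is modeled as two independent SE
events: the inner fluid dispersed into the middle fluid at FF1, and the
middle fluid dispersed into the outer fluid at FF2 with dispersed flow
$Q_i + Q_m$, as conservation of mass requires. Each junction's diameter is
normalized by its own hydraulic diameter. Stability is classified by the
generation-rate difference
$\mathrm{GRD} = 100\,(F_1 - F_2)/F_1$: within a strict band
$|\mathrm{GRD}| < 15\%$ generation is stable single-core (experimentally
stable DEs show mismatches up to this magnitude, plausibly inflated by the
cubic propagation of small diameter measurement errors); at
$\mathrm{GRD} \ge 15\%$ FF1 outruns FF2 and shells acquire multiple cores;
at $\mathrm{GRD} \le -15\%$ shells miss cores. Boundary values are
classified unstable because the stability condition is strictly less-than.
Both the sign (mode of instability) and the magnitude are exposed, since
downstream users may want either. A predicted core at least as large as its
shell raises a feasibility flag rather than an error — the rate arithmetic
remains defined and a flagged result is more useful than a refusal.

## Design automation

**Single emulsions.** The request is a desired diameter and/or rate plus
fluid properties and optional constraints over seven search parameters
(orifice width, four normalized geometric parameters, Ca, Φ). Flows follow
from (Ca, Φ) by the algebra above, so searching dimensionless space keeps
every candidate physically consistent. The search:

1. checks feasibility — requested outputs must lie inside the supported
   envelope (diameters ≈ 15–245 µm, rates 5–11 774 Hz), otherwise the
   request is rejected as infeasible;
2. if experimental data are supplied, returns the closest admissible
   datapoint outright when it is within 3 µm and 15 Hz of the request
   (distance is scalar-normalized Euclidean in the requested outputs);
3. otherwise runs bounded coordinate descent from the warm start (or the
   bound midpoints): at each of at most 5000 iterations every free
   parameter is stepped up and down by 1% of its admissible range, the
   single best cost-reducing move is accepted, and the loop stops when the
   cost reaches zero, the improvement drops below 10⁻⁹, or the budget runs
   out (then the best design found is returned with `converged = FALSE`).

The cost is
$C(x) = |\tilde{D}_{des} - \tilde{D}_x| + |\tilde{F}_{des} - \tilde{F}_x|$
with diameters scaled by 250 µm and rates by 12 000 Hz — the envelope maxima
of the two outputs — so the numerically larger rate range cannot dominate;
unspecified targets are dropped from the sum. Steps are clipped to the
bounds, so constrained parameters are never violated; fixed constraints
collapse a parameter's interval to a point and remove it from the search.
A ±25% performance heat map around the returned operating point is
available as a device-specific operating guideline.

**Double emulsions.** The desired inner and outer diameters plus three
fluids are matched by exhaustively enumerating the flow space of both
junctions (defaults 50–650, 200–1200 and 1500–10 000 µL/h for inner, middle
and outer fluids; six preset devices with FF1 orifices of 15, 22.5 and
30 µm, FF2 twice as wide and deep, normalized depth 1 or 1.33, or a custom
geometry pair). FF2 candidates are paired with the matching combined FF1
flow, combinations with $|\mathrm{GRD}| \ge 5\%$ are excluded as unstable
(the tighter in-design threshold buys margin against model error), and
survivors are ranked by the mean percentage error of the two predicted
diameters. Ties break deterministically: smaller |GRD|, then smaller total
flow, then lexicographic flows. If nothing passes the filter the result is
an explicit empty solution, not an error. Default grid steps of 25/50/250
µL/h keep a full six-device enumeration near 10⁵ evaluations, which the
vectorized junction-wise prediction (FF1 depends only on the inner and
middle flows, FF2 only on their total and the outer flow) completes in
seconds.

## The synthetic benchmark

Because the experimental dataset is an external deposit, every test in this
package runs against synthetic data with known ground truth. The generator
samples geometry, fluid properties and dimensionless flow inputs
log-uniformly over the training-support envelope of the comprehensive
dataset (orifice 15–175 µm, normalized depth 1–3, inlets 1–4, outlet 1–6,
Ca 0.014–9.399, Φ 0.69–22, dispersed viscosity 0.861–3.431 mPa·s,
continuous viscosity 1.303–57.2 mPa·s, tension 0.318–12.84 mN/m), produces
normalized diameters from the law
$\bar{D} = a\,\Phi^b\,\mathrm{Ca}^c\,\lambda^d\,\bar{H}^e$ (defaults
$a=1, b=-0.10, c=-0.25, d=0.05, e=0$ — monotone in Ca and Φ with a weak
viscosity effect, chosen once to keep $\bar{D}$ near the observed 0.35–1.60
band; these are test fixtures, not physical claims), applies multiplicative
lognormal diameter noise (relative sd 2%, matching the scale of
experimental measurement scatter), and derives rates from the noisy
diameter by conservation of mass so that the ×3 rate-error amplification is
reproduced. Rows are rejection-sampled until every raw and derived field
lies inside the envelope, so generated datasets validate with zero
warnings; the published envelope corners (e.g. minimum Ca together with
minimum Φ) would otherwise push $\bar{D}$ above the observed band.
Synthetic DE experiments reuse the experimental device family (FF1 orifice
15–30 µm, FF2 doubled) and solve for the outer flow by root-finding so the
noise-free GRD lands at a target drawn from a configurable band (default
±5%).

What passing on synthetic data does and does not show: it verifies the
pipeline end to end — featurization, training, inversion, conservation
arithmetic — against a recoverable ground truth, and it calibrates
parameter-recovery precision. It does not certify accuracy on real
droplet data: the synthetic law is smooth and low-dimensional where real
dripping-regime data carry regime boundaries, correlated measurement error
and fluid-specific effects the generator deliberately omits. Retraining on
the deposited experimental dataset with the defaults above is expected to
land near the published accuracy ordering (trees ≈ 5% diameter MAPE,
network ≈ 7%, scaling laws ≈ 14–18%, rate MAPEs about three-fold higher),
but that reproduction requires the external download and is therefore
documented rather than asserted by the test suite.

## Numerical choices and degenerate inputs

* Scaling-law fits happen in log space; a rank-deficient design (any
  dimensionless input constant) raises an "unidentifiable coefficients"
  error instead of silently dropping terms.
* Non-finite training losses abort neural-network training with
  diagnostics; empty datasets are rejected up front.
* CSV output serializes doubles at 17 significant digits and input parses
  through `strtod`, so a write/read round trip is bit-exact; stored derived
  columns disagreeing with raw fields by more than 1% are warned about and
  recomputed values always win.
* Out-of-envelope records load with warnings, never rejection — the
  envelope describes training support, not validity, and generalization
  tests intentionally exceed it.
* The test suite and worked examples use 100–2000-record synthetic
  datasets, 300-epoch network budgets and coarsened design grids; these
  sizes were chosen to exercise every code path at interactive speeds and
  are stated here so results can be reproduced exactly.

## Known limitations

* Everything rests on the dripping-regime assumption behind conservation-of-
  mass rate prediction; jetting or unstable generation invalidates it.
* The DE model treats the junctions as fully decoupled, which matches
  devices with a flow resistor between them; strongly coupled junctions
  break the assumption.
* The SE search is local (coordinate descent with a warm start); it inherits
  the usual vulnerability to local minima, mitigated but not removed by the
  dataset warm start.
* No uncertainty quantification is attached to predictions; the stability
  classifier is a thresholded physical criterion, not a trained classifier.
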