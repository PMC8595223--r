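---
title: "In-silico screening of arterial disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico screening of arterial disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hemoscreen` builds virtual patient cohorts with a one-dimensional
pulse-wave model of the systemic arteries, injects parameterised stenoses
and aneurysms, and asks whether machine-learning classifiers can detect
the lesion from a handful of peripheral pressure and flow-rate
measurements. This vignette explains the models, the numerical choices,
and what the packaged synthetic cohorts can and cannot say about real
patients.

## The forward model

Each vessel segment is a compliant axisymmetric tube governed by the 1D
blood-flow equations in area/velocity form,

$$\frac{\partial A}{\partial t} + \frac{\partial (Au)}{\partial x} = 0,
\qquad
\frac{\partial u}{\partial t} + \frac{\partial}{\partial x}
\left(\tfrac{1}{2}u^2 + \frac{p}{\rho}\right) = -f\,\frac{u}{A},$$

closed by the tube law
$p = p_\mathrm{ext} + \beta/A_d(x)\,(\sqrt{A} - \sqrt{A_d(x)})$ with
reference (zero-transmural-pressure) area $A_d(x)$ and wall coefficient
$\beta$. The friction closure is $f = 2(\gamma + 2)\pi\mu/\rho$ with
velocity-profile order $\gamma = 9$ by default; blood density is
1.06 g/cm^3 and viscosity 0.04 P. The local pulse-wave speed is
$c = \sqrt{\beta \sqrt{A} / (2\rho A_d)}$.

The velocity (Bernoulli) form of the momentum equation is a deliberate
choice: lesions multiply $A_d(x)$ by factors between 0.05 and roughly 27,
and across such reference-area jumps the conservative momentum flux
$Q^2/A$ is badly conditioned while $u^2/2 + p/\rho$ stays smooth. The
mass equation is kept in conservative flux form, so blood volume is
conserved to discretisation accuracy.

Junctions impose conservation of mass and continuity of total pressure
($p + \rho u^2/2$; a static-pressure variant is available behind a
settings flag), solved per time step by Newton iteration on the vessels'
outgoing Riemann invariants $u \pm 4c$. Terminal vessels couple to
three-element Windkessel models (characteristic-impedance proximal
resistance, peripheral compliance, distal resistance) integrated
implicitly. The inlet prescribes a periodic flow waveform — a half-sine
ejection over the first third of the cycle at the configured mean flow.

### Numerics

The interior scheme is two-step MacCormack (forward predictor, backward
corrector), second order in smooth regions. Three details matter in
practice:

* **Well-balancing.** The momentum flux is evaluated from the pointwise
  pressure, so a uniform-pressure, zero-velocity state is an exact
  discrete equilibrium even with tapering or diseased $A_d(x)$. The
  rest-state test asserts this to machine precision.
* **Serial merging.** At discretisation time, chains of single-child
  vessel connections are merged into one computational segment.
  Disease chains always span such connections, so lesions end up in
  segment interiors where the scheme is conservative; only true
  branching junctions remain as coupled boundaries. Boundary nodes are
  advanced with one-sided MacCormack steps and the boundary conditions
  are then imposed on the evolved state; this removed a systematic
  first-order volume drift that plain characteristic extrapolation
  produces in tapering vessels.
* **Convergence to the periodic state.** A run starts from a uniform
  75 mmHg state with the inflow amplitude ramped up over the first two
  cycles, and stops when (a) the cycle-to-cycle waveform change at the
  measurement sites, scaled per site by pulse amplitude, falls below
  `tol` (default 1e-3, maximum 20 cycles) and (b) the net volume stored
  by the network over a cycle is below 2% of the cycle inflow. The
  second criterion exists because a large aneurysm sac can swallow
  volume for many cycles while the peripheral waveforms barely change;
  a shape-only residual declares victory too early in exactly those
  runs.

Default resolution is 0.5 cm cells at CFL 0.9, with lesion-carrying
segments refined by a factor of 2 (the cohort generator retries a failed
diseased run once at twice that refinement before redrawing the
subject). A selective sawtooth-sensing artificial dissipation is
implemented but disabled by default — the merged-segment scheme proved
stable without it across the full severity range, and any dissipation
slightly damps the physics.

## The arterial network

The packaged network is a bilaterally symmetric reduction of the human
systemic tree with 30 segments: ascending aorta and arch; two-segment
common carotids; subclavian-brachial-radial arm chains; thoracic aorta;
a lumped visceral branch absorbing 45% of cardiac output (so that leg
and arm flows stay physiological); a four-segment abdominal aorta; and
iliac-femoral-popliteal leg chains. Geometry and wave speeds are adapted
from published 1D benchmark values and shipped as a YAML config with
explicit units, not hard-coded. The four disease chains are the common
carotid (CA), subclavian (SA), iliac-femoral-popliteal (PA) and
abdominal aortic (AA) chains; the reference abdominal aortic areas taper
from 1.76 to 1.09 cm^2 so that the aneurysm severity bands correspond to
4-6 cm sac diameters.

Measurements mirror clinically accessible sites: pressure in the carotid
(P1), brachial (P2) and radial (P3) arteries, flow in the carotid (Q1),
brachial (Q2) and femoral (Q3) arteries, both sides. The source does not
state where along each artery its measurements are taken; segment
midpoints are assumed. Windkessel parameters distribute a total
peripheral resistance of about 1.1 mmHg s/mL and peripheral compliance
of 0.8 mL/mmHg across the seven outlets in proportion to assumed flow
shares, giving brachial pressures of roughly 136/75 mmHg at the
reference state.

## Disease model

A lesion multiplies the reference area along its chain by a cosine
profile in the normalised chain coordinate $x_n$ (arc length over total
chain length): outside $[b, e]$ the multiplier is 1; inside it is
$(1 \pm S/2) \mp (S/2)\cos\!\big(2\pi (x_n - b)/(e - b)\big)$, reaching
$1 - S$ (stenosis) or $1 + S$ (aneurysm) at the midpoint and returning
continuously to 1 at both ends. The printed sign convention in the
source is typographically ambiguous; the reading adopted here is the one
consistent with its worked examples (a severity-0.6 stenosis dips to
0.4x, a severity-8 aneurysm peaks at 9x) — the alternative would give
negative areas.

Parameters are drawn sequentially: reference location
$r \sim U(0.2, 0.8)$, start $b \sim U(0.1, r - 0.05)$, end
$e \sim U(r + 0.05, 0.9)$ — which enforces a minimum lesion length of
10% of the chain — then severity $S$ uniform on 0.50–0.95 for stenoses,
7.13–25.93 for aneurysms, and 3.0–7.0 for the low-severity aneurysm
variant. Bilateral chains get their side with equal probability. Each
diseased patient carries exactly one lesion.

## Virtual patient cohorts

Healthy subjects perturb the reference network with independent uniform
scale factors: cardiac period $U(0.7, 1.1)$ s, and ±20% bands on inflow
amplitude, global area, wall stiffness, outlet resistance and outlet
compliance, plus a ±5% left/right area asymmetry. These distributions
are this package's own choices — the deposited cohort the study design
descends from is out of scope — and are config-exposed. A plausibility
filter accepts only subjects with brachial systolic pressure in
[90, 180] mmHg and diastolic in [50, 100] mmHg; candidates failing the
filter or the solver are redrawn, with an error if the rejection rate
exceeds its cap.

Each diseased database pairs every healthy subject with a diseased twin:
identical subject parameters, one freshly sampled lesion, re-simulated.
Dataset assembly then guarantees twin exclusivity: a random half of the
subjects contributes healthy records and the *other* half's diseased
twins contribute diseased records, giving an exactly balanced pool in
which no subject appears with both labels; the pool is split 2/3 train /
1/3 test (or 50/25/25 train/validation/test when early stopping needs a
validation set). "Five-fold validation" follows the source's own usage:
five independent random resplits of one pool, not disjoint-fold
cross-validation.

## Features and classifiers

Each waveform (one converged cycle, 64 uniform samples) is projected
onto a Fourier series truncated at $N = 5$:
$u(t) = \sum_{n=0}^{N} a_n \sin(n\omega t) + b_n \cos(n\omega t)$ with
$\omega = 2\pi/T$. The $n = 0$ sine term is identically zero, so 11
coefficients describe a waveform and 22 a bilateral measurement; the
projection is exact for signals band-limited to $5\omega$. Columns are
standardised by Z-score with the population (1/M) variance convention,
fitted on the training split only and applied unchanged to validation
and test data; whether the source standardises before or after splitting
is not stated, and the train-only choice is the standard anti-leakage
practice.

Six classifiers run behind one interface: random forest and
gradient-boosted trees (tree count and depth as hyper-parameters), naive
Bayes with normal likelihoods, an RBF-kernel SVM with the
variance-scaled width rule $\gamma = 1/(d\,\mathrm{Var}(X))$,
L2-regularised logistic regression, and a multi-layer perceptron with
equal-width logistic hidden layers. The MLP is implemented in the
package (mini-batch gradient descent with momentum, batch 32, learning
rate 0.05) because its early-stopping protocol needs per-iteration
validation log-loss traces; an "iteration" is taken to be one epoch,
which the source leaves undefined. Early stopping halts training once
more than 75 iterations have run and the validation log-loss improvement
between consecutive iterations is below 1e-3, capped at 200; the
returned model is the state at the stopping iteration. Published-scale
hyper-parameter grids (RF 40x19, GB 10x19, MLP 20x6) are available
behind `paper_scale = TRUE`; the default grids are thinned for desk use.

The evaluation layer enumerates all 63 non-empty subsets of the six
bilateral measurements, records F1, sensitivity and specificity per
method, combination and resplit (diseased is the positive class —
the screening convention; metrics are computed per fold and then
averaged), and provides the per-count summaries, the
carotid-flow-inclusion partition (32 include / 31 exclude), summed
split-improvement importance (the 22 per-coefficient gains of each
measurement summed and normalised to 100%), low-severity aneurysm F1
ratios, and unilateral (11-feature) evaluations.

## Problem sizes and what the tests show

The test-suite and acceptance cohorts are deliberately small: the
package's own acceptance runs use 150 twin pairs per disease form, and
the in-suite checks 20 pairs, against tens of thousands in the study the
design descends from. At these sizes the qualitative findings are stable
— near-perfect aneurysm detection from a single carotid-flow waveform,
high-accuracy carotid stenosis detection from all six measurements,
carotid-flow dominance in feature importance — but fold-to-fold F1
scatter of several points is expected, and exact published values are
not reproducible without the original cohort and full 71-segment
network.

The synthetic generator emulates inter-subject variability with global
scale factors; it does not model measurement noise or bias (explicitly
out of scope), wave-shape variability of the inflow, local geometric
variants, or pathologies other than the single configured lesion.
Passing tests therefore demonstrate the pipeline's correctness and the
in-silico separability of lesion signatures, not clinical performance.

## Known limitations

* The tube law keeps $\beta$ fixed while disease rescales $A_d$, so a
  large aneurysm sac is much more compliant than a real, stiffened
  aneurysm wall; this makes the transient filling dynamics (and hence
  the volume-balance convergence gate) more demanding than reality.
* Windkessel parameters are tuned to plausible mean flows, not fitted to
  any patient data.
* The reduced network omits the cerebral circulation, ulnar branches and
  visceral detail; lesion-to-measurement path lengths therefore differ
  from the full-network setting.
* The MLP is a minimal reference implementation; it is adequate for the
  early-stopping protocol and traces, not a deep-learning benchmark.
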