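---
title: "Modelling dual prism adaptation: methods and design choices"
author: "dualadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual prism adaptation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualadapt)
```

## The scientific problem

When a person points at a target while the visual scene is horizontally
displaced — classically by wedge prisms, in modern setups by a virtual
reality mapping — the first movements miss by roughly the optical shift
(the *direct effect*). Repeated pointing with terminal feedback corrects
the error. When the displacement is removed, pointing errs in the opposite
direction (the *aftereffect*), which is corrected in turn. If the two
viewing conditions alternate repeatedly, people eventually acquire *both*
visuo-motor mappings and switch between them almost instantly
(*dual adaptation*).

A basic question about this learning process is what sets its speed: the
number of *phase changes* (switches between conditions) or the total
number of *executed movements* with error feedback. `dualadapt` implements
a minimal neural model that makes this question quantitative, an
experiment engine that runs alternating-schedule protocols, and the
behavioural analysis pipeline that measures adaptation speed in both unit
systems.

## The perceptron–gain model

The model has two stages.

**Input stage.** The perceived target is a one-dimensional Gaussian
activation profile in a head-centred angular frame, sampled by
`n_channels` populations on a grid $\theta_i$:
$$A_i = A_0 \exp\!\left(-\frac{(\theta_i - \theta_T - s)^2}{2\sigma^2}\right),$$
where $\theta_T$ is the true target angle, $s$ the visual shift in degrees
(the image displacement; negative is leftward) and $\sigma$
(`sigma_input`) the tuning scale. A nonnegative weight vector $w$ reads
the profile out as a scalar, $r = \sum_i w_i A_i \ge 0$.

**Output stage.** The pointing angle is
$$\varphi = (1 + w_c\,c)\,r - \varphi_0 + \varepsilon,$$
where $c \in \{0, 1\}$ is a binary *cognitive cue* signalling which
condition is present (on exactly when the shift is on), $w_c \ge 0$ a
learned gain weight, $\varphi_0$ (`phi0`) a constant that converts the
positive neural signal into a signed angle, and $\varepsilon$ optional
zero-mean motor noise (`sigma_motor`, 0 by default). The displacement
(pointing error) is $d = \varphi - \theta_T$ and the learning loss is
$d^2$.

With the cue off, the output is independent of $w_c$: the cue-gated
multiplicative gain is what lets the network store a second mapping
without relearning the spatial one. At a single target, the dual problem
is exactly solvable — `dual_solution()` constructs $w^*$ satisfying the
normal condition and $w_c^* = (\theta_T + \varphi_0)/r_{\mathrm{ON}} - 1$
— but no single $(w, w_c)$ solves it for all targets at once, which is why
generalization to untrained targets is informative.

Under this orientation of the output equation the readout increases with
angle, so only shifts that *reduce* the readout (leftward image
displacements for the default grid) are compensable by a nonnegative
gain; canonical simulations therefore use $s = -15°$, matching the
leftward displacement used in pointing experiments. The sign is a free
parameter everywhere else in the package.

## Learning by weight perturbation

Training signals reach the synapses only through the scalar error. Each
movement, all weights are jointly perturbed by independent Gaussian draws
($\xi_w \sim N(0, \sigma_w^2)$ per spatial weight,
$\xi_c \sim N(0, \sigma_c^2)$), the perturbed movement is executed, and
the change in squared error relative to the unperturbed loss on the same
trial, $\delta L$, is broadcast back. Each weight then moves by
$-\eta\,\xi\,\delta L$ and is clamped at zero. A fluctuation that lowered
the error is partially retained; one that raised it is reverted. In
expectation this equals gradient descent scaled by the exploration
variance,
$$E[\Delta w_i] = -\eta_w \sigma_w^2\, \partial L / \partial w_i,$$
which the package verifies against a central-difference gradient
(`stochastic_update_expectation()` vs. `gradient_step()`); the test suite
requires agreement within 10% per coordinate at $10^5$ draws.

Two design details are worth stating:

* **Baseline for $\delta L$.** The unperturbed loss on the identical
  trial (two forward passes per movement). This makes the update unbiased
  and directly testable; the executed, recorded movement is the perturbed
  one.
* **Cue-off gain updates.** With $c = 0$, gain fluctuations have no
  effect on the output, so their correlation with the error is exactly
  zero; `stochastic_step()` leaves $w_c$ unchanged rather than letting it
  random-walk against the clamp. Re-adaptation therefore exploits only
  spatial weight changes, while shifted-condition adaptation uses both —
  the mechanism behind the slower aftereffect decay.

**Pre-training.** Before any dual-adaptation schedule, the normal mapping
is learned from scratch: spatial weights start uniform on
$(0, 2\varphi_0/Z)$ ($Z$ the Gaussian activation mass), targets are drawn
uniformly from the grid inside $\pm 70°$, each presented for 10
consecutive learning steps, 12{,}000 targets per run, and the final
weights of 4 independent runs are averaged (averaging reduces run-to-run
variance in subsequent ensembles). The stochastic rule leaves an
equilibrium residual: across seeds the maximum absolute probe error on
the interior workspace settles around 0.3–0.7°, so the convergence
contract (`tol`) is 1°. Probes avoid the outer $3\sigma$ of the training
range, where the uniform target distribution no longer surrounds a probe
and the mapping is systematically biased.

## Protocols and the two unit systems

A schedule is $B$ blocks of $P$ shifted (ON) movements followed by $P$
original (OFF) movements, after 15 familiarization movements. The five
canonical schedules use $P \in \{5, 15, 30, 60, 120\}$ with the total
$M = 2PB = 1200$ held fixed, so they differ 24-fold in the number of
phase changes while spending identical movement counts.
`ensemble_run()` simulates 100 independent model instances per schedule
(shared pre-trained spatial weights; per-run cognitive weight drawn from
the uniform prior `w_c_init`, default $U(0, 0.1)$), with per-run seeds
derived deterministically from one master seed.

The analysis mirrors standard practice: displacements are
baseline-corrected by the mean of the first 15 familiarization trials per
run; the *direct effect* series takes the first movement of each block
($m = (b-1)2P + 1$) and the *aftereffect* series the first movement after
restoration ($m = (b-1)2P + P + 1$); series are averaged across
runs/subjects and then fitted by nonlinear least squares with
$$d(b) = d_\mathrm{off} + d_1 e^{-(b-1)/\tau_b}.$$
The decay constant converts as $\tau_{pc} = 2\tau_b$ (two phase changes
per block) and $\tau_m = 2P\tau_b$. If speed were set by phase changes,
$\tau_{pc}$ would be constant across schedules; if by movements, $\tau_m$
would be.

The fit is anchored at the first block ($b - 1$ in the exponent) so that
$d_1$ is the first-block excess over the offset; this makes the
normalization $(d(b) - d_\mathrm{off})/d_1$ of the fitted curve exactly
$e^{-(b-1)/\tau_b}$ and lets the synthetic-data generator round-trip its
parameters exactly. The time constant is fitted on the log scale (always
positive, no box constraints), from a deterministic initialization policy
($d_\mathrm{off}$: mean of the last quartile; $d_1$: first value minus
that; $\tau_b = B/3$) extended by a fixed multi-start grid
(extreme-amplitude and slow-decay starts, lowest deviance wins) that
guards against a degenerate local minimum fitting only the first point
when the series is non-monotone. Degenerate outcomes (vanishing
amplitude, time constant at either extreme, non-convergence) are returned
as flagged fits with the failure retained — never a silent fallback.
Confidence intervals are asymptotic, from the least-squares covariance,
with the $\tau_b$ interval delta-method transformed from the log scale.

## Calibration of the learning constants

The four learning-rule constants were calibrated once on the $P = 30$
schedule and then frozen for every other schedule and experiment, in the
same spirit as fixing free parameters on one condition and predicting the
rest. The calibration targets were: a direct effect that decays within
roughly the first third of the session ($\tau_m \approx 110$ movements),
an aftereffect of realistic amplitude that decays from the first block
and more slowly than the direct effect, and end-of-session noise-free
errors below half a degree in both conditions. The frozen values are

| constant  | value | role |
|-----------|-------|------|
| `eta_w`   | 0.3   | spatial learning rate |
| `eta_c`   | 0.03  | gain learning rate |
| `sigma_w` | 0.03  | spatial exploration SD |
| `sigma_c` | 0.005 | gain exploration SD |

The exploration SDs control single-run movement variability (about
0.4° from the gain pathway, 0.13° per spatial channel mass); the rates
set the decay time course. The balance matters: much faster spatial
learning quenches the error within long phases and breaks the
movement-count invariance at $P = 120$, while much slower spatial
learning makes the aftereffect rise for many blocks before decaying.

## What the simulations show

At these frozen constants, 100-run ensembles of all five schedules give
direct-effect $\tau_m$ within a max/min ratio of about 1.3 (about 109
movements for $P \le 60$, inflated to about 147 at $P = 120$), while
$\tau_{pc}$ spreads by a factor of 17–19, close to the 24-fold spread of
$P$ — adaptation speed tracks movements, not phase changes. The residual
inflation at $P = 120$ is partly a fitting artefact: with only 5 blocks
the offset is poorly constrained and the time constant biases toward
slower decay, a bias the package reproduces on surrogate data (the mean
log estimation error grows monotonically as block count falls). Note that
at ensemble precision the fitted $\tau_m$ of $P = 120$ is nevertheless
statistically distinguishable from the short-phase schedules: the
asymptotic confidence intervals of the mean-series fits are a few percent
wide, far tighter than those of a five-subject experiment.

The aftereffect decays more slowly than the direct effect in every
schedule, because gain learning is disabled during re-adaptation. The
first shifted movement errs by exactly the shift magnitude when the gain
prior is flat ($E[w_{c,0}] = 0$) and by strictly less when the prior is
positive — a prior on compensatory gain, one interpretation of why human
initial errors are smaller than the optical shift (the default prior
$U(0, 0.1)$ gives about 11.3° for a 15° shift).

**Spatial transfer.** After adapting at a single target, the direct
effect probed across test angles shows a local dip at the trained angle
whose width scales with `sigma_input`, superimposed on a global, readout-
proportional tilt from the gain: because the gain's correction is
$w_c\,r(\theta)$ and $r$ grows across the workspace while the required
correction is constant, residual errors are larger on the side the image
was displaced toward (in prism terminology, contrary to the prism-base
direction — prisms displace the image away from their base).
`asymmetry_index()` is positive under this prediction. Two controls
isolate the mechanism: pure spatial adaptation (`eta_c = 0`, flat prior)
produces a dip but no asymmetry, and an additive-shift output stage
(`output_stage = "additive"`), which would generalize the correction
uniformly, reproduces schedule invariance but not the asymmetry — the
argument for a multiplicative gain. Single-run transfer curves carry a
random-walk imprint of the global reinforcement signal of a degree or
two; curves should be averaged over an ensemble (20 runs in the package's
experiments) before reading off the dip or the index.

**Width of the input representation.** Broader input tuning slows dual
adaptation: over $\sigma \in \{5°, 10°, 20°\}$ the fitted $\tau_m$ rises
monotonically (about 64 to 146 movements in 50-run ensembles). This
experiment scales the activation amplitude as $A_0 = 10°/\sigma$ — the
length-scale-normalized reading of the Gaussian input — so that the
summed squared activation, and with it the effective spatial learning
rate, is matched across widths; without that control the rate change with
$\sigma$ masks the interference effect of interest. The same overlap
mechanism widens the local transfer dip, linking representation noise to
broader generalization.

**Two shifted conditions.** Learning two oppositely shifted mappings
($\pm 7.5°$) takes about 1.5 times more movements to reach a 2° criterion
than learning a normal and a 15°-shifted mapping, at matched parameters:
the overlapping input representations of the two shifted conditions
interfere, and the gain must work against a spatial mapping that is
correct for neither. The cue is assigned to the more-leftward condition
of each pair (the gain-compensable one under the default orientation).

## The synthetic-subject generator

`gen_subject()` produces movement records with known ground truth,
independent of the neural model: the first ON movement of block $b$ has
expectation $d_\mathrm{off} + d_1 e^{-(b-1)2P/\tau_m}$ (plus a constant
per-subject baseline bias), within-phase values decay toward the current
mapping's asymptote with their own constant (default $\tau_m/4$ in
movements — irrelevant to the first-movement analysis), the aftereffect
mirrors the direct effect at a fixed amplitude ratio (default 0.6,
opposite sign, decaying toward zero), and Gaussian noise is added
everywhere. It emulates the statistical structure the analysis assumes —
exponential across-block decay, offsets, subject heterogeneity, additive
noise — and deliberately not the features the neural model provides
(no exploration-driven error correlations, no gain/spatial decomposition,
no non-adapting subjects), so passing recovery tests validates the
pipeline, not the model.

Noiseless generation round-trips exactly. At the pipeline's operating
point — groups of five subjects averaged before fitting, as in a
five-subject experimental group, with noise 10% of the initial amplitude
— the median $\tau_m$ recovery error is about 6%. A single noisy series
at that noise level has an asymptotic floor near 13%, which is why
recovery is evaluated on group averages.

## Numerical choices and degenerate inputs

* Problem sizes in the packaged experiments: 100 runs per canonical
  schedule, 50 per tuning width, 20-run transfer ensembles, 12
  condition-pair comparisons, 200 recovery replicates, $10^5$
  perturbation draws for the gradient-equivalence check. One full pass of
  the heavy experiments runs in a few minutes on a single core.
* Grid resolution is 1° over $\pm 90°$; refining it is a configuration
  change (`n_channels`) that rescales nothing else.
* A shifted target leaving the grid span is a validation error, not a
  truncation.
* Exact zero weights are legal states (the clamp); readouts and trials
  remain well defined.
* `movements_to_criterion()` evaluates the noise-free errors of both
  conditions at block boundaries only, so its resolution is one block.
* All ensemble and generator functions consume R's global RNG and derive
  per-run seeds from one master seed; identical seeds give bit-identical
  output.

## Known limitations

* Breaks, fatigue and inter-session forgetting are not modelled; the
  learner is stateless between trials except through its weights.
* One gain factor: oppositely signed shifts within one session would need
  an agonist/antagonist pair of gains, which is out of scope.
* The gain can only scale the readout up ($w_c \ge 0$), so which shift
  direction is compensable is fixed by the output-stage orientation.
* The exponential-plus-offset description is misspecified for
  aftereffect series that rise before decaying (short phases early in
  training); fits there are returned but may be flagged, and their time
  constants should be read as "slower than resolvable".
* No trajectory-level modelling: movements are endpoint angles only.
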