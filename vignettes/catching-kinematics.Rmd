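---
title: "Models and methods behind catchkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind catchkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchkin)
```

catchkin is a pipeline for studying how people catch a flying ball with one
hand: where and when along the ball's path they intercept it, how their wrist
speed profile decomposes into elementary submovements, and whether those
choices differ systematically between individuals. Because raw motion-capture
recordings of such experiments are rarely shared, the package pairs the
analysis chain with a synthetic-data generator that emulates the study
conditions end to end, so every stage is testable against a known ground
truth.

## Ball flight and the virtual launcher

A 20 g, 7 cm ball is light enough that air drag shapes its flight
substantially. The simulator integrates

$$\mathbf{a} = \mathbf{g} - \frac{k}{m}\,\lVert\mathbf{v}\rVert\,\mathbf{v},
\qquad k = \tfrac{1}{2}\,\rho\, C_d\, \pi\, (d/2)^2,$$

with sphere defaults $C_d = 0.5$ and $\rho = 1.2\ \mathrm{kg\,m^{-3}}$ —
the standard quadratic drag law for this Reynolds regime; the true drag law
of the physical ball is not documented, so both parameters are exposed in
`drag_params()`. Integration is fixed-step RK4 at 1 ms, resampled to the
100 Hz capture rate; RK4 is exact on the drag-free parabola, which the test
suite uses as a closed-form oracle. The frame follows the laboratory
convention: x horizontal from the catcher's hand toward the launcher, z
vertical up, right-handed.

The experimental apparatus projected balls so as to realize six flight
conditions — arrival times $T \in \{0.55, 0.65, 0.75\}$ s crossed with low
(1.3 m) and high (1.9 m) arrival heights at the 6 m plane — by fitting
polynomials from launch parameters to measured arrival characteristics and
inverting them, with launch speed adjustable only in 1 mph steps.
`calibrate_launcher()` reproduces this procedure on simulated flights. The
launch parameters are speed, elevation angle, and the vertical translation
of the exit point (the machine sat on an actuated lift); with speed
quantized, the two continuous parameters are what allow the inversion to hit
both $T$ and $Z$ — with speed and angle alone, the 1 mph lattice alone
would bound the attainable flight-time accuracy near the 2% tolerance
itself. Defaults (a 20 x 20 speed-angle grid crossed with 5 heights,
total-degree-3 surfaces) are package choices; the source experiment does not
document its grid or degree. The inversion minimizes the combined relative
error with each term normalized by the apparatus accuracy bound (2% on
flight time, 4% on arrival height).

## Synthetic subjects

`generate_cohort()` creates subjects that cycle through three movement
archetypes mirroring the strategies reported for real catchers:

* **type1** — a direct reach: a single minimum-jerk submovement, or two
  strongly overlapping ones producing a gently decelerated approach;
* **type2** — a transport submovement followed by a distinct corrective
  submovement whose peak is timed onto the ball; the hand does not stop at
  impact, so the speed profile is still high when the ball arrives;
* **type3** — hook-like movements composed of three or four submovements,
  usually with trunk involvement.

Each trial picks an impact point from the subject's *catch-zone preference*:
a target interception index $p$, realized by placing the impact at the arc
fraction $p$ of the ball path between the frontal-plane crossing and the
first reachable point. The wrist follows an archetype-specific cubic Bezier
path from the rest posture to that point, and its progression along the path
is driven by the composite minimum-jerk speed profile, so the generated
tangential speed is exactly the sum of the ledger's submovements up to
path-integration error. The elbow comes from two-link inverse kinematics,
the two wrist-stick markers (21 cm apart) encode the pronosupination angle,
trunk users translate the whole shoulder cluster by a minimum-jerk
displacement, and Gaussian noise of sd 1 mm per axis and sample — the
typical optical reconstruction residual — is added last.

Outcomes are sampled from a logistic model whose fixed effects encode the
documented direction of the task (success increases with flight time,
decreases with arrival height) plus a per-subject random intercept; trials
intended as "touched" or "missed" displace the hand target off the ball by
8–11 cm or 15–25 cm, and the recorded outcome is then assigned by the
distance rule (caught within ball radius + 3 cm). An unreachable ball
produces a missed trial, not an error.

What the generator does **not** emulate: marker dropout and swaps, soft
tissue artifact, grasp/finger kinematics, lateral (y) strategies, online
corrections to visual feedback, or any learning across trials. Passing
recovery tests on these data therefore demonstrates the correctness of the
pipeline's computations, not its robustness to every pathology of real
captures.

Default anthropometry places the shoulder at 1.38 m with 0.30 m arm and
0.26 m forearm segments, so that the low flight condition arrives near the
reference normalized height of -0.11 used by the trial-selection rule.

## Signal processing and events

Markers are filtered with a zero-phase (forward–backward) FIR low-pass at
25 Hz. The filter order (30, Hamming window, taps renormalized to exact
unit DC gain) is a package default — standard practice for a 25 Hz cutoff
at 100 Hz — as the source procedure documents only the cutoff. The series
is padded by odd reflection so output length equals input length.
Differentiation uses central differences (one-sided at the edges), exact
for quadratics.

Per-trial events:

* **Latency (LT)** — first time the wrist tangential speed reaches
  0.05 m/s and stays there for 50 ms. The threshold is the documented
  value; the 50 ms debounce is a robustness addition (disable with
  `debounce = 0` for noiseless data).
* **Impact (IT)** — time of minimum distance between the ball and the
  plane through the two wrist-stick markers and the forearm marker.
  Because that plane is unbounded, its distance to a ball still metres away
  can dip incidentally; candidate frames are gated to those with the ball
  within 0.5 m (preferring 0.2 m) of the wrist midpoint, and flat minima
  resolve to the earliest frame. A quadratic sub-sample refinement
  (optional, on by default) sharpens the 10 ms quantization.
* **Speed extrema** — first local maximum after LT with prominence at least
  0.05 m/s (the latency threshold doubles as the prominence floor, since no
  prominence rule is documented), then the first trough before IT; a trough
  may be absent. Windows without an interior maximum fall back to the
  flagged global maximum.
* **Timing** — tau-margin = IT − t_peak; MT is defined as IT − LT (the
  quantity is named but never defined in the source description); flight
  duration = IT − launch; and t_C − t_B, where t_C is the spline-extrapolated
  ball arrival at the frontal plane through the shoulder at launch and
  t_B = IT.

Ball-path queries (plane crossings, interception geometry) evaluate
per-coordinate cubic splines; extrapolation beyond the last ball sample is
capped at 150 ms. The splines are interpolating rather than smoothing: the
ball track is filtered upstream, and an interpolating spline is exact on the
drag-free test parabola.

## Interception geometry

Limb length is 1.2 x (arm + forearm), the scaling accounting for the palm.
The normalized arrival height Zn references the shoulder at launch in limb
units; the selection rule keeps caught trials within 0.30 of the
condition's reference (-0.11 low, 0.58 high), with the reference chosen by
the trial's condition label rather than proximity. The interception index

$$I = \Gamma_{BC} / \Gamma_{AC}$$

uses arc lengths along the sagittal (x–z) projection of the ball path,
computed by piecewise-linear integration at 1 ms resampling; A (first
reachable point) is also defined on that projection, so both arcs use the
same geometry. An impact outside the segment [C, A] is clamped into [0, 1]
and flagged rather than rejected. The pronosupination angle measures the
wrist stick (ulnar to radial marker) against the arm-plane normal
`(elbow -> shoulder) x (elbow -> wrist)`; the generator's pronated reference
posture validates the sign convention end to end.

## Submovement decomposition

Each submovement contributes the minimum-jerk speed profile

$$v(t) = 30\,\frac{A}{D}\,\tau^2 (1 - \tau)^2, \qquad
\tau = \frac{t - t_0}{D} \in [0, 1],$$

the derivative of the minimum-jerk displacement $10\tau^3 - 15\tau^4 +
6\tau^5$ scaled by the amplitude $A$ (metres of displacement — consistent
with the total-amplitude constraint below); its integral is $A$ and its peak
$1.875\,A/D$. The observed tangential speed is modeled as the scalar sum of
$N$ components — speeds, not velocity vectors, are superposed, matching the
choice to fit tangential speed for strongly curved wrist paths.

`decompose()` searches for the smallest $N$ whose best fit explains more
than 99% of the variance ($R^2$ about the window mean; whether the original
analysis centered its $R^2$ is undocumented). For each $N$ a scattershot
search runs 20 constrained local least-squares fits (L-BFGS-B with an
analytic gradient) from randomized onsets: amplitudes start at $A_M/N$ and
durations at $MT/N$, onsets are drawn from Gaussians centered at equi-spaced
times with sd $D/2$. Constraints: $A \in [0.1, A_M]$ with $A_M$ the wrist
path length over the window (the 0.1 lower bound is interpreted as 0.1 m,
the same units as $A_M$); $D \geq 0.1$ s; onsets within
$[LT - 0.1, IT - 0.1]$ s. The onset window follows from reading the
documented bound $[(LT - minD), (MT - minD)]$ on a clock that starts at
movement onset — on a launch-relative clock it would forbid the late
corrective submovements the classification itself describes. Ordering
applies to both onsets and offsets via a smooth hinge penalty; the printed
constraint `t_off(k) < t0(k+1)` would forbid any overlap, contradicting the
smooth composite profiles, and is read as offset ordering. The fitting
window extends 100 ms past impact when the speed never drops below
0.05 m/s in that interval (the mover did not stop on the ball, keeping the
last component identifiable), otherwise it ends at impact.

$N$ is capped at 6 (observed movements used at most 4); the best fit for
$N$ seeds one extra restart of the $N+1$ fit augmented with a small
component, which makes the attained $R^2$ non-decreasing in $N$. If no $N$
reaches the threshold the best attempt is returned with a flag.

Movement types: type 1 for single-peaked profiles, or $N = 2$ with the
second component peaking before the speed trough; type 2 for $N = 2$
peaking after the trough; type 3 for $N \in \{3, 4\}$. Two declared
fallbacks: $N = 2$ without a detectable trough classifies as type 1 with a
flag, and $N > 4$ maps to type 3 with a flag.

## Mixed models

Catch success is modeled by a logistic mixed model with fixed effects of
flight time, arrival height and trial number and a random intercept per
subject; kinematic parameters of selected trials by linear mixed models
with fixed T and Z (trial number optional via configuration, since the
source description is ambiguous on whether it entered the kinematic
models). The question of interest — do subjects differ? — is answered by
comparing the mixed model's AIC with that of the fixed-effects-only
companion. REML fits provide the reported fixed-effect estimates, but the
AIC comparison refits the mixed model by maximum likelihood, because REML
likelihoods are not comparable with a least-squares fit; both AICs are
reported. Fixed-effect inference is Wald-based. A singular random-effect
fit (estimated subject variance zero) is flagged but still yields a
verdict — under a true null that is exactly the expected outcome, and both
AICs remain well defined; the verdict is withheld only when fitting fails
or separation is suspected (logistic coefficients beyond 15 on the logit
scale).

## Numerical choices and test problem sizes

Tolerances and sizes used by the test suite, chosen to exercise each claim
well away from its failure modes while keeping a full run in the low
minutes on a single core: the recovery suite decomposes 100 noiseless
archetype profiles (median relative errors of A and D below 5%, onsets
within 20 ms, correct N in at least 95%); calibration is verified on the
six conditions after fitting 2000 simulated launches; the mixed-model
verdict is checked over 100 simulated replicates of a 6-subject,
60-trials-per-subject design with the subject intercept sd at twice the
residual sd; cohort-level checks use 6 subjects x 1 trial x 6 conditions
(noiseless) and 3 x 2 x 6 (1 mm noise).

Degenerate inputs are surfaced as typed conditions (`catchkin_no_movement`,
`catchkin_no_crossing`, `catchkin_degenerate_plane`, `catchkin_out_of_range`,
...) so the pipeline can skip and log individual trials without aborting a
run.

## Known limitations

* The generator's archetype templates are stylized; real speed profiles mix
  strategies within subjects more than the templates do.
* Arc lengths use the sagittal projection throughout; if the original
  analysis used 3D arc lengths, indices on strongly lateral trials would
  differ (generated trials are essentially sagittal, so the distinction is
  unobservable here).
* Impact on touched/missed trials is only loosely defined — there is no
  contact — so event recovery there is looser than on caught trials, and the
  selection rule excludes those trials from kinematic modeling anyway.
* Per-subject regression p-values are classical OLS; no multiplicity
  correction is applied across parameters.
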