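---
title: "Methods: simulating and analysing dyadic board-ball collaboration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dyadic board-ball collaboration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boardball)
```

## The task and its physics

Two agents (or one person using both hands) each control one end of a
virtual board through a spring–damper "handle", and must slide a ball
along the board into a target area and keep it there for 1.5 s. The board
hangs on a central spring, translates vertically and rotates about one
axis; the ball rolls freely along the frictionless board. The equations
of motion implemented in `step_dynamics()` are

$$F_{side} = k_h\,(z_{side} - z_{P,side}) + c_h\,(\dot z_{side} - \dot z_{P,side}),
\qquad z_{P,L/R} = z_{board} \mp l \sin\theta,$$

$$M\ddot z_{board} = F_L + F_R - Mg - mg\cos^2\theta - k_s z_{board},$$

$$I\ddot\theta = (F_R - F_L)\,l\cos\theta - m g\, x_{ball}\cos\theta,
\qquad \ddot x_{ball} = -g\sin\theta.$$

The normal-force simplification $mg\cos^2\theta$ keeps the ball on the
board during rapid movements; exact contact mechanics are out of scope.
Default constants (`model_params()`): board mass $M = 0.01$ kg, ball mass
$m = 0.15$ kg (the heavier, dyadic-study ball; $0.05$ kg is the lighter
variant), $g = 9.81$ m/s², handle stiffness $k_h = 200$ N/m and damping
$c_h = 2$ N·s/m, central spring $k_s = 140$ N/m, control-point half-length
$l = 0.25$ m, inertia $I = 4\times10^{-4}$ kg·m². Integration and
sampling run at $1/dt = 1000$ Hz.

**Integrator.** Velocities are updated first from accelerations evaluated
at the pre-step state; positions then advance with the trapezoid of old
and new velocity. For constant acceleration this is exact, which matters
for the free-roll contract: with the board frozen at angle $\theta$, the
simulated ball must track $x_0 - \tfrac12 g\sin\theta\,t^2$ to within
$10^{-4}$ m over a second — a plain first-order velocity-then-position
update leaves an $\mathcal O(g\sin\theta\,t\,dt)$ bias several times that
tolerance, while the trapezoidal position update removes it entirely. The
scheme is stable for the stiff handle springs at these masses
($\omega\,dt \approx 0.25$ at worst).

**Trial protocol.** The ball starts at rest at the centre of one target
(released at $t = 0$); success fires at the first sample where the
continuous in-target dwell reaches the 1.5 s hold, so completion time
includes the final hold; the trial fails if $|x_{ball}| > l$ (roll-off)
or at a 60 s safety cap (reported distinctly as a timeout). Target
geometry is not fixed by the apparatus description, so defaults — centres
at $\pm 0.15$ m, half-width 0.03 m — were chosen once to give transit
distances and completion times in the few-second range, and are
configurable (`trial_config()`).

## Haptic feedback sources

`feedback_forces()` renders one of five conditions: `Without` (zero),
`Full` ($-F_{side}$), `Partner` ($F_s/2$ per side — the central-spring
share that carries the partner's action), `Environment`
($-F_{side} - F_s/2$), and `Unrelated` (replay of a pre-recorded force
profile). Partner and Environment sum to Full by construction, an
identity the tests check to $10^{-12}$ N. When a trial outlasts an
Unrelated profile, a 100 ms linear ramp bridges the profile's end and
start before replaying, keeping the rendered force continuous; the ramp
duration is a package choice (the replay rule only requires continuity).

## Synthetic dyads

No controller model is inherited from the experimental literature, so the
generator is the package's own design, built to reproduce the
phenomenology the analysis assumes — discrete, intermittent submovements
with stationary interludes — while giving exact ground truth for every
role metric:

* a shared trigger watches the ball; when the leader's previous
  submovement has finished (plus a 100 ms pause) and the ball error
  leaves a 5 mm deadband (or the commanded tilt is stale), a
  proportional–derivative rule maps ball error and velocity to a desired
  tilt, $\theta^\ast = \mathrm{clamp}(-k_p e + k_d \dot x,\ \pm 0.05)$
  with $k_p = 0.14$ rad/m and $k_d = 0.20$ rad·s/m;
* the required hand-height differential is
  $\Delta z = 2l\sin\theta^\ast + mgx/(lk_h)$ (the second term offsets
  the static torque of the off-centre ball);
* each agent executes a 300 ms minimum-jerk submovement toward its
  *share* of $\Delta z$ (`gain_share`, the leadership ground truth), with
  its onset delayed by its `reaction_delay` (the follower's lag) and its
  amplitude perturbed by Gaussian motor noise (SD 1 mm).

The gains were tuned once so that the default cooperative dyad completes
trials reliably (success rate above 0.9 is asserted in the tests) in
3–5 s — the order of magnitude a practised human pair reaches — and were
then frozen. Sessions are organised as in the five-condition design:
blocks in sets of five covering all five haptic conditions in
seed-randomised order, alternating start sides, failed trials repeated
and excluded from analysis. Unrelated-condition profiles are recorded
from a Full-condition run of the same synthetic dyad.

What the generator does *not* emulate: adaptation and learning across
blocks, any use of the haptic feedback by the synthetic agents (the
policy is vision-only, so conditions differ only in the feedback
channels), visual or proprioceptive noise, and between-dyad strategy
diversity. Passing recovery tests therefore shows that the analysis
pipeline measures what it claims on data with known structure — not that
human data will be as clean.

## Preprocessing and segmentation

Channels are low-pass filtered with a 10th-order 20 Hz Butterworth
applied forward and backward (`zero_phase_filter()`): zero phase lag, and
the single-pass magnitude is squared, giving an amplitude ratio of 0.5 at
the nominal cutoff. The design is built as a cascade of five biquads from
the analytic Butterworth poles via the bilinear transform, because a
single 10th-order transfer function is numerically ill-conditioned at a
0.02 normalised cutoff (DC errors around $10^{-4}$, versus the package's
$10^{-9}$ contract). Edges are handled by odd-reflection padding of three
times the filter order plus steady-state initialisation of each section,
so constant series pass through exactly. Velocities are central
differences (`estimate_velocity()`).

Movement states are decoded with a 3-state Gaussian hidden Markov model
on the velocity profile (`fit_segmenter()`, `decode_segments()`):
down/stationary/up for hands, clockwise/stationary/counterclockwise for
the board. Choices the method description leaves open, fixed here as:
scalar Gaussian emissions; one model per channel per session, fit by EM
on the concatenated trial velocities; k-means initialisation with ten
restarts (best likelihood kept), seed-controlled; Viterbi decoding;
states relabelled by ascending emission mean; segments shorter than 50 ms
merged into the neighbour with the higher posterior mass to suppress
label chatter. Near-constant input is rejected rather than fit. The
forward-backward and Viterbi recursions are compiled (Rcpp) — EM over
session-length 1000 Hz series is otherwise the pipeline's bottleneck.

## Coordination and role metrics

*Interaction dynamics* (`classify_interaction()`): per sample, opposite
hand directions are `aligned` (both rotate the board the same way), equal
directions `opposed`, one moving `single`, neither `stationary`; ratios
divide category time by completion time and sum to one.

*Delay* (`aligned_delays()`): for each board-rotation segment whose
dominant category is aligned, each hand's onset is the nearest
non-stationary hand-segment onset within ±0.5 s whose direction is
consistent with the rotation sign; the delay is
$\mathrm{onset}_L - \mathrm{onset}_R$, positive when the right side moved
first. The source material states this sign convention inconsistently in
two places; the package fixes the convention just given and documents it
at every surface. The ±0.5 s pairing window and the direction-consistency
requirement are package choices to reject spurious pairings; unpairable
rotations are counted, not silently dropped.

*Movement ratio* (`movement_ratio()`): ordinary least squares of
$z_L = -k_L\theta + b_L$ and $z_R = k_R\theta + b_R$ over the samples at
the ends of board-rotation segments (where a discrete movement has just
realised its intended position), pooled per block;
$p_L = k_L/(k_L + k_R)$. Intercept-full OLS is used so height offsets are
absorbed; fits need at least five endpoints; a non-positive gain sum is
flagged undefined rather than reported.

*Corrective movement* (`corrective_ratio()`): mean absolute deviation of
each hand from its trailing 200 ms moving average, window truncated to
$\min(k, t)$ samples including the current one; the ratio of the two
sides. A motionless pair (both values at floating-point residue level) is
reported as 0.5/0.5 with a flag.

*Unilateral manipulation* (`unilateral_ratio()`): each side's path length
over the samples where it moves alone, as a fraction of the joint total.

*Motion-triggered trajectory averaging* (`mtta()`): trajectories in a
window from 0.5 s before to 1 s after each board-rotation onset, shifted
to zero at onset, left side sign-flipped, normalised by the rotation's
required total movement
$L_{req} = 2l(\sin\theta_{end} - \sin\theta_{start})$, then averaged per
role × condition over all segments. Windows that cross trial boundaries
are dropped rather than padded, and rotations with $|L_{req}|$ under
$10^{-4}$ m are excluded to avoid a near-zero normaliser.

*Leader call* (`leadership_summary()`): the movement-ratio side leads
when $|p_L - 0.5| \ge 0.05$; otherwise at least two of the remaining
metrics (delay sign, corrective ratio, unilateral ratio, each with its
own indifference band) must agree unanimously, else the dyad is reported
as having no clear leader. The bands operationalise the qualitative
"no clear leader" exclusions; a single weakly-decisive metric is not
allowed to decide on its own.

## Statistics

`compare_conditions()` runs the one-way repeated-measures ANOVA on
per-subject condition means (uncorrected F alongside a
Greenhouse–Geisser-corrected p, both labelled, since the sphericity
treatment is otherwise unspecified) and all pairwise paired t-tests with
Holm step-down adjustment. Subject-level aggregation uses the mean over
all analysed trials in the condition. The degenerate all-equal design is
reported as $F = 0$, $p = 1$. Linear mixed models for partially crossed
designs are deliberately out of scope; the per-trial tables exported by
`run_study()` are the interface to external mixed-model software.

## Problem sizes and numerical conventions

The test and verification workloads use reduced layouts chosen for
desk-scale runs: recovery studies use one set of five blocks with four
trials per block (20 trials per dyad); the end-to-end determinism check
uses five blocks of two trials. These sizes are sufficient for the
contracts they verify — roughly a hundred pooled delay observations and
several hundred rotation endpoints per dyad. Other conventions:
in-target dwell is counted in whole samples (1500 samples at 1000 Hz
equals the 1.5 s hold, boundary inclusive); failure takes precedence over
success within a sample; recordings serialise channels with 17
significant digits so disk round-trips are bit-exact; every stochastic
stage (trial noise, schedule order, EM restarts) draws from a seed
recorded in the output metadata, and rerunning a study with the same
configuration reproduces byte-identical tables.

## Known limitations

The synthetic agents do not close the loop on haptic feedback, so
condition effects on coordination — the central empirical question for
human dyads — cannot emerge from generated data; the generator validates
the measurement pipeline, not the behavioural hypotheses. The HMM
assumes three velocity regimes with Gaussian emissions; hand tremor or
drift outside that family will blur segment boundaries. The movement
ratio assumes the linear angle-to-hand map holds at rotation endpoints;
strongly nonlinear strategies would need the fit diagnostics (per-side
$R^2$) inspected before trusting $p_L$. Ball-board contact is simplified
as described, and the board's rotational inertia excludes the ball's
contribution, following the printed constant.
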