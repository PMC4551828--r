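---
title: "Models and methods behind flextrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flextrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flextrack)
```

# The scientific problem

In a homonym relatedness-judgment task, participants see a homonym (a word
with two unrelated meanings) together with an associate and indicate by a
mouse movement whether the two are related. Two orthogonal manipulations
probe two putative types of cognitive flexibility:

* **priming** (primed / unprimed): an immediately preceding prime trial
  activates one of the homonym's meanings; identifying an associate of the
  *other* meaning requires shifting away from the primed cognitive set
  ("shifting flexibility");
* **association strength** (strong / weak): weakly related associates
  require a broader search through semantic space
  ("spreading flexibility").

The package provides, as tested code, everything such a study needs short
of human participants: the exact trial schedule, a neural-field model that
generates the design's qualitative predictions, a synthetic data generator
with known ground truth, and the full analysis chain (trajectory
preprocessing, time-continuous multiple regression with temporal-segment
detection, repeated-measures ANOVA, signal detection, effect correlations).

# Session design

One session has 504 trials: 84 homonym trials, each immediately preceded by
its prime trial (84), 84 associated filler trials, 84 homonym catch trials
(homonym + unrelated word) and 168 filler catch trials — 252 related and
252 unrelated word pairs. Each of 42 homonyms appears once per block across
two blocks, with each meaning primed exactly once; priming and association
are crossed so that each factor level receives 42 homonym trials (21 per
2×2 cell). `build_session()` shuffles each prime+homonym pair as a single
unit among the other trials of its block, which preserves prime–homonym
adjacency while leaving the order otherwise uniformly random under the
seed.

Counterbalancing decisions that the design leaves open were resolved
deterministically so that they are reproducible: the side of the "related"
response box alternates with participant-id parity, and which meaning is
primed first is drawn per homonym from the session seed and reversed in
block 2. Homonym identities are abstract tokens (`h01`–`h42`); word
material is out of scope.

```{r design}
sched <- build_session(1, default_design(), seed = 1)
table(homonym_conditions(sched)$priming,
      homonym_conditions(sched)$association)
```

# The dynamic neural field model

Word meanings are activation peaks in a one-dimensional field over a
topographic semantic space $x \in [0,1]$, governed by Amari-type dynamics
with logistic gain $f(u) = 1/(1+e^{-\beta u})$:

$$\tau \dot u(x,t) = -u(x,t) + h + S(x,t) + \int w(x-x')\, f(u(x',t))\, dx'$$

with lateral interaction $w(\Delta) = c_\mathrm{exc}
e^{-\Delta^2/2\sigma_\mathrm{exc}^2} - c_\mathrm{inh}$ (local excitation on
top of global inhibition, zero padding at the field boundary: semantic
space is not circular). The input $S$ is the sum of Gaussians at the two
meaning positions ($m_1 = 0.3$, $m_2 = 0.7$, width `input_sigma`), a
Gaussian at the associate's position (distance `d_strong` = 0.03 or
`d_weak` = 0.08 from the target meaning), and a priming peak at the primed
meaning whose amplitude decays as `prime_amp`·exp(−t/`prime_tau`).

Two modelling choices deserve comment. First, priming is modelled as a
*decaying input* rather than decaying pre-activation of `u`; both realize a
fading head start for the primed subspace, and only the input variant is
implemented. Second, the priming peak has its own width `prime_sigma`
(default 0.1, broader than the word-level `input_sigma`): a prime activates
a semantic neighbourhood, not a single word. This breadth also keeps the
priming advantage approximately independent of the associate's distance,
which is what makes the two factors additive in the model's identification
times.

A trial is simulated from rest ($u = h$); the *identification time* is the
first crossing of threshold `theta` by the activation at the associate's
site. Divergence onsets compare the activation traces of a factor's two
levels (averaged over the other factor) against a tolerance
(`divergence_tol`, activation units).

Default parameters (`field_params()`) were chosen once so that the field
shows all the qualitative properties the framework claims, with margins:
primed < unprimed and strong < weak identification times; an interaction
contrast below 20% of the smaller main effect; priming divergence before
association divergence; monotone benefits of `sigma_exc` (spreading) and
`prime_amp` (shifting). The time constant `tau` = 120 ms and `dt` = 0.5 ms
put identification times in the 70–100 ms range; the model's timescale is
conceptual, not fitted. The dynamics are deterministic: identical
parameters give bit-identical traces.

```{r field}
predict_design(field_params())
```

# The synthetic data generator

`generate_dataset()` emulates the study's conditions: 20 participants, one
full 504-trial session each, cursor samples at 92 Hz on a 1280×1024 px
screen (200 px response boxes, 140 px start box), 2.5 s response deadline,
and small abort rates (late start-box click 0.14%, late movement start
0.01%) so exclusion code paths are exercised.

RT and error rates are additive in the two factors with no built-in
interaction: RT = 1084 + 100·[unprimed] + 80·[weak] + N(0, 150²) ms
(truncated into (0, 2500]), so the grand-mean homonym RT is 1174 ms; error
rates are 0.10 + 0.22·[unprimed] + 0.18·[weak], clipped to [0.02, 0.6],
putting the hardest cell (unprimed–weak) at the 50% chance level and the
average homonym error rate at 30%. A Gaussian RT is a modelling convenience
(human RTs are right-skewed); it is isolated behind the generator
interface. Non-homonym trial types have their own base rates, with catch
trials slower but more accurate than related trials.

Trajectories are generated *phenomenologically* as a heading-angle process,
not from the neural field, because recovery tests need exactly known
ground truth. The heading at normalized time $s = t/\mathrm{RT}$ is

$$\theta(s) = \theta_\mathrm{base}(s)
  \;-\; \mathrm{sgn}\cdot\big(15^\circ s_p\, w_1(s) + 12^\circ s_a\, w_2(s)\big)
  \;+\; \varepsilon(s),$$

where $w_1, w_2$ are raised-cosine bumps on the priming window
(0.47–0.79 of movement time) and association window (0.61–0.76) — the
published temporal segments — and $s_p, s_a = +1$ pull toward the wrong box
for unprimed / weak trials. $\varepsilon$ is AR(1) noise at the 92 Hz
sample level (coefficient 0.8, stationary SD 8°). The generator refuses
configurations whose priming window does not open before the association
window, since that ordering is the ground truth the analysis must recover.

Two implementation details protect the ground truth. The endpoint must land
inside the chosen response box, but a warp computed from the
condition-deflected path would smear condition information over *every*
time slice (the correction is condition-correlated). The warp is therefore
computed from a reference path integrated *without* the condition bumps, so
it is condition-independent and the condition influence on headings stays
exactly inside its window. Second, the AR(1) noise has its first-order
lateral drift projected out (a closed-loop-control interpretation: heading
noise wanders but does not carry the endpoint away); without this, the
residual warp installs a per-trial heading bias common to all 100 slices,
which masquerades as long-range temporal correlation in the regression.

What the generator does **not** emulate: word-level semantics, practice
trials, right-skewed RT distributions, speed–accuracy coupling within a
trial, or trajectories driven by the field model itself (an adapter could
map activation differences to heading bias, but recovery tests would then
lack known windows). Passing recovery tests therefore show that the
analysis chain detects the temporal structure it assumes, not that human
data contain that structure.

# Trajectory preprocessing

The chain is fixed: validate → canonicalize → start-align → time-normalize
→ heading angles → smooth. Erroneous, deadline and aborted trials are
excluded (with per-reason rates reported); only correct homonym trials
enter the regression. Trajectories are mirrored about the screen midline so
the correct box lies at canonical right, converted to y-up coordinates,
and rigidly translated to a common start.

Each movement is linearly interpolated at 101 equally spaced *time* points
(normalization is in time, not arc length), giving exactly 100 difference
vectors and hence 100 heading angles — matching the "100 slices → 100
regressions" convention downstream. The heading angle is
`atan2(Δx, Δy)` in degrees: 0° is straight up, +90° toward the correct box,
−90° toward the incorrect box. Zero-length difference vectors inherit the
previous angle.

Angles are smoothed with an 8-point Gaussian window before regression; the
window length is deliberately equal to the 8-slice segment criterion, which
is the multiple-comparison control. The Gaussian's σ is not dictated by the
window length; σ = 2 points (half-width ≈ 2σ) is the default and it is
configurable, as is turning smoothing off for sensitivity checks. Edge
handling is reflect (edge-mirror) padding with a kernel normalized to sum
one: constants pass through unchanged, but note that reflect padding does
*not* conserve the mean of an arbitrary series exactly — boundary columns
of the effective smoothing matrix do not sum to one. The test suite pins
the smoother to an independent brute-force oracle instead.

Curvature is the shoelace (signed polygon) area between the path and the
straight start→end line, with deviation toward the incorrect side positive,
so larger curvature means more response conflict. Whether the published
curvature measure was signed or absolute is not stated; the signed variant
is implemented.

# Time-continuous multiple regression

Per participant and per slice, the heading angle over correct homonym
trials is regressed on an intercept and three regressors: association
(strong −1 / weak +1), priming (primed −1 / unprimed +1) and their product
(already in {−1, +1}, not re-normalized). With balanced cells the
regressors are orthogonal and every variance inflation factor is exactly 1;
error-based exclusions unbalance cells, and the pipeline warns when the
maximum VIF exceeds 1.1.

The per-slice beta weights are averaged across participants and tested
against zero with two-tailed one-sample t-tests (df = n−1; a directional
choice is not stated in the source convention, so two-tailed was chosen).
Temporal segments are maximal runs of at least 8 consecutive slices with
p strictly below α = 0.05; a slice at exactly α counts as non-significant.
Steps map to milliseconds linearly through the grand-mean RT of included
homonym trials: ms = round(step/100 · RT̄). A single grand-mean RT of
1174 ms reproduces all four published segment endpoints (steps 47, 61, 76,
79 → 552, 716, 892, 927 ms) within 1 ms, which the suite checks as an
internal-consistency property.

`recover_windows()` is the recovery harness: it reports, per regressor, the
Jaccard overlap between all detected slices and the true window, and
whether the priming onset precedes the association onset. Onsets are taken
from each regressor's *dominant* (longest) segment, mirroring the
convention of reporting one temporal segment per regressor; with
autocorrelated noise the detector occasionally adds a short spurious run,
and the dominant segment is the meaningful one.

# Discrete statistics

For the fully within-subject 2×2×2 design (priming × association ×
repetition) every effect has one numerator degree of freedom, so the
repeated-measures ANOVA uses the contrast-score formulation: the
per-participant contrast (mean of +1 cells minus mean of −1 cells) is
tested with a one-sample t, F(1, n−1) = t², and partial eta squared is
F/(F + n − 1). This is exact, dependency-free, and testable against an
`aov()` sums-of-squares oracle, which the suite does. The trial-type
analysis (5 levels) uses a one-way RM-ANOVA with the Greenhouse–Geisser
epsilon estimated from the double-centered covariance of level scores,
bounded to [1/(k−1), 1]; post-hoc pairwise paired t-tests are reported
uncorrected, as in the source analysis.

Signal detection treats relatedness as the signal: unprimed–weak homonym
trials (related) are signal trials, homonym catch trials (unrelated) noise
trials; a hit is a "related" response on signal, a false alarm a "related"
response on noise. All unprimed–weak homonym trials enter, both
repetitions. Extreme rates are corrected by the 1/(2N) rule (the correction
used in the source is unstated), and d′ = z(hit) − z(fa). A guessing
responder has expected d′ = 0; under the default generator the hardest cell
errs at 50% yet d′ stays far above zero, because catch-trial false alarms
are rare — the structural signature that errors are not guesses.

Cross-participant effect correlations (association effect vs priming
effect, per participant, for RT and error rate) use Pearson correlation;
error rates are computed over non-aborted trials only.

# Numerical choices and degenerate inputs

* Explicit Euler with `dt` < `tau` (default dt/τ ≈ 0.004); non-finite
  activation raises an error naming the parameters.
* Zero-variance contrast scores, zero-variance betas and perfectly
  collinear regressors are flagged rather than silently propagated
  (t = 0 or ±∞ with p = 1 or 0; VIF capped at 10⁶ with a warning).
* Degenerate paths (start = end) give curvature 0 with a warning; fewer
  than 2 trajectory samples is an error.
* The master seed fans out to per-participant sub-seeds with a fixed
  stride, so adding participants never perturbs existing ones; all
  randomness is isolated from the caller's RNG state.

# Known limitations

* The segment criterion (8 consecutive significant slices) controls the
  family-wise false-segment rate only relative to the temporal correlation
  of the per-slice statistics. With smoothing alone the suite's null
  datasets are almost always segment-free, but the generator's AR(1)
  heading noise lengthens the correlation of the t-series beyond the
  smoothing window, and occasional spurious runs then survive the 8-slice
  criterion. The acceptance suite measures this specificity directly on 20
  seeded null datasets and documents the shortfall rather than relaxing
  either the noise model or the criterion.
* The contrast-score ANOVA covers 2^k within-subject designs only; there is
  no mixed-model or cluster-permutation alternative, by design.
* The field model is 1-D, unfitted, and deterministic; it produces ordinal
  predictions, not quantitative RTs.

# Problem sizes used by the test suite

Unit tests run on 2–4 synthetic participants; the acceptance tests use the
full study conditions (20 participants × 504 trials) with 20 seeded
replicates per recovery claim and a 1000-replicate null calibration of the
ANOVA — sizes at which the whole suite completes in a few minutes on a
single CPU.
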