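---
title: "Neuromechanics of slip- and trip-induced falls: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromechanics of slip- and trip-induced falls: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slipgait)
```

## The scientific problem

Falls in older adults are dominated by slips (too little foot-ground
friction) and trips (unexpected foot-ground contact during swing, favoured by
too much friction when the swing foot skims the floor).  Age changes gait in
ways that pull in both directions: shorter strides lower the required
coefficient of friction and so protect against slips, while reduced foot
clearance raises the heel's landing speed (raising the required friction) and
brings the swing toe closer to the floor (raising trip exposure).
Experiments over a whole range of floor frictions with frail participants are
not ethical, so `slipgait` studies the trade-off in a closed-loop
neuromechanical simulation: a planar walker whose gait is not prescribed but
*emerges* from the coupling of a rhythm-generating neural network, a
segmented body, and the ground.  Friction of the floor is then a dial that
can be set anywhere from icy (0.05) to high-grip rubber (2.0), and falls are
classified automatically.

## The mechanical model

The body is eight rigid segments — head-arms-trunk (HAT), pelvis, and left
and right thighs, shanks, and feet — with total mass 70 kg and stature
1.8 m.  The segment masses, lengths, centre-of-mass offsets, and moments of
inertia follow standard proportional body-segment-parameter tables
(Winter-style fractions), normalised so the totals are exact; the stack
ankle + shank + thigh + pelvis + HAT reproduces the stature identically.
The seven joints (trunk, hips, knees, ankles) are ideal pins.

The equations of motion are written in redundant coordinates: each segment
carries $(x, y, \theta)$ and each pin joint contributes two algebraic
constraints.  At every evaluation the solver forms the KKT system

$$\begin{pmatrix} M & -J^{\mathsf T} \\ J & 0 \end{pmatrix}
\begin{pmatrix} \ddot q \\ -\lambda \end{pmatrix} =
\begin{pmatrix} f \\ \gamma \end{pmatrix}$$

with diagonal mass matrix $M$, constraint Jacobian $J$, applied forces $f$
(gravity, ground forces, joint torques), and $\gamma$ collecting the
centripetal terms plus Baumgarte stabilization
($\gamma \mathrel{{-}{=}} 2\zeta\omega\,\dot C + \omega^2 C$ with
$2\zeta\omega = 100\ \mathrm{s^{-1}}$, $\omega^2 = 2500\ \mathrm{s^{-2}}$).
Because $M$ is diagonal the system is solved by a Schur complement on the
$14\times14$ constraint block.  The Lagrange multipliers are the joint
constraint forces; action and reaction are equal and opposite by
construction.  After every accepted step the state is projected back onto
the constraint manifold (mass-weighted Newton projection, tolerance
$10^{-10}$ m), so joint residuals stay at solver accuracy over arbitrarily
long runs.

Integration is a fixed-step classical Runge-Kutta (4th order) scheme at
$\Delta t = 2\times10^{-4}$ s for the coupled mechanical and neural state.
The step is set by the ground contact stiffness (the fastest local rate is
roughly $b_{gx}/m_{\rm foot} \approx 2.2\times10^3\,\mathrm{s^{-1}}$, well
inside the stability region at this step).  A fixed-step explicit scheme was
chosen over an adaptive one so that trajectories are bit-reproducible from
`(model, mu_s, seed)`.

Passive joint torques are viscoelastic limit stops: zero inside the neutral
range and a stiff restoring torque plus damping beyond documented limits
(knee extension stop at 0 rad prevents hyperextension; trunk, hip, and ankle
ranges are physiological).  There are no muscle-tendon models: actuation is
by joint torques, as in the original rhythm-generator formulation.

## Ground contact and friction

Each foot touches the ground at its heel and toe.  Contact is a penalty
spring-damper pair per point ($k_{gx} = 27{,}000$, $k_{gy} = 18{,}000$ N/m,
$b_{gx} = 2250$, $b_{gy} = 1000$ N s/m), anchored horizontally at the
touchdown position and re-anchored at every new touchdown.  Forces are
smoothed by a ramp indicator over the first centimetre of penetration;
vertical damping acts only against downward motion and the vertical force is
never negative.  Where a static coefficient of friction $\mu_s$ is set, the
horizontal force is clipped to $|F_{gx}| \le \mu_s F_{gy}$ with sign
preserved, so forward and backward shear are capped symmetrically; sliding
is emergent (the anchor is *not* dragged during a capped episode).  The
friction schedule is piecewise-constant in floor position; in the sweep
protocol it is "unset" (no cap) for the first 5 m and $\mu_s$ beyond.  We
treat $\mu_s$ as a property of the floor evaluated at the contact point's
anchor, while the trial's classification window is measured at the
whole-body CoM; the distinction only matters within a single step length.

## The neural rhythm generator

Fourteen leaky neurons with adaptation form seven flexor/extensor pairs, one
per joint.  Neuron $i$ obeys

$$\tau_i \dot u_i = -u_i - \beta f(v_i) + \textstyle\sum_j w_{ij} f(u_j)
  + u_0 + S_i, \qquad
  \tau'_i \dot v_i = -v_i + f(u_i), \qquad f(u) = \max(0, u),$$

with mutual inhibition inside each pair and between the contralateral hip
pairs (anti-phase alternation), plus a small ipsilateral hip-to-knee and
hip-to-ankle swing synergy.  A configuration switch (`literal_coupling`)
preserves the alternative self-indexed reading of the coupling sum for
comparison runs; the standard cross-coupling is the default.  The separate
"input from other neurons" pathway is folded into the weighted coupling sum.

The three gait models differ only in the tonic drive $u_0$, the ratio
$\tau_i/\tau'_i$ (uniform across neurons), the eighteen torque transfer
coefficients $p_k$, and the percentage of multiplicative white noise applied
to $u_0$ (young adult: $u_0 = 7.08$, ratio 0.036, noise 8.5%; elderly
non-faller: 5.16, 0.100, 2%; elderly faller: 5.10, 0.076, 0.1% with reduced
$p_k$).  Noise is drawn once per integration step, shared by all fourteen
neurons, from the trial's seeded stream; "percentage" is interpreted as the
standard deviation of the multiplicative perturbation, the only reading
consistent with noise quoted as a percentage of $u_0$.

### Torque channels and sensory feedback

The published description of this model family fixes the *number* of torque
transfer channels (eighteen) and the per-model values of $p_k$, but not the
channel-to-joint map, the connection weights, the feedback law, or the
absolute time constants.  Those are this package's own musculoskeletal
calibration, frozen in `cpg_network_default()` and archived in
`inst/cpg/default_network.yaml`.  The channel map is mirrored left/right and
gated by the stance/swing state: hip flexor ($p_1$, plus $p_{14}$ in swing),
hip extensor ($p_2$, weighted toward stance, with an early-stance boost
$p_8$ and a small swing retraction channel $p_{17}$); knee flexor ($p_3$,
plus $p_4$ in swing), knee extensor ($p_9$ in stance, $p_{11}+p_{18}$
through terminal swing); ankle dorsiflexor ($p_6$, plus $p_{15}$ in swing
and $p_{12}$ in stance), plantarflexor ($p_7$, plus $p_{13}$ in swing and
the push-off channel $p_5$ gated by the shank passing forward over the
ankle); trunk extensor $p_{16}$ and flexor $p_{10}$.  Under this map the
elderly faller's strongest reductions ($p_4 \times 0.43$,
$p_{14} \times 0.49$, $p_{15} \times 0.60$, $p_3 \times 0.665$) all strike
swing-limb flexion — exactly the channels that generate foot clearance —
which is what produces its low-clearance, trip-prone gait.

Because the transfer coefficients are dimensionless, a torque unit constant
converts $p_k f(u)$ into N·m.  We calibrate one constant per joint group
(trunk, hip, knee, ankle); the knees carry a deliberately small constant so
that swing-knee folding and unfolding are largely passive whip dynamics, as
in the human leg.

Sensory feedback $S_i$ implements, in mirror-symmetric form:

* a signed thigh-angle stretch reflex at each hip with a velocity lead, so
  the antagonist terminates an overlong swing burst;
* a speed-dependent swing target (capture-point-style foot placement): the
  stretch reference of the *unloaded* leg shifts forward in proportion to
  the CoM velocity, so faster walking lands the foot farther ahead;
* contralateral-contact excitation of the hip flexor (swing is triggered
  once the other leg accepts load);
* pelvis-posture correction through the stance hip and an upright-lean
  servo at the trunk joint;
* a stance knee-extensor angle servo that fires only when the knee yields
  under load (low duty, so it does not saturate its own adaptation);
* pre-swing knee flexion of the trailing leg in double support;
* swing dorsiflexion for toe clearance, a stance plantarflexor push-off
  triggered when the shank passes forward over the ankle, and an
  ankle postural strategy that recruits the stance plantarflexors under
  forward body pitch (moving the centre of pressure toward the toes) and
  the dorsiflexors under backward pitch.

All load gating uses the normalised vertical force on the foot (reference
0.3 body weights).  The adaptation coefficient $\beta$ and the uniform
absolute time constants are not printed for this model family and were
calibrated together with the feedback gains and torque unit constants by a
seeded stochastic search (a simple (1+1) evolution strategy) that maximised
first the distance walked under the young-adult parameter set and then the
closeness of the emergent gait to the reference means (stride length
1.47 m, speed 1.29 m/s), with penalties against non-walking solutions
(sustained trunk pitch, overspeed, and gaits demanding unphysiological
traction).  The calibration was run once and frozen in
`cpg_network_default()`; the elderly models are *not* separately
calibrated — they only change $u_0$, $\tau/\tau'$, $p_k$, and the noise
level, as specified.  The calibration's achieved accuracy (and where it
falls short, notably the robustness of the elderly configurations) is
reported by the package's own acceptance checks, not asserted here.

## Trials, outcomes, and the sweep protocol

A trial starts from a frozen near-standing split stance with a small forward
push and a fixed asymmetric neural kick; the first metres are start-up
transient and are excluded from all metrics.  The friction coefficient is
unset for the first 5 m and switched to the trial's $\mu_s$ beyond; the
trial ends when the CoM passes 15 m, when the hip has fallen well below the
fall threshold, or at the simulated-time limit.

A **fall** is a hip height (midpoint of the hip joint centres, matching the
0.70 m criterion for a 1.8 m body) below 0.70 m within the 5-15 m window.
A **slip** is a loaded foot whose horizontal CoM speed exceeds 0.3 m/s for
at least 10 ms (the hold suppresses single-sample touchdown spikes).  A fall
preceded by a slip in the window is **slip-induced**; a fall without one is
**trip-induced**, with the fall direction — extrapolated CoM against the
base-of-support borders at the fall instant, ties broken by the CoM velocity
sign — recorded as an annotation.  In the model's repertoire no-slip falls
are forward trips; a `direction_consistent` flag guards the assumption.
Trials whose integration diverges are rerun once at half the step and
otherwise marked `invalid`, never silently classified.

The sweep grid is 0.05-0.50 in steps of 0.05 and 0.60-2.00 in steps of 0.10
(25 values), five seeded trials per value; per-trial seeds derive
deterministically from the sweep seed, the model, and the grid/trial
indices, so any single trial is reproducible in isolation.  The slip
threshold $\mu_{s\text{-slip}}$ is the largest grid value with at least one
slip-induced fall.

## Gait metrics

Gait events come from 1 N threshold crossings of the per-foot vertical
ground force with 10 ms debounce.  Stride length is the right-toe
displacement between consecutive right touchdowns; speed is stride length
over stride time; cadence its reciprocal.  Minimum (toe) and maximum (heel)
foot clearance are extrema over the mid-swing window, taken as the middle
tercile of each swing by time.  Summaries use 10 consecutive strides of
stable gait (strides starting after the 2 m transient cutoff); the CV uses
the sample (n-1) standard deviation.  The stride-length/foot-clearance
ratio SL_FC defaults to the *maximum* clearance in the denominator: with
the reference means, that reading makes the ratio largest for the faller
model, consistent with its largest slip threshold, whereas the
minimum-clearance reading would rank the young model first; an option
selects the minimum-clearance convention.

The margin of stability uses the extrapolated centre of mass
$\mathrm{XCoM} = X + V/\sqrt{g/l}$.  The anterior border of the base of
support is the toe of the leading (double support) or standing (single
support) foot; the posterior border the corresponding heel; both margins
are positive when the XCoM lies inside the base.  The effective pendulum
length $l$ is recomputed per step as the stance-ankle-to-CoM distance at
mid-stance; per-step minima are reported over both feet.  The traction
coefficient $|F_{gx}|/F_{gy}$ is computed per contact point with frames
below 1 N of vertical force excluded (the ratio is undefined at contact
onset), and its per-stance maximum is the required coefficient of friction.

## Synthetic fixtures

The metrics and classification layers are tested against kinematic fixtures
with analytic ground truth: stance is constant, swing paths are sinusoids
chosen so the programmed minimum toe clearance is the exact mid-swing
minimum (a clearance dip between two lift humps) and the maximum heel
clearance the exact mid-swing maximum, square-wave vertical forces follow
the duty factor, and per-stride multiplicative noise with a known SD is
applied to stride lengths and clearances.  Scripted fall fixtures reverse
the outcome definitions (a loaded foot driven past the slip speed before a
hip drop; frozen feet with the CoM running beyond the anterior border; a
hip that never descends).  These fixtures share the trajectory schema with
the simulator, so everything downstream of the dynamics engine is exercised
without it.  What fixture-based tests do *not* show is dynamical realism of
the simulated gait itself; that is covered separately by the physics
property tests (energy conservation, friction-cone satisfaction, constraint
residuals) and the calibration checks.

## Numerical choices and limitations

* Problem sizes in the shipped tests are chosen for a desk-scale run: the
  calibration checks use single-seed 20 m walks and the sweep checks a
  reduced grid ($\mu_s \le 0.5$ plus 1.0 and 2.0); the full 3 x 125-trial
  figure-scale sweep is a long-running job driven by the same functions.
* Motion is sagittal-plane only; mediolateral balance, compensatory
  stepping to large disturbances, and anthropometric variation between the
  age models are out of scope by design.
* The gait is an emergent limit cycle: quantitative agreement with the
  reference means is calibration-limited, and the elderly models inherit
  whatever the shared network produces under their parameter sets.  Results
  should be read as qualitative trends, not subject-level predictions.
* The shipped calibration is an honest partial success, and the acceptance
  checks report it as such.  The young-adult configuration completes its
  trials and tolerates a high-friction floor, but its limit cycle is an
  asymmetric step pattern (alternating long and short steps) with stride
  variability and traction demand well above the reference gait; the
  elderly faller configuration walks on several seeds while the elderly
  non-faller typically falls near 9 m.  Consequently the reference-mean,
  cross-model-ordering, and sweep-threshold checks fail against their
  stated bands, and the friction thresholds the acceptance script computes
  differ from the reference values.  We left these checks at their stated
  tolerances rather than widening them: the gap is a property of this
  calibration, not of the machinery, and a future calibration can be
  dropped in through `cpg_network_default()` without touching any other
  layer.
* The contact model is a penalty method: static loads distribute across the
  four points through finite penetration (about 4 cm at full body weight on
  one foot), and the smooth indicator makes contact onset gradual over the
  first centimetre.
* With friction unset the traction ratio is unconstrained, which is the
  protocol's intent for the approach phase.
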