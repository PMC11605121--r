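# slipgait

Neuromechanical simulation of slip- and trip-induced falls during walking.

`slipgait` implements a planar (sagittal-plane) neuromusculoskeletal walker:
an eight-segment rigid body (head-arms-trunk, pelvis, thighs, shanks, feet;
70 kg, 1.8 m) driven by a central pattern generator of fourteen
Matsuoka-type oscillator neurons — one flexor/extensor pair per joint — and
coupled to the ground through spring–damper contact elements at the heels
and toes whose horizontal force is capped by a static coefficient of
friction μs.  Gait is not prescribed: it emerges from the interaction of
the neural rhythm, the body, and the floor, so the walker slips when μs is
low, trips when the swing foot grazes a high-friction floor, and falls when
its own feedback cannot recover.

The package is aimed at computational biomechanists studying fall risk: it
registers three gait parameterizations (young adult, elderly non-faller,
elderly faller, differing in the tonic neural drive u0, the oscillator
time-constant ratio τ/τ′, the eighteen torque transfer coefficients p_k,
and the white-noise level on u0), runs seeded friction sweeps with
automated fall classification, and computes the standard gait and stability
metrics.

## The model in brief

* Dynamics: redundant-coordinate rigid-body equations
  `M ẍ = A_x F_x + A_gx F_gx` (and likewise vertically and in rotation),
  solved each step together with the seven pin-joint constraints for the
  accelerations and internal joint forces; fixed-step 4th-order
  Runge–Kutta at Δt = 2·10⁻⁴ s.
* Neurons: `τ u̇ = −u − β f(v) + Σ w f(u) + u0 + S`, `τ′ v̇ = −v + f(u)`,
  `f(u) = max(0, u)`, with contact- and posture-dependent feedback `S`.
* Ground: per-point forces
  `F_gx = (−k_gx (x_f − x_ft) − b_gx ẋ_f)·1(−y_f)`,
  `F_gy = (−k_gy y_f + b_gy f(−ẏ_f))·1(−y_f)`, and the Coulomb cap
  `|F_gx| ≤ μs F_gy` wherever μs is set.
* Falls: hip height below 0.70 m within the 5–15 m window; slip-induced if
  a loaded foot moved faster than 0.3 m/s beforehand, trip-induced
  otherwise.
* Stability: margin of stability from the extrapolated centre of mass
  `XCoM = X + V/√(g/l)` against the toe (anterior) and heel (posterior)
  base-of-support borders.

See the methods vignette (`vignettes/slipgait-methods.Rmd`) for the full
account, including which constants are the package's own calibration.

## Worked example

```r
library(slipgait)

# one young-adult trial on a slippery floor (mu_s = 0.1 beyond 5 m)
trial <- run_trial("young", mu_s = 0.1, seed = 1)
trial$result
#> # A tibble: 1 x 8
#>   model  mu_s  seed outcome   fall_x fall_t max_traction status
#>   <chr> <dbl> <dbl> <chr>      <dbl>  <dbl>        <dbl> <chr>
#> 1 young   0.1     1 slip_fall   5.01   3.34         80.3 fell

# gait metrics of the same model with friction left unset
traj <- simulate_walk("young", mu_s = NA, seed = 1,
                      config = sim_config(t_max = 45, x_stop = 24))
ev <- detect_gait_events(traj)
sm <- summarize_gait(stride_metrics(traj, ev),
                     clearance_metrics(traj, ev, feet = "R"))
sm
#> # A tibble: 4 x 3
#>   variable            mean cv_pct
#>   <chr>              <dbl>  <dbl>
#> 1 stride_length      1.85    97.5
#> 2 walking_speed      1.27    67.8
#> 3 max_foot_clearance 0.297   83.0
#> 4 min_foot_clearance 0.217  106.

plot_stick_diagram(traj, interval = 0.5)   # classic gait strip
autoplot(run_sweep("young", mu_values = seq(0.05, 0.5, 0.05),
                   trials_per_mu = 5, base_seed = 1))  # fall map
```

The trial outcome reads: on a μs = 0.1 floor the young model's first stance
foot planted beyond the friction switch slid faster than the 0.3 m/s slip
threshold and the hip dropped below 0.70 m at x ≈ 5.0 m — a slip-induced
fall at the first step after the switch.  The summary is the 10-stride
mean/CV table of the emergent gait (stride length in m, speed in m/s,
clearances in m).  Note the large CVs: the shipped calibration walks the
distance but settles into an asymmetric step pattern rather than the
regular alternating gait of the reference model, so its variability is far
above the reference values — see the methods vignette for what the
calibration does and does not achieve.

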