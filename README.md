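# groupsync

Coupled phase-oscillator modeling of human group synchronization — in
particular, of the *slowing down* people exhibit when they synchronize
rhythmic movements with each other. The package is for researchers in
sensorimotor coordination and joint action who want to simulate, calibrate
and compare Kuramoto-type models against group experiments, and for anyone
needing the associated synchronization metrics and phase-reconstruction
chain.

## What it implements

Groups of $N$ players oscillating together align their phases *and* slow
down relative to their solo tempi. The standard heterogeneous Kuramoto
model on a complete graph,

$$\dot\theta_i = \omega_i + c \sum_{j=1}^{N} \sin(\theta_j - \theta_i),$$

captures the alignment but conserves the mean frequency, so it cannot slow
down. `groupsync` implements it together with three extensions that can:

| model | mechanism | extra parameters |
|---|---|---|
| `standard` | phase coupling only | — |
| `adaptive` | natural frequencies decay ($\dot\omega_i = -\omega_i/r^2$) until the order parameter reaches a threshold $\tilde r$ | $\tilde r$ |
| `weighted` | selective attention: coupling weights $w_{ij} = \sigma_i/\sigma_j$ from solo motor variability | — (weights from data) |
| `delayed` | perception–action delay: agents couple to partners' phases $\tau$ s in the past | $\tau$ |

Around the models sit:

* **metrics** — order parameter $r(t)$, group phase $\psi(t)$, windowed
  frequency-coordination index $\rho(t)$, group frequency, trial summaries;
* **preprocessing** — spline resampling of 10 Hz position traces to 100 Hz,
  zero-phase Butterworth low-pass, analytic-signal (Hilbert) phase
  extraction, solo frequency statistics;
* **calibration** — grid search over model parameters minimizing composite
  relative-error costs ($J_s$, $J_m$) against experimental summary
  statistics;
* **evaluation** — 36-pair experimental-vs-simulated trial costs, one-way
  ANOVA with Bonferroni post-hoc tests, solo-vs-group t-test, random-phase
  chance baseline;
* **synthetic data** — a Chronos-style generator of solo and group position
  trials with known ground truth, plus the packaged five-player study
  fixtures (`chronos_solo_ensemble()`, `chronos_group_summary()`,
  `chronos_optimal_specs()`).

## Worked example

Simulate the variability-weighted model at its calibrated coupling and
compare all four calibrated models against the experimental summaries:

```r
library(groupsync)

ens <- chronos_solo_ensemble()      # solo means 3.40 ... 9.91 rad/s
traj <- simulate_model(model_spec("weighted", coupling_c = 1.1), ens,
                       sim_config(duration = 30, seed = 1))
summarize_trial(traj)
#> <trial_summary> r_bar = 0.959, rho_bar = 0.994, omega_g = 3.301 rad/s

res <- evaluate_models(chronos_optimal_specs(include_delayed_self_coupling = FALSE),
                       ens, chronos_group_summary(), master_seed = 1)
res
#> <comparison_result> mean pair cost per model:
#>     model  mean_cost    sd_cost
#>  standard 0.65098216 0.17297332
#>  adaptive 0.36200050 0.45739516
#>  weighted 0.02053475 0.01035897
#>   delayed 0.02604743 0.01163608
#> ANOVA: F(3, 140) = 55.19, p = 1.31e-23
```

Reading the numbers: the weighted trial locks near 3.3 rad/s — well below
the 5.21 rad/s mean solo frequency, approaching the observed 2.97 rad/s —
with high phase coherence (`r_bar`) and near-perfect frequency coordination
(`rho_bar`). In the comparison, the attention-weighted and delayed models
achieve mean pair costs more than an order of magnitude below the standard
model (which cannot slow down and pays a large frequency-error term), and
the ANOVA confirms the model effect. (`evaluate_models` output above is
from `master_seed = 1`; exact values vary with the seed since trials draw
random initial phases and frequencies.)

Reconstruct phases from raw position traces (columnar CSV, `t, p1..pN`):

```r
trial <- read_position_trial("group-01.csv")
traj  <- preprocess_trial(trial)          # 100 Hz, 6 Hz low-pass, Hilbert
summarize_trial(trim_trajectory(traj, 0.5, 0.5))
```

A thin command-line front end is included at `inst/cli/groupsync.R`
(subcommands `simulate`, `synth`, `calibrate`, `evaluate`, `baseline`).

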