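---
title: "Coupled-oscillator models of frequency reduction in group synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-oscillator models of frequency reduction in group synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsync)
```

## The phenomenon and the models

When several people perform a rhythmic task together — oscillating a finger
in synchrony with partners they see on a screen — two things happen: their
phases align, and the whole group slows down relative to each member's solo
tempo. The five-player study packaged here (solo means 3.40, 3.04, 6.36,
3.34, 9.91 rad/s, average 5.21 rad/s) synchronized in the group condition at
2.97 rad/s, far below that average.

The classical heterogeneous Kuramoto model on a complete graph,

$$\dot\theta_i = \omega_i + c \sum_{j=1}^{N} \sin(\theta_j - \theta_i),$$

reproduces the phase alignment but, because the coupling is antisymmetric,
the mean instantaneous frequency equals the mean natural frequency at every
instant: a locked group oscillates at the average solo tempo, never slower.
`groupsync` therefore implements three extensions, each encoding a
biologically motivated mechanism for the slow-down:

* **Adaptive frequencies** (behavioral plasticity). While the order
  parameter $r(t)$ is below a desired coordination level $\tilde r$, each
  natural frequency decays as $\dot\omega_i = -\omega_i / r(t)^2$ — the
  further the group is from coordinated, the faster individuals slow down —
  and freezes once $r \ge \tilde r$.
* **Variability-weighted coupling** (selective attention). Coupling gains
  $w_{ij} = \sigma_i/\sigma_j$ built from solo frequency variability: more
  variable players adapt more, and everyone attends most to the most
  consistent partners. The $1/\sigma_i^2$-weighted mean frequency is
  conserved, so a locked group runs at
  $\sum_i \omega_i/\sigma_i^2 \,/\, \sum_i 1/\sigma_i^2$ — dominated by the
  most consistent (often slower) players.
* **Delayed coupling** (perception–action latency). Agents couple to their
  partners' phases $\tau$ seconds in the past,
  $\dot\theta_i = \omega_i + c\sum_j \sin(\theta_j(t-\tau) - \theta_i(t))$.
  A homogeneous locked solution satisfies
  $\Omega = \omega - c\,\kappa \sin(\Omega\tau)$, which for positive
  $\Omega\tau$ is below $\omega$: the lag itself produces the slow-down.

## Synchronization metrics

All analyses consume a `phase_trajectory` (uniform time grid, unwrapped
per-agent phases) and reduce it to:

* the order parameter $r(t) = |q(t)|$, $q(t) = N^{-1}\sum_i e^{j\theta_i}$,
  and the group phase $\psi(t) = \arg q(t)$;
* the frequency-coordination index $\rho(t)$: each agent's relative phase
  $\phi_i = \theta_i - \psi$ is compared to the angle $\bar\phi_i$ of its
  trailing windowed mean of $e^{j\phi_i}$, and
  $\rho = |N^{-1}\sum_i e^{j(\phi_i - \bar\phi_i)}|$. $\rho \approx 1$ means
  the agents' frequencies match even if their phase offsets do not vanish;
* the group frequency $\bar\omega_g$: the time-averaged finite-difference
  slope of the unwrapped $\psi(t)$.

Two choices here were genuinely open. The moving-average window for $\rho$
is not fixed by the study; the default is 1 s (100 samples at the 100 Hz
analysis grid), a full-to-half cycle at the frequencies involved, exposed as
`window_w` everywhere. Before a full window has accrued, the average is
taken over the growing available window, keeping $\rho$ defined on the whole
trial (the first sample then has $\rho = 1$ by construction; with 1 s out of
30 s the bias on $\bar\rho$ is below the trial-to-trial spread). Likewise
the reported group frequency differentiates $\psi$ rather than averaging
per-agent slopes; the `agent-mean` variant is kept because for the standard
model it equals the mean natural frequency *exactly* at every discrete step,
which the tests exploit as a conservation oracle.

## Integration

All four variants run through one fixed-step explicit Euler path (Rcpp) at
`dt = 0.01` s, matching the 100 Hz grid the experimental data are analysed
on and making any delay an integer number of steps. Sharing one code path
makes the reduction identities exact: $\tau = 0$, equal $\sigma_i$, or
$\tilde r$ below the realized order parameter reproduce the standard
trajectory *bitwise*, and the tests assert this with `identical()`. An RK4
integrator is available for the undelayed, non-adaptive members; halving
`dt` or switching integrators moves 30 s trial summaries by less than
$10^{-3}$, so Euler at 0.01 s is comfortably inside the discretization
tolerance of every reported quantity.

Numerical corner cases are handled explicitly:

* *Delay history.* For $t < \tau$ the partner phases are held at
  $\theta_j(0)$. This affects only the first $\tau \le 0.35$ s of a trial.
* *Delayed self-coupling.* Read literally, the delayed coupling sum includes
  $j = i$, whose term $\sin(\theta_i(t-\tau) - \theta_i(t)) \approx
  -\sin(\Omega\tau)$ does not vanish and lowers the locked frequency
  (effective $\kappa = N$ instead of $N-1$). The default follows the literal
  reading; `include_delayed_self_coupling = FALSE` selects the partners-only
  convention. Both are simulated and reported in the model-comparison
  outputs because the choice shifts the locked frequency by several percent.
* *Adaptive update.* The Euler step multiplies $\omega_i$ by
  $(1 - dt/r^2)$, floored at zero: when $r^2 < dt$ (a nearly perfectly
  incoherent instant) the unfloored step would push $\omega_i$ through zero
  and destabilize. With the floor, $\omega_i(t)$ is non-increasing under
  $r < \tilde r$ and never negative; in the continuous model it stays
  strictly positive.
* *Frequency draws.* Per-agent Gaussian draws $N(\bar\omega_i, \sigma_i)$
  reject and redraw non-positive values (relevant only for the most variable
  player, $3.40 \pm 1.55$ rad/s, at about 1.4% per draw).

Reproducibility uses one master seed per study; per-trial sub-seeds are
derived from it by an affine mixing of the trial index (and, in model
comparisons, a key computed from the model's *name*, so results are
invariant to the order in which models are listed).

## Phase reconstruction from position traces

Raw trials are position time series at 10 Hz. The chain is: cubic-spline
interpolation onto a 100 Hz grid; zero-phase (forward–backward) Butterworth
low-pass; mean-centering; FFT analytic signal; angle; unwrap. Open choices,
fixed as defaults and exposed as arguments:

* cutoff 6 Hz — twice the ~3 Hz upper rate of natural human oscillatory
  movement — and order 2, applied in both directions (the effective
  attenuation is the squared magnitude response);
* odd-symmetric padding before the filter pass suppresses the recursion's
  start-up transient at both ends;
* mean-centering removes the finger-position DC offset, which otherwise
  corrupts the analytic-signal angle;
* slope-based frequency estimates exclude 0.5 s at each end
  (`trim_trajectory()`, `edge_trim` in `solo_frequency_stats()`), where the
  FFT analytic signal has wrap-around artifacts.

For pure tones across 0.3–1.7 Hz (the study's solo range in Hz) the
reconstructed phase slope is accurate to better than 1%; a full
simulate → sinusoid → 10 Hz sampling → preprocess round trip recovers
$\bar r$ within 0.02 and $\bar\omega_g$ within 0.05 rad/s of the values
computed from the true phases over the same span.

## Calibration and model comparison

Tuning minimizes composite relative-error costs over a parameter grid
($c \in [0,2]$ step 0.1; $\tilde r \in [0.40, 0.95]$ step 0.05;
$\tau \in [0.01, 0.35]$ s step 0.01), with 10 simulated trials per grid
point, uniform random initial phases and Gaussian per-agent frequencies:

$$J_s = \lambda\Big(\tfrac{\bar r_{exp}-\bar r_{sim}}{\bar r_{exp}}\Big)^2
 + (1-\lambda)\Big(\tfrac{\bar\rho_{exp}-\bar\rho_{sim}}{\bar\rho_{exp}}\Big)^2,
 \qquad
 J_m = J_s + \Big(\tfrac{\bar\omega_{exp}-\bar\omega_{sim}}{\bar\omega_{exp}}\Big)^2,$$

with $\lambda = 0.30$ biasing the fit toward frequency coordination. The
standard model is scored by $J_s$ only (its locked frequency is structurally
fixed), the extensions by $J_m$. Ties in the argmin break toward the
smallest coupling, then the smallest second parameter, so reports are
deterministic. Simulation failures at a grid point are recorded and the
point marked invalid rather than aborting the search. Near the optimum the
cost surface is flat (the synchronization terms saturate once the ensemble
locks), so replicate searches scatter the argmin over one or two grid
steps; the calibration tests therefore assert recovery *within one grid
step*, in the majority of replicates.

Model comparison evaluates, for each model at its calibrated optimum, the
pairwise cost between every experimental and every simulated trial
($N_t = 6$ each, 36 pairs),

$$J^{e,l} = \Big(\tfrac{\omega_e-\omega_l}{\omega_e}\Big)^2
 + (1-\lambda)\Big(\tfrac{\rho_e-\rho_l}{\rho_e}\Big)^2
 + \lambda\Big(\tfrac{r_e-r_l}{r_e}\Big)^2,$$

followed by a one-way ANOVA across models and Bonferroni-corrected pairwise
post-hoc t-tests (pooled SD) over the six comparisons. Degrees of freedom
are always computed from the samples actually present. When only the
published trial-averaged experimental summaries are available, every
experimental trial is set to the average — the *table-average
approximation* — which removes the experimental trial-to-trial spread from
the pair costs; simulated spread remains, so comparisons across models are
unaffected. The solo-vs-group frequency comparison uses the classical
pooled-variance independent t-test (consistent with $df = n_1 + n_2 - 2$).

## The synthetic-trial generator

`generate_solo_trials()` and `generate_group_trials()` emulate the
acquisition platform's output so the full pipeline is testable without the
experimental dataset: 5 players, 30 s trials at 10 Hz, 7 solo / 6 group
trials, pure sinusoids of the (drawn or simulated) phases with amplitude 1
and additive Gaussian noise of sd 0.05 amplitude. Solo frequency
variability is realized *across* trials, matching how the solo statistics
were estimated (one mean frequency per trial, spread across 7 trials). The
amplitude and noise defaults are plausible placeholders, not claims about
the real traces; the generator does not emulate sensor noise spectra,
dropouts, network jitter, or amplitude drift. Consequently, passing
round-trip tests demonstrate the correctness of the phase-reconstruction
and analysis code on band-limited sinusoidal motion — not robustness to
every artifact of real motion-capture data.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script use the study-scale protocols
directly where they are cheap (36-pair model comparisons on 30 s trials;
$10^5$-draw Monte-Carlo baselines; the full 21-point coupling grid with 10
simulations per point, replicated 10 times) and reduced instances (shorter
trials, coarser grids, fewer replicates) for property-style checks where
the property holds at any size.

## Known limitations

* Complete interaction topology only; no structural couplings other than
  the variability weights, no stochastic terms inside the dynamics, no
  higher-harmonic coupling.
* The adaptive model's discrete update is Euler with a positivity floor;
  trajectories entering deeply incoherent states ($r^2 < dt$) are handled
  gracefully but not accurately — at the study's 5-agent scale this regime
  is transient and rare.
* $\rho$ depends on the window choice; values computed with different
  `window_w` are not directly comparable.
* The delayed model's pre-history convention (constant at $\theta_j(0)$) is
  one of several defensible choices and matters only during the first
  $\tau$ seconds.
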