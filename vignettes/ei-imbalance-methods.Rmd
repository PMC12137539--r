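---
title: "Methods: excitation/inhibition imbalance in reservoir models of spinal pattern formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excitation/inhibition imbalance in reservoir models of spinal pattern formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalres)
```

## Scientific background

Spinal pattern-formation circuits can be modelled as *reservoirs*: recurrent
random rate networks whose internal weights stay fixed while a linear
readout is trained to produce muscle-activation-like output. This package
studies how the **anatomical excitation/inhibition imbalance** of such a
reservoir shapes its dynamics and its ability to produce locomotor
patterns.

The network has an excitatory population (`N_E` neurons) and an inhibitory
population (`N_I` neurons) obeying Dale's law: all outgoing weights of a
neuron share one sign. Activations follow leaky rate dynamics

$$\tau \dot x = -x + J^{rec}\,\phi(x) + J^{Fb} Y + J^{In} U(t),$$

with $\phi(x) = \max(0, \tanh x)$ (a pluggable transfer mapping into
$[0,1)$), readout $Y = W \phi(x)$, and a sinusoidal drive
$U(t) = 1 + \sin(\omega t)$ whose frequency encodes the gait.

## Weight construction and the imbalance algebra

Recurrent weights are sparse half-normal: nonzero with probability $p$,
magnitudes $|\mathcal N(0, V_0)|$, negated for inhibitory neurons. The
pre-truncation variance

$$V_0 = \frac{v}{p\,(1 - 2p/\pi)}, \qquad v = g^2/N,$$

is chosen so the *full-set* variance (zeros included) equals $v$
independent of $p$ (`truncated_gaussian_variance()`). The full-set mean is
$m = \sqrt{2/\pi}\sqrt{p v/(1-2p/\pi)}$. Two composite parameters
summarize the anatomy:

- the **imbalance** $A = m_E N_E + m_I N_I$, the mean summed recurrent
  weight onto a neuron (positive = excitation-dominated), and
- the **total strength** $g_{tot} = \sqrt{g_E^2 + g_I^2}$.

`solve_params_for_imbalance()` inverts this algebra: holding $g_{tot}$
(closed form), $N_{tot}$ (integer split) or $p_{tot}$ (numeric root) fixed,
it finds the anatomy realizing a target $A$:

```{r algebra}
p <- solve_params_for_imbalance(-5, "by_g", g_tot = sqrt(2 * 1.5^2),
                                N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1)
round(c(g_E = p$g_E, g_I = p$g_I), 2)
```

## Mean-field theory

Averaging over connectivity realizations, the input to a neuron is
Gaussian with mean $\mu$ and variance $\Delta$ satisfying, at a
quasi-stationary drive value $U$,

$$\mu = A\,[\phi], \qquad \Delta = g_{tot}^2\,[\phi^2] + v_{in} U^2,$$

where $[\phi], [\phi^2]$ are Gaussian averages of the transfer
(`gaussian_moments()`). Quasi-stationarity is justified because the drive
period (0.7–1.3 s) is much longer than $\tau = 10$ ms. `solve_stationary()`
solves the four self-consistent equations by damped (0.5) fixed-point
iteration with a derivative-free root-solve fallback, to residual
$<10^{-10}$.

**Quadrature note.** The rectified transfer has a kink at $x = 0$, which
destroys the spectral accuracy of plain Gauss–Hermite quadrature (errors
of order $10^{-3}$ were observed). The moments are therefore evaluated as
$E[g(x)\,\mathbf 1(x>0)]$ with 64-node Gauss–Legendre quadrature on
$[\max(0, \mu - 12\sigma),\ \mu + 12\sigma]$, where the integrand is
smooth; this restores $<10^{-8}$ agreement with adaptive quadrature.
Smooth transfers (the sigmoid) use 64-node Gauss–Hermite.

```{r mft}
mft_curves(c(-10, 0, 10), g_tot = 2.1213)[, c("A", "mu", "Delta", "phi_mean")]
```

### Stability

Linearizing around the stationary state gives the variance-gain criterion:
fluctuations decay when $g_{tot}^2\,E[\phi'(\mu_0 + \sqrt{\Delta_0} z)^2] < 1$
(`stability_margin()`). For the driven network this criterion is
*conservative*: it ignores the stabilizing effect of the strong sinusoidal
drive and flags cells (e.g. $g_{tot} = 2.25$ near $A = 0$) that are in fact
operationally stable. `stability_boundary()` therefore re-examines
analytically-flagged cells with an **echo-state convergence probe**: two
copies of the same driven network started from independent random states
must contract their state distance by $10^{-6}$ within 10 s, for every
probe seed. The probe separates the regimes by many orders of magnitude
(contraction ratios $\sim 10^{-15}$ at $g_{tot} = 2.25$ versus $\sim 10^{-1}$
at $2.5$), and the resulting boundary on the grid $\{0.5, \dots, 2.5\}$ is
$g_{tot} = 2.25$ for all integer $A \in [-15, 15]$. When the probe's anatomy
cannot realize an extreme $(A, g_{tot})$ pair (it would need a negative
$g_I$), the probe populations are doubled until it can.

A caveat for mean-field comparisons at $A = 0$: the network then sits at
the mean-field criticality, and each finite realization carries a quenched
mean-input offset (standard deviation $\approx 0.15$ at $N_{tot} = 2000$)
that does not average out over time. Instance averages converge to the
theory only slowly ($\propto 1/\sqrt{n}$ in the number of networks).

## Target signals

The study-scale targets are 17 nonnegative channels in $[0,1]$, periodic at
activity-specific stride frequencies. Because the original muscle data are
derived from proprietary processing of one participant's motion capture,
the package ships a **synthetic generator** (`synthetic_muscle_targets()`)
emulating their structure:

- three activities — slow walk (1.30 s), fast walk (1.00 s), run (0.72 s);
- every channel a nonnegative mixture of five bell-shaped primitive bumps
  (centers at 10/30/50/70/90% of the cycle, width 8%, amplitude 0.8) shared
  across activities, each channel using 4–5 of them;
- one activity-specific bump (centers 15/45/75%, width 10%) with
  per-channel amplitudes, making the activities mutually distinguishable;
- channels rescaled to peak 0.9 and clipped to $[0,1]$.

By construction the whole set spans at most
$5 + 3 = 8$ principal components, matching the low dimensionality of real
muscle-activation sets. `primitive_patterns()` provides the 5-channel
bell patterns for the speed-generalization experiment, with a linear
speed-to-frequency map $f = 0.6 + 0.25\,\mathrm{speed}$ Hz (an artifact
choice, recorded here so it can be swapped).

`assemble_signal()` implements the assembly protocol: 15 training strides
(5 consecutive per activity) or 21 shuffled test strides, joined with a
one-sample interpolated gap, low-pass filtered at 20 Hz (2nd-order
bidirectional Butterworth), and trimmed by 50 samples at each end. The
paired input wave resets its phase at stride boundaries so every stride is
driven identically.

## Training and evaluation

`train_network()` applies FORCE learning: the network runs with feedback
of its own output while the readout is updated by recursive least squares
(`P_0 = I/\alpha`, $\alpha = 1$, update every 2 steps — the conventional
choices; with every-step updates RLS is exactly ridge regression with
penalty $\alpha$, a property the test suite checks). Training repeats for
5 iterations with activations redrawn from the standard normal each time.

`evaluate_network()` computes the outcome parameters on a frozen-weight
test run (first stride excluded as transient):

- **performance**: % of muscle–stride cells with RMSE $\le 0.05$;
- **effective dimensionality**: number of principal components for 99% of
  the firing-rate variance;
- **coactivation index**: $2\min(Y_1, Y_2)/(Y_1 + Y_2)$ on own-max
  normalized pairs, averaged over time and all unordered pairs;
- **between-task variance**: variance across per-activity mean cycles
  (strides time-normalized to 101 points; population convention);
- **firing-rate statistics**: time-averaged across-neuron mean/variance
  and pooled skewness.

```{r headline, eval = FALSE}
# The qualitative headline (about 1 min per instance at N_tot = 750):
tg <- synthetic_muscle_targets(seed = 1)
tr <- assemble_signal(tg, "train")
te <- assemble_signal(tg, "test", seed = 1)
for (A in c(-5, 0, 10)) {
  prm <- solve_params_for_imbalance(A, "by_g", g_tot = 2.1213,
                                    N_E = 375, N_I = 375,
                                    p_E = 0.1, p_I = 0.1, seed = 1)
  trained <- train_network(build_connectivity(prm), tr)
  print(evaluate_network(test_network(trained, te)))
}
# Inhibition-dominated and balanced networks reach ~85-95% success;
# the excitation-dominated network saturates (rate variance collapses,
# strongly negative pooled skewness) and fails (~2%).
```

## Numerical choices and limitations

- Euler-forward integration with $dt = 5$ ms and $\tau = 10$ ms
  ($dt/\tau = 0.5$); the shared 200 Hz time base is also the target sample
  rate. Divergence ($|x| > 10^6$ or non-finite) aborts loudly.
- Seeds: one master seed per network expands into independent named
  streams (connectivity, initial state, shuffling, probes) via a
  counter-based map (`derive_seed()`), keeping all seeds below $2^{31}$.
- Serialization is plain text (triplet CSV + JSON for connectivities,
  commented CSV for stride patterns) so artifacts stay portable and
  diffable.
- The mean-field theory omits the output-feedback term, so comparisons use
  untrained networks ($W = 0$).
- Finite-size effects at $A = 0$ (quenched criticality, above) limit how
  tightly simulation can match theory for few instances.
- Spiking dynamics, recurrent-weight plasticity, and structured spinal
  connectivity motifs are out of scope.
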