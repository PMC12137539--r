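# spinalres

Reservoir-computing models of spinal locomotor pattern formation, focused on
one anatomical knob: the **excitation/inhibition imbalance** of a sparse
Dale's-law random network.

The package provides:

- **Network core** — sparse half-normal Dale's-law connectivity with a
  prescribed imbalance `A = m_E N_E + m_I N_I` and total strength
  `g_tot = sqrt(g_E^2 + g_I^2)`; leaky rate dynamics with a rectified-tanh
  transfer, sinusoidal drive and output feedback, integrated in compiled code
  (`network_params()`, `solve_params_for_imbalance()`, `build_connectivity()`,
  `run_network()`).
- **Mean-field theory** — quasi-stationary self-consistent input mean and
  variance, firing-rate moments, E/I current split, analytic variance-gain
  stability plus an echo-state convergence probe for the driven network
  (`solve_stationary()`, `mft_curves()`, `stability_boundary()`).
- **Target signals** — a synthetic 17-channel locomotor target generator
  built from shared motor primitives, plus 5-channel primitive patterns with
  a speed-to-frequency map, and the stride assembly / filtering protocol
  (`synthetic_muscle_targets()`, `primitive_patterns()`, `assemble_signal()`).
- **Training** — FORCE learning of the linear readout by recursive least
  squares with output feedback (`train_network()`, `test_network()`).
- **Metrics** — stride success rate, effective dimensionality, coactivation
  index, between-task variance, firing-rate statistics
  (`evaluate_network()` and the individual metric functions).
- **Experiment drivers & CLI** — resumable imbalance sweeps, mean-field
  comparisons and speed-generalization runs (`run_sweep()`,
  `run_mft_comparison()`, `run_generalization()`, and the
  `inst/cli/spinalres` command-line front end).

## Worked example

Train one study-scale network at an inhibition-dominated imbalance and
evaluate its motor output (about a minute on a laptop):

```r
library(spinalres)

## Anatomy: 375 E + 375 I neurons, p = 0.1, total strength fixed,
## imbalance A = -5 realized by adjusting (g_E, g_I).
prm <- solve_params_for_imbalance(
  A_target = -5, mode = "by_g", g_tot = sqrt(2 * 1.5^2),
  N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1,
  n_outputs = 17, seed = 1
)
round(c(g_E = prm$g_E, g_I = prm$g_I), 2)
#> g_E  g_I
#> 0.92 1.91

## Synthetic 17-channel targets for slow walk / fast walk / run,
## assembled into training (15 strides) and test (21 shuffled strides).
targets <- synthetic_muscle_targets(seed = 1)
train_sig <- assemble_signal(targets, "train")
test_sig  <- assemble_signal(targets, "test", seed = 1)

## FORCE training of the readout, then a frozen-weight test run.
conn    <- build_connectivity(prm)
trained <- train_network(conn, train_sig)
run     <- test_network(trained, test_sig)

evaluate_network(run)
## performance_pct ~ 95 (muscle-stride cells with RMSE <= 0.05),
## plus effective dimensionality, coactivation index,
## between-task variance and firing-rate statistics.
```

Compare simulated networks against the mean-field theory across the
imbalance axis:

```r
mft_curves(seq(-10, 10, by = 2), g_tot = 2.1213)
cmp <- run_mft_comparison(A_grid = c(-5, 0, 5), n_instances = 3)
```

Map the stability boundary of the driven network:

```r
sb <- stability_boundary(g_grid = seq(0.5, 2.5, by = 0.25))
max(sb$g_tot[sb$stable])   # largest stable total strength on the grid
```

Or run a full sweep from the shell:

```sh
Rscript inst/cli/spinalres sweep --mode by_g --A="-10,-5,0,5,10" \
  --instances 10 --seed 1 --out results/
```

## Documentation

The methods vignette (`vignettes/ei-imbalance-methods.Rmd`) documents the
weight/imbalance algebra, the mean-field equations and their quadrature, the
stability probe, the synthetic target design, and all numerical conventions.
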