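# priomatch

Behavioral and EEG analysis of **friend-prioritization** versus
**self-prioritization** in the shape-label matching task.

In this task, participants learn arbitrary pairings between shapes and the
labels *self*, *friend* and *stranger*, then judge under time pressure
whether a word–shape pair matches the learned association. Most people
respond faster and more accurately to self-associated shapes, but a
subpopulation shows the reverse advantage for a friend's shape. priomatch
is for cognitive neuroscientists who want to detect these subgroups and
characterize the latent mechanisms behind them. It implements the full
inference chain:

- **Synthetic-data generation** — forward drift-diffusion simulation of
  choices/RTs with known per-subject ground truth, template-based EEG
  epochs with a drift-coupled, non-phase-locked alpha/low-beta
  oscillation, and trait/economic-game tables with a calibrated latent
  factor.
- **Behavioral classification** — response efficiency $E = \mathrm{RT} /
  \mathrm{accuracy}$; subjects with $E_\mathrm{self} - E_\mathrm{friend} >
  0$ form the friend-prioritization (FP) group, matched against the most
  strongly self-prioritizing (SP) controls.
- **Signal detection theory** — $d' = \Phi^{-1}(H) - \Phi^{-1}(F)$ and
  $\beta = \exp[(\Phi^{-1}(F)^2 - \Phi^{-1}(H)^2)/2]$ per subject and
  label, with extreme-rate correction.
- **Hierarchical drift-diffusion modelling** — Wiener first-passage
  likelihood (Navarro–Fuss series) with a 5% uniform outlier mixture,
  slice-within-Gibbs sampling of drift rate $v$, boundary $a$, starting
  point $z$ and non-decision time $t_0$ under a 15-model factor-dependency
  space, DIC model comparison, posterior contrasts
  ($P_\mathrm{Bayes}$), and trial-by-trial regression of ERP amplitudes
  onto $v$ or $a$.
- **EEG** — baseline correction, ±70 µV artifact rejection, the six ERP
  component definitions (N1, posterior N1, P2, N2, P3, LPP) with their
  electrode clusters, Morlet wavelet time-frequency decomposition
  ($f_0/\sigma_f = 5$, 1–40 Hz), removal of phase-locked activity, and
  ERS/ERD baseline normalization $(P(t) - P_0)/P_0$.
- **Cluster-based permutation statistics** — time × electrode clusters of
  paired t values tested against the max-cluster-mass permutation null;
  point-by-point rank correlations with a 100-consecutive-point criterion;
  group moderation of the power–drift coupling.
- **Canonical correlation** — first canonical pair between interpersonal
  traits and friend-related behavior with a permutation test, plus
  Spearman correlations with economic-game contributions.

## Worked example

```r
library(priomatch)

coh <- generate_cohort(n_fp = 3, n_sp = 3, effect_size_v = 0.8, seed = 5)
eff <- response_efficiency(coh$trials)
head(eff, 3)
#> # A tibble: 3 x 7
#>   subject label    n_trials mean_rt_ms accuracy efficiency diff_score
#>   <chr>   <chr>       <int>      <dbl>    <dbl>      <dbl>      <dbl>
#> 1 s001    friend        107       527.    0.953       552.       107.
#> 2 s001    self          103       531.    0.806       659.       107.
#> 3 s001    stranger       93       645.    0.860       750.       107.

table(classify_groups(eff)$group)
#>   FP         SP unassigned
#>    3          3          0
```

Subject `s001` is a generated friend-prioritizer: responses to the friend's
shape are as fast as to its own but ~15 points more accurate, so its
efficiency difference score (+107 ms) lands it in the FP group.
All six subjects are classified according to their latent group. Fitting
the full drift-diffusion model and contrasting the drift rates:

```r
fit <- fit_hddm(coh$trials, ddm_spec(), n_samples = 600, burn_in = 150,
                seed = 8)
p_bayes(fit, "v", c("friend_match", "self_match"), "greater", group = "FP")
#> [1] 0.9533333
p_bayes(fit, "v", c("self_match", "friend_match"), "greater", group = "SP")
#> [1] 0.9777778
```

The posterior probability that evidence accumulates faster from
friend–shape than self–shape pairs is 0.95 in the FP group (at this short
desk-scale chain) and the reverse contrast dominates in the SP group — the drift-rate signature of the two
prioritization styles. `run_pipeline(pipeline_config("desk", seed = 1))`
chains every stage (simulation, classification, SDT, DDM, synthetic EEG,
ERP components, induced-power coupling, traits and CCA) into one
reproducible result bundle.

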