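---
title: "Models and methods behind priomatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind priomatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

priomatch analyzes behavior and EEG from the shape-label matching task, in
which participants learn arbitrary pairings between geometric shapes and the
labels *self*, *friend* and *stranger*, then judge under time pressure
whether a displayed word–shape pair matches the learned association. Most
people respond fastest and most accurately to self-associated shapes
(self-prioritization), but a subpopulation shows the reverse pattern for
their friend's shape (friend-prioritization). The package provides the full
chain needed to detect and characterize the two groups: a synthetic-data
generator with known ground truth, response-efficiency classification,
signal detection indices, hierarchical drift-diffusion modelling with model
comparison, ERP and time-frequency analysis with cluster-based permutation
statistics, trial-by-trial brain–behavior coupling, and canonical
correlation with interpersonal traits.

## The decision model

Choices and response times are modelled as a Wiener diffusion: evidence
accumulates from a relative starting point $z \in (0,1)$ between two
absorbing boundaries separated by $a$, with drift rate $v$ (evidence units
per second; diffusion coefficient fixed at 1) and a non-decision time $t_0$
added to the first-passage time. A "yes" (match) response is absorbed at the
upper boundary, a "no" at the lower. The likelihood of a response is the
Wiener first-passage-time density, evaluated with the small-time and
large-time series expansions and an automatic switch to whichever needs
fewer terms at truncation tolerance $10^{-7}$; the lower-boundary density
follows from the $(v, z) \to (-v, 1-z)$ reflection. The analytic absorption
probability $P_\mathrm{upper} = (1 - e^{-2vza}) / (1 - e^{-2va})$ is used
throughout the tests as an independent oracle.

Each trial's likelihood is the mixture
$(1 - p_\mathrm{out})\,\mathrm{WFPT} + p_\mathrm{out}\,U$, where $U$ is a
uniform contaminant over the observed RT range with a random choice and
$p_\mathrm{out} = 0.05$ by default. The mixture stabilizes estimation under
fast guesses and attentional lapses, and keeps the likelihood finite for
responses faster than $t_0$.

### Hierarchical estimation

`fit_hddm()` estimates the model under a dependency map that states which
design factors (label, match, between-subjects group) each parameter may
vary over; the full hypothesized structure (Model 1) is
$v \sim \mathrm{label} \times \mathrm{match} \times \mathrm{group}$,
$a, z \sim \mathrm{label} \times \mathrm{group}$,
$t_0 \sim \mathrm{match} \times \mathrm{group}$. Sampling is on
unconstrained scales — $v$ as is, $\log a$, $\mathrm{logit}\, z$,
$\log t_0$ — with subject-level parameters Normal around their group mean
and Half-Normal priors on the group sds. Weakly-informative priors are
$\mu_v \sim N(0, 2^2)$, $\mu_{\log a} \sim N(\log 1.5, 1)$ (a log-normal,
i.e. positive, marginal for $a$), $\mu_{\mathrm{logit}\,z} \sim N(0, 1)$,
and $\mu_{\log t_0} \sim N(\log 0.25, 1)$ capped below the fastest observed
response. A hard upper truncation of $t_0$ at the minimum RT is
unnecessary because the contaminant keeps the likelihood finite. The
sampler is component-wise stepping-out slice sampling within Gibbs (group
means have conjugate Normal updates); all randomness comes from R's RNG so
a seed makes runs bit-reproducible. Convergence is monitored with split
R-hat on the group-level draws and flagged (not silently ignored) above
1.1.

The desk-scale default is 2000 samples with 500 burn-in; the full-scale
preset in `pipeline_config("paper")` is 10000/1000. Model fit is compared
with the classic DIC, $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$ and $\bar\theta$ the posterior mean of the
subject-level parameters on the sampling scale.

### The 15-model space

The candidate space reduces Model 1 by removing hypothesized factor
dependencies: Models 2–6 and 8–11 drop a single dependency ($v$ losing
label, match or group; $a$ or $z$ losing label or group; $t_0$ losing match
or group), Model 7 removes the label dependence of both $a$ and $z$ (the
structure used in earlier self-prioritization work), and Models 12–15
collapse progressively until only the drift rate carries condition
dependence. Which dependency each reduced model drops is a package
convention — the mapping is exposed by `enumerate_model_space()` — since
only the count and the reduction principle are fixed by the design.

### Model comparison at desk scale

A point worth documenting: the conditional-focus DIC used here (deviance of
the data given subject-level parameters) is nearly insensitive to
*group-level* dependency structure when each subject contributes many
trials, because subject parameters absorb group differences and only
hierarchical shrinkage transmits the hyper-structure to the likelihood.
With hundreds of subjects this shrinkage signal accumulates; at desk-scale
cohort sizes it is of the same order as the Monte-Carlo noise of the DIC.
The scaled-down model-recovery analysis therefore uses the pooled
estimation mode (`hierarchical = FALSE`), in which trials are pooled and
the dependency structure — including the group factor — enters the
likelihood cells directly, making DIC differences large and stable.
Hierarchical estimation is exercised separately by the parameter-recovery
analysis, where it is the appropriate tool.

### Trial-by-trial neural regression

`fit_neural_regression()` links a standardized single-trial covariate (an
ERP amplitude) to the drift rate, $v_i = v_0 + \beta x_i$, or to the
boundary on the log scale, $a_i = \exp(\log a_0 + \beta x_i)$, with
per-subject parameters Normal around group means. The reported quantities
are $P_\mathrm{Bayes}(\beta > 0)$ and $P_\mathrm{Bayes}(\beta < 0)$, the
fractions of post-burn-in draws on each side of zero.

## Behavioral indices

Response efficiency is mean correct RT divided by accuracy (ms; lower is
better), computed on matching trials; trials without a response before the
1100 ms deadline ("slow" feedback in the task) enter neither the RT mean
nor the accuracy. The self-minus-friend efficiency difference classifies
subjects: positive differences form the friend-prioritization (FP) group,
and the equally many most-negative differences form the self-prioritization
(SP) control group. An exactly zero difference is unassigned (the rule is
strictly "larger than zero"), and ties at the SP boundary break by subject
id. RTs entering the efficiency are untrimmed by default; a trimming window
is exposed as an option since the upstream convention is unstated.

Sensitivity and bias follow signal detection theory with hits = "yes" to
match and false alarms = "yes" to nonmatch:
$d' = \Phi^{-1}(H) - \Phi^{-1}(F)$ and
$\beta = \exp[(\Phi^{-1}(F)^2 - \Phi^{-1}(H)^2)/2]$. Rates of exactly 0 or
1 are replaced by $1/(2N)$ and $1 - 1/(2N)$ before the quantile transform
(the standard remedy; a log-linear alternative is exposed).

The bootstrap display of condition means resamples subjects (their
per-condition means) with replacement, 1000 times at full scale, matching
the estimand of a population-mean scatter. Mixed-design ANOVAs use the
classic balanced sums-of-squares decomposition with partial $\eta^2$ and a
90% CI from inverting the noncentral-F distribution, plus
Bonferroni-corrected pairwise contrasts.

## EEG analyses

ERP epochs span $-200$ to $+800$ ms around stimulus onset with the mean of
the 200 ms pre-stimulus window subtracted per trial and channel; trials
exceeding ±70 µV at any electrode are rejected. Component amplitudes are
means over fixed windows and electrode clusters (frontal N1 100–150 ms at
FCZ/FZ/CZ; posterior N1 147–167 ms at TP7/T5; P2 180–240 ms; N2 240–300
ms; P3 320–360 ms; LPP 500–700 ms, each with its printed cluster), with
window endpoints inclusive at sample resolution. Peak latencies search the
component window, except for the LPP where the search extends to 800 ms so
late peaks near the 700 ms window edge remain measurable — an
interpretation the latency range of real data makes necessary. Old and new
10/20 temporal electrode names (T3/T7 and so on) are reconciled by an alias
table.

Time-frequency analysis uses complex Morlet wavelets
$w(t, f_0) = A\, e^{-t^2/2\sigma_t^2} e^{2i\pi f_0 t}$ on a 1–40 Hz grid in
1 Hz steps with $f_0/\sigma_f = 5$ and $A = (\sigma_t\sqrt{\pi})^{-1/2}$
(unit kernel energy). The family constraint fixes only the spectral width;
the temporal width follows the standard reciprocal relation
$\sigma_t = 1/(2\pi\sigma_f)$. Instantaneous power is
$P(t) = \mathrm{Re}[TF(t)]^2 + \mathrm{Im}[TF(t)]^2$, and ERS/ERD is the
proportional change $(P(t) - P_0)/P_0$ against the $-300$ to $-100$ ms
baseline, computed per trial and then averaged (the alternative order is
exposed). Phase-locked activity is removed by subtracting each condition's
ERP from its trials before decomposition. Convolution is FFT-based with
explicit edge-invalid masks (±2$\sigma_t$) instead of padding, so power
near the epoch edges is never biased — frequencies whose valid region is
empty on a short epoch are dropped with a warning. Because the baseline
window precedes $-200$ ms, time-frequency epochs are cut $-500$ to $+800$
ms, longer than ERP epochs; statistics run on 0–800 ms in the three bands
delta/theta 2–7 Hz, alpha/low-beta 8–18 Hz, and beta 19–29 Hz.

### Cluster-based permutation statistics

For paired condition contrasts, one-sample t statistics over subjects are
computed at every channel × time point; points beyond the two-sided
per-point threshold ($\alpha = .05$) form signed clusters under channel
adjacency (derived from 2D montage distances, threshold chosen so the
median neighbor count is about 4) crossed with consecutive-sample time
adjacency. Each observed cluster's mass (summed t) is referred to the
permutation distribution of the maximum absolute cluster mass under random
per-subject sign flips, pooling positive and negative clusters (two-sided);
p-values are $(b + 1)/(n_\mathrm{perm} + 1)$. Zero-variance points are
excluded from clusters rather than propagating NaNs. Point-by-point
brain–behavior coupling uses a rank correlation at every sample with a
consecutive-run criterion of 100 points, which at the native 1000 Hz
sampling spans 100 ms; group moderation of the coupling is the interaction
term of `diff_drift ~ diff_power * group`.

## Canonical correlation

The trait block (four empathy subscales, two self-construal scores, four
friendship indices) and the friend-match behavior block (accuracy, RT, d′,
β) are standardized and the first canonical pair extracted; loadings are
structure correlations, and the global sign is fixed so the accuracy
loading is nonnegative (larger canonical scores mean better performance).
Pearson-based estimation is the default. Significance comes from permuting
the rows of one block, $p = (\#\{\rho_\mathrm{perm} \ge \rho_\mathrm{obs}\}
+ 1)/(n_\mathrm{perm} + 1)$. Incomplete trait rows are dropped listwise.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against known ground truth without any data download. Its defaults encode
the study conditions: 110 trials in each of the six label × match cells, a
100 ms stimulus, responses within 1100 ms, 900–1700 ms fixation jitter and
500 ms feedback. Decision data are simulated forward by Euler–Maruyama at
1 ms steps with unit diffusion; the discrete-barrier crossing test is given
the Broadie–Glasserman–Kou continuity correction (barriers shifted inward
by $0.5826\sqrt{dt}$), which removes the leading $O(\sqrt{dt})$ absorption
bias so simulated choice fractions match the analytic absorption
probability to Monte-Carlo precision. Trials undecided at the deadline are
"slow" (no response); a 5% contaminant fraction with uniform RTs mirrors
the fitting mixture.

Cohort truths place the prioritized label's match drift 0.8 (the default
effect size) above the non-prioritized one with 0.1 between-subject sd, and
the stranger drift lowest; boundaries near 1.5, starting points near 0.5
(with a small self-ward bias in SP subjects), and non-decision times of
0.25/0.29 s produce accuracies around 75–97% and mean RTs around 550–650
ms, the realistic operating range of this task. The defining drift
inequality of each group is enforced at draw time, so generated truths are
never mislabelled.

EEG epochs are phenomenological: Gaussian-bump component templates on their
electrode clusters, plus an 8–18 Hz amplitude-modulated sinusoid with
per-trial random phase (hence non-phase-locked: it cancels in the ERP
average but survives in induced power) whose single-trial amplitude decays
exponentially with the trial's condition drift when the coupling gain is
positive, and white (optionally 1/f) Gaussian noise. Epochs are synthesized
on $-500$ to $+800$ ms so the time-frequency baseline exists. What the
generator does **not** emulate: volume conduction and realistic head
geometry, ocular or muscle artifact morphology (rejection is exercised with
planted threshold violations), latency jitter or amplitude covariation
between components, and 1/f-plus-oscillation spectra unless requested.
Passing tests therefore validate the analysis chain's correctness, not its
robustness to every pathology of real recordings.

Trait and game tables share a latent interpersonal factor whose correlation
with each subject's friend-priority magnitude is calibrated so the
population canonical correlation against a well-measured friend-priority
criterion equals the requested value; empathic concern, closeness and
likability carry the largest loadings, and game contributions respect the
endowments (0–10 for the trust game, 0–80 for the public-goods game).
Within-subject trial-to-trial drift variability is exposed as a parameter
and defaults to 0, since no value for it is established for this task.

## Problem sizes and numerical choices

The package's test suite and the acceptance script run everything at
desk scale, which the package treats as its default study conditions for
verification: density-vs-simulation checks on a 9-point parameter grid with
$10^6$ Euler trials; drift-contrast recovery with 20 subjects × 110
trials/condition at 2000 MCMC samples; model recovery with 12 subjects × 10
trials/condition across all 15 pooled candidates, 10 replicates; type-I
error of the cluster test over 200 null datasets of 20 subjects × 30
channels × 200 samples at 1000 permutations; CCA calibration over 200 null
replicates and a planted-factor recovery at n = 400. Tolerances follow the
sampling error of each design (e.g. ±0.03 on a planted ERD of −0.30,
±0.1 on a planted canonical correlation of 0.6).

Other numerical conventions: Wiener series tolerance $10^{-7}$; slice
sampler stepping-out width 0.3–0.5 per parameter scale with shrinkage
capped at 100 iterations; ERS/ERD errors if the baseline overlaps
edge-invalid samples; peak-latency ties resolve to the earliest sample and
flat windows warn; permutation p-values are never zero by the $+1$
convention. Known limitations: no inter-trial variability parameters
($s_v, s_z, s_t$) in the decision model, mass-univariate cluster statistics
only (no TFCE), only the first canonical pair, and ICA-based artifact
removal is out of scope — threshold rejection is the only artifact defense.
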