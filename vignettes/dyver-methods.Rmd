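---
title: "Mapping dynamic genetic effects on expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dynamic genetic effects on expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyver)
```

## The problem

In a panel of homozygous inbred strains (e.g. yeast segregants or mouse
recombinant inbreds), a genetic variant may modulate a gene's expression
only during part of a stimulation time course: a sustained switch to a new
level, a transient pulse, or a more complex multi-pulse profile. Standard
eQTL mapping either tests each time point separately (losing power and any
notion of dynamics) or collapses the time course (losing timing entirely).
`dyver` maps such variants and, for every association, reports *when* the
variant acts, as a sequence of high-effect (`H`) and low-effect (`L`)
states over the measured time points.

## Model

Expression is first made comparable across time: within every
(gene, time point, allele group) cell the log expression is rescaled to
unit sample variance with its mean untouched (`stabilize_variance()`).
The model then works not on expression but on **observed effects**: for a
variant that splits the panel into allele groups $A$ and $B$, every pair
$(i \in A, j \in B)$ observed at time $t$ contributes
$e^t_{ij} = y^t_i - y^t_j$. Differences remove the shared stimulation
response; the collection $D_t$ has $n_A(t)\,n_B(t)$ entries.

A **temporal two-state model** assigns each time point a hidden state
$s_t \in \{H, L\}$. States form a first-order Markov chain with fixed
transition probability $\lambda \in (0, 0.5]$ (the *penalty*; at
$\lambda = 0.5$ every state sequence is equiprobable) and symmetric
initial probability $\pi = 1/2$. Given states, effects are i.i.d.
Gaussian, $e \sim N(\mu_{s_t}, \sigma_{s_t})$, with one $(\mu, \sigma)$
pair per state shared across all time points in that state — so the
parameter count does not grow with the number of time points. Means are
unrestricted in sign, so effect inversions ($\mu_L < 0 < \mu_H$) are
representable. `fit_two_state()` maximises the joint likelihood
(sequence prior times emissions) by Baum–Welch EM with $\lambda$ held
fixed, Viterbi-decodes the hidden sequence, refits the Gaussian
parameters in closed form given that sequence, and labels as `H` the
state of larger $|\mu|$.

The association statistic (**DyVER score**) is a log-likelihood ratio.
The background sample $B_t$ collects differences between strains carrying
the *same* allele; under the null the variant has no effect and one model
suffices for $D \cup B$, while under the alternative $D$ and $B$ are
modelled separately:

$$\log \Lambda \;=\; \ell^*(D) + \ell^*(B) - \ell^*(D \cup B).$$

Significance comes from permuting strain genotype labels and recomputing
everything (stabilisation included); the empirical p-value uses add-one
smoothing, $p = (1 + \#\{\Lambda_{perm} \ge \Lambda\})/(1 + n_{perm})$,
so it is never exactly zero. Multiple testing follows the chain:
Bonferroni over variants within a gene, Benjamini–Hochberg over genes
(default FDR 6%), and a second Benjamini–Hochberg pass (default 15%) on
the post-hoc **dynamic association score** — a Welch t-test comparing
effects pooled over `H` versus `L` time points, defined only when both
states occur.

Because every quantity is computed per time point, strains may differ
across time points: missing measurements simply drop pairs, and a time
point is dropped for a variant when either allele group has fewer than
two observed strains (a variant with fewer than two retained time points
is untestable). No imputation is performed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.5 | state-transition probability; smaller values penalise switches. 0.5 reproduces the unpenalised scan used for unbiased biological analysis |
| `pi` | 0.5 | initial H-state probability; symmetric so that at `lambda = 0.5` all sequences are equiprobable |
| `n_perm` | 999 | permutations per gene; the smallest attainable p is `1/(n_perm+1)` |
| `tol`, `max_iter` | 1e-8, 500 | EM stopping rule on the marginal log-likelihood gain |
| `sigma_floor` | 1e-6 | lower bound on emission standard deviations (prevents zero-variance collapse on degenerate samples) |
| `q`, `q_dynamic` | 0.06, 0.15 | FDR levels of the two gene-level stages |
| `cis_window_kb` | 50 | cis/trans boundary for module building, a conventional yeast-scale window |

`perm_variants = "top"` (default) computes the permutation p-value for the
top-scoring variant only — the score itself ranks variants, so this
reproduces the min-p-then-Bonferroni protocol at a fraction of the cost.
`perm_variants = "all"` shares each permutation across all variants and
additionally reports `fw_p`, an empirical familywise p-value based on the
permutation distribution of the maximum score over variants; it is
calibrated for gene-level selection without Bonferroni and is what
`benchmark_methods()` uses for accuracy curves.

## Numerical choices

Within a time point the emission likelihood depends on the effect sample
only through its size, sum and sum of squares, so the compiled core runs
forward–backward over per-time-point sufficient statistics: cost per EM
iteration is O(T) regardless of panel size, which is what makes
999-permutation scans over 100 variants routine. EM is initialised
deterministically and low-effect-like: both states start at the pooled
standard deviation, with means at the pooled mean ± half that standard
deviation. `restarts = N` adds random initialisations (means drawn around
the pooled mean, standard deviations scaled by 0.25–2) and keeps the best
joint likelihood. Viterbi ties prefer the lower-indexed state; exact
$|\mu|$ ties in labelling are broken by the larger $\sigma$, then by
state order, so patterns are reproducible. An exhaustive-enumeration
optimiser (`enumerate_ml_oracle()`, closed-form Gaussian MLE for each of
the $2^T$ sequences, refused for $T > 12$) serves as an independent
correctness oracle in the test suite.

## What the synthetic generators emulate

`sim_genotypes()` draws a 50-strain × 100-variant panel of fair biallelic
homozygous genotypes without linkage. `sim_collection()` builds a
collection of 500 genes, 300 of which are associated with one uniformly
chosen variant: allele-A strains express $N(\mu(t), \sigma)$ and allele-B
strains $N(0, \sigma)$, so the expected observed effect traces the
waveform $\mu(t)$. Waveforms cover a sustained sigmoid
($q = v = 0.5$, rising through $h/2$ at the midpoint), an impulse
(product of two sigmoids, duration $l$, default $T/3$, normalised so the
peak equals the effect size $h$, and placed so that exactly $l$ grid
points exceed $h/2$), a complex pattern (two back-to-back impulses of
$T/2$ points each), and a linear ramp. The truth pattern thresholds
$\mu(t)$ at $h/2$. `sim_markov_collection()` instead samples each gene's
truth path from the model's own Markov prior and emits state-conditional
Gaussian expression — the dataset used to measure pattern error rates.
`apply_missingness()` drops k% of strains independently at each time
point. Effect sizes run over 0.125–1 against noise $\sigma = 1$; the full
8 × 9 grid of effect sizes and time-point counts (72 collections) is one
`sim_grid()` call.

Two deliberate design choices matter when reading results. First,
expression noise is simulated at **strain level** with $\sigma = 1$
(per-pair effects are then correlated through their shared strains), and
the variance stabilisation pins the within-allele spread to 1, so the
per-time-point mean observed effect carries a standard error of
$\sqrt{1/n_A + 1/n_B} \approx 0.28$ at a 50-strain panel. That scale —
not the nominal $\sigma$ — is what limits how finely state transitions
can be timed, and it makes small effect sizes (and short impulses)
substantially harder than the same nominal sizes would be under
independent pair-level noise. Second, because the emission likelihood
weights all $n_A n_B$ pairs, the data term at panel scale is orders of
magnitude larger than the transition penalty; the penalty then changes
fitted paths only for time points whose mean effect sits almost exactly
between the two state means, and pattern error rates respond only weakly
(in the limit, not at all) to $\lambda$. Both properties are inherent to
the stated simulation conditions and are visible in the acceptance
numbers; they do not affect the relative ordering of variants within a
gene, the calibration of permutation p-values, or the recovery of
co-association modules, which is what the end-to-end tests check. The
generators emulate no linkage disequilibrium, no strain-specific baseline
offsets, no heteroscedastic measurement error and no shared stimulation
profile, so passing tests speak to the statistical machinery, not to
robustness against those real-data complications.

## Evaluation metrics

Predictions are scored variant-aware: a true positive requires the
*correct* variant to be significant; an associated gene mapped
significantly to a wrong variant counts as a false positive. Accuracy is
the trapezoidal area under sensitivity versus 1 − specificity swept over
200 log-spaced thresholds in $[10^{-6}, 1]$: ~0 for random prediction
(random variants are almost never the correct one), 1 for perfect. The
two-state pattern error rate is the fraction of wrong fitted patterns
among significant correct-variant calls — stringent (exact string match)
or flexible (equal after collapsing consecutive repeats, i.e. correct
state order, timing free). Baselines: per-time-point one-way ANOVA with
the minimum p over time points; PCA projection on the first principal
component followed by ANOVA (complete strains only); an
expression-dynamics F-test of per-genotype intercept and slope against a
shared line; and a random predictor.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full pipeline at
reduced scale, chosen so the whole suite completes in minutes on one
core: 150 associated genes and 999 permutations for the error-rate
dataset, 100 associated genes for the impulse sensitivity runs, 500
single-variant genes with 199 permutations for null calibration, 200
fits × 100 restarts for initialisation robustness, and 5 replicate
40-gene collections per waveform for the method comparison. Significance
at "cutoff 0.001" is realised as a permutation p of exactly
$1/(999+1)$ — the finest level 999 permutations support, equivalent to
Bonferroni-corrected 0.1 over 100 variants.

## Known limitations

* Two states only; no time-varying penalty; first-order Markov dependence.
* Homozygous biallelic panels only — no heterozygotes, no multi-allelic
  markers, no kinship/relatedness correction, no covariates.
* The top-variant permutation shortcut reports a per-variant p for the
  selected variant; for genome-wide null genes that p is selection-biased
  (use `perm_variants = "all"` and `fw_p` when calibrated gene-level
  error control matters).
* Cataloguing treats each marker as its own locus; adjacent markers are
  not merged into intervals unless requested.
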