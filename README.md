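# dyver

Mapping genetic variants that control **time-course** gene expression in
panels of homozygous inbred strains — and classifying *when* each variant
acts.

Classical eQTL mapping treats expression as a static trait. In a
stimulation time course, however, a variant may act only transiently (an
impulse), switch on at a particular time and stay (sustained), or show
more complex dynamics. `dyver` detects such associations and reports the
temporal effect pattern of each as a sequence of high-effect (`H`) and
low-effect (`L`) states over the measured time points. It is aimed at
statistical geneticists and computational biologists working with
segregant/recombinant-inbred panels (e.g. yeast crosses, mouse BXD lines)
profiled over time.

## The method in brief

For a gene and a variant splitting the panel into allele groups $A$/$B$,
the **observed effects** at time $t$ are all cross-allele differences
$e^t_{ij} = y^t_i - y^t_j$, $i \in A$, $j \in B$, computed after the log
expression of each (time point, allele) cell is rescaled to unit variance
(means preserved). A **temporal two-state model** is a hidden Markov
model over time points with states $\{H, L\}$, fixed transition
probability $\lambda \in (0, 0.5]$ (the *penalty*; $\lambda = 0.5$ leaves
sequences unpenalised) and Gaussian emissions $N(\mu_s, \sigma_s)$ shared
across all time points in state $s$. Fitting is Baum–Welch EM plus
Viterbi decoding (an exhaustive-enumeration oracle backs it in the
tests). The association statistic is the **DyVER score**

$$\log \Lambda = \ell^*(D) + \ell^*(B) - \ell^*(D \cup B),$$

where $B$ collects *same-allele* differences (the empirical null) and
$\ell^*$ is the maximised two-state log-likelihood. Significance comes
from strain-label permutation; multiple testing is Bonferroni over
variants, then Benjamini–Hochberg over genes, with a post-hoc Welch
t-test of `H` versus `L` effects (the *dynamic association score*)
flagging genuinely dynamic associations. The package also ships the
companion simulation study (sustained / impulse / complex / linear
waveforms plus Markov-sampled truth paths), the baseline methods
(per-time-point ANOVA, PCA + ANOVA, expression-dynamics F-test, random),
variant-aware accuracy metrics, and post-scan cataloguing into pattern
groups and co-association modules.

## Worked example

```r
library(dyver)
set.seed(42)

# 20 genes (12 associated) on a 50-strain x 50-variant panel, sustained
# effect of size 1 over 9 time points, noise sd 1
sim  <- sim_collection("sustained", n_time = 9, effect_size = 1,
                       n_genes = 20, n_assoc = 12,
                       n_strains = 50, n_variants = 50)
scan <- dyver_scan(sim$expr, sim$geno, lambda = 0.5, n_perm = 999)
dplyr::select(scan, gene, variant, dyver_score, perm_p, bonf_p,
              pattern, dynamic_p)
#> # A tibble: 20 x 7
#>   gene  variant dyver_score perm_p bonf_p pattern   dynamic_p
#>   <chr> <chr>         <dbl>  <dbl>  <dbl> <chr>         <dbl>
#> 1 g0001 v026           397.  0.001   0.05 LHLLHHLHH  3.14e-42
#> 2 g0002 v021           302.  0.001   0.05 LLLHHHHHH  5.56e-67
#> 3 g0003 v044           393.  0.001   0.05 LLLLLHHHH  3.46e-52
#> 4 g0004 v014           382.  0.001   0.05 LLLHHHHHH  4.24e-85
#> 5 g0005 v041           174.  0.002   0.1  LLLHHHHHH  4.95e-47
#> 6 g0006 v043           215.  0.001   0.05 LHLLHHLHL  1.36e-53
#> # i 14 more rows

eval_confusion(scan, sim$truth, alpha = 0.1)
#> # A tibble: 1 x 7
#>   alpha    tp    tn    fp    fn sensitivity specificity
#>   <dbl> <int> <int> <int> <int>       <dbl>       <dbl>
#> 1   0.1    10     8     0     2       0.833           1
```

Reading the output: each row is a gene's best variant. `dyver_score` is
the log-likelihood ratio, `perm_p` its add-one-smoothed permutation
p-value (0.001 means the observed score beat all 999 permutations),
`bonf_p` the variant-corrected p, `pattern` the fitted state string —
`LLLHHHHHH` says the effect switches on at the fourth time point — and
`dynamic_p` the H-versus-L Welch test. Here the scan recovers the true
variant for 11 of the 12 associated genes; at threshold 0.1 it makes 10
correct significant calls (variant-aware sensitivity 0.83) and no false
positives. `autoplot(scan)`, `autoplot(fit)` and
`plot_variant_scores(scan, gene)` give Manhattan-style and state-path
views; `tidy()`/`glance()` return tibbles.

A thin command-line wrapper with `simulate`, `scan`, `benchmark` and
`catalogue` subcommands is installed at `inst/cli/dyver.R`.

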