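# dbnpanel

Discrete dynamic Bayesian networks (DBNs) for longitudinal categorical
panel data: the kind of multi-wave cohort survey used to study child
undernutrition, where an 8-state nutrition outcome, household covariates
and programme-participation indicators are recorded for a few thousand
children over five survey rounds, with late-entering variables and
missing cells everywhere.

The package is aimed at epidemiologists and biostatisticians who want the
whole DBN workflow — structure learning, parameter learning with missing
data, exact inference, and causal "what-if" queries — as scriptable,
testable R functions rather than a GUI tool.

## The model

A DBN is a template graph over `(variable, lag)` pairs with lag-0
(within-wave) and lag-1/lag-2 (between-wave) arcs. Unrolled over `T`
waves it is an ordinary acyclic network factorising as

    P(X_0..X_{T-1}) = prod_t prod_i P(X_{t,i} | Pa(X_{t,i}))

with one conditional probability table per variable: a shared,
time-homogeneous transition table wherever all template parents exist,
and wave-specific initial tables where they do not (first waves, or
variables that enter the panel late). On top of this representation the
package provides:

* **Exact inference** by sum-product variable elimination (min-fill
  order): posterior marginals, smoothing across waves, soft evidence,
  per-record log-likelihood, missing-cell posteriors and anomaly scores.
* **Parameter learning**: maximum likelihood with pseudocounts
  (`fit_mle`) and EM for records with missing cells (`fit_em`), with a
  provably non-decreasing objective trace.
* **Structure learning**: the PC algorithm with G² conditional
  independence tests under temporal tiering, expert forbid/require
  constraints, v-structure + Meek orientation, and a BIC diagnostic;
  `count_graph_structures(13)` reports the 2^78 search space that makes
  exhaustive search hopeless.
* **Causal queries**: marginal-MAP / MPE with top-k (`map_query`),
  do-operator surgery (`intervene`, `counterfactual_query`), best-/
  worst-case scenario reports with direction flags
  (`scenario_analysis`), and per-arc pathway strengths.
* **Information metrics**: entropy, mutual information, target-entropy
  reduction, feature ranking and value of information (bits).
* **A seeded synthetic cohort generator** (`sample_cohort`) emulating a
  five-wave child-nutrition panel — 14 variables, 8-state target,
  8-category programme indicator entering at wave 2, MCAR/MAR
  missingness — so the entire pipeline is testable without any data
  download.
* **An end-to-end pipeline** (`run_pipeline`) and a CLI
  (`inst/scripts/dbnpanel.R`) producing delimited-text reports and a
  manifest that reproduces the run byte-for-byte.

## Worked example

```r
library(dbnpanel)

# a seeded synthetic cohort: 1999 children, 5 waves, 10% missing cells
bundle <- sample_cohort(cohort_config(n_subjects = 1999, seed = 1, missing_rate = 0.1))
bundle
#> Synthetic cohort: 1999 subjects, strong effects, 13201 masked cells

# EM parameter learning on the generating structure
fit <- fit_em(bundle$network$structure, bundle$data, pseudocount = 1,
              max_iter = 10, restarts = 0)
fit
#> dbn_fit (em): loglik -60991.96, 8 iteration(s), converged

# posterior of the nutrition target given wave-4 evidence
g <- unroll(fit$network)
posterior(g, list(`FS@4` = "Secure", `WQ@4` = "Wealthy"), "CNS@4")
#> Posterior report; log P(evidence) = -2.017684
#>   CNS@4 : N=0.6770 U=0.0385 S=0.0541 W=0.0492 US=0.0511 UW=0.0520 SW=0.0337 USW=0.0443

# best-case scenario: clamp the target to "N" at every wave and watch the
# upstream drivers move against the evidence-free baseline
best <- scenario_analysis(fit$network, "CNS", "best", c("FS", "WQ", "MSW"))
subset(best$table, state %in% c("Secure", "Wealthy", "High") & wave == 4)
#>  node wave   state  baseline predicted      delta flag
#>    FS    4  Secure 0.4335953 0.8058377 0.37224237    +
#>    WQ    4 Wealthy 0.1865754 0.5767025 0.39012711    +
#>   MSW    4    High 0.3922352 0.4435785 0.05134329    +

# pathway strengths along programmes -> wealth -> nutrition
pathway_strength(fit$network, c("PS", "WQ", "CNS"))
#>  parent child lag wave parent_map_state  strength
#>      PS    WQ   0    2                C 0.8800843
#>      PS    WQ   0    3                C 0.9085763
#>      PS    WQ   0    4                C 0.9151597
#>      WQ   CNS   0    0             Poor 0.4016674
#>      ...
```

Reading the numbers: with food security and wealth observed favourable at
the last wave, the model puts 67.7% on the normal nutrition state; under
the best-case clamp the probability of a food-secure household at wave 4
rises by 37 percentage points over baseline (flag `+`), and the
maternal-well-being shift is smaller because its link to the target runs
through the programme indicator. Pathway strengths use a declared
max-conditional convention (see the methods vignette) — they are not the
undocumented "edge probabilities" of proprietary tools.

The full workflow (simulate → rank features → PC structure learning → EM →
anomaly screen → scenarios → pathways, with a reproducibility manifest):

```r
run_pipeline(pipeline_config(out_dir = "run1",
                             synthetic = cohort_config(n_subjects = 2000, seed = 7),
                             seed = 42))
```

or from the shell:

```sh
Rscript inst/scripts/dbnpanel.R pipeline --n 2000 --seed 42 --out run1
```

## Documentation

`vignettes/dbn-methods.Rmd` describes the model and its assumptions, the
numerical choices (scaled-linear factors, elimination orders, tie-breaks),
the EM plan compiler, the PC determinism conventions, what the synthetic
cohort does and does not emulate, and known limitations.
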