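---
title: "Discrete dynamic Bayesian networks for categorical panel data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete dynamic Bayesian networks for categorical panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnpanel)
```

## The model

`dbnpanel` works with discrete dynamic Bayesian networks (DBNs) over
longitudinal categorical panel data: a roster of categorical variables
observed for each subject at a small number of survey waves. A DBN is a
template graph over `(variable, lag)` pairs. Lag-0 arcs act within a wave;
lag-1 and lag-2 arcs connect a parent at wave $t-\ell$ to a child at wave
$t$. The joint distribution of the unrolled model factorises as

$$P(X_{0:T-1}) = \prod_{t}\prod_{i} P\!\left(X_{t,i} \mid \mathrm{Pa}(X_{t,i})\right),$$

with one conditional probability table (CPT) per variable. Transition
tables are **time-homogeneous**: a single table governs every wave at which
all of the variable's template parents exist. Waves at which some parents
are not yet available (lagged parents at the first waves, or parents that
enter the panel late) are governed by wave-specific *initial* tables whose
parent slots are exactly the available subset of the template slots.

Two representation choices matter downstream:

* **Structural absence, not placeholder states.** A variable that enters
  the panel late (a programme-participation indicator recorded only from
  wave 2, say) is represented by a `first_wave` attribute. Its ground
  nodes simply do not exist before that wave. The alternative — a fake
  "zero" state padding the early waves — would contaminate every learned
  distribution that conditions on the variable.
* **Waves are 0-indexed** internally so that lag arithmetic is exact;
  reports print wave indices as given.

## Exact inference

All queries run on the unrolled ground network (at the package's scale, at
most 66 nodes with at most 8 states) by sum-product variable elimination
with a min-fill elimination order; ties in the min-fill score are broken
lexicographically so that every computation is deterministic. Evidence may
be *hard* (a state) or *soft* (a likelihood vector over states). Posterior
marginals are computed with one elimination per query node: keeping many
query nodes uneliminated in a single run can square the intermediate
factor sizes, while per-node runs keep every intermediate factor small.

Smoothing is automatic: evidence at later waves influences earlier-wave
queries, which is precisely how missing panel cells are treated.
`impute()` returns a *posterior distribution* for every missing cell, not
a filled-in value; `record_loglik()` marginalises missing cells, and
`anomaly_scores()` flags subjects whose negative log-likelihood lies
strictly above the `1 - q` empirical quantile. The flagging rule is a
declared convention — the proprietary tool the field often uses does not
document its anomaly threshold — and with strictly-above semantics a
constant-score dataset flags nobody.

**Numerics.** Factors are kept in scaled linear space: each factor carries
a log-scale offset and values are renormalised after every product. This
gives the same underflow protection as elementwise log-space with
log-sum-exp (the design alternative), is exact for structural zeros, and
is several times faster; the log-scale offsets accumulate into
log-evidence without ever exponentiating small numbers. Evidence whose
probability falls below `1e-300` raises a classed `dbn_impossible_evidence`
condition; because scaling removes ordinary underflow, that signal fires
only on genuinely contradictory evidence.

## Parameter learning

`fit_mle()` estimates each CPT row as
$(\text{count} + c)/(\text{total} + c k)$ with pseudocount $c$ (default
$c = 1$, a uniform Dirichlet prior). The default is deliberate: with an
8-state target and a few thousand subjects, empty rows are certain, and an
unsmoothed table makes every downstream log-likelihood degenerate. With
$c = 0$ an unseen row is left uniform with a warning, never 0/0.

`fit_em()` handles missing cells. Records are deduplicated; for each
unique record the missing cells are split into connected components given
the observed cells, and each component's joint posterior is an exact
renormalised product of the reduced family tables. These products are
precompiled into integer index plans, so an EM iteration is a sequence of
vectorised gathers — this is what makes EM at 50,000 subjects practical in
pure R. Components whose joint state space exceeds 4,096 cells fall back
to generic variable elimination.

With a positive pseudocount EM ascends the *penalised* likelihood
$\log P(D \mid \theta) + c \sum \log \theta$; `objective_trace` records
that objective (guaranteed non-decreasing), `loglik_trace` the data term.
Iteration stops when the objective gain drops below `tol`; hitting
`max_iter` flags the report as non-converged rather than raising. The
returned tables are those at which the reported log-likelihood was
evaluated, so `loglik` always equals `dataset_loglik(network, data)` — a
reporting convention chosen over "one more M-step" because it keeps the
report internally consistent. Initialisation uses available-case counts,
which under MCAR are already consistent, so few iterations are needed;
`restarts` adds seed-controlled random restarts for multimodal problems.

## Structure learning

`pc_learn()` implements the PC algorithm under temporal tiering: nodes are
`(variable, lag)` pairs, inter-slice candidates default to self-lags
($V_{t-\ell} \to V_t$), and every inter-slice edge is oriented past to
present. The conditional-independence test is the G² likelihood ratio with
a chi-square reference — the standard choice for categorical PC — with
degrees of freedom $(|X|-1)(|Y|-1)$ per non-empty stratum and a
reliability guard: tests with fewer than `5 * df` complete cases are
treated as independent and logged as unreliable. Edge visits and
conditioning-set enumeration follow lexicographic order, which makes the
(classically order-dependent) algorithm deterministic.

Orientation proceeds by v-structures, then Meek propagation rules, then a
deterministic fallback for residual undirected lag-0 edges: orient from
the higher causal tier to the lower (interventions upstream of household
conditions, upstream of parental covariates, upstream of child-level
outcomes), ties by name. The tier list mirrors the node categories of the
motivating application. We orient *downstream* along this hierarchy —
interventions into household conditions into the child-level target —
because that is the substantive causal reading of the tiers; fallback
orientations are tagged `"fallback"` in the output so that test-driven and
convention-driven arrows are never confused. Forbidden directions flip the
fallback; a forbidden direction demanded by a v-structure or Meek rule is
logged as a conflict and skipped (constraints win).

Expert constraints are directed arcs: a required arc is never removed (a
test verdict of independence on it is logged as a conflict), a forbidden
arc never appears; a lag-0 edge is removed from the candidate set only
when both directions are forbidden.

`bic_score()` is provided as a score-based diagnostic only — the
constraint-based learner is the primary route, and exhaustive score search
is hopeless anyway: `count_graph_structures(13)` reports $2^{78}$ candidate
skeletons (the count is returned both as a double, exact for powers of
two, and as an exact decimal string).

**Finite-sample behaviour worth knowing.** On the synthetic cohort, PC at
$\alpha = 0.01$ reliably keeps the arcs whose conditional effects are
large under any small conditioning set, but can drop arcs into co-parents
of the 8-state target: conditioning on the target (a collider) induces a
dependence of opposite sign that partially cancels the direct effect, and
the 8-category programme variable dilutes the G² degrees of freedom. This
is a property of the algorithm at these effect sizes, not a bug; the test
suite asserts recovery of the robustly identifiable subset.

## Causal and MAP queries

`map_query()` computes marginal MAP: nuisance nodes are summed out first
(min-fill), then query nodes are max-eliminated in reverse lexicographic
order with traceback, which makes the lexicographically first assignment
win under exact ties. Full MPE is the special case where the query is
every non-evidence node. Top-k enumeration re-solves subproblems with
fixed prefixes and per-variable state exclusions (Lawler partitioning), so
the k best assignments arrive in exactly descending probability.
Max-product elimination with traceback replaces the proprietary
"relevance tree" of the motivating workflow; its correctness is
established against exhaustive enumeration, not against that tool.

`intervene()` performs do-operator graph surgery — incoming arcs severed,
the table replaced by a point mass (truncated factorisation) — and
`counterfactual_query()` composes surgery with inference. Surgery is
idempotent and never mutates its input.

`scenario_analysis()` reproduces the best-/worst-case pattern of the
motivating analysis. *Best* clamps the target to its designated normal
state by hard evidence at every wave where the target exists. *Worst*
applies soft evidence with zero likelihood on the normal state and uniform
likelihood over the remaining states: the paper-style "undernourished =
100%" pooling does not say how mass is distributed among the pooled
states, and a uniform likelihood preserves their relative priors (the
least-informative choice; it is configurable through the custom mode).
*Custom* clamps specify the desired per-wave target distribution and are
realised as likelihood `clamp / baseline`, so clamping a wave to its own
baseline marginal is an exact no-op — a useful self-check that the spec of
the scenario machinery satisfies by construction. Evidential clamping is
the default mode (a `"do"` mode exists for hard clamps) because in the
motivating tables the upstream covariates *do* change under the clamp,
which only evidential conditioning produces. Reports carry per-cell deltas
against the evidence-free baseline with `+`/`-` direction flags (deltas
within `1e-12` of zero are flagged `0`).

`pathway_strength()` reports, for each arc $A \to B$ along a declared
chain and each wave, $\max_b P(B = b \mid A = a^\ast, E)$ with $a^\ast$
the MAP state of $A$ under the evidence. This *max-conditional convention
is a declared stand-in*: published "edge probabilities" from proprietary
tools have undocumented semantics, and no attempt is made to imitate them.
A deterministic copy arc scores 1; an independent child scores $1/|B|$.

## Information metrics

Entropy and mutual information are in bits. `rank_features()` sorts
candidates by MI with the target (ties by entropy reduction, then name)
and flags those at or above a threshold, emulating a
many-covariates-to-few screen. For the pairwise definitions used
throughout, MI equals the target-entropy reduction and the residual equals
marginal entropy minus reduction; the package asserts these identities.
Published node-ranking tables in this domain sometimes print "mutual
information" values that exceed the listed target entropy — impossible
under the standard pairwise definitions, evidently a normalised or
otherwise redefined metric. The package implements the standard
definitions and does not imitate those numbers. Empirical joints use a
0.5-per-cell pseudocount to avoid `log 0`; `value_of_information()` is the
expected posterior-entropy reduction from observing a candidate node,
clipped to zero at `-1e-12`.

## The synthetic cohort: what it emulates and what it does not

The raw panel behind the motivating study is not redistributable, so the
package ships a generator whose defaults state the emulated world: 1,999
subjects, five waves, a 14-variable roster — an 8-state nutrition target
(normal plus all single and combined undernutrition conditions), an
8-category programme-participation variable entering at wave 2, food
security entering at wave 2, binarised household and parental covariates,
three-band ages, and a non-temporal child sex. Tables come from a
logistic-contrast recipe: a base distribution tilted per parent
configuration, with contrast scaled by `effect_strength`
(weak/moderate/strong = 0.25/0.6/1.0 on the logit scale). The base
nutrition mix uses the published baseline category frequencies; everything
else is a plausibility choice, fixed once. The generating arcs follow the
described pathway structure (programmes raise well-being, wealth and food
security; wealth and food security with parental education drive
nutrition; self-lags everywhere; child age advances deterministically
through its bands using lag-1 *and* lag-2 parents), and the
expert-implausible arcs are absent. Missingness is MCAR by default, or MAR
driven only by the always-observed child sex and the wave index — which
keeps EM's ignorability assumption valid by construction.

Known artifacts, accepted deliberately:

* **Child sex is resampled per wave.** The model declares CS non-temporal
  (no lagged arcs), and the generator samples exactly from the model, so
  CS draws are independent across waves rather than constant per subject.
  Making them constant would sample from a different model than the one
  the learners assume. Consequence: nothing in the pipeline may rely on
  within-subject sex constancy, and none does.
* **Equal wave spacing.** Waves are indices; the unequal calendar gaps of
  real panels are not modelled.
* No attrition, no survey design (regions, sentinels), no informative
  missingness beyond the declared MAR mechanism.

A green test on this cohort therefore establishes that the *algorithms*
are correct and that the *pipeline* recovers a known world of realistic
shape — not that any substantive conclusion about real nutrition data is
reproduced.

## Scale choices in the test suite

Acceptance criteria run at their stated sizes (50 random networks against
enumeration, MAP on 30 instances, parameter recovery at n = 50,000, PC
motifs at n = 20,000, the full pipeline at n = 2,000 with byte-identical
reproduction from its manifest). Two module-level property tests are
scaled down with the reasoning recorded in the test file: the cohort-wide
EM recovery runs at n = 6,000 with the 0.03 bound asserted on table rows
with at least 1,500 expected observations (a blanket max over the
1,024-cell target transition table is not statistically attainable even at
n = 50,000), and the cohort PC recovery asserts the robustly identifiable
arc subset discussed above.

## Limitations

Only categorical nodes (the motivating workflow quantises everything);
only time-homogeneous transition tables; no approximate inference (not
needed at this scale); population-level interventional and evidential
queries only — no unit-level twin-network counterfactuals. The CLI wraps
the same functions the tests exercise; it adds no semantics of its own.
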