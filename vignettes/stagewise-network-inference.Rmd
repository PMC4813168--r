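---
title: "Stagewise protein interaction network inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stagewise protein interaction network inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

## The problem

Blood transcriptomes sampled at successive clinical stages of a disease —
here the motivating setting is early cardioembolic stroke, with a control
stage and three post-onset time points — carry information not only about
which genes change level, but about how the *interactions* among proteins
rewire as the disease progresses. stagenet reconstructs a weighted, directed
protein–protein interaction network (PPIN) per stage from an expression
matrix and a list of candidate interactions, then compares consecutive
stages at two granularities: networks of enriched functions, and core
networks of the proteins that dominate the network's principal structure.

Candidate interaction lists mined from interaction databases are
deliberately permissive: they pool heterogeneous experimental and predicted
evidence and therefore contain many pairs that are not active in the tissue
and condition at hand. The central statistical task is to prune this
candidate set against the expression data, stage by stage.

## The protein interaction model

For target protein $i$ in sample $m$,

$$y_i(m) = \sum_{k=1}^{P} \alpha_{ik}\, y_k(m) + \beta_i + \epsilon_i(m),$$

where $y_k(m)$ is the level of protein $k$, $\alpha_{ik}$ is the
*interaction activity* of $k$ on $i$ ($\alpha_{ik}=0$ when $\{i,k\}$ is not
a candidate pair, and $\alpha_{ii}=0$: no self-regulation), $\beta_i \ge 0$
is the protein's *basal level*, and $\epsilon_i(m)$ is stochastic noise.
Stacking the $M$ samples gives the regression form
$y_i = \Phi_i \theta_i + \epsilon_i$ with
$\theta_i = (\alpha_{i1},\dots,\alpha_{iP},\beta_i)^\top$, estimated by

$$\min_{\theta_i} \lVert \Phi_i\theta_i - y_i\rVert_2^2
  \quad\text{s.t.}\quad \beta_i \ge 0 .$$

Because $\beta_i$ is the only constrained coordinate, the active-set method
for this quadratic program collapses to two phases
(`fit_constrained_lsq()`): solve the unconstrained least-squares problem;
if the fitted intercept is negative the constraint is active at the
optimum, so refit with $\beta_i = 0$. This is exact, not an approximation.
Rank-deficient designs return the minimum-norm solution with a warning.

### Model-order detection

The number of true interactors of protein $i$ among its candidates (the
model order $L$) is selected by minimising

$$\mathrm{AIC}_i(L) = \log\frac{\lVert \Phi_i\hat\theta_i -
y_i\rVert_2^2}{M} + \frac{2L}{M}$$

with greedy forward selection plus backward elimination
(`stepwise_select()`): at each step the candidate whose inclusion most
decreases the AIC is added; after each addition beyond the first, any
selected candidate whose removal decreases the AIC is eliminated. The
retained coefficients are then tested against $H_0\!: \alpha_{ij} = 0$ with
a two-sided t-test (`prune_by_ttest()`); coefficients with $p \ge 0.05$ are
deleted and the model refitted once on the survivors.

Numerical and procedural choices that the model statement leaves open:

* **Perfect fits.** $\mathrm{AIC}$ is undefined at zero residual; a residual
  sum of squares below `rss_tol` (default $10^{-9}\max(\lVert y\rVert^2,1)$)
  maps to a $-\infty$ sentinel, and ties at $-\infty$ are broken toward the
  *smaller* order, so backward elimination strips superfluous terms from an
  exact fit.
* **Tie-breaking.** Equal AIC decreases resolve to the lexicographically
  smallest interactor id, making every fit deterministic.
* **Order cap.** $L \le M - 2$ so the pruning t-test keeps at least one
  residual degree of freedom. With $M = 23$ samples per stage this caps the
  per-target order at 21 — a real restriction at database-scale candidate
  degrees, and an inherent one for this sample size.
* **Covariance for the t-test.** Standard errors come from the
  unconstrained ordinary-least-squares covariance of the selected design
  with $M - L - 1$ degrees of freedom; only the $\alpha$ coefficients are
  tested, since the constraint binds on $\beta$ alone.
* **Direction.** Candidate pairs are undirected, but the model is
  directional; both orientations of a pair enter their respective target
  models and are estimated independently. Benchmarks therefore score
  recovered support as *undirected* pairs: when a responder's level is an
  exact linear image of its drivers, the inverse regression is an equally
  valid description of the same pair.

### Post-selection inflation (known limitation)

The t-test is calibrated for coefficients in a *given* model: under the
global null, forced-in noise coefficients are retained at the nominal 5%
rate. When the same data first pass through AIC selection, the selected
coefficients have inflated t-statistics, and the per-candidate retention
rate rises with the candidate degree (about 7% at 5 candidates and $M=23$,
and far higher at degrees near the order cap). This bias is intrinsic to
select-then-test procedures; `scripts/acceptance.R` reports both rates
(`ttest_null_retention_rate`, `stepwise_null_retention_rate`) so the gap is
visible rather than hidden.

## Functional networks

Network proteins are grouped by an annotation catalog (any GMT file; the
synthetic generator fabricates one). Functions over-represented among the
network's proteins are found with a one-sided hypergeometric test against
the measured background, Benjamini–Hochberg corrected
(`enrich_functions()`). The enrichment statistic is a configurable
stand-in — the grouping idea, not a specific test, is what matters here —
and a user-supplied enriched-function list bypasses it.

The activity between two enriched functions is the *signed* sum of the
interaction activities between their member proteins
(`functional_network()`); signed summation preserves the up-/down-direction
of stage-to-stage changes. A protein in both functions contributes once per
ordered containment; the brute-force double loop over member pairs is the
tested contract.

## Core networks by principal network projection

The stage network's dense adjacency $N$ ($N_{ik} = \alpha_{ik}$) is
decomposed as $N = U\Sigma V^\top$. The columns of $V$ are
*eigen-interactions*; mode $i$ explains
$r_i = \sigma_i^2 / \sum_j \sigma_j^2 \times 100\%$ of the network, and the
$K$ principal modes are the smallest set with cumulative energy $\ge 85\%$
(the usual principal-component convention). Each protein's interaction row
$(\alpha_{i1},\dots,\alpha_{iP})$ is projected onto those $K$ modes;
its *similarity* is the 2-norm of the projection coefficients, chosen so
that with all modes kept the similarity equals the row norm exactly
(Parseval). The largest absolute single-mode inner product is available as
`method = "max"` where a sharper notion of alignment is wanted. Proteins
with similarity strictly above a threshold (default 6) form the core;
similarities scale linearly with the network weights, so the fixed default
is meaningful only relative to the data scale and is exposed in the
configuration.

Differential networks (`differential_network()`) difference edge weights
between stages over the union of edges (absent edges count as zero) and,
for core/stage networks, difference the basal levels per protein.
Basal-level shifts are the readout used by `flag_regulation_candidates()`:
large-$|\Delta\beta|$ proteins with a known targeting miRNA are candidate
miRNA regulations, the remainder candidate methylation regulations.

Dense SVD is used throughout: the networks this package fits in test and
benchmark settings are a few hundred proteins at most, well inside dense
territory; at several thousand proteins a truncated solver would be the
natural substitution behind the same interface.

## The synthetic-data generator

`generate_truth()` fabricates a ground truth: sparse true activities
$\alpha$, half-normal basal levels ($\beta \ge 0$ by construction), and a
candidate set of the true pairs plus uniformly drawn decoy pairs
(`candidate_excess` times the true edge count), mimicking database false
positives without topology assumptions. `simulate_expression()` closes the
model into a generative law — the only self-consistent joint reading of the
per-protein equations:

$$y(m) = (I - A)^{-1}\left(\beta + \epsilon(m)\right),$$

so every sample satisfies $y = Ay + \beta + \epsilon$ exactly. Activities
are globally rescaled so the spectral radius of $A$ is at most 0.8, keeping
the fixed point well defined with margin.

Two wiring modes serve different purposes:

* **cyclic** (default): every protein receives about `true_degree` incoming
  edges from arbitrary partners; $\epsilon$ (scalar `noise_sd`) is the sole
  source of sample-to-sample variation. This exercises feedback loops and
  is the general-purpose truth for perturbation and aggregation tests.
* **layered**: the first half of the proteins are *drivers* whose levels
  vary exogenously across samples (`signal_sd`, default 1 — the signal
  scale); the second half are *responders*, each with exactly `true_degree`
  incoming edges from drivers and equation noise `noise_sd`. In a cyclic
  network every equation's noise is also every other equation's signal, so
  "noise-free" data would be constant and nothing would be identifiable;
  the layered mode separates the two roles. `noise_sd = 0` then yields
  exactly identifiable noise-free interaction equations (the recovery
  benchmark demands parameter errors below $10^{-6}$), and `noise_sd = 0.1`
  means literally 10% noise relative to unit signal.

`perturb_truth()` derives later-stage truths by removing a fixed fraction
of true edges and shifting a fixed fraction of basal levels (clamped at
zero), leaving the candidate set unchanged — removal rather than rescaling
so that exact set-level bookkeeping holds: the symmetric difference of true
edge sets equals the requested count. `generate_function_catalog()` draws
overlapping memberships with per-protein inclusion probability
`mean_size / P`, so the expected set size is `mean_size` and saturation
(`mean_size = P`) is deterministic; each function carries one of the four
display groups (immune, neuro/hormone, growth/death, general). All
generators are bit-reproducible under a fixed seed.

What the generator does *not* emulate: probe-level effects and array
chemistry, realistic pathway topology (decoys are uniform), heavy-tailed or
correlated noise, and the scale of genome-wide candidate sets. Passing
benchmarks therefore demonstrate correctness of the estimation machinery
under the model's own assumptions, not performance on microarray data.

## Benchmark problem sizes and tunable parameters

The test-suite and acceptance-script benchmarks use: exact recovery at
$P=30$, degree 2, $M=100$ samples, no decoys, `noise_sd = 0`; noisy
recovery at $P=60$, degree 3, decoy ratio 1.0, $M=100$, `noise_sd = 0.1`
(precision and recall of undirected support $\ge 0.8$); stepwise-versus-
exhaustive agreement on 50 targets with 8 near-orthogonal candidates
($2^8$ subsets enumerated per target); pruning calibration over 1,000
global-null replicates at $M=23$, 5 candidates; projection and aggregation
contracts on random networks of 50–100 proteins. These sizes make every
property checkable exactly or by enumeration while each suite runs in
seconds.

Defaults a user may want to revisit: t-test level 0.05 (the pruning
strictness), enrichment FDR 0.05, energy threshold 85% (how much network
structure the core must explain), similarity threshold 6 (scale-dependent;
tune to the desired core size), and `beta_change_min` (units of the
expression scale) for regulation flagging.

## Limitations

Estimated activities are associational: the model is directional but the
data cannot orient a pair, and simultaneity in cyclic truths biases
coefficients at high noise. The $M-2$ order cap binds hard for
database-scale candidate degrees at small $M$. Post-selection inflation of
retained-edge error rates grows with candidate degree (above). Enrichment
and the similarity aggregation rule are explicit conventions, exposed as
configuration rather than fixed claims.
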