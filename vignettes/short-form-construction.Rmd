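---
title: "Calibrating an item pool and constructing a Rasch-conforming short form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an item pool and constructing a Rasch-conforming short form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtforge)
```

## The measurement model

Every function in this package works on binary correctness data from a
forced-choice task with `K` response options, so a child who does not know
the word can still be right by chance. The probability model is therefore
a logistic item response curve with a *fixed* lower asymptote:

$$
\Pr(x_{ij} = 1) \;=\; c + (1 - c)\,
\mathrm{logistic}(a_j\,\theta_i + \beta_j),
$$

where $\theta_i$ is person $i$'s latent ability, $\beta_j$ is item $j$'s
*easiness* (the additive inverse of the conventional difficulty, so larger
means easier), $a_j$ is its discrimination, and $c$ is the guessing floor
— $1/4$ for a four-picture task, and never estimated: with four options
the chance rate is known by design, and freeing it both destabilizes the
likelihood and answers a question the task design already answers. The
Rasch (1PL) model constrains $a_j \equiv 1$; the 2PL frees one slope per
item. Only under the Rasch constraint (and $c = 0$) is the raw sum score
a *sufficient statistic* for ability, which is what makes a
Rasch-conforming test easy to score in practice; with $c > 0$ the sum
score remains a near-sufficient summary (EAP abilities are monotone in it
up to small pattern effects), which is the practical sense in which the
short forms built here are "sum-scorable".

### Estimation

`fit_rasch()` and `fit_2pl()` maximize the marginal likelihood by EM,
integrating abilities over a normal distribution with 61-node
Gauss–Hermite quadrature (enough nodes that the quadrature error is far
below the statistical error at any realistic sample size; configurable
via `n_quad`). Identification follows the standard conventions: the Rasch
fit estimates the SD of the ability distribution (`ability_scale`), while
the 2PL fixes abilities to $N(0,1)$ and lets the slopes absorb the scale,
so a Rasch model with scale $\sigma$ is exactly the 2PL with all
$a_j=\sigma$ — which is why the 2PL marginal likelihood can never fall
below the Rasch one, a property the test suite asserts. Weak ridge
penalties — normal with SD 5 on $\beta_j$ and SD 1 on $\log a_j$ — keep
near-degenerate items (nearly all correct, or slopes running away) from
diverging while being far too diffuse to move well-identified estimates;
items whose slope still hits the bound of 10 are flagged. The EM is fully
deterministic (starting values come from classical proportions), so
refitting the same data reproduces the same fit bit for bit. Wholly
degenerate items — no variation at all — are a hard error naming the
item, because no easiness is identified for them.

Abilities are expected-a-posteriori (EAP) means with posterior SDs as
standard errors; item standard errors come from the expected information
at the optimum. Each fit also stores the per-cell conditional
log-likelihood at the EAP abilities (`pointwise_loglik()`), which is the
raw material for model comparison.

## Item-fit, reliability, DIF

`item_fit_stats()` computes the two classic mean-square residual
statistics, with the model-implied probability (including the guessing
floor) as the expectation: outfit is the unweighted mean of squared
standardized residuals, infit the information-weighted version. Both have
expectation near 1 under a correct model; the usual screening band is
$[0.7, 1.3]$.

`kr20()` implements the Kuder–Richardson formula with item variances
$p_jq_j$ and the sample ($n-1$) variance of the sum score — the
convention is declared because the two choices of denominator give
slightly different values at small $n$ (the package's hand-checked
reference value, 0.9375 on a 4-person, 3-item table, pins the convention
down). Persons with missing responses on the scored subset are dropped
listwise for this classical statistic only; all model-based quantities
use every observed cell. `andrich_reliability()` is the person-separation
ratio $(\operatorname{Var}\hat\theta - \overline{se^2}) /
\operatorname{Var}\hat\theta$, floored at zero.

`dif_analysis()` fits one joint Rasch model in which every item gets a
separate easiness per group while all persons share a single zero-mean
ability distribution with a common estimated SD. Fitting jointly rather
than fitting the two groups separately keeps both sets of easiness
estimates on the same latent scale without an ad-hoc equating step — the
price is the assumption that the two groups have the same ability
distribution, which is appropriate when the grouping is randomized
(administration order) or expected to be ability-neutral (sex). Items are
flagged when the two Wald 95% intervals fail to overlap; this is a
deliberately conservative screen (stricter than a Wald test on the
difference), which keeps the false-flag rate on null data well under the
10% the test suite demands.

## The subset objective and the annealer

A good short form should (a) spread its items evenly over the latent
scale so it measures equally well at all ability levels, (b) contain only
items the Rasch model describes well, and (c) contain items of similar
discrimination, since that is what the Rasch constraint assumes. Four
per-subset numbers operationalize this, all "smaller is better":

| component | definition |
|---|---|
| `spread` | SD of gaps between adjacent sorted easiness values |
| `infit_dev` | mean of \|infit − 1\| |
| `outfit_dev` | mean of \|outfit − 1\| |
| `disc_var` | variance of 2PL discriminations |

The components live on incomparable scales, so each is divided by its
mean over random same-size subsets (`calibrate_normalizers()`, 1000 draws
by default — enough that normalizers are stable to a few percent across
seeds) and then weighted. The default weights 2 : 2 : 2 : 1 put the
emphasis on model fit and equal spacing, with discrimination homogeneity
as a lighter tie-breaker; they are configurable and recorded in every
solution object. The objective is the negative weighted sum, so 0 is the
unattainable ideal and higher is better.

`anneal_select()` maximizes this objective over size-$m$ subsets by
simulated annealing: single-item swaps (configurable), Metropolis
acceptance $\exp(\Delta/T)$, geometric cooling by 0.995 every 10
proposals, 20,000 proposals in total, and the best-ever subset returned.
The initial temperature is auto-tuned from 200 warm-up proposals so that
roughly 80% of worsening moves would be accepted at the start — hot
enough to traverse the subset space freely before the cooled phase
degenerates into hill climbing (by the final schedule step the
temperature is ~$10^{-5}$ of the initial one, making worsening
acceptances astronomically unlikely; the trace records this). Everything
is driven by one integer seed and fully reproducible. On pools small
enough to enumerate, `exhaustive_select()` provides the ground truth, and
the test suite holds the annealer to the exhaustive optimum on random
12-choose-6 instances; ties are broken lexicographically by item id.

## Choosing the size: the ELPD stopping rule

For each candidate size, the selected subset is refit with both models
and compared by expected log predictive density. Without a posterior
sample there is no importance-sampling LOO, so the package uses a
deterministic information-criterion analogue with the same algebra: each
model's per-cell conditional log-likelihood is penalized by its parameter
count spread over the cells ($J+1$ for Rasch including the ability-scale
SD, $2J$ for the 2PL), the difference of the two penalized totals is
`elpd_diff`, and its standard error is $\sqrt{N}$ times the SD of the
per-cell differences. The reported ratio
$\max(0,\text{elpd\_diff})/(2\,\text{se\_diff})$ encodes the conventional
2-standard-error rule: at or below 1, the extra slopes buy nothing and
the subset counts as Rasch-conforming; the floor at 0 marks subsets where
the Rasch model predicts better outright. Simulations in the test suite
show the rule has the right operating characteristics at a realistic
scale (600 persons, 20 items): ratio ≤ 1 almost always under Rasch truth,
ratio > 1 almost always under strong discrimination heterogeneity
(log-normal slopes with SD 0.7).

`size_sweep()` assembles the full evidence table — per size and run: the
annealed objective, the comparison ratio, and the correlation between
subset and full-pool sum scores, overall and within sex and age-tercile
strata. The intended reading is graphical (`plot_size_sweep()`): pick the
smallest size past the correlation plateau whose ratio still sits at or
below 1.

## Trial orders

`assign_positions()` constructs target-corner sequences satisfying three
counterbalancing rules — equal position counts (exact when 4 divides the
trial count), no position more than 3 trials in a row, all four positions
in every 7-trial window — by randomized sequential construction: at each
step a feasible corner is drawn uniformly, corners that have been absent
for six trials become forced, and contradictions trigger a fresh restart.
The rules are constraints rather than a construction, so sampling under
them with restarts is the simplest auditable generator; for 52 trials a
valid sequence is typically found within a handful of restarts.
`assign_distractor_positions()` then balances the three distractor types
over the free corners greedily, choosing per trial the type-to-corner
permutation that minimizes the running imbalance (random tie-breaks), which
keeps every type's per-corner count within ±1 of parity.

`generate_order()` targets a trial-number/AoA correlation (default
$r = 0.85$, tolerance 0.02): starting from the AoA-sorted order (which
has $r = 1$) it proposes random transpositions and accepts only those
that move the correlation toward the target — a monotone, auditable
descent that reaches the default target in well under a thousand
accepted swaps for a 52-item bank. A correlation below 1 is deliberate:
the task should get harder as it proceeds, but not deterministically so.

## The synthetic cohort generator

`sim_config()` defaults describe the study design the package is built
around: 581 children with ages uniform on 3–8 years, 52 items with AoA
ratings spread evenly over 6–10 years, guessing floor 0.25, balanced sex
and order-group covariates. The generative links are linear-logistic:
ability $= 0.5 \cdot (\text{age} - 5.5) + N(0, 1)$ logits and easiness
$= 4.8 - 0.6 \cdot \text{AoA} + N(0, 0.5^2)$ logits. The slopes and SDs
are the generator's own configuration, chosen so the synthetic cohort
reproduces the qualitative facts such a study reports — accuracy well
above the 0.25 floor for every item, rising steadily with age, declining
with AoA, older children near ceiling on early-acquired words — and they
are placeholders in the strict sense: no empirical variance decomposition
backs them, and tests passing on this generator certify the *algorithms*,
not any real cohort. Real data also contain things the generator omits by
design: position effects, attention lapses, multidimensionality, and
item-order effects beyond the built-in uniform DIF hook (`dif_items` /
`dif_shift`, applied to order group B).

One master seed expands into fixed per-stage substreams, so the bank,
cohort and responses can be regenerated independently and reproducibly.

## Numerical choices and limitations

* Quadrature: 61 Gauss–Hermite nodes; EAP oracle tests agree with a
  200-point brute-force grid to $10^{-3}$.
* Convergence: EM stops when no parameter moves by more than $10^{-5}$
  (cap 500 iterations); the penalized marginal likelihood trace is stored
  and asserted non-decreasing.
* Problem sizes in the test suite — cohorts of 400–600, pools of 12–52
  items, 10-replicate recovery and power loops, 100-seed annealer
  stability on a 12-item instance — were chosen as the smallest scales at
  which the statistical claims are meaningful, so the whole suite runs in
  minutes on one core.
* The comparison ratio's effective-parameter correction is an
  IC-style approximation, not PSIS-LOO; its absolute ELPD values should
  not be compared across packages, though the diff/SE ratio behaves as
  intended in simulation.
* No polytomous models, no free guessing (3PL), no multidimensional or
  longitudinal extensions; adaptive testing is out of scope.
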