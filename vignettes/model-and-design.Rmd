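---
title: "Reproductive skew and the evolution of social learning: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproductive skew and the evolution of social learning: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewlearn)
```

## The question the simulator addresses

Animals differ — between species, between populations, and between the
sexes — in how much they rely on social information. `skewlearn`
implements an agent-based foraging model in which that variation emerges
from *reproductive skew*: the fraction of a population whose foraging
success is good enough to permit breeding. Social learning (copying the
patch choices of other foragers) turns out to be a risk-averse strategy:
it produces less variable returns, because copied patches are vetted but
also more crowded. Individual learning (sampling patches directly) is
risk-prone: more exposure to terrible patches, but also sole access to
undiscovered bonanzas. Which strategy evolves then depends on the shape
of the payoff-to-reproduction mapping, which skew controls: when only the
very best foragers breed, gambling pays; when most adequate foragers
breed, reliability pays.

## The model

**Environment.** `M` patches carry payoffs drawn i.i.d. from a gamma
distribution with mean $\bar\pi$ (default 4) and variance $\sigma^2$.
Moment matching fixes the gamma parameters: shape $\bar\pi^2/\sigma^2$,
scale $\sigma^2/\bar\pi$. $\sigma^2 = 1$ gives an *even* world (most
patches near the mean), $\sigma^2 = 100$ an *uneven* world (a few rich
patches among many poor ones). Payoffs replenish every round; with
probability $\tau$ per patch per round the payoff is redrawn from the
same distribution (*environmental turnover*). Turnover is the only
process that changes patch quality: there is no depletion and no spatial
structure.

**Rounds.** Each of `N` individuals, each round, either learns (with
probability 0.2) or exploits a patch (0.8). Exploiters commit
simultaneously to the best patch in their memory; if $n_m$ exploiters
chose patch $m$, each collects $\pi_m / n_m$ (exploitative scramble).
Each exploiter's memory entry for its patch is updated to that realised
share. Learners either sample one uniformly random patch (individual
learning) or pick a uniformly random previous-round exploiter and learn
the patch it used (social learning); a learning turn is social with
probability $\alpha_i$, the individual's heritable social-learning
propensity. In either case the learner stores the patch's *expected*
payoff $\hat p_m = \pi_m / n_m$ under the current round's occupancy
($\pi_m$ if unoccupied). Information persists until overwritten or
death; it can silently go stale through turnover or occupancy change.

**Fitness proxy and reproduction.** Reproductive potential in round $t$
is the discounted payoff window
$$F_i(t) = \sum_{j=0}^{\delta-1} e^{-rj}\, p_{i,t-j},$$
with window $\delta = 5$ and discount $r = 0.2$; rounds spent learning
contribute 0, and individuals become eligible to reproduce (mature) at
age $\delta$. A single-round variant $F_i(t) = p_{i,t}$ is available via
`fitness_params(mode = "single_round")`. Individuals die randomly
(probability 0.01 per round) or at age 100, and every death is replaced
immediately, keeping `N` constant. Replacement depends on the mode:

* `fixed_proportion` — the dead individual is replaced by a naive copy
  of itself (same $\alpha$ and sex, empty memory). No selection; used to
  compare the yield distributions of the two strategies at a frozen
  50/50 composition.
* `asexual` — mature survivors are ranked by $F$, and the top
  $\lceil \beta\, n \rceil$ form the parent pool. Under the
  `minimum_income` criterion all pool members are equally likely
  parents; under `relative_income` they are drawn proportionally to
  $F$. Offspring inherit the parent's $\alpha$, flipped with probability
  $\mu = 1/N$.
* `sexual` — pools are formed within each sex using sex-specific
  proportions $\beta_f$, $\beta_m$; each replacement draws a mother and
  a father, assigns sex fairly, and inherits $\alpha$ from the same-sex
  parent (sex-linked inheritance, so the sexes evolve independently
  except through ecological competition).

Runs stop when all individuals share one $\alpha$ (fixation) or after
`max_rounds` (default 5000).

## Parameters at a glance

| parameter | meaning | default |
|---|---|---|
| `n_individuals` | population size N | 1000 |
| `n_patches` | patch count M | 1000 |
| `mean_payoff` | mean patch payoff (resource units/round) | 4 |
| `payoff_variance` | patch payoff variance; 1 even, 100 uneven | 100 |
| `turnover` | per-patch redraw probability/round | $10^{-1.5}$ |
| `learn_prob` | probability a round is spent learning | 0.2 |
| `delta`, `discount_r` | fitness window and discount rate | 5, 0.2 |
| `beta` (`beta_f`, `beta_m`) | proportion eligible to breed | 1 |
| `mutation_rate` | strategy flip probability per offspring | `"1/N"` |
| `death_prob`, `max_age` | mortality | 0.01, 100 |
| `max_rounds`, `replicates` | run length, replicate count | 5000, 200 |

The defaults are the model family's benchmark conditions; the reference
environment (uneven, intermediate turnover) is the one that supports
intermediate social-learning levels and is the backdrop of the sexual
experiments.

## Design choices in the open corners

The model statement leaves several mechanics open; the package fixes
them as follows, each exposed where a user might reasonably want the
alternative.

**Naive foragers.** An exploiter whose memory is empty (a newborn) has
nowhere to go; it spends the round learning instead. By default that
forced turn is an *ordinary* learning turn — social with probability
$\alpha$ — since the model defines every learning turn that way
(`naive_learning = "alpha"`). The alternative, forcing naive
individuals to sample a random patch regardless of $\alpha$
(`naive_learning = "individual"`), weakens the distinction between the
strategies at the start of life and measurably inflates the uneven-world
variance ratio (to roughly 0.48 from 0.36 with the default, against a
benchmark value of 0.34): vertical information flow to naive social
learners is a real part of the strategy difference, so the
alpha-respecting reading is the default.

**Within-round ordering.** Exploiters commit simultaneously, then
learners observe using the *current* payoffs and occupancy, then
histories and ages advance, then turnover, then mortality and
replacement. A single occupancy per round is required by the payoff and
expectation formulas; resolving learning after exploitation means
observations are current when made and stale by at most one round when
used.

**Demonstrators.** The demonstrator pool is every individual that
exploited in the previous round, regardless of success, strategy or sex
(no payoff-biased copying); an individual that exploited last round can
be sampled by itself. If nobody exploited (possible only in the first
round or in all-learner configurations), social learners fall back to
individual learning rather than idling.

**Ties and cutoffs.** Ties among equally remembered patches, and ties
at the parent-pool cutoff rank, are broken uniformly at random. The
pool size is $\lceil \beta\, n_{\text{mature}} \rceil$, which guarantees
at least one parent even for $\beta$ below $1/n$.

**Initial state.** Starting ages are uniform on $\{0, \dots, 99\}$ so
mature individuals exist from the first rounds (a cold start with all
ages 0 would leave the parent pool empty for $\delta$ rounds); memories
and histories start empty, and initial payoff histories are treated as
zeros. Fixed and asexual runs start with exactly half social learners;
sexual runs draw each individual's binary $\alpha$ fairly.

**Maturity.** Eligibility to reproduce requires age $\ge \delta$ in
windowed mode (age $\ge 1$ in the single-round variant). Immature
individuals are excluded from the candidate ranking rather than ranked
with zero fitness, keeping the ranking semantics clean. If no mature
candidate survives a round — unreachable under the default mortality
parameters — parents are drawn uniformly from survivors and a warning is
raised.

## Measuring yield variability: two readings

The headline risk statistic is the ratio of the variance of resources
collected by exploiting social learners to that of exploiting individual
learners in the final round of fixed 50/50 runs.
"Variance" admits two readings, and `variance_ratio()` implements both:

* `"within_round"` (default): variance across the final round's
  exploiting individuals, per strategy, averaged over replicates before
  taking the ratio. This reading reproduces the benchmark uneven-world
  ratios (~0.34–0.36) and is the one consistent with the reported
  contrast between strategies.
* `"replicate_means"`: variance across replicates of the
  within-replicate strategy mean. This measures between-population
  spread instead; in this model it sits near or above 1 in all four
  environments and cannot produce the benchmark uneven-world values, so
  it is provided for audit rather than as the default.

Bootstrap confidence intervals (percentile, resampling replicates,
10,000 resamples by default) are attached to both readings.

## The two engines

Every model operation — environment creation, action draws, scramble
resolution, learning, the fitness proxy, parent pools, each replacement
rule — is an exported, documented R function, and `step_round()`
composes them into the reference engine (`run_single(engine = "r")`).
Full-scale runs use a C++ engine implementing the identical algorithm
(`engine = "cpp"`, the default), with per-individual memories in a
contiguous arena whose capacity bound (one new patch per round lived)
makes scans cache-friendly. Both engines draw all randomness from R's
RNG, so each is exactly reproducible given a seed; they do not consume
random numbers in the same order, so they are compared statistically in
the test suite (throughput and evolutionary outcomes on shared small
configurations) rather than bitwise. Exact invariants — payoff
conservation to $10^{-9}$, occupancy consistency, constant population
size, frozen fixed-mode composition — are asserted on both.

## What the checks do and do not show

The package's checks rerun the benchmark experiments at reduced
replicate counts: 100 replicates per fixed-composition cell (the full
design uses 200) and 60 per
neutral-limit cell, with full-size populations, patch counts and round
counts. With the within-round reading the variance-ratio estimator is an
average over replicates of an already stable per-replicate statistic, so
100 replicates put its standard error in the few-percent range;
replicate counts were fixed from that precision argument. Qualitative
surface checks (skew, resource-distribution and between-sex contrasts)
use 20 replicates per cell and one-sided comparisons of replicate means,
which is ample for effects that span most of the [0, 1] frequency
range.

The synthetic worlds are exactly the model's assumptions — gamma
payoffs, independent turnover, global mixing, equal sharing — so passing
checks demonstrate a faithful implementation of the model, not claims
about any real foraging system. Real populations have spatial structure,
depletion, state-dependent strategy switching and payoff-biased copying,
all deliberately outside this model.

## Known limitations

* Continuous social-learning propensities ($0 < \alpha < 1$) are
  supported in fixed-composition runs, but evolutionary runs evolve
  binary strategies only; there is no mutation scheme for continuous
  $\alpha$.
* Reproduction thresholds are always relative (rank-based); fixed
  absolute income thresholds are not implemented.
* Blended (mid-parent) inheritance in sexual mode is not implemented;
  inheritance is strictly sex-linked.
* The sweep runner is sequential; replicate seeds are pre-derived so
  results are independent of execution order, but no parallel backend
  is bundled.
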