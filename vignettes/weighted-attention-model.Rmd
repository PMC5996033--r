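---
title: "Modelling multidimensional discrimination learning with dimension-specific attention weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multidimensional discrimination learning with dimension-specific attention weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(wamaze)
library(dplyr)
```

## The task

wamaze models trial-by-trial choice behavior in a four-arm plus-maze
discrimination task with intra- and extra-dimensional set shifts.  On
every trial two of the four arms are offered; the two offered options
always carry the two different odors and the two different LED colors,
one each, on two distinct arms.  Throughout a *learning set* exactly one
sensory dimension (odor or LED color — never location) determines
reward, deterministically: choosing the option that carries the set's
correct feature is always rewarded, the alternative never.  Animals run
50–100 trials a day; a day at or above 75% correct counts as having
learned the set.  The odor-first protocol trains ODOR1 → ODOR2
(intra-dimensional shift: a new odor pair, odor still rules) → LED
(extra-dimensional shift); the LED-first protocol trains LED → ODOR1.

A behavioral log is a plain tibble, one row per trial:

```{r}
prot <- maze_protocol("odor_first", n_days = c(2, 1, 2), trials_per_day = 60)
pars <- set_params(alpha = 0.35, beta = 6, weights = c(0.2, 0.6, 0.2))
pars <- list(ODOR1 = set_params(c(0.35, 0.35), 6, c(0.2, 0.6, 0.2)),
             ODOR2 = pars, LED = set_params(c(0.35, 0.35), 6, c(0.2, 0.6, 0.2)))
log <- simulate_agent(prot, "wam", pars, seed = 11)
head(log, 3)
```

## The two models

Both models share the Rescorla–Wagner delta rule.  If the chosen item
has cached value $x$ and the trial pays reward $R \in \{0, 1\}$, then

$$x \leftarrow x + \alpha\,(R - x), \qquad \alpha \in [0, 1],$$

applied only to what was chosen; nothing unchosen is ever updated.
Values start at zero at the beginning of every set, so they always stay
in $[0, 1]$.

**Naive reinforcement learning (NRL).**  One value per feature
*combination* — $4 \times 2 \times 2 = 16$ states $V_{ijk}$ for arm $i$,
odor $j$, LED color $k$.  The decision index of an offered pair $(a, b)$
is $\Delta V = V_a - V_b$.  Because the schedule is deterministic and
values start at zero, a combination lacking the correct feature can only
ever receive $R = 0$ and stays at zero forever: the deterministic NRL
can predict correct choices but never mistakes, and under sustained
reward of the correct option $\Delta V \to 1$ monotonically.

**Weighted attention model (WAM).**  One value per *feature*: four
location values $l_i$, two odor values $o_j$, two color values $c_k$.  A
choice updates its three features.  Decisions compare weighted sums: the
decision index of the pair $a = (i, j, k)$ versus $b = (i', j', k')$ is

$$I = w_l\,(l_i - l_{i'}) + w_o\,(o_j - o_{j'}) + w_c\,(c_k - c_{k'}),$$

with attention weights $w_l, w_o, w_c \ge 0$, $w_l + w_o + w_c = 1$.
The weights separate *learning* (the values) from *decision-making*
(which dimensions the values are allowed to influence), so the WAM can
explain systematic mistakes — e.g. perseverative reliance on a formerly
relevant dimension — that the NRL structurally cannot.

**Choice rule.**  Both models choose option $a$ with the softmax
probability $P = 1 / (1 + e^{-\beta\,\mathrm{index}})$.  The inverse
temperature $\beta \ge 0$ is shared across the days of a set;
$\beta = 0$ is random choice.  The *deterministic* prediction is the
sign of the index; an exactly zero index is a tie.  The a/b labelling of
options is arbitrary, so ties are scored as half a match everywhere a
fraction of explained choices is computed — breaking ties toward either
label would leak the labelling into the score.

## Parameters and estimation

Per set, the NRL has one learning rate per day plus $\beta$
($N + 1$ parameters over $N$ days); the WAM adds two free weight
coordinates per day ($3N + 1$).  Weights are fit day-by-day because
trial-resolution weights are not identifiable from a single binary
choice per trial.

`fit_set()` maximizes the choice log-likelihood jointly over all day
parameters plus $\beta$.  Joint (rather than day-wise) optimization is
exact here because values carry over between days, coupling every day's
likelihood to all earlier learning rates.  Numerically:

* bounds $\alpha \in [0, 1]$, $\beta \in [0, 30]$ are enforced by
  L-BFGS-B; the simplex is handled by a per-day softmax
  reparameterization with the location coordinate pinned at 0 (two free
  coordinates per day, bounded in $[-9, 9]$, which covers the simplex
  up to weights of order $10^{-4}$ — boundary weights are recovered to
  that resolution);
* the start is the optimum of an exhaustive grid — $\alpha$ in steps of
  0.05, $\beta$ in steps of 1, weights on the 0.1 simplex lattice, one
  shared $(\alpha, w)$ point across days to keep the grid small; grid
  ties resolve to the lexicographically smallest parameter vector;
* five seeded random restarts guard against local maxima; the reported
  likelihood is never below the grid optimum (the exact grid point is
  kept if no start improves on it);
* the logistic and its logarithm are computed in overflow-safe forms,
  so likelihoods are finite for any $\beta \le 30$;
* non-convergence is reported as `converged = FALSE` with the best
  parameters found, never as an error, and a $\hat\beta$ at the upper
  bound is flagged (`beta_at_bound`), which degenerate all-one-way days
  can produce.

An optional overnight decay $\lambda \in [0, 1]$ multiplies the carried
values at each day boundary (default 1, plain carry-over), supporting
robustness checks of the carry-over assumption.

## Model comparison

`aic_compare()` implements the score
$\ln L_{\mathrm{WAM}} - \ln L_{\mathrm{NRL}} - d$ with $d = 2N$ over the
$N$ *included* days — days on which the NRL's deterministic fit exceeds
50% strictly.  The conventional factor of 2 on the log-likelihoods is
deliberately absent; the score is used as reported by the original
analysis, and only its sign (positive favors the WAM) is interpreted.
With zero included days the result is an explicit "no comparable days"
record, not a zero.

`cross_validate()` refits on each day truncated to its first
$\lceil 0.9\,n \rceil$ trials (earlier days intact, later days excluded
— parameters are never informed by test trials) and scores the held-out
tail by the maximum-probability choice, ties 0.5.  The ceiling keeps the
training split nonempty for short days; days whose test split would be
empty are skipped with a warning.

`deterministic_fit()` gives the no-exploration fraction of explained
choices per day.  On tie-free days of a deterministic-reward log the NRL
deterministic fit equals the day's success rate exactly — the model can
only predict successes — which is the structural signature that
motivates the WAM.

## Descriptive analyses

`daily_success_rate()`, `criterion_day()` (75%, inclusive),
`stage_split()` (early/late at the first day ≥ 70%; the crossing is
permanent, matching a two-stage partition of each set),
`choice_matrix()` (choices against the correct arm; spatial biases show
as dominant columns), `cohort_weights()` / `aggregate_weights()` (per
day mean ± SEM across animals; day cells with fewer than half the
animals are dropped by default, single-animal cells are flagged) and
`stage_weight_table()` (the animal × set × stage × dimension table that
a repeated-measures ANOVA consumes — the test itself is left to the
user's statistics environment).  The location weight is fitted and
exported like the others even where standard plots show only odor and
LED.

## The synthetic cohort

`simulate_agent()` runs either model generatively: per trial the arm
pair is drawn uniformly from the 6 unordered pairs, odor and LED labels
are assigned uniformly and independently, the choice is sampled from the
model's softmax, and the reward follows the deterministic rule (draw
order: arms, odors, LEDs, choice — logs are bit-reproducible from
protocol, parameters and seed).  Defaults mirror the task as run: 100
trials per day within the 50–100 range, value reset at set boundaries,
odor-pair identity tracked as metadata across shifts.

The generator reproduces the *reward structure and choice statistics* of
the task, not the animal: there is no satiety, no side-preference drift
beyond what value learning induces, no apparatus errors, and arm pairs
are i.i.d. uniform rather than counterbalanced within a day (the
original counterbalancing scheme is not documented).  Tests passing on
synthetic cohorts therefore validate the estimation and comparison
machinery under the task's generative assumptions; they do not certify
behavior on rat data with structure the generator lacks.

## Identifiability limits

Two regimes deserve explicit caution; both are properties of maximum
likelihood on this design, not of the implementation.

*Random choosers.*  When $\beta = 0$ generated the data, the product
$\alpha \beta$ is what the likelihood sees: fits can land at
$\hat\alpha \approx 0$ with a nonzero $\hat\beta$ (or vice versa) at
essentially the chance likelihood.  Recovered *policies* are
near-random, but neither coordinate alone is a reliable readout.

*Saturated performers.*  Once an agent is nearly always correct, the
relevant dimension's value difference is almost constant and only
$\beta \cdot w_{\mathrm{relevant}}$ is pinned down; the per-day weight
freedom (3 parameters per day) then soaks residual noise, shifting
weight mass toward irrelevant dimensions while $\hat\beta$ inflates to
compensate.  Day-wise weight estimates on long, highly-trained sets are
therefore noisy and systematically shrunk toward the irrelevant
dimensions, and should be read as cohort averages (as in the stage
analyses), not as per-day point estimates.  Hierarchical or regularized
estimation would mitigate this but is deliberately out of scope.

## Problem sizes

The shipped tests exercise the pipeline at sizes a single desk CPU
handles comfortably: single sets of 1–3 days for oracle-equivalence
checks against dense parameter grids, 10-day × 100-trial sets for
parameter recovery, 20-seed replicate studies for the stochastic
recovery and cross-validation comparisons, and an 8-animal odor-first
cohort (4 + 3 + 6 days at 80 trials) for the end-to-end perseveration
analysis.  All simulation sizes are package choices encoded in the tests
and can be scaled up by the user.
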