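---
title: "Measuring delayed-lottery discounting by adjusting and conjoint: models, choices, and what the simulations can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring delayed-lottery discounting by adjusting and conjoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaydisc)
```

## The measurement problem

A delayed lottery pays an amount $A$ with probability $p$ after a delay
$D$. How strongly a person devalues such a prospect — their *discounting
strength* — is a stable individual trait that predicts consequential
choices, but it has to be measured indirectly, from sequences of binary or
multi-way choices. This package implements the two measurement routes used
in the delayed-lottery literature, reduces both to the same
per-person summary, and evaluates them head-to-head on synthetic
respondents whose true preferences are known.

Both routes operate on the same 3 × 3 study grid: delays of 1 week, 3
months and 2 years ($\{7, 90, 730\}$ days) crossed with payment
probabilities $\{0.01, 0.1, 0.7\}$, all at a nominal amount of 1000
currency units (`lottery_grid()`).

## The adjusting (staircase) route

Each lottery is pitted against a certain immediate amount for six choices.
The first offer is $A/2$; after each choice the offer moves *down* (if the
certain side was taken) or *up* (if the lottery was) by an adjustment that
starts at $A/4$ and halves every step. This is plain bisection: after six
steps the respondent's internal equivalent is bracketed within $A/64$, and
the indifference point — defined here as the mean of the last two offers
presented — is provably within $A/32$ of any internal value consistent
with the response path. The test suite verifies this by exhaustive
enumeration of all $2^6$ paths.

Two readings of the verbal titration rule were possible: "changes by half
of its previous value" is literally true only at the first transition
($2500 \to 1250$ for a \$5{,}000 lottery). We use the halving-adjustment
schedule throughout, because it reproduces both canonical transitions
($1250$ and $3750$) *and* converges to arbitrary equivalents, which a
literal always-half rule does not. Similarly, "the mean of the two last
alternatives" is read as the offers presented at steps 5 and 6; the
alternative reading (final offer ± half the final step) differs by at most
$A/64$ and would not change any conclusion. Ties at exact indifference go
to the certain option, making noiseless respondents fully deterministic.

Indifference points scaled by $A$, with delays min–max scaled onto
$[0, 1]$ ($7 \to 0$, $730 \to 1$), form one discount curve per probability
level; the trapezoidal area under each curve,
$\mathrm{AUC} = \sum_i (e_i + e_{i+1})(t_{i+1} - t_i)/2$, is the
discounting-strength summary (three numbers per person, one per
probability level; smaller = steeper discounting). The alternative
$d/d_{\max}$ time scaling is available via `time_convention = "max"`; it
rescales all trapezoid widths by the same factors and is recorded in the
output metadata.

## The conjoint route

Respondents complete 25 tasks, each a choice of the best among 3 lotteries
from the 9-profile grid. Designs are generated per respondent
(`generate_cbc_design()`) by random-start hill climbing on the stated
design goals — level balance (each attribute level appears equally often)
and near-orthogonality (levels co-occur evenly, which for full profiles is
per-profile balance) — with a penalty on duplicated tasks. With 75
exposures over 9 profiles the optimum is 8 or 9 exposures per profile and
exactly 25 per attribute level, which the optimizer reliably reaches in
400 swap moves. Full D-efficiency optimization is deliberately out of
scope: the implemented objective is the verbal definition of the design
goals, and the diagnostics (`design_diagnostics()`) let a user audit any
design.

Choices are modelled by a multinomial logit in dummy-coded attribute
levels: the utility of a profile is the sum of its part-worths, with the
shortest delay and lowest probability as reference levels (so the
reference profile has utility zero; a location shift common to all options
in a task leaves the likelihood unchanged). Delay × probability
interaction columns are available behind `interactions = TRUE` but are off
by default — a 3 × 3 grid with 25 triples identifies main effects
robustly, while the 4 extra interaction parameters roughly double the
dimension for little gain at these sample sizes. (Effects coding, the
convention of some commercial CBC tools, differs from the dummy coding
used here by a reparameterization that leaves choice probabilities and
cumulative-utility differences unchanged.)

Individual part-worths $b_i$ get the hierarchical prior
$b_i \sim N(a, D)$ with a flat prior on $a$ and an inverse-Wishart prior
on $D$ (identity scale — "initial variance unity, covariance zero" — and
degrees of freedom = dimension + 5, a proper but weakly informative
choice). `run_hb()` iterates the three conditional updates:

1. $a \mid b, D \sim N(\bar b, D/n)$;
2. $D \mid b, a \sim \mathrm{IW}(\nu_0 + n,\; S_0 + \sum_i (b_i - a)(b_i - a)^\top)$;
3. one Metropolis–Hastings step per respondent on
   $\pi(b_i) \propto \mathrm{MNL}(b_i)\, N(b_i \mid a, D)$ with a Gaussian
   random-walk proposal of covariance $s^2 D$.

Initialization follows the win-ratio heuristic: each respondent's
attribute-level win ratios (times chosen / times shown), clipped to
$[0.05, 0.95]$ and mapped through the logit relative to the reference
level. The proposal scale $s$ adapts toward ~30% acceptance in batches
during burn-in only, so the retained chain is a fixed-kernel Markov chain
satisfying detailed balance. The default budget is 20000 iterations with
half discarded as burn-in; the test suite and acceptance script run
1500–6000 iterations, which this low-dimensional model (4 parameters, 60
respondents) comfortably mixes within — the sampler-vs-dense-grid check
agrees to 2% at those lengths, and two chains with different seeds agree
within Monte-Carlo error.

Posterior-mean cumulative utilities for the 9 profiles, min–max rescaled
to $[0, 1]$ within each respondent, feed the identical AUC computation as
the adjusting route. The within-respondent min–max map is the natural
choice because HB utilities are location- and scale-arbitrary: it makes
the AUC exactly invariant to affine transformations of the utility scale
(asserted to $10^{-12}$ in the tests), preserves within-person ordering,
and bounds AUC in $[0, 1]$. A respondent whose 9 utilities are all equal
has no preference information; the curve is flat by convention (AUC = 1)
and flagged.

## The synthetic respondents

Since no raw participant data are available, the study is replicated on
simulated cohorts (`generate_cohort()`). Ground truth is a multiplicative
hyperbolic model, the standard form in this literature:
$$V = \frac{A}{(1 + k_d D)(1 + k_o \theta)}, \qquad \theta = \frac{1-p}{p},$$
with per-day delay rate $k_d$ and odds-against rate $k_o$. Choices are
softmax in subjective values with logistic scale
$\tau \times \max(A)$, so the temperature $\tau$ is scale-free. Between
waves (3 weeks apart) each rate is multiplied by an independent
$\mathrm{LogNormal}(0, \sigma_r)$ jitter — traits are stable but not
frozen.

Default population (units and rationale):

| parameter | default | meaning / why |
|---|---|---|
| $k_d$ | LogNormal($-4.6$, $1$) /day | median 0.01/day, the typical order for monetary delay discounting; wide spread matches the large SDs of published equivalent tables |
| $k_o$ | LogNormal($\log 0.5$, $0.7$) | median 0.5; equivalents fall steeply from $p=0.7$ to $p=0.01$, as in the published group means |
| $\tau$ | 0.01 | calibrated so the simulated external choice task reproduces the order of magnitude of the reported choice-task repeatability (kappa ≈ 0.35–0.6 on the decisions the trait model differentiates) and reported choice shares (e.g. ~5% picking the low-probability option in decision 1 vs 8% reported) |
| $\sigma_r$ | 0.3 | cross-wave correlation of $\log k$ ≈ 0.96, "stable trait with mild drift" |
| adjusting noise ×10 | staircase choices use $10\tau$ | see below |

**The adjusting-noise multiplier is the key structural assumption.** With
identical softmax noise in every task, a simulated staircase is *more*
reliable than conjoint — six bisection steps pin the equivalent within
$A/32$, far below the between-person spread — which contradicts the
well-documented unreliability of titration with abstract probabilistic
content (irrational-choice exclusion rates of 20–50%, the incentive to
"sell" the constant alternative high, low attention to near-identical
repeated screens). The default therefore makes respondents ten times
noisier in staircase choices than in pick-the-best tasks. This encodes the
hypothesized mechanism rather than testing it: the simulated
method-comparison demonstrates that the pipeline *propagates* a
method-specific reliability difference into the reported statistics
(test–retest correlations, AIC), not that conjoint is superior in real
humans. Setting `adjusting_noise = 1` makes both methods comparably
reliable in simulation.

The generator deliberately does **not** emulate nonlinear probability
weighting, lexicographic or other heuristic strategies, attention drift
over a session, or non-random dropout. Consequently decision 2 of the
external choice task (0.01 in 3 months vs 0.1 in 2 years — both options
nearly worthless to every hyperbolic agent) shows near-zero simulated
repeatability no matter the temperature, whereas humans are reported
moderately consistent on it; quantitative matches to the published
human tables are out of reach by design, and passing tests show pipeline
correctness under this model, not behavioral realism.

## The evaluation layer

*Repeatability*: Cohen's kappa per choice-task item from the 2 × 2
cross-classification of waves, with the large-sample null-SE $z$ test;
undefined (and flagged) when neither margin varies. *Predictive validity*:
for each choice-task decision and method, a binary logistic regression of
the decision on that method's three AUC parameters with backward
elimination on likelihood-ratio tests (removal threshold $p > 0.10$, the
conventional stepwise default; the "conditional" stepwise statistic of
GUI packages is an approximation to this LR test). Reported per model:
retained predictors, AIC ($2k - 2\ell$, intercept counted) and Nagelkerke
pseudo-$R^2$. Degenerate decisions (everyone chose alike) are skipped and
flagged; quasi-separation is detected from divergent coefficients and
flagged. An inestimable (aliased or constant) predictor is treated as
maximally removable. *Stability*: Pearson correlations of AUC across
waves per method × probability level, with zero-variance cells flagged.
Study-2-style dropout is emulated by randomly subsampling the retest
cohort to 22 of 60 (`retest_n`); whether real dropout was random is
unknown, so random is the neutral choice.

`run_study()` composes everything: cohort → wave 1 (choice task first, so
the criterion cannot be influenced by the measurement tasks; then the
adjusting battery and conjoint task in a randomized, recorded order) →
trait jitter → wave 2 → HB per wave → AUC profiles per method × wave →
validity (wave 1 only, by default) and stability statistics, replicated
`n_replicates` times under one master seed. Everything is deterministic
given `(config, seed)`, including the MCMC chains; per-respondent design
sub-seeds are derived from the master seed so designs differ across
respondents but reproduce exactly.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 60 (the larger
study session), 25 tasks, 20 study replicates, and HB chains of
1500–6000 iterations; the `hb_config()` default stays at 20000. AUC
arithmetic is asserted to $10^{-12}$; the MNL gradient to $10^{-6}$
relative against central finite differences; the MH sampler to 2% against
dense-grid integration on a 2-parameter toy. Part-worth recovery is
assessed on cohorts generated from known $b \sim N(a, 1.5^2 I)$ with
$a = (-1.5, -3.5, 1.5, 4)$ — the monotone preference pattern of the
published utility tables at a scale where the favored option is chosen
most but not all of the time. The heterogeneity SD of 1.5 reflects that
25 triples bound the per-coefficient posterior SE near 0.7 logits:
individual measurement is only meaningful when traits vary more than
that, as real conjoint heterogeneity does. At these settings the rank
correlation between posterior-mean and true utilities per attribute curve
exceeds 0.8; resolution of single coefficients across respondents is
lower (Spearman ≈ 0.7–0.8), which is the honest ceiling of 25 triples per
person.

## Limitations

The comparison inherits every assumption of the generator; in particular
the headline direction (conjoint more stable and more predictive) is a
consequence of the adjusting-noise assumption, as discussed. The MNL/HB
model is intentionally the analyst's model, not the generator's — the
multiplicative hyperbolic truth is not additive in dummy-coded levels — so
part of the estimation error is structural, as it would be with real
respondents. Holdout-task hit rates, mixture population models, partial
profiles and adaptive designs are out of scope.
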