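---
title: "Local continual reassessment for drug combinations: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local continual reassessment for drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locrm)
```

## The problem

A combination trial explores a grid of J doses of drug A crossed with K
doses of drug B.  Toxicity is assumed monotone in each drug separately
(the partial-ordering assumption), so only some dose pairs are comparable.
At phase-I sample sizes (around 50 patients for 15 combinations), global
dose–toxicity surfaces are hard to estimate and easy to misspecify.  The
designs in this package instead model only the immediate neighborhood of
the current dose and re-fit at every cohort, trading global coverage for
local stability.

## Local toxicity model

For current dose (j,k) the local set A holds the dose itself and its
one-step axis neighbors, clipped to the grid.  All complete orderings of A
consistent with componentwise dominance are enumerated by backtracking over
the local poset (`enumerate_orderings()`): 4 orderings at an interior dose,
2 at the (1,1) and (J,K) corners, 1 at (J,1) and (1,K), 2 along edges.  The
generic enumeration makes the edge cases fall out automatically; the tests
check it against a brute-force permutation filter and against the four
hand-written interior orderings.

Under ordering $O_i$, dose $(j,k)$ has rank $r_i(j,k)$ in A and the
empiric one-parameter CRM model applies:
$p^{(i)}_{jk} = \pi(r_i(j,k))^{\exp(a_i)}$ with prior
$a_i \sim N(0, \sigma_a^2)$, $\sigma_a^2 = 2$ by default (an
exponential-prior variant is available via `tox_bma(prior =
"exponential")`).  The skeleton $\pi$ is rebuilt for the current local-set
size by the indifference-interval recursion (`crm_skeleton()`): the
skeleton equals the target at the prior-MTD position, and neighboring
values solve the boundary conditions at target ± halfwidth (halfwidth
0.05 by default; 0.03 is a supported sensitivity setting).  Two anchoring
rules are offered for the prior-MTD position and the choice matters: the
default anchors it at the current dose's rank in the local set (so the
design treats the dose it stands on as the prior MTD guess); the
alternative puts it one position below the top, which makes every
neighborhood fit expect its MTD above the current dose and is therefore
noticeably more escalation-friendly.  Skeletons are memoized per (size,
position, halfwidth, target).

Per-ordering marginal likelihoods and posterior-mean toxicities are 1-D
integrals, computed by adaptive Gauss–Kronrod quadrature
(`stats::integrate`) on $a \in [-10, 10]$ — more than seven prior standard
deviations — with the log-likelihood shifted by its maximum on a coarse
grid for numerical stability.  A 20,001-point trapezoid oracle in the test
suite agrees to relative error below 1e-6 across randomized count tables.
Bayesian model averaging with equal prior model probabilities $1/I$ yields
the weighted estimate $\bar p_{jk}$.

## The LOCRM trial engine

Cohorts (default 3 patients, maximum 51) start at (1,1).  After each
cohort:

* **Safety.**  Any dose with at least `elim_min_n = 3` patients and
  $\Pr(p_{jk} > \phi_T \mid \mathrm{Beta}(1 + y, 1 + n - y)) > c_T$ is
  eliminated together with every dose dominating it.  The Beta(1,1) prior
  is the standard non-informative choice; one full cohort is required so a
  single patient cannot eliminate a dose.  If (1,1) is eliminated the
  trial stops with no selection.
* **Allocation.**  The next cohort goes to the non-eliminated dose in A
  with $\bar p$ closest to $\phi_T$; exact ties are split uniformly at
  random.  With no toxicity data this reduces to randomly escalating one
  drug by one level, because all orderings carry equal weight.  A
  *coherence restriction* (on by default, `coherence =`) forbids
  escalation to a strictly dominating dose immediately after a cohort that
  contained a DLT; without it the design treats one to two extra patients
  per trial at overly toxic combinations.
* **Selection.**  At the sample-size limit, per-dose Beta(1,1)
  posterior-mean DLT rates $(y + 0.5)/(n + 1)$ — the same posterior the
  safety rule evaluates — are smoothed by weighted bivariate isotonic
  regression (weights $n_{jk}$) and the tried, non-eliminated dose closest
  to $\phi_T$ is selected.  Equidistant estimates are frequent because
  observed rates are multiples of $1/n$ and isotonic pooling equalizes
  whole blocks; following the convention of established combination-design
  implementations, ties resolve through a $10^{-5}(j + k)$ perturbation of
  the fitted rates, i.e. toward the higher dose when the shared estimate
  sits below the target and toward the lower dose when above.

Untried cells enter the isotonic fit with value $\phi_T$ and weight
$10^{-6}$: in the limit this reproduces the projection restricted to the
tried cells, and untried doses are excluded from candidacy regardless.

## Bivariate isotonic regression

`biviso()` computes the weighted least-squares projection onto the cone of
matrices non-decreasing along both axes using Dykstra's
alternating-projection algorithm, with exact weighted pool-adjacent-
violators steps for the row-monotone and column-monotone cones.  Cyclic
row/column PAVA alone is not exact for the intersection cone; Dykstra's
increments make the iteration provably convergent to the projection.
Convergence is declared when a full cycle moves no entry by more than
1e-8 (1e-10 in the oracle tests).  A quadratic-programming oracle
(`pracma::quadprog`) confirms agreement to 1e-6 on random matrices.

## Efficacy model and the LOCRM12 engine

Efficacy is modeled on the extended neighborhood B (A plus diagonal
neighbors, up to 9 doses) by robit regression: the response probability is
the Student-t CDF with $v$ degrees of freedom evaluated at a quadratic
form in the standardized doses (mean 0, unit sample SD per drug).  The
quadratic terms let the fit track unimodal dose–response shapes; the
degrees of freedom interpolate between heavy-tailed and probit-like links
($v \approx 7$ approximates the logistic).  No interaction term is
included.  Priors: $\alpha \sim N(0, 1.3)$,
$\beta_1, \beta_2 \sim N(0.8, 1.3)$ (a positive slope mean favors
escalation early), $\gamma_1, \gamma_2 \sim N(0, 1.3)$, $v$ half-t with
df uniform on (2, 10) — the stated t(0,1,df) prior is truncated to
$v > 0$, the only positivity-respecting reading.

The posterior is sampled by adaptive random-walk Metropolis on
$(\alpha, \beta_1, \beta_2, \gamma_1, \gamma_2, \log v,
\mathrm{logit}\,df)$, implemented in compiled code against R's RNG so
`set.seed` gives bitwise reproducibility.  The proposal scale adapts
during burn-in toward ~0.3 acceptance; an acceptance rate outside
[0.05, 0.8] after adaptation is recorded as a diagnostic, not an error.
Default 3000 iterations with 1000 burn-in; the simulation studies shipped
with the package use 2000/500, which leaves operating characteristics
unchanged at the replication levels used.  Tests verify seed determinism,
prior-predictive behavior, recovery of a known surface at n = 200 per
dose, and invariance to the storage order of B.

LOCRM12 proceeds in two stages with $\phi_T = 0.35$, $c_T = 0.85$
(looser than MTDC finding, so that a slightly toxic but efficacious dose
remains reachable), $\phi_E = 0.2$, $c_E = 0.9$, $z = 2$:

1. **Startup** (budget 21): escalate one randomly chosen drug per
   DLT-free cohort; at a boundary the other drug moves; at the top corner
   the dose holds.  The first DLT (or the budget) hands over to the main
   stage.  Startup efficacy outcomes are kept — there is no reason to
   discard data.  Safety elimination runs during startup; futility does
   not (the model-based rule needs a fit, and the stage ends at the first
   DLT anyway).
2. **Main stage** (to 51 patients total): the admissible set Ã keeps the
   doses of A whose $\bar p$ does not exceed that of the local MTDC
   estimate, minus eliminated and futile doses.  The most efficacious
   member $(j^\dagger, k^\dagger)$ of Ã (by posterior-mean efficacy
   $\bar q$) is exploited if it is untried, if all of Ã is tried, or if
   $\bar q_{j^\dagger k^\dagger}$ exceeds the cutoff $((N - n)/N)^z$ with
   $N = 30$ and $n$ the main-stage enrollment (clamped at 0 once
   $n \ge N$, which happens when startup ended early); otherwise the
   untried admissible dose with the highest $\bar q$ is explored (ties
   random; a uniform-exploration variant is available).  Futility flags
   doses in B with at least 3 patients and
   $\Pr(q_{jk} < \phi_E) > c_E$; flags are permanent.  The coherence
   restriction is off by default here: the admissible set already caps
   estimated toxicity at the local MTDC and safety elimination runs
   continuously, so a further no-escalation rule makes the design doubly
   conservative.
3. **Selection**: among tried, non-eliminated doses the isotonic MTDC
   anchor is found as in LOCRM (at $\phi_T = 0.35$); the safe set keeps
   tried doses with isotonic toxicity no higher than the anchor's,
   excluding futile ones; the OBDC is the safe dose with the highest
   estimated efficacy, by default from a robit fit on all tried doses
   (`final_eff = "empirical"` switches to observed proportions), ties to
   the lower combination.  The trial stops with no selection if every
   dose is eliminated or futile.

When the local candidate set empties entirely, the engine de-escalates to
the nearest admissible dose dominated by the current one (largest
$j + k$; ties at the lower drug-A level) — the simplest rule consistent
with never jumping to an unexplored region.

## The simulator and what it does (not) emulate

Scenarios fix true per-dose DLT and response probabilities; cohort
outcomes are independent binomial draws from these marginals.  Real trials
correlate toxicity and efficacy within patients, accrue patients over
time, and suffer missing or late outcomes — none of which is modeled, so
passing operating-characteristic checks says nothing about those aspects.
The 16 bundled scenarios (5 x 3 grids; toxicity-only ones target
$\phi_T = 0.3$, joint ones $\phi_T = 0.35$ with raw doses 0.08–0.40 and
0.08–0.24) span monotone, unimodal and hostile surfaces, including one
grid where every dose is overly toxic and early stopping is the correct
outcome.  Derived dose classes per scenario: MTDCs (true toxicity exactly
at target), overdoses (above target), OBDCs (maximum-efficacy safe doses)
and target dose combinations, TDCs (safe doses with efficacy at least
0.45).

Replication draws one vector of well-separated per-trial seeds from the
base seed.  Consecutive integer seeds are deliberately avoided: they
produce correlated early Mersenne–Twister output, and because a trial's
first draws drive its startup path, adjacent replicates become visibly
correlated — batch selection percentages then swing several points beyond
binomial noise.  With scattered seeds, block-level dispersion matches the
binomial standard error (checked on a 3000-trial run).

The shipped studies use 1000–2000 trials per toxicity-only scenario and
250–500 per joint scenario, which puts Monte-Carlo standard errors on
selection percentages near 1–1.5 and 2–3 points respectively.

## Known limitations

* Two drugs only; the local-set machinery does not generalize as written
  to three or more agents.
* The efficacy model is intentionally underparameterized (5 coefficients
  for up to 9 cells); it smooths, it does not interpolate, and with
  saturated data it can disagree with empirical rates by a few points.
* Futile doses never re-enter, even if later neighborhood fits would have
  cleared them.
* The beta-binomial safety rule uses each dose's own counts only; it does
  not borrow strength across doses (by design — it must stay model-free).
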