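---
title: "Methods: simulating a cigarette tax reform with industry price-setting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a cigarette tax reform with industry price-setting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigsim)
```

## The policy problem

Brazil's Bill no. 3887-2020 replaces PIS/COFINS, a federal contribution on
company turnover, with the CBS, a general tax on goods and services whose
special regime for cigarettes charges **22% ad valorem on the highest
retail price of the brand in any state** plus a **specific 1.10 BRL per
20-cigarette pack**. Because the ad valorem base is the *national maximum*
price, a producer that sells a brand below that maximum pays the same CBS
amount while collecting less revenue per pack: its tax burden rises and
its markup falls. The economically interesting question is therefore not
only how much tax is due, but how the industry re-prices. `cigsim`
simulates three price-setting strategies and their consequences for
prices, consumption, and state-level tax collection.

## Tax algebra

A regime is a list of components, each either ad valorem (rate $a_j$ on a
declared base) or specific (amount $b_j$ in BRL/pack). Collapsing a
regime in state $s$ gives a combined ad valorem rate $\alpha_s$ and
specific amount $\beta_s$, so the per-pack tax at uniform national price
$p$ is $T_s(p) = \alpha_s p + \beta_s$ and the burden is $T_s(p)/p$.
Two inversions drive the scenarios:

* **minimum feasible price** — the smallest $p$ with
  $p - T_s(p) \ge c$ (unit cost $c$) and burden strictly below 100%:
  $p^\* = (\beta_s + c)/(1-\alpha_s)$, rounded **up** to the cent
  (rounding down would violate feasibility). If the closed form lands
  exactly on a cent with zero margin at $c = 0$, the next cent is the
  first feasible price.
* **price from a markup target** —
  $p = ((1+m)c + \beta_s)/(1-\alpha_s)$, with `markup_of()` as its exact
  inverse when rounding is disabled.

Both are verified against an independent 0.01-BRL grid-search oracle on
randomized instances in the test suite (1,000 draws in the acceptance
test).

```{r}
cbs <- tax_regime(list(
  tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
                base = "highest_national_brand_price"),
  tax_component("cbs_specific", "specific", amount = 1.10)))
assess(10.00, 14.00, "SP", cbs)$total_tax   # 14 * 0.22 + 1.10 = 4.18
floor_price(0, "SP", cbs)                   # 1.10 / 0.78 -> 1.42
```

### The default regimes

The statutory IPI rate schedule and the per-state ICMS rates on cigarettes
are not part of the package: both regimes are fully configuration-driven
(YAML or constructors), and the shipped defaults are *effective* rates on
the retail price. The ICMS "por dentro" (tax-inclusive) computation is
likewise represented as an effective rate on the retail price, since every
quantity the simulation reports is a burden on that price. The default
current regime (PIS/COFINS 11.15% + IPI 14.25% + 1.50 BRL specific + ICMS
around 25%, varying by state) was calibrated once so that the simulated
population-weighted baseline burdens are about 78/69/62% of the retail
price in the low/medium/premium categories, the published aggregate
pattern for the Brazilian market. The reform regime swaps PIS/COFINS for
the CBS components and leaves IPI and ICMS untouched. A pack is 20
cigarettes throughout.

## The two-part elasticity model

Demand sensitivity is estimated in two parts, per macro-region $r$ and
price category $k$:

* **prevalence (extensive margin)** — a probit of smoking status on the
  log state-average price interacted with region, controlling for age,
  gender, log income and education. The elasticity is the **average
  marginal effect** of log price (sample-representative, rather than the
  effect at the covariate means) divided by the region's mean prevalence.
* **conditional (intensive margin)** — among smokers, OLS of log
  cigarettes/day on the log state-average price *of the smoker's price
  category*, interacted with region and category, with the same controls
  plus years of smoking. Standard errors are heteroskedasticity-robust
  (HC1).

The total elasticity is the sum, $\varepsilon_{rk} =
\varepsilon^{prev}_r + \varepsilon^{cond}_{rk}$, an identity that holds
cell by cell by construction of `elasticity_table()`.

Design choices worth recording:

* **State-average price substitution.** Individually reported prices are
  endogenous (consumers down-trade after price rises), so both equations
  use state-level average prices; no instrumental-variable machinery is
  layered on top. Identification therefore comes entirely from
  cross-state price variation, which is why the generator places price
  variation at the state level and refuses configurations without it.
* **Years of smoking is excluded from the probit** (it is kept in the
  conditional equation). Smoking duration is an outcome of the decision
  modelled by the probit; conditioning the extensive margin on it is
  post-treatment conditioning and, in data where never-smokers have zero
  duration, can separate the model perfectly. In the intensive-margin
  equation duration is predetermined relative to current daily intensity.
* **Region-interacted price terms.** Prevalence elasticities differ by
  region, so the probit interacts log price with region; the conditional
  regression interacts it with region x category. Pooled survey years
  enter as a year indicator when present.

## The synthetic survey generator

Real smoking microdata (phone-survey and household-survey records) cannot
ship with the package, so every downstream stage is exercised on seeded
synthetic records with *known* generating elasticities.

What the generator emulates:

* 27 federative units with fixed regions and approximate populations;
  smoker shares between 4 and 13% of the population;
* a four-way price-category split with an illicit segment (PC1) strictly
  below the official 5.00 BRL floor and the legal market split in three
  equal parts (the percentile-based low/medium/premium classification);
* smoking status from a latent-index probit whose log-price coefficient
  $\gamma_r = \varepsilon^{prev}_r \bar P / \phi(\Phi^{-1}(\bar P))$
  reproduces the configured prevalence elasticity at the configuration's
  mean prevalence $\bar P$;
* log daily consumption linear in the log state-category price with the
  configured conditional elasticity as slope, plus covariate effects and
  Gaussian noise. Daily consumption is log-normal with median 12,
  truncated to [1, 60] and rounded to whole cigarettes (no distributional
  form is prescribed by the literature; this is a package choice).

Two semantics deserve emphasis. First, the configured `smoker_share` is
the share *at the national-average price*; realized state prevalence is
$\Phi(\Phi^{-1}(\text{share}_s) + \gamma_r(\log p_s - \log \bar p))$.
Without this convention a per-state share map and a generating price
coefficient would contradict each other, and state-level share noise
uncorrelated with price would swamp the price signal at realistic sample
sizes. Second, the consumption equation uses the *realized* state-category
mean price — the same regressor the estimator constructs — so parameter
recovery is a clean test of the estimator rather than of an
errors-in-variables correction.

Default prices rise linearly in a state price index that spans nearly the
full [0, 1] range *within* every region (cross-state price dispersion of
roughly ±25%, consistent with the price gaps that motivate cross-border
shopping), and the illicit share falls in the same index. Survey weights
default to 1 but are honoured everywhere so weighted data can be used.

What it does **not** emulate: real survey layouts and nonresponse,
cluster sampling designs, brand-level price heterogeneity within a
category, income-gradient selection into categories, or measurement error
in self-reported consumption. Passing recovery tests therefore show that
the estimators are consistent for the model they assume — not that the
published point estimates would be reproduced from the restricted
microdata.

## Calibration of the illicit market

Phone surveys understate the illicit segment, so the baseline is
calibrated: every legal category's smoker count is scaled by a single
national factor $(1-\delta)$ — the same proportional reduction in every
state — and the freed mass is added to PC1, until simulated yearly
revenue under current rules matches the observed 17.75 BRL billion 2019
collection. A proportional (multiplicative) rule is used rather than
subtracting equal percentage points because it can never drive a legal
share negative, which is exactly the constraint the procedure must
respect; a single national $\delta$ is used because a per-state
calibration is underdetermined by one aggregate revenue figure. Revenue
is linear and strictly decreasing in $\delta$, so the bisection (relative
tolerance $10^{-6}$) has a unique solution whenever the target does not
exceed the uncalibrated revenue; a zero target returns the full shift
with a warning. After calibration the illicit segment is **held fixed**
in every reform scenario: illicit prices track legal prices, credible
cross-price elasticities are unavailable, and a monitored tax
administration limits substitution into the illicit market — assuming
anything else would be arbitrary.

## Scenarios and demand response

All scenarios price uniformly across states within a category (pricing
below the national maximum only raises the burden), and each category's
price is the **maximum over states** of the state-level solution, because
the uniform price must be feasible in the state with the highest combined
rate:

* **I — minimum price adjustment**: the feasibility floor
  $\max_s (\beta_s + c_k)/(1-\alpha_s)$;
* **II — average pre-reform markup**: the markup inversion at the
  consumer-share-weighted average baseline markup $\bar m_k$, floored at
  the scenario I price (a safeguard: any non-negative markup already
  implies a price at or above the floor, so the constraint cannot bind
  mathematically, only through rounding);
* **III — maximum pre-reform markup**: the same inversion at
  $\max_s m_{sk}$.

Baseline markups $m_{sk} = (p_{sk} - T_s(p_{sk}) - c_k)/c_k$ come from
the calibrated market under current rules. Unit costs are configuration
inputs; the defaults (0.650 / 0.653 / 2.90 BRL for low/medium/premium)
were back-solved from the default baseline price grid so that every
state's implied markup is positive and low/medium brands share an almost
identical manufacturing cost — their price difference is markup, not
cost. That near-equality is what makes the scenario I floors of PC2 and
PC3 collapse to (essentially) one price; the premium cost is bounded
above by the cheapest premium state's net-of-tax price.

The demand response applies **linear point elasticities**: for a cell
with relative price change $\Delta$ against the state's own baseline
price, consumption scales by $1 + \varepsilon_{rk}\Delta$ and the smoker
count by $1 + \varepsilon^{prev}_r\Delta$, both floored at zero (a change
beyond the extrapolation limit $|\varepsilon\Delta| \ge 1$ clamps the
cell with a warning). The published comparison arithmetic is consistent
with the linear total form, so the package applies the total elasticity
to consumption exactly and derives intensity as consumption per remaining
smoker; the second-order cross-term between the margins is deliberately
left in the intensity, not in consumption. Smokers do not switch
categories, and PC1 cells never change. Aggregate per-category changes
are consumption-weighted across states.

## Numerical choices and degenerate inputs

* Prices from inversions are rounded up to the cent; reported money to
  0.01 BRL and percentages to 0.1 p.p.; internal arithmetic is unrounded.
* Bisection: relative revenue tolerance $10^{-6}$ on [0, 1].
* Empty survey cells (a small state with no sampled smokers in a
  category) aggregate to zero smokers with national category means as
  price placeholders, so scenario price arithmetic stays defined without
  affecting revenue or consumption.
* A configuration with zero cross-state price variance, shares that do
  not sum to 1, positive generating elasticities, or legal prices below
  the floor is rejected at construction; a revenue target above the
  uncalibrated revenue, a region without non-smokers, or a cost table
  implying negative markups raise immediate, named errors.

## Problem sizes

The default pipeline generates 50,000 respondents (roughly the scale of
the pooled phone-survey waves). The Monte-Carlo recovery experiment in
the acceptance suite uses 20 seeds at n = 50,000 with homogeneous
generating values (prevalence -0.24, conditional -0.60) and compares the
precision-weighted grand mean of the estimates — precision weighting is
the natural meta-analytic average here because sampling variances differ
by an order of magnitude across cells (the floor compresses PC2's
cross-state price spread). The oracle comparisons use 1,000 random
instances for the floor-price grid search and a 0.001 grid for the
calibration bisection.

## Limitations

Partial equilibrium only: no dynamics, no second-order price adjustments,
no endogenous illicit-market response, no brand-level pricing below the
category, and no income-level incidence analysis (categories are price
segments, not income groups). Statutory rate schedules are represented by
effective rates; anyone with access to the true schedules can supply them
through the regime configuration without touching the engine.
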