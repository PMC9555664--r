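---
title: "State-based synchrony and environmental buffering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-based synchrony and environmental buffering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggsync)
```

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which parameters matter, what the synthetic
generator does and does not emulate, and where we made genuine design
choices.

## 1. From calliper to time series

Egg volume is computed as $V = \beta L W^2$ with $L$, $W$ in millimetres
and $V$ in cm³; the species constants ($\beta = 0.476\times10^{-3}$ gull,
$0.509\times10^{-3}$ shearwater) are the standard morphometric pair for
these taxa and are validated (strictly positive) rather than hard-coded
into the arithmetic, so other taxa can be analysed by overriding them.

Aggregation is clutch-first: eggs are averaged within `nest_id` × year,
then clutch means within year. For single-egg clutches this is the plain
egg mean; for 3-egg gull clutches it prevents large clutches from
dominating the annual mean. Pooled per-egg averaging is available
(`clutch_first = FALSE`) but off by default.

Two data-hygiene decisions: a record with width > length raises a
*warning*, not an error, because real calliper data contain transcription
swaps; an `autoswap` flag can repair them. A year with zero clutches for a
species inside the study window is an *error*, because the synchrony
statistic is defined on contiguous series and silently skipping a year
would misalign the state sequences.

## 2. The synchrony statistic

Each interior point of a series of $k$ annual values is classified by the
inequalities against its neighbours into trough (1), increase (2), peak
(3) or decrease (4), giving a derived sequence of $k-2$ states. The four
conditions use $\le$ on the rising side and $>$ on the falling side, so
they partition *every* real triplet, ties included — a flat stretch is an
"increase". We deliberately add no jitter: tie-breaking is part of the
statistic's definition, and the partition property is verified exhaustively
in the test suite.

The state sequence is treated as a first-order Markov chain. The 4×4
transition matrix $\mathbf{T}$ is estimated by row-normalised transition
counts pooled over **both** series. Pooling is a design choice: the null
hypothesis is "two independent chains with *the same* dynamics", which is
only meaningful with a shared $\mathbf{T}$; a per-series option exists for
diagnostics. A state never observed as a source gets the uniform row
$(\tfrac14,\tfrac14,\tfrac14,\tfrac14)$ — this keeps $\mathbf{T}$
row-stochastic without distorting observed transitions the way global
pseudo-counts would.

At each year $t$ the occupancy vector $\mathbf{s}_t$ holds the proportion
of series in each state (entries 0, ½, 1 for two series) and the entropy
$H_t = -\sum_j s_{jt}\ln s_{jt}$ (with $0\ln 0 := 0$) measures state
disagreement: 0 when the series agree, $\ln 2$ when they differ. The null
expectation $\bar H_{null}$ is approximated by simulating pairs of
independent chains from $\mathbf{T}$, initial states drawn from its
stationary distribution, and pooling the per-step entropies over steps and
replicates (stationarity makes per-step expectations equal; per-step means
are retained for diagnostics). The synchrony score is
$\Phi_t = 1 - H_t/\bar H_{null}$: exactly 1 iff the series share a state,
around 0 under independence, negative when disagreement exceeds the null
expectation.

Numerical choices:

* **Stationary distribution** by power iteration from the uniform vector,
  max-norm tolerance $10^{-10}$, capped at $10^5$ iterations; an
  independent eigen-decomposition is used in the tests as an oracle, and
  non-ergodic matrices (unit eigenvalue with multiplicity > 1, e.g. the
  identity) are flagged on the returned vector.
* **Null replicate count** defaults to 10,000. At that size the pooled
  Monte-Carlo standard error of $\bar H_{null}$ is below $10^{-3}$ nats
  for a 16-step chain, an order of magnitude tighter than any decision
  made with it.
* **p-values** are one-sided toward synchrony (low entropy) with the
  add-one correction $p = (1 + \#\{H_{null} \le H_t\})/(1+n)$, so no
  year can report $p = 0$ from a finite simulation. The source analysis
  reported "significant" synchrony without stating a test; this explicit
  construction is our choice, and `alpha` (default 0.05) only labels the
  `summary()` output.
* **Degenerate nulls.** A short series can yield a fitted $\mathbf{T}$
  with an absorbing state; the stationary-start null then produces
  $\bar H_{null} = 0$ and $\Phi$ is undefined. We flag this with a warning
  and return `NA` scores rather than inventing a fallback. Downstream
  consumers that only need *perfect* synchrony can use the identity
  $\Phi_t = 1 \iff H_t = 0$, which needs no null at all — `code_synchrony()`
  and the acceptance checks rely on it.

## 3. Breakpoint cross-correlation

`split_cc()` reports the lag-0 Pearson correlation of the paired annual
means before and after a breakpoint year. Lag 0 matches the before/after
scalar summary the method complements; full lagged CCFs are deliberately
out of scope. The breakpoint year itself belongs to the "after" segment
(a closure taking effect in year $y$ first influences laying in year $y$);
both segments must hold at least 3 paired years. Spearman correlation is
available via `method` for heavy-tailed series.

## 4. The buffering GLM

The modelling frame has one row per species × year: response = annual mean
egg volume, `sync` = 1 in years of perfect synchrony, `wnao` = the winter
(December–March) NAO index, plus phase (before/after closure) and centred
year for the optional extended candidate set.

* **Standardisation.** The response is globally z-scored by default. The
  two species differ by several cm³ in raw volume; on the raw scale the
  species coefficient dwarfs every environmental effect and coefficients
  are not comparable across analyses. A `standardize = FALSE` option keeps
  the cm³ scale (the parameter-recovery study below uses it, because a
  generating slope in cm³ per NAO unit is only well defined there).
* **Likelihood and k.** Fits are ordinary least squares; the reported
  log-likelihood is the Gaussian ML value (residual variance RSS/$n$, not
  the unbiased estimator), and $k$ counts *slopes + intercept + residual
  variance*. Both conventions are forced by the AICc arithmetic of the
  published model table this package reproduces: with any other counting
  the printed values are unreachable. AICc
  $= -2\ell + 2k + 2k(k+1)/(n-k-1)$; when $n \le k+1$ the correction is
  undefined and the fit reports `NA` rather than an extrapolated value.
* **Candidate set.** All 18 hierarchical subsets of {Sp, Sync, W_NAO} with
  the three two-way interactions (an interaction only enters with both
  mains). Year and Closure main effects can be added
  (`candidate_specs(include_year=, include_closure=)`); they are off by
  default to keep one model per scientific hypothesis rather than per
  nuisance term.
* **Averaging** is full (zero-substitution) over the ΔAICc ≤ 4 set with
  renormalised weights; a term absent from a model contributes an estimate
  of 0 with variance 0, and the unconditional standard error
  $\sum_i w_i \sqrt{se_i^2 + (b_i-\bar b)^2}$ folds between-model spread
  into the interval. Conditional averaging would overstate support for
  weak terms that happen to appear only in a few models.
* **Intervals** are Wald, estimate ± 1.96·SE; significance is CI exclusion
  of zero, with a boundary at zero counting as overlap.
* **Phase slopes.** `phase_slopes()` fits the full
  species × W_NAO × phase model and extracts per-species per-phase NAO
  slopes and the gull's between-phase contrast via `emmeans`. The
  buffering percentage $100\,(1 - b_{gull}/b_{shearwater})$ per phase is
  reported as a descriptive ratio only: its denominator is itself a noisy
  estimate, so inference should rest on the slope contrasts, not on the
  percentage.

## 5. What the synthetic generator emulates

`sim_config()` encodes the study design: 18 breeding seasons (2002–2019),
a regime switch in 2010, a gull population whose egg volume is decoupled
from the environmental index before the switch (slope 0 plus extra
independent noise of 0.6 cm³) and coupled after it, and a shearwater
population coupled throughout. Defaults, chosen once as a realistic
emulation of the system:

| parameter | gull | shearwater | units / rationale |
|---|---|---|---|
| baseline volume | 82 | 78 | cm³, typical for the two species |
| coupled NAO slope | −0.4 | −0.4 | cm³ per index unit; the shared driver |
| annual process SD | 0.06 | 0.06 | cm³; sized so the coupled phase shows perfect synchrony in about 7 of the 9 interior post-closure years in the median replicate |
| buffered extra SD | 0.6 | — | cm³; subsidy-era idiosyncratic variation |
| clutches / year | 30 | 100 | study-like sampling effort |
| eggs / clutch | 3 | 1 | species biology |
| clutch-level SD | 1.5 | 1.5 | cm³ between-clutch spread |
| egg width | 49 ± 1 | 46.5 ± 1 | mm |
| index | N(0, 1), AR(1) ρ = 0 | | the index enters the models as an exogenous regressor, so only its marginal distribution matters; ρ is configurable |

Egg records are realised by drawing a clutch target volume, drawing a
width, and *solving* the length from $L = V/(\beta W^2)$ before rounding
both axes to 0.1 mm — so fixtures are exactly consistent with the volume
formula and the morphometric round-trip is testable down to rounding
error. Draws with $L \le W$ are redrawn (capped, then an error naming the
inconsistent configuration).

What it does **not** emulate: demographic structure, laying-order effects
within clutches, observation gaps, temporally autocorrelated process
noise, and any density dependence. Passing tests therefore demonstrate
that the *estimators* behave correctly under the assumed generative model,
not that real field data satisfy those assumptions.

One attenuation effect is worth knowing about: at study-like clutch
counts, the sampling error of the realised annual mean (clutch SD /
√clutches) is comparable to the annual process signal, so egg-level
analyses show weaker synchrony and wider slope intervals than analyses of
the latent annual series — visible in the bundled small fixture. This
mirrors a real property of morphometric proxies, and it is why the
statistical performance checks operate on the annual-series pathway while
the egg pathway is checked for round-trip fidelity.

## 6. Verification strategy and problem sizes

The test suite works at three levels. Exact oracles: the state partition is
enumerated over all 27 order patterns of a triplet, entropy is checked
against brute force on all 16 two-series state combinations, the stationary
distribution against an eigen-solver, and OLS coefficients against the
normal equations. Closed forms: under a uniform transition matrix
$\bar H_{null} = \tfrac34\ln 2$, checked at 10,000 simulations. Simulation
studies at the study's own scale ($n = 36$ species-years): CI coverage of
the model-averaged NAO slope over 500 replicates of the fully coupled
scenario; prevalence of the regime signature (correlation rise plus a
post-closure majority of perfectly synchronous years) over 200 replicates
of the buffered scenario; and the self-consistency of $\Phi$ — 2,000
independent length-18 chain pairs drawn from a fitted transition matrix,
scored against a 10,000-replicate null, average to zero synchrony. A
single 16-step pair has a Monte-Carlo standard deviation of roughly 0.15
in time-averaged $\Phi$, so only the ensemble mean is a sharp diagnostic;
that is why the self-consistency check averages over many pairs.
`scripts/acceptance.R` re-runs all of the above from scratch under a
user-supplied seed and writes the measured quantities as JSON.

## 7. Known limitations

* First-order Markov states only; longer memory or spectral/wavelet
  synchrony measures are out of scope.
* Two series only in the occupancy statistic as exposed here (the entropy
  generalises to $n$ series and `simulate_null()` accepts `n_series`, but
  the pipeline is written for the two-species design).
* The empirical p-value tests each year marginally; it makes no claim
  about runs of consecutive synchronous years.
* Wald intervals and z-quantiles throughout; at $n = 36$ a t-quantile
  would be ~4% wider. The coverage study quantifies the practical effect.
* The study window default (2002–2019, 18 seasons) is configurable; the
  source material describes the same records as a "fifteen-year period",
  an inconsistency we resolve in favour of the explicit year range.
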