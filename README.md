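# eggsync

Interspecific synchrony and environmental buffering of seabird breeding
investment.

## The problem

When two sympatric predators respond to the same environmental driver, their
vital rates should fluctuate in step (the Moran effect). Anthropogenic food
subsidies — landfill waste, fishery discards — can mask that coupling: a
subsidised consumer is *buffered* from environmental stochasticity, and its
dynamics decouple from those of an unsubsidised neighbour. Removing the
subsidy should reveal the underlying synchrony.

`eggsync` implements the analysis chain used to test this
*subsidy-decoupling* hypothesis on annual mean egg volume — a proxy of
breeding investment in income-breeding seabirds — for a yellow-legged gull
(subsidised by a landfill until its closure) and a Scopoli's shearwater
population breeding on the same island. The raw field data are not public,
so the package ships a seeded synthetic generator that emulates the study
design end to end; every statistical property is tested against it.

## Methods in brief

**Morphometrics.** Egg volume is V = β·L·W² (L, W in mm, V in cm³) with
species-specific constants β = 0.476×10⁻³ (gull) and 0.509×10⁻³
(shearwater). Eggs are averaged within clutch, clutch means within year,
giving one contiguous annual series per species.

**State-based Markov-chain synchrony.** Each interior year of a series is
classified by its neighbours into four states — trough (1), increase (2),
peak (3), decrease (4). A shared 4×4 transition matrix **T** is estimated
from the pooled state sequences. At each year the occupancy entropy
H_t = −Σ_j s_j ln s_j of the state distribution across series is compared
with its expectation under independent stationary chains driven by the same
**T** (approximated by Monte-Carlo simulation), giving the synchrony score

    Φ_t = 1 − H_t / H̄_null

Φ_t = 1 means both series occupy the same state (perfect synchrony); values
near 0 are what independence predicts. A one-sided empirical p-value with
add-one correction accompanies each year.

**Breakpoint cross-correlation.** Lag-0 Pearson correlation of the paired
annual means before vs after a breakpoint year (the closure year counts as
"after").

**Environmental buffering GLM.** Gaussian identity-link models of annual
mean egg volume (z-scored by default) on species, a binary perfect-synchrony
indicator, and the December–March NAO index (W_NAO), over all 18
hierarchical candidate subsets with two-way interactions. Models are ranked
by AICc (k counts intercept *and* residual variance), candidates within
ΔAICc ≤ 4 are combined by full (zero-substitution) model averaging, and an
effect is called significant when its Wald 95% CI excludes zero. Per-phase,
per-species W_NAO slopes and their contrasts quantify buffering.

## Worked example

The package bundles a small synthetic data set (8 gull clutches × 3 eggs and
15 shearwater single-egg clutches per year, 2002–2019, regime switch in
2010) under `inst/extdata/`:

```r
library(eggsync)
eggs <- system.file("extdata", "synthetic_eggs.csv", package = "eggsync")
env  <- system.file("extdata", "synthetic_wnao.csv", package = "eggsync")
rep  <- run_pipeline(eggs, env, n_sims = 10000, seed = 1)
print(rep)
```

```
eggsync pipeline report
=======================
State-based Markov-chain synchrony analysis
  years: 2003-2018 (k-2 = 16 interior points)
  H_null_mean = 0.5007 nats (10000 null sims)
  perfectly synchronised years (Phi_t = 1): 2003, 2004, 2005, 2010, 2011, 2012, 2013, 2018
Cross-correlation around 2010: before = 0.369 (n = 8), after = 0.580 (n = 10)

Top of the AICc table:
                                     model k loglik  aicc delta_aicc  weight
            Sp + Sync + W_NAO + Sync:W_NAO 6 5.2600 4.377      0.000 0.36926
 Sp + Sync + W_NAO + Sp:W_NAO + Sync:W_NAO 7 6.2772 5.446      1.069 0.21637
  Sp + Sync + W_NAO + Sp:Sync + Sync:W_NAO 7 5.4160 7.168      2.791 0.09145
                                Sp + W_NAO 4 0.9787 7.333      2.956 0.08421
                         Sp + Sync + W_NAO 5 2.1995 7.601      3.224 0.07365

Averaged coefficients (delta AICc <= 4, 5 model(s)):
             term  estimate      se    ci_lo    ci_hi significant
      (Intercept) -0.909320 0.06589 -1.03847 -0.78017        TRUE
      speciesgull  1.892009 0.07967  1.73585  2.04817        TRUE
             sync -0.119199 0.08612 -0.28799  0.04959       FALSE
             wnao -0.091001 0.05579 -0.20036  0.01835       FALSE
        sync:wnao -0.124681 0.08058 -0.28262  0.03326       FALSE
 speciesgull:wnao  0.021665 0.03900 -0.05478  0.09811       FALSE
 speciesgull:sync -0.008563 0.02603 -0.05959  0.04246       FALSE
```

Reading this: cross-correlation rises across the 2010 breakpoint (0.37 →
0.58) and a block of perfectly synchronised years (Φ_t = 1) appears from
2010 onward, the qualitative signature of subsidy decoupling. The gull's
eggs are larger on the standardised scale (`speciesgull` positive and
significant); the environmental and synchrony effects are present but not
individually significant at this small fixture size — egg-level sampling
noise (few clutches per year) attenuates both, which is the expected
behaviour, not a defect. With more clutches per year (e.g. the generator
defaults of 30 and 100) the environmental slope is recovered with ≈95% CI
coverage; `scripts/acceptance.R` measures exactly that.

Single stages are exposed as functions (`annual_series()`,
`run_synchrony()`, `split_cc()`, `model_selection()`, `model_average()`,
`phase_slopes()`, `simulate_dataset()`) and as subcommands of the optional
CLI:

```sh
Rscript inst/scripts/eggsync.R run-all --eggs eggs.csv --env wnao.csv --out results/
```

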