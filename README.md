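# partsaCEA

Partitioned-survival cost-effectiveness analysis of first-line
pembrolizumab + gemcitabine/cisplatin versus gemcitabine/cisplatin for
advanced biliary tract cancer (ABTC), with country-specific inputs for
China, Japan, the United States and Switzerland.

The package is a complete, tested pipeline for analysts doing
trial-based economic evaluation when individual patient data are not
public:

1. **Synthetic trial generation** — two-arm pseudo-data (per-subject PFS
   and OS with PFS ≤ OS by construction, administrative censoring and
   dropout), calibrated exactly to published medians (experimental arm:
   OS 12.7 months, PFS 6.5 months, n = 533).
2. **Kaplan–Meier digitization and pseudo-IPD reconstruction** — the
   Guyot-style interval-by-interval allocation from digitized curve
   coordinates plus numbers-at-risk tables.
3. **Parametric survival fitting** — right-censored maximum likelihood
   for exponential, Weibull, gamma, log-logistic and lognormal families;
   model selection by AIC/BIC with deterministic tie-breaks.
4. **Three-state partitioned survival model** — occupancy
   `π_PFS = min(S_PFS, S_OS)`, `π_death = 1 − S_OS`,
   `π_PD = S_OS − π_PFS` over 174 21-day cycles (10 years), vial-rounded
   BSA dosing, treatment caps (pembrolizumab 35 cycles, cisplatin 8),
   second-line FOLFOX/immunotherapy/BSC mixture, first-cycle adverse-event
   costs, end-of-life costs, discounting, and
   `ICER = ΔCost / ΔQALY` with explicit dominance statuses.
5. **Uncertainty analysis** — one-way DSA (tornado), 5,000-draw PSA with
   moment-matched gamma/beta parameter distributions and optional
   survival-parameter sampling, CEAC and ICE-quadrant summaries, and
   pembrolizumab price-reduction scenario/threshold analysis.

All model inputs (per-vial drug prices, AE costs and probabilities,
per-cycle costs, utilities, BSA, discount rate, WTP threshold) live in
one YAML config per country; the four published configurations ship with
the package and are verified field-by-field against a checked-in copy of
the published input table.

## Worked example

```r
library(partsaCEA)

res <- run_pipeline(builtin_configs()[["china"]],
                    specs = default_arm_specs(seed = 42))
print(res)
#> <pipeline_result>
#>   selected families: experimental.os gamma, experimental.pfs lognormal,
#>                      control.os gamma, control.pfs lognormal
#>   max reconstruction error: 0.0014
#> <cea_result> china
#>   experimental: cost    75,595.36  QALY 0.9194
#>   control     : cost    10,776.52  QALY 0.8296
#>   incremental : cost    64,818.84  QALY 0.0898
#>   ICER: 722,058.8 USD/QALY (WTP 37,663)
```

Reading the output: with median-calibrated synthetic curves, adding
pembrolizumab buys ~0.09 discounted QALYs at ~$64,800 extra discounted
cost per patient in China, an ICER of ~$722,000/QALY — roughly nineteen
times the Chinese willingness-to-pay threshold of $37,663/QALY. The
reconstruction stage introduced at most 0.0014 absolute deviation in the
KM curves, and per endpoint/arm the best-fitting of the five families was
selected by AIC. Sensitivity and scenario analysis continue from the same
context:

```r
ctx <- res$context
head(one_way_dsa(ctx), 3)        # tornado: pembrolizumab price, u_PFS lead
draws <- run_psa(ctx, n_draws = 5000, seed = 1)
ice_quadrants(draws)             # essentially all draws in quadrant I
price_threshold_for_wtp(ctx)     # >95% price cut needed in China
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/partsa-cli.R` with subcommands `simulate`, `reconstruct`,
`fit`, `run`, `dsa`, `psa`, `scenario`, e.g.

```sh
Rscript inst/cli/partsa-cli.R run --country japan --seed 42 --out japan
```

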