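# odkinetics

Mass-transfer kinetics of osmotic dehydration (OD) in R.

Osmotic dehydration immerses plant tissue (apple slices, typically ~20 g
samples) in a concentrated solution of an osmotic agent — sucrose, a
sugar alcohol such as erythritol, xylitol or maltitol, or
dihydroxyacetone (DHA) — so that water leaves the tissue while some
solute enters it. A bench study records, per solute, replicate and
immersion time τ (min), the sample mass m and dry-matter mass fraction s.
`odkinetics` turns such tables into the field's kinetic parameters, fits
the standard empirical models, and runs the accompanying treatment
statistics. It is aimed at food-process engineers analysing OD (or
similar sorption/desorption) experiments.

## What it computes

From the mass balance, per sample and time (then averaged over
replicates):

* water content `WC = (1 − s_τ)/s_τ` (g H₂O/g d.m.)
* solid gain `SG = (s_τ·m_τ − s₀·m₀)/(s₀·m₀)`
* water loss `WL = [(1 − s₀)·m₀ − (1 − s_τ)·m_τ]/(s₀·m₀)`
* true water loss `WL_T = WL/(1 + SG)` — water loss corrected for the
  concurrent solute uptake
* the dehydration-to-impregnation ratio `CR = WL_T/WL = 1/(1 + SG)`

Each response series Y(τ) can be fitted with three families:

* Peleg: `Y = Y₀ ± τ/(k₁ + k₂·τ)` — 1/k₁ is the initial rate, Y₀ ± 1/k₂
  the equilibrium value
* Kelvin–Voigt: `Y = A·(1 − exp(−τ/B))` — saturation to A with time
  constant B (min)
* Burgers: `Y = A·(1 − exp(−τ/B)) + C·τ` — adds a constant-rate period
  with velocity C

by bounded Levenberg–Marquardt least squares, with the four fit
statistics used in this literature: R², reduced χ² `= SS/(N − n)`,
`RMSE = sqrt(SS/N)` and the coefficient of residual variation
`CRV = 100·sqrt(χ²)/mean(Y)`; fits with CRV < 20 % are flagged usable for
prediction. Treatment effects are assessed with a main-effects two-way
ANOVA (solute × time), Tukey HSD contrasts with compact letter groups,
and Pearson correlation of water activity against water content. A
study simulator (`generate_study()`) produces complete raw-measurement
tables from known true kinetics — its defaults reproduce the published
five-solute apple study design — so the whole chain is testable without
laboratory data.

## Worked example

```r
library(odkinetics)

study <- generate_study(od_sim_config(seed = 42))   # 5 solutes x 7 times x 2 reps
kin   <- kinetics_table(study$measurements, study$initial)
kin$averaged[kin$averaged$solute == "sucrose", ]
#>     solute tau_min       WC        SG        WL       WLT        CR
#> 22 sucrose       0 5.690000 0.0000000 0.0000000 0.0000000        NA
#> 23 sucrose      30 3.192318 0.4876676 0.9409012 0.6324629 0.6721934
#> 24 sucrose      60 2.750723 0.6027549 1.2815595 0.7996344 0.6239644
#> 25 sucrose      90 2.540819 0.6510274 1.4951081 0.9055613 0.6056907
#> 26 sucrose     120 2.382838 0.6773006 1.6932643 1.0095175 0.5961960
#> 27 sucrose     150 2.268266 0.6813239 1.8763174 1.1159764 0.5947703
#> 28 sucrose     180 2.094756 0.7198961 2.0872499 1.2135874 0.5814311
```

After 3 h in 50 % sucrose the simulated tissue has lost ~2.09 g water and
gained ~0.72 g solids per g initial dry matter; the ratio CR ≈ 0.58 shows
substantial impregnation alongside the dehydration. Fitting the
water-loss series:

```r
av  <- kin$averaged[kin$averaged$solute == "sucrose", ]
fit <- fit_model(av$tau_min, av$WL, "burgers")
fit
#> Kinetic model fit: burgers
#>   parameters: A = 0.924076, B = 17.9657, C = 0.00641973
#>   N = 7, n = 3 | R2 = 0.9999, chi2 = 4.951e-05, RMSE = 0.005319, CRV = 0.53%
#>   usable for prediction (CRV < 20%): TRUE
```

The recovered parameters sit close to the generating truth (A = 0.941,
B = 19.074, C = 6.332e-3): a saturating loss of ~0.92 g/g with an
18-min time constant plus a sustained constant-rate loss of
~0.0064 g/g per min. Comparing all families per solute:

```r
best_model(fit_report(kin, responses = "WL"))
#>       solute       family     A    B        C k1 k2    R2 CRV_pct usable
#> 1        DHA      burgers 1.250 25.0 0.000615 NA NA 1.000   0.103   TRUE
#> 2 erythritol kelvin_voigt 1.552 36.8       NA NA NA 0.999   2.004   TRUE
#> 3   maltitol      burgers 0.560 25.6 0.002080 NA NA 0.999   1.682   TRUE
#> 4    sucrose      burgers 0.924 18.0 0.006420 NA NA 1.000   0.525   TRUE
#> 5    xylitol      burgers 0.991 20.8 0.003096 NA NA 1.000   1.170   TRUE
```

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/odkin.R`): subcommands `simulate`, `kinetics`, `fit`, `stats`
and `report` (which chains the last three); every run writes a
`manifest.json` recording inputs, outputs, seed and package version.

```sh
Rscript inst/cli/odkin.R simulate --out study --seed 42
Rscript inst/cli/odkin.R report --measurements study/measurements.csv \
    --initial study/initial.csv --out study/report
```

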