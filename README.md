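# seatrade

Dietary exposure to persistent hydrophobic contaminants — short-chain
chlorinated paraffins (SCCPs) being the motivating case — reaches people
through seafood, and interprovincial trade redistributes that exposure away
from the contaminated coastlines where the seafood was caught. `seatrade`
implements the full exposure-through-trade chain as a tested, seeded R
pipeline for exposure scientists and food-safety modellers:

1. **Synthetic world** — seeded generation of coastal contaminant fields
   (nearshore-high, lognormal), species biology, provincial supply/demand,
   distances, and noisy observed trade flows, so the whole analysis is
   runnable and testable without any external data. Real tabular inputs
   with the same file contracts can be swapped in.
2. **Food web** — steady-state bioaccumulation per species *i*:
   `C_i (k2 + kE + kG + kM) = 1e-3 k1 [(1-φ)C_w + φ C_pw] + kD (Σ_j P_ij C_j + diet bases)`,
   solved as one linear system over all species, with benthic sediment
   exposure via diet and pore water (`C_pw = 1000 C_sed / (f_oc K_oc)`,
   `K_oc = 0.35 K_ow`).
3. **Trade** — doubly-constrained Leontief–Strout gravity flows
   `T_ij = a_i b_j S_i D_j d_ij^(-β)` balanced by iterative proportional
   fitting, a slack destination for the national supply surplus, exponent
   recovery from observed flows, and the diagonal no-trade counterfactual
   `T_ii = min(S_i, D_i)`.
4. **Exposure** — provincial estimated daily intake
   `EDI = C̄ · I / W` (ng·kg⁻¹·day⁻¹, W = 63 kg default), scenario
   differencing `EDI_DF = EDI_T − EDI_NT`, origin attribution, the
   population-weighted trade-embodied share of national exposure,
   model-evaluation metrics (MB, NMB, R², factor-2/5 coverage) and
   multiplicative uncertainty intervals.
5. **Optimizer** — per-species transportation LP minimising
   `w_c · cost/cost₀ + w_h · EDI/EDI₀` subject to supply caps and demand
   equality, with the health coefficients constructed so the second term
   *is* the population-weighted national mean EDI; includes a cost–health
   Pareto sweep.

## Worked example

```r
library(seatrade)
cfg <- default_run_config(seed = 1)   # 31 provinces, 11 coastal
dir <- tempfile()
run_pipeline(cfg, dir)
```

```
[info] simulate: 31 provinces (11 coastal), seed 1
[info] foodweb: 11 regions x 8 species
[info] trade: estimated beta = 1.0008
[info] expose: national mean EDI 1.159 ng/kg/day; trade-embodied 81.71%
[info] optimize: national EDI change -10.49%
```

Reading it: the gravity exponent recovered from the noisy synthetic flow
table is 1.0008 (true value 1); the population-weighted national mean EDI
under trade is 1.159 ng·kg⁻¹·day⁻¹, of which 81.7% is embodied in
interprovincial trade (eaten in a different province than it was produced);
health-aware re-routing at equal cost/health weights lowers the national
mean EDI by 10.5%. The per-province tables are written alongside:

```r
head(read_csv_strict(file.path(dir, "edi_total.csv"))[,
     c("province", "edi_t", "edi_nt", "edi_df", "rel_change_pct")], 4)
#>   province    edi_t   edi_nt      edi_df rel_change_pct
#> 1      P01 2.357655 2.439738 -0.08208396      -3.481594
#> 2      P02 2.421994 2.567501 -0.14550726      -6.007746
#> 3      P03 1.890338 2.592251 -0.70191281     -37.131595
#> 4      P04 3.039374 2.917838  0.12153647       3.998734
```

Province P03 is a coastal province whose local waters are relatively
contaminated: trade cuts its EDI by 37% because it imports cleaner seafood,
while P04's EDI rises 4% for the mirror-image reason. `metrics.json` in the
same directory holds the evaluation metrics (here MB −0.32 ng·g⁻¹ ww,
R² 0.68, 94.3% of species–region pairs within a factor of 2 of the
synthetic measurements) and the NOAEL margin (national mean EDI is ~1e-7 of
the 10 mg·kg⁻¹·day⁻¹ reference level).

A command-line wrapper with per-stage subcommands ships in the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "seatrade.R", package = "seatrade"))')" \
    run-all --config inst/extdata/example_config.json --seed 4 --out out/
```

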