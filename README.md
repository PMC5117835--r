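# methanemix

Quantifies methane-derived — and potentially *ancient* — carbon subsidies to
floodplain-aquifer invertebrate food webs from stable-isotope and
radiocarbon data. Gravel-bed river aquifers carry almost no labile organic
carbon yet support abundant amphibitic stoneflies; methane-oxidizing
bacteria (MOB), strongly ¹³C-depleted and carrying the radiocarbon age of
whatever organic matter the methane came from, are the suspected basal
resource. The package is aimed at isotope ecologists and biogeochemists
working with well-based groundwater sampling.

## What it computes

* **Radiocarbon algebra** — conversions among conventional age
  (t = −8033 ln F), fraction modern F, and Δ¹⁴C = (F − 1)·1000 ‰, plus the
  two-endmember mass-balance bound on the radiocarbon-dead share of a
  mixture, x = 1 − e^(−t/8033) (`max_dead_fraction()`). Mixing is linear in
  F, never in age.
* **Gas chemistry** — Henry's-law mole balance recovering dissolved
  CH₄/C₂H₆/C₃H₈ from headspace-equilibrated vials
  (`dissolved_from_headspace()`), detection-limit censoring, and the
  Bernard ratio C₁/(C₂+C₃) with its thermogenic (<100) / methanogenic
  (>1000) thresholds.
* **Methane genetic classification** — Schoell-diagram (δ¹³C, δ²H) field
  assignment with editable polygon data, and Rayleigh modelling of
  oxidation's ¹³C enrichment.
* **Two-source δ¹³C mixing** — per-individual methane-derived carbon
  fractions `f = (δ_bio − δ_OM)/(δ_MOB − δ_OM)` under "average"
  (δ_MOB = −68.79 ‰) and "conservative" (−100.86 ‰) MOB endmembers, with
  well-stratified floodplain summaries and the ln(age + 1000) dependence
  regression.
* **Bayesian (δ¹³C, Δ¹⁴C) mixing** — `mix_fit()`, a SIAR-style
  Dirichlet-prior MCMC model partitioning each well's biomass among
  organic matter, modern methane and aged/ancient methane across four
  source scenarios (`build_scenarios()`), with `print`/`summary`/`coef`/
  `plot`/`simulate`/`residuals` methods.
* **Synthetic floodplain** — `simulate_floodplain()` generates the full
  CSV bundle (gas, methane isotopes, biomass, ground truth) from known
  per-well source proportions, and `run_pipeline()` orchestrates the whole
  analysis with byte-deterministic, provenance-stamped outputs.

## Worked example

```r
library(methanemix)

# printed study constants: Nyack floodplain mean biomass delta-13C
100 * f_methane(-55.1)[1:2]
#>    f_avg  f_cons
#> 66.57715 37.34082        # 66.6% average / 37.3% conservative estimate

max_dead_fraction(6900)
#> 0.5763962               # up to 58% radiocarbon-dead methane at 6,900 yr BP

# a synthetic floodplain with known truth, analysed end to end
b <- simulate_floodplain(floodplain_config(seed = 42))
floodplain_table(b$biomass)
#>   floodplain n_wells n_insects pct_conservative pct_conservative_se pct_average
#> 1        SYN       7       140         21.79718            3.896592    38.86347
#>   pct_average_se mean_d13c mean_d13c_se n_out_of_range
#> 1       6.947465 -43.74848     2.845681              2

fit <- mix_fit(data.frame(d13c = b$biomass$d13c_permil,
                          d14c = b$biomass$d14c_permil),
               group = b$biomass$well_id,
               scenario = build_scenarios()[["Avg-Aged"]], seed = 42)
fit
#> Bayesian isotope mixing model (scenario Avg-Aged)
#>   140 observation(s), 7 group(s), 3 sources, tracers: d13c, d14c
#>   10000 iterations (1000 burn-in), seed 42
#> Posterior mean proportions:
#>     methane_aged methane_modern organic_matter
#> W01        0.022          0.074          0.904
#> W02        0.403          0.258          0.339
#> ...
```

The posterior means recover the generator's truth (well W01 was built at
90 % organic matter, W02 at 40 % aged methane / 25 % modern methane), and
the floodplain percentages say that roughly 22–39 % of synthetic stonefly
biomass carbon is methane-derived, bracketed by the conservative and
average MOB endmember assumptions.

A thin command-line wrapper ships in `inst/cli/methanemix`
(`methanemix simulate|validate|all`).

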