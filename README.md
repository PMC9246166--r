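# pmfteq

Source apportionment and probabilistic cancer-risk assessment for the 16
US-EPA priority polycyclic aromatic hydrocarbons (PAHs) in surface soils.

Soil PAH surveys routinely report total burdens, but management decisions
need to know *which emission sources* carry the burden — and, because the
16 priority compounds differ in carcinogenic potency by three orders of
magnitude, which sources carry the *toxicity*. `pmfteq` is aimed at
environmental scientists and risk assessors who have (or can compile)
sample-by-compound concentration tables and want a reproducible chain from
raw concentrations to source-resolved toxicity and lifetime cancer risk.

## What it computes

1. **Screening.** Isomer diagnostic ratios — BaA/(BaA+Chr), Flt/(Flt+Pyr),
   Ant/(Ant+Phe) — with the standard literature breakpoints, and a
   correlation-matrix PCA (eigenvalue > 1 retention, varimax rotation) with
   multiple-linear-regression apportionment of the total burden to
   components.
2. **Receptor modelling.** An uncertainty-weighted positive matrix
   factorization: X ≈ G·F with G ≥ 0 (n samples × p source contributions)
   and F ≥ 0 (p × 16 source profiles), minimizing

   Q = Σᵢⱼ (eᵢⱼ / uᵢⱼ)², eᵢⱼ = xᵢⱼ − (G·F)ᵢⱼ,

   where the measurement uncertainty is equation-based:
   uᵢⱼ = 5/6·MDLⱼ when xᵢⱼ ≤ MDLⱼ, else √((EFⱼ·xᵢⱼ)² + MDLⱼ²).
   The solver uses multiplicative updates with multi-start seeding and an
   exact alternating weighted-NNLS polish; `scan_factors()` explores p = 3…8
   and recommends a factor count from the pooled R² and the dof-normalized
   Q improvement.
3. **Toxicity apportionment.** BaP-equivalent toxicity
   BaP_TEQ = Σᵢ TEFᵢ·cᵢ (Nisbet–LaGoy TEFs) is distributed over the fitted
   sources via (PAHᵢ)ₖₚ = Sₖₚ·fᵢₚ and (BaP_TEQ)ₖₚ = Σᵢ TEFᵢ·(PAHᵢ)ₖₚ, so each
   source's share of the carcinogenic potency is explicit and sums to 100%.
4. **Risk.** Adult incremental lifetime cancer risk (ILCR) through soil
   ingestion, dermal contact and particulate inhalation, with USEPA-style
   exposure defaults and cube-root body-weight-adjusted slope factors;
   concentration uncertainty is handled by fitting candidate distributions
   (log-normal, gamma, Pareto, Weibull, normal; Anderson–Darling selection)
   and propagating 10,000 Monte Carlo draws to a 95th-percentile high-end
   estimate, classified against the 10⁻⁶ / 10⁻⁴ risk bands.

The package bundles a 41-study literature table of PAH burdens in urban,
suburban and rural soils of the Beijing–Tianjin conurbation
(`load_study_table()`), and a synthetic mixture generator
(`simulate_dataset()`) whose four source profiles and contribution
distributions are calibrated to that table, so the full chain is testable
end to end with known ground truth.

## Worked example

Study-table workflow — group statistics, contamination census and
probabilistic risk:

```r
library(pmfteq)
tab <- load_study_table()
urban <- tab[tab$land_use == "urban", ]

summarize_group(urban, "bapeq", "mean")   # 121.6364  (ng/g BaP-equivalents)
count_by_level(urban)
#>     not_contaminated  weakly_contaminated         contaminated
#>                    0                    4                    2
#> heavily_contaminated
#>                    5

fit <- fit_best_distribution(urban$bapeq)
#> Best-fit distribution: lognormal (AD = 0.1964)
#>  meanlog    sdlog
#> 4.632296 0.590997
monte_carlo_ilcr(fit, n_iter = 10000, seed = 1)
#> Monte Carlo ILCR (lognormal, 10000 draws): 95th percentile 1.45e-06 (low_risk)
```

The high-end (95th percentile) adult cancer risk for urban soils, 1.45e-06,
sits above the 10⁻⁶ safe level but far below the 10⁻⁴ marginal-safety
threshold: a low risk level.

Full-chain workflow on a synthetic four-source mixture (n = 50 samples):

```r
sim <- simulate_dataset(n = 50, seed = 1)
u <- build_uncertainty(sim$x)
model <- fit_pmf(sim$x, u, p = 4, n_starts = 8, seed = 2, max_iter = 2500)
#> PMF model: 4 factors, 50 samples x 16 compounds
#> Q = 634.379, R^2 = 0.9743, converged: TRUE

norm <- normalize_profiles(model)
norm$labels <- label_sources(norm)
round(setNames(source_contribution_percent(norm), norm$labels), 1)
#> vehicular_emission biomass_combustion    coal_combustion         petrogenic
#>               32.5               27.1               23.5               16.9
round(apportion_teq(norm)$share, 1)
#> vehicular_emission biomass_combustion    coal_combustion         petrogenic
#>               21.6               57.2               12.6                8.6
```

Note how the toxicity shares differ sharply from the mass shares: biomass
combustion carries 27% of the PAH mass but 57% of the BaP-equivalent
toxicity, because its profile concentrates on the high-TEF 5–6 ring
compounds. `run_pipeline(pipeline_config(...))` chains every stage and
writes per-stage CSVs plus a JSON summary.

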