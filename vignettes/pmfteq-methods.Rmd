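---
title: "Methods: PMF source apportionment, BaP-TEQ toxicity and probabilistic ILCR for soil PAHs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMF source apportionment, BaP-TEQ toxicity and probabilistic ILCR for soil PAHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `pmfteq`, the choices
behind their defaults, the numerical conventions, and the limitations a
user should keep in mind. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

# The data model

All concentration tables are samples × the 16 US-EPA priority PAHs in a
fixed catalog order (naphthalene through benzo[g,h,i]perylene), units
ng g⁻¹ dry soil. The catalog (`default_catalog()`) carries, per compound:

* **ring count** (2–6), used to group low-molecular-weight (2–3 ring) vs
  high-molecular-weight (4–6 ring) compounds. Conventional structural ring
  counts are used (Flt and BaA are 4-ring; BbF/BkF/BaP/DBahA 5-ring;
  IND/BghiP 6-ring), which keeps the LMW marker set at
  Naph/Acy/Ace/Flu/Phe/Ant — the set relevant for petrogenic screening.
* **TEF**, the toxic equivalency factor of the Nisbet–LaGoy scheme
  (BaP = DBahA = 1; Ant, Chr, BghiP = 0.01; BaA, BbF, BkF, IND = 0.1;
  the remaining 2–4 ring compounds 0.001).
* **MDL** (method detection limit, ng g⁻¹) and **error fraction**
  (relative measurement uncertainty, dimensionless). Compilations rarely
  publish these, so the package defaults — MDL 1 ng g⁻¹, error fraction
  0.1 — are configuration values typical of GC-MS soil analyses, not
  measured constants; both are per-compound overridable via a catalog CSV.

Values below the MDL are substituted at MDL/2 and flagged
(`substitute_below_mdl()`), the common receptor-modelling pre-treatment.

The bundled study table (`load_study_table()`) compiles 41 literature
records of total PAHs and BaP-equivalents in urban (11), suburban (11) and
rural (19) surface soils of the Beijing–Tianjin conurbation. Two
inconsistencies in the source compilation are preserved rather than
repaired: the stated overall concentration range starts at 175.7 ng g⁻¹
although the table itself contains 142.0 ng g⁻¹ (Jinghai), and the printed
suburban mean BaP-equivalent (72.8 ng g⁻¹) does not equal the mean of the
suburban column (78.2 ng g⁻¹). The urban (121.6) and rural (48.6) means do
match their columns exactly.

## Contamination classes

Total burdens are graded *not contaminated* (< 200 ng g⁻¹), *weakly
contaminated* (200–600), *contaminated* (600–1000) and *heavily
contaminated* (> 1000). Published class limits share their endpoints, so a
boundary convention is required; `classify_contamination()` uses
[0, 200), [200, 600), [600, 1000], (1000, ∞) — the unique convention
consistent with all 41 printed labels (e.g. 602.5 is "contaminated" and
1003.9 "heavily contaminated"). Classification is monotone by
construction.

# Diagnostic ratios and PCA/MLR

The three screening ratios are of the form numerator/(numerator+partner)
and therefore scale-invariant:

| ratio | < lower | middle | > upper |
|---|---|---|---|
| BaA/(BaA+Chr) | < 0.2 petroleum | 0.2–0.35 mixed | > 0.35 wood/coal combustion |
| Flt/(Flt+Pyr) | < 0.4 petroleum | 0.4–0.5 petroleum combustion | > 0.5 biomass/coal combustion |
| Ant/(Ant+Phe) | < 0.1 petrogenic | — | ≥ 0.1 combustion |

Boundary values are assigned to the middle class where one exists,
otherwise to the lower class; 0/0 ratios are undefined and the sample is
excluded from classification (reported in the `excluded` attribute) rather
than imputed. For Ant/(Ant+Phe) above 0.1 the generic label "combustion"
is used.

`run_pca()` standardizes compounds to z-scores, retains components with
eigenvalue > 1 (Kaiser criterion), and varimax-rotates the retained
loadings with Kaiser normalization — the de-facto standard in this
literature when only "rotated loadings" are reported. Each component is
sign-flipped so its largest-magnitude loading is positive. Note that
varimax preserves the *rotation's* orthogonality and the per-compound
communalities, but the rotated loading columns themselves are not mutually
orthogonal unless all retained eigenvalues are equal; the tests assert the
two properties that actually hold. Constant compounds carry no correlation
information and are dropped with a warning; fewer than 3 samples is an
error. `apportion_mlr()` regresses the standardized per-sample total on
the rotated component scores and converts positive coefficients to shares
(plain score regression; negative coefficients are clipped to zero and the
rest renormalized — if no coefficient is positive the apportionment is
undefined and signalled).

# The PMF model

The factorization X ≈ G·F (G: n × p contributions, F: p × 16 profiles,
both non-negative) minimizes the uncertainty-weighted objective
Q = Σ(eᵢⱼ/uᵢⱼ)² with the equation-based uncertainty

* uᵢⱼ = 5/6 · MDLⱼ for xᵢⱼ ≤ MDLⱼ (the boundary uses this branch),
* uᵢⱼ = √((EFⱼ xᵢⱼ)² + MDLⱼ²) above the MDL.

## Optimizer

Each start initializes G ~ U(0.1, 1)·(mean row sum)/p and F as
row-normalized U(0.1, 1), then runs multiplicative updates for weighted
non-negative factorization (weights 1/u²), which never increase Q. A
single top-level seed expands deterministically into per-start seeds, so
fits are reproducible. Convergence is declared at relative Q change
< `tol` (default 1e-8) or at an absolute floor Q ≤ 1e-9·n·m (an
essentially exact reconstruction, far below the statistically adequate
Q ≈ n·m); `max_iter` (default 5000) caps each start with a warning, not an
error.

Multiplicative updates approach active-set boundaries — exact zeros in G
or F — only asymptotically, which matters for noise-free benchmark
problems. The winning start is therefore polished by up to
`polish_sweeps` (default 50) alternating sweeps of exact weighted
non-negative least squares (one small NNLS per sample row and per compound
column, via `pracma::lsqnonneg`). Each sweep is a block-coordinate descent
step, so the monotone Q trace is preserved, and the polish reaches
machine-precision local optima that plain multiplicative updates cannot.

Degenerate input (X identically zero) returns the trivial all-zero model
with Q = 0 and a warning. No rotational (Fpeak-style) exploration is
performed.

## Choosing the number of factors

`scan_factors()` fits p = 3…8 (defaults) and tabulates Q, Q/Q_expected
with Q_expected = n·m − p(n+m) (the residual degrees of freedom), and the
pooled-cell R² (squared Pearson correlation between all observed and
reconstructed cells — pooled because no finer definition is standard). The
recommended p is the smallest with R² ≥ 0.91 and a relative improvement of
**Q/Q_expected** below 10% when adding one more factor. The improvement is
measured on the dof-normalized ratio deliberately: each added factor
consumes n+m parameters, so even past the true factor count raw Q keeps
dropping by roughly (n+m)/dof per factor (12–20% at n = 50, m = 16), and a
raw-Q rule would never level off; the normalized ratio flattens as soon as
added factors stop capturing structure.

## Normalization and labelling

`normalize_profiles()` rescales each profile row to sum to 1 and folds the
scale into the contribution column, so S·f = G·F exactly and Sₖₚ reads as
the total PAH mass of source p in sample k. `label_sources()` assigns each
factor the reference profile with maximal cosine similarity, greedily and
injectively while candidates remain; ties break toward the factor with the
larger projection on the candidate, and best similarities below 0.5 are
flagged low-confidence.

# Toxicity apportionment

BaP-equivalents are linear in concentrations, so the source decomposition
passes through exactly: (BaP_TEQ)ₖₚ = Σᵢ TEFᵢ·Sₖₚ·fᵢₚ. Shares are computed
on the model reconstruction S·f rather than on raw X, so per-sample and
overall shares sum to exactly 100% with no residual-handling convention;
non-negativity is inherited from the factorization.

# Incremental lifetime cancer risk

`ilcr_pathways()` implements the three-pathway adult model. Two published
renderings of these formulas do not close dimensionally and are resolved
as follows, flagged prominently here because they change results:

* the body-weight term in the slope-factor adjustment is the standard
  USEPA cube-root scaling (BW/70)^(1/3) — a typeset "BW/703" or "BW/70³"
  is dimensionally and historically unsupportable;
* the concentration is converted ng g⁻¹ → mg kg⁻¹ internally and the 10⁶
  factor in the ingestion/dermal pathways is the mg-soil → kg-soil
  conversion, so every pathway dose is mg kg⁻¹ d⁻¹ as the slope factors
  require.

With the default exposure constants (BW 62 kg, EF 180 d y⁻¹, ED 24 y,
IR_ing 100 mg d⁻¹, IR_inh 20 m³ d⁻¹, SA 5700 cm², AF 0.07 mg cm⁻²,
AT 25550 d, ABS 0.13, PEF 1.36×10⁹ m³ kg⁻¹, CSF 7.3/25/3.85 for
ingestion/dermal/inhalation) the closed-form pathway ratios are
dermal/ingestion = 1.776 and inhalation/ingestion ≈ 7.8×10⁻⁵ — dermal
contact dominates, inhalation is negligible. Every pathway is exactly
linear in the concentration.

`fit_best_distribution()` fits log-normal, gamma, Weibull and normal
families by maximum likelihood through `fitdistrplus`, and the classical
two-parameter Pareto by its closed form with the scale fixed at the sample
minimum (the natural anchoring when the support's lower end is observed).
The winner minimizes the Anderson–Darling statistic — chosen because the
risk estimate is a tail quantile and AD weights tail fit more heavily than
Kolmogorov-style distances — with ties broken toward fewer parameters.
Constant or non-positive inputs are a signalled error. `monte_carlo_ilcr()`
draws `n_iter` ≥ 1000 concentrations (default 10,000), truncates at zero,
applies the deterministic risk model, and reports the percentile table;
the 95th percentile is the conventional high-end estimate and is
classified against the bands < 10⁻⁶ *safe*, 10⁻⁶–10⁻⁴ *low risk*,
> 10⁻⁴ *marginal safety*. The per-study BaP-equivalent column of the
bundled table is the concentration input for the study-table workflow
(per-sample compound data are not available at that level).

# The synthetic generator

`simulate_dataset()` draws per-source contributions log-normally
(strictly positive and heavy-tailed, as environmental totals are), forms
the exact bilinear product with four canonical source profiles, and adds
zero-mean Gaussian noise whose standard deviation follows the same
equation-based uncertainty model the PMF stage assumes; negatives are
truncated at zero and flagged (truncated mass is negligible at the default
noise level).

The four profiles (`make_source_profiles()`) encode the marker structure
of the receptor-modelling literature — vehicular emission on the 4–6 ring
compounds, coal combustion on Ant/Flt/Pyr/BbF/BkF, biomass combustion on
BkF/BaP/IND/DBahA/BghiP, petrogenic on the LMW compounds — with fraction
values engineered for identifiability (pairwise cosine ≤ 0.8), **not**
measured source profiles; a small seeded log-normal jitter (sd 0.04) keeps
replicate libraries distinct while preserving the marker structure.

The contribution defaults are calibrated once against the bundled study
table: per-source median contributions 170/95/75/38 ng g⁻¹ (vehicular,
coal, biomass, petrogenic; nominal shares 45/25/20/10) with per-source
log-sd 1.1 jointly reproduce the table's median total (≈536 simulated vs
538 observed) and its between-site dispersion (sd of log totals ≈0.66 vs
0.65 observed). The dispersion matters scientifically: it controls how
close individual samples come to single-source compositions, which is what
makes a 4-factor PMF identifiable at all.

What the generator does **not** emulate: spatial or temporal correlation
between samples, congener chemistry beyond the 16 compounds, profile
variation between samples (a site's true source signature drifts),
censoring patterns of real laboratories, or correlated multi-source
emission events. Passing recovery tests on this generator therefore shows
the solver recovers the stated generative model — not that four sources
are identifiable in any real soil survey.

# Test and benchmark problem sizes

The recovery experiments run at n = 50 samples, p = 4 sources, error
fraction 0.1, with 10 seeded replicates (8 solver starts each) — large
enough for stable recovery statistics while keeping the full suite fast.
Exact-recovery benchmarks use a two-source construction satisfying the
classical separability condition (disjoint-support profiles plus a few
pure "anchor" samples per source), because that is the regime in which the
non-negative factorization is provably unique up to permutation and scale;
without anchors, exact reconstructions with slightly rotated profiles
exist and no solver can distinguish them. Monte Carlo risk runs use
10,000 draws.

# Known limitations

* **Rotational ambiguity of TEQ shares.** Mass shares recover within a few
  percentage points in the replicate experiments, but TEQ shares
  concentrate on a handful of high-TEF 5–6 ring compounds where the
  vehicular and biomass profiles overlap, and inherit roughly twice the
  rotational uncertainty — replicate-mean TEQ-share errors up to about
  ±20 points, with a systematic vehicular→biomass transfer. Conservation
  (Σₚ(BaP_TEQ)ₖₚ equal to the reconstruction's TEQ) is exact regardless.
  Users comparing TEQ shares between surveys should treat differences
  under ~20 points as within model uncertainty.
* **Risk-band boundary cases.** With the Anderson–Darling-selected fit,
  the rural study group's 95th-percentile ILCR computes to just below the
  10⁻⁶ threshold (category *safe*), while urban and suburban fall in the
  low-risk band; a different fit engine or family ranking can move a
  boundary case like this across the threshold. Point risk values from
  proprietary fitting software are not reproducible and are not targeted.
* **Catalog defaults are configuration.** MDLs and error fractions are
  typical values, not measured ones; PMF weights, and hence Q and the
  factor scan, depend on them.
* **The study table is a literature compilation.** Heterogeneous sampling
  depths, years and analytical methods stand behind its 41 records; the
  package preserves, and does not attempt to repair, the two documented
  internal inconsistencies noted above.
* The PCA/MLR stage identifies mixed components on real compilations;
  interpretation of loadings into named sources is left to the analyst,
  as is conventional.
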