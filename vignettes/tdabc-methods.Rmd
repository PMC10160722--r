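---
title: "Time-driven activity-based costing and equity analysis: methods"
author: "tdabcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-driven activity-based costing and equity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The costing model

`tdabcost` implements time-driven activity-based costing (TDABC) for
health-service encounters. TDABC assigns the cost of every facility
resource to the patients who consume it through two primitives:

1. **Capacity cost rate.** Each resource (a staff member, a room, a piece
   of equipment) has an annual cost and a *practical capacity*: the
   minutes per year it is realistically available for patient-facing
   work. The rate is

   $$r_j = \frac{\text{annual cost}_j}{\text{practical capacity}_j}
   \quad [\text{currency}/\text{minute}].$$

   Equipment enters through linear depreciation with zero salvage value:
   an item purchased for $C$ with useful life $L$ years contributes
   $C/L$ per year (`annualize_equipment()`).

2. **Patient-level cost.** A patient's encounter is a sequence of
   observed process steps. The direct cost of the encounter is the sum
   over steps of rate × observed minutes, plus price × quantity of every
   consumable dispensed:

   $$\text{cost}_i = \sum_{s \in i} r_{j(s)}\, t_s
   + \sum_{k \in i} p_k q_k + \text{indirect}_i.$$

Costs decompose into exactly four categories that partition the total:
human resources, space/equipment, indirects, and consumables.

**Indirect allocation.** Facility overhead (support staff, utilities) is
not attributable to individual encounters, and no allocation rule is
forced by the accounting identity. The default allocates each facility's
pool *proportionally to direct staff minutes*, standard TDABC practice
because overhead scales with clinical activity; an equal-share basis is
available (`allocation_basis = "equal_share"`) for sensitivity analysis.
Annual pools are prorated to the observation window by
`period_days / 365` (default 45 days, a typical field window), and the
allocation conserves the prorated pool exactly.

**Currency.** All internal arithmetic is in Tanzanian Shillings;
conversion to US dollars happens once, at reporting, at a configurable
rate defaulting to 2,300 TZS/USD. Costing is homogeneous of degree one in
the price vector, so converting inputs first and costing afterwards gives
identical results.

**Annualization.** Antiretroviral therapy is a recurring service: stable
(virally suppressed) clients attend quarterly and unstable clients
monthly, so per-visit costs are multiplied by 4 and 12 respectively.
All other services (testing and counseling, PMTCT, PrEP, circumcision)
are treated as one-time encounters.

**Rounding.** Money is reported to 2 decimals and percentages to 1
decimal using half-up rounding (`round_half_up()`), matching how cost
tables are conventionally printed; internal computation is never rounded.

## Descriptive summaries

`summarize_service_costs()` reports, per service line, the mean and
sample standard deviation (n − 1 denominator) of each category, the
category's share of mean total cost, and the interquartile range of
*facility-level mean costs*. The IQR is taken across facility means, not
raw encounters, because it summarizes between-facility variation; an
encounter-level option exists. Quantiles use linear interpolation between
order statistics (`stats::quantile` type 7). When a category is constant
across facilities — as with standardized ART medication bundles — the IQR
is flagged not applicable rather than reported as (c, c). Because the
total is the sum of the categories and the mean is linear, the unrounded
category shares sum to exactly 100 for every service line.

## The equity layer

### Household asset index

Household wealth is proxied the standard way: binary/ordinal possession
and dwelling-quality indicators (electricity, mobile phone, refrigerator,
television, flooring and roofing quality, ...) are centered and scaled to
unit variance, and each household's score is its projection onto the
first principal component (`build_asset_index()`). Scores have mean zero
by construction. Two conventions are fixed and documented:

* **Sign.** The principal component is defined only up to sign; the score
  is oriented to correlate positively with the raw indicator row sum, so
  higher always means wealthier.
* **Degenerate columns.** Zero-variance indicators carry no information
  after standardization and are dropped; an all-constant matrix is an
  error. Missing indicator values are an error — no imputation.

Standardization makes the score invariant to positive affine rescaling of
any single indicator.

### Fixed-effects linear models

Three models share one design matrix and differ only in outcome:
provider-patient contact minutes, visit cost without consumables, and
visit cost with consumables. Covariates are patient characteristics —
gender (ref. female), age group (18–30 ref., 31–50, 51–70, 71+), marital
status (ref. unmarried), education level entered as ordinal categories
0–1 (ref.)/2–3/4–5/6+ years, comorbidity (ref. none), and the continuous
asset index — a service-line indicator with testing-and-counseling as the
reference (stable and unstable ART are distinct levels), and facility
fixed effects: region (ref. Dar es Salaam), facility type (ref.
dispensary), rurality (ref. urban), funder (ref. government), and HIV
client volume tier (ref. high). Education is entered as an ordinal
category rather than a continuous year count because the reference-group
convention for the models is categorical.

Estimation is ordinary least squares with classical homoskedastic
standard errors, t-based 95% confidence intervals on n − rank degrees of
freedom, two-sided p-values at α = 0.05, and centered R². Whether
standard errors should be cluster-adjusted by facility is genuinely open
(facility heterogeneity is partly absorbed by the fixed effects); both
options are provided (`se_type = "cluster"` uses a facility-clustered
sandwich estimator) and classical is the default.

Two numerical policies matter:

* **Rank deficiency** among populated columns is an error naming the
  linearly dependent columns — never a silent drop — because an implied
  dummy usually signals a specification mistake.
* **Empty levels** (a category no sampled patient occupies, e.g. age 71+
  in a small study) are dropped from the design with a classed warning.
  This is distinct from collinearity: the column is identically zero, the
  corresponding coefficient is simply not estimable from the data, and
  failing hard would make pipelines crash on unlucky samples. The
  expected count of patients over 70 in a default-size study is about 3,
  so a few percent of random studies genuinely lack the level.

The duration outcome is provider-patient *contact* time: the sum of
staff-resource minutes over the encounter's observed steps. Non-contact
staff time is out of scope.

## The synthetic study generator

No field data ship with the package; `simulate_study()` generates a
complete, seeded study so that every downstream stage is testable, with
ground truth stored beside (never inside) the analysis inputs.

**What it emulates.** The default configuration reproduces the structure
of a national HIV costing study design: 22 facilities spanning purposive
strata (5 dispensaries, 10 health centres, 7 hospitals; seven regions;
urban/rural; one non-PEPFAR facility; 3 private/faith-based; low, medium
and high volume tiers), and 886 patients across six service lines
(240 stable ART, 214 unstable ART, 198 HTC, 200 PMTCT, 15 PrEP,
19 VMMC), with service-specific demographic margins (every PMTCT patient
female, every VMMC patient male, ages 18+). Patients are assigned to
facilities with probability proportional to volume-tier weights
(1 : 3 : 8 for low : medium : high), since only tier labels are knowable.

**Durations.** Total contact minutes are a linear predictor over the
ground-truth effects — using exactly the design encoding the analysis
applies — plus mean-zero, right-skewed gamma noise (shape 4, SD 6
minutes), floored at 1 minute. The noise is *homoskedastic* by
construction: a raw gamma with variance proportional to the squared mean
would violate the constant-variance assumption of the classical OLS
inference the analysis performs, and the recovery experiments would then
measure that misspecification rather than the estimator. Default effect
magnitudes encode plausible service-delivery patterns (a surgical VMMC
visit +51 minutes versus HTC, PrEP −7.5, comorbidity +5.4, +0.9 minutes
per asset-index unit, externally funded facilities +11.6); they are
illustrative defaults, not estimates.

**Wealth.** A standard-normal latent wealth underlies the asset
indicators: indicator j is 1 when `loading × wealth + noise` exceeds the
threshold matching its target prevalence. The duration effect of wealth
is applied to the *realized PCA score* of the generated indicator matrix
— the same deterministic quantity the analysis recomputes — so the
stated true coefficient is defined on the analysis scale and is not
attenuated by measurement error. The latent draws are stored only in
`ground_truth.json` for the recovery-correlation check (the default
study's index correlates with latent wealth at about 0.86).

**Costs.** All clinical cadres share one capacity cost rate (13.8M
TZS/year over 100,000 min/year = 138 TZS/min ≈ $0.06/min) and all rooms
another (9.2 TZS/min including annualized equipment); indirect pools are
sized on the facility's realized workload so overhead runs at exactly
23 TZS per staff minute. These uniformity choices are deliberate: they
make the true cost-model coefficients an exact multiple — the combined
direct rate ρ = (138 + 9.2 + 23)/2300 ≈ $0.074/min — of the duration
coefficients, so coverage checks on the cost models have well-defined
truth. The registry schema fully supports heterogeneous rates; the
defaults trade that realism for exact ground truth.

**Consumables.** ART bundles are fixed, standardized packages identical
across facilities and encounters (their across-facility IQR is therefore
flagged not applicable, as in practice when dispensing is standardized).
Other services receive mostly-fixed bundles plus a small Poisson-count
supplies component whose facility-level mean varies (multiplier CV 0.03),
so non-ART consumable costs genuinely differ across facilities and
encounters. Expected bundle costs are calibrated so that per-visit
category means sit near the reference cost structure (consumable shares
of roughly 64–94% of total, within the observed 61–95% band; the HTC
bundle is set slightly above the band edge so sampling noise cannot
straddle it) and per-service mean totals fall within a factor of two of
the reference means. Dispersion is deliberately modest: per-encounter
consumable SD of a few tenths of a dollar. Real consumable costs are far
more dispersed; strongly heteroskedastic or facility-clustered consumable
noise would invalidate the classical-SE inference the default analysis
uses, and the generator's job is to provide data under which a correctly
specified analysis should succeed. Passing recovery tests therefore shows
the pipeline and estimator are correct — not that real data satisfy these
assumptions.

**Determinism.** Everything derives from one integer seed; component
stages use collision-free derived seeds (5·seed + offset), so identical
configurations give byte-identical CSV bundles, and distinct seeds never
share an underlying RNG stream.

## Validation experiments and problem sizes

Two experiment harnesses back the acceptance checks, run at the study's
native size (n = 886, 22 facilities) over 100 replicate seeds:

* `recovery_experiment()` simulates, costs, fits the three models, and
  checks per term whether the 95% CI covers the truth. All 84 model terms
  achieve ≥ 90% empirical coverage; terms whose level is absent in a
  replicate are excluded from that term's denominator for that replicate.
* `type1_experiment()` zeroes all patient-level effects and measures the
  significant-term rate among the duration model's patient terms, which
  lands within 99% binomial bounds of α = 0.05. Only the duration model
  is used because in the generator the cost outcomes are near-exact
  linear transforms of duration, so their tests are not independent
  replicates of the same hypothesis.

Unit-level checks compare the costing engine against a brute-force
hand-sum oracle on 1,000 random small encounters (agreement to 1e-9
USD), the asset index against a direct covariance eigendecomposition
(1e-8, up to sign), and the OLS fit against the normal equations (1e-6
relative).

## Known limitations

* Above-facility costs (supply chain, program management,
  community-based delivery) are out of scope by design, as is
  queueing/waiting time: only provider-patient contact time is costed.
* Whether real overhead was allocated by staff minutes, encounter counts
  or floor area is unknowable from published material; both implemented
  bases are assumptions. Shared space/equipment must be pre-apportioned
  in the resource registry.
* The generator does not target published per-encounter SDs or real
  consumable dispersion, does not simulate step-skipping (process-map
  frequencies default to 1), cadre pay heterogeneity, appointment
  scheduling, or missing covariates; pipeline exclusion logging is
  exercised by tests, not by the default generator.
* Published regression coefficients from field data are not reproducible
  targets — the underlying data are private — which is precisely why the
  equity layer is validated by synthetic ground-truth recovery.
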