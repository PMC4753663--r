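---
title: "Methods: rates, PLS/VIP typing and pathway networks for ABE fermentation profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rates, PLS/VIP typing and pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`fermentomics` analyses time-resolved intracellular metabolic profiles of
acetone–butanol–ethanol (ABE) fermentations, where acid production
(acidogenesis) during growth is followed by a solvent switch
(solventogenesis) during which butanol accumulates. The pipeline relates a
samples × metabolites GC-MS peak-area table to two process phenotypes — the
specific growth rate μ and the specific butanol production rate q — and
summarizes the result as a bipartite metabolite–pathway network.

The quantitative backbone is three definitions:

* relative abundance `A_r = A_i / (DCW · A_s)`, with `A_i` the metabolite
  peak area, `A_s` the spiked deuterated internal-standard area
  (succinic-d4 type channel) and DCW the dry cell weight (g/L);
* `q = (dc/dt) / DCW` (butanol concentration c, 1/h);
* `μ = d ln(OD) / dt` (natural log, 1/h).

## Rate estimation

The fermentation is sampled on a coarse grid, and nothing in the data
dictates how the derivatives should be evaluated. The default is central
finite differences on the sampled grid (one-sided at the ends): it is exact
on piecewise-exponential growth (ln OD piecewise linear), second-order
accurate otherwise, and requires no tuning. An interpolating natural cubic
spline derivative (`method = "spline"`) is available for noisy series.
Negative decline-phase rates are deliberately retained — the estimator is
sign-honest and clipping would hide the decline phase.

`μ` is invariant to OD rescaling, so the OD→DCW conversion factor (default
0.3 g DCW per litre per OD unit, a conventional value; the factor is
strain-specific and configurable) only affects the scale of `q` and of
`A_r`, never any VIP, coefficient sign, p-value or network edge, because
the PLS inputs are autoscaled per column.

## PLS, Q², coefficients, VIP

One single-response PLS model is fitted per phenotype (μ and q separately),
not one two-block model: the two responses are reported and interpreted
independently. Fitting is NIPALS with deflation of both `X` and `y`;
columns are mean-centred and unit-variance scaled (the chemometric default
the VIP > 1 rule presumes); each weight vector's sign is fixed so its
largest-magnitude element is positive, removing the NIPALS sign ambiguity.
Coefficients are reported on the autoscaled metric, so a positive
coefficient reads "this metabolite favors the response".

Cross-validation uses 7 interleaved folds with a deterministic,
seed-controlled assignment. `Q²_A = 1 − PRESS_A / SS_tot`, and the number
of components is the largest A whose Q² increments all reach 0.01 (at
least one component is always kept). All of these — folds, increment rule,
maximum A — are configurable; the defaults mirror common chemometrics
software behaviour since the choice cannot be recovered from data alone.

VIP uses the standard Wold formulation
`VIP_j = sqrt(p · Σ_a SS_a (w_aj/‖w_a‖)² / Σ_a SS_a)`, which satisfies
`Σ_j VIP_j² = p` exactly; this identity is asserted in the tests.

## The nine types

Each metabolite's four scores (VIPb, Coeffb, VIPg, Coeffg) map to one of
nine types, with VIP given priority: the coefficient sign is consulted only
for a response whose VIP exceeds the threshold (default 1.0). The labels
A–I and their two-slot codes (growth slot first: `*` insignificant, else
the coefficient sign) are documented in `classify_metabolites()`.

Boundary policy, which the rule table leaves open:

* VIP exactly at the threshold counts as **not** significant (conservative);
* a coefficient exactly 0 on a significant response inherits the sign of
  the other response's coefficient (positive as last resort) and the row is
  flagged `ambiguous` — a measure-zero corner that must still yield a total
  classification;
* non-finite scores are reported `unclassified` with a warning, never
  dropped.

Types H (both positive) and I (both negative) are retained even though
real ABE data sets may leave them empty: the scheme must partition the
score space, and the partition property is brute-force verified on grids
and random quadruples.

## Over-representation and topology impact

For a metabolite set of size `n` against a background universe of `N`
compounds, a pathway with `K` members and `x` hits gets the one-sided
upper-tail hypergeometric p-value (Fisher's exact test), accumulated in
log-space. The filter is `−log₁₀(p) > 1`, i.e. `p < 0.1`; the base is
configurable since "−log" alone is ambiguous. No multiple-testing
correction enters the filter (a BH FDR column is emitted for information
only) — this mirrors the raw-p convention of pathway tools in this field.

The background defaults to **all metabolites measured in the experiment**,
not the pathway library's union: over-representation is judged relative to
what was measurable. Pathway impact is
`Σ_hits c_i / Σ_pathway c_i` with `c_i` the out-degree of the compound in
the pathway's directed reaction graph (relative betweenness available);
edgeless pathways get impact 0.

Because each classification type is tested against every pathway with raw
p-values and the final network takes the union, a pathway has roughly a
`1 − (1 − 0.1)^T` chance of entering the network by luck across `T`
non-empty types (~25% observed per neutral pathway in the synthetic
world). This uncorrected-multiplicity behaviour is inherent to the
typewise raw-p procedure being reproduced; per matched query the
false-pass rate stays below the nominal 10%.

## The synthetic world

The generator states one fixed world; its parameters were chosen once and
are not test dials.

* **Fermentation**: four phases (lag 0–12 h, log 12–45 h, stationary
  45–63 h, decline 63–84 h); piecewise-exponential OD (rates 0.008,
  0.085, 0.005, −0.004 h⁻¹ — mid-log μ ≈ 0.07–0.09 h⁻¹, slow stationary
  growth, slow decline); butanol a trace (≤ 0.1 g/L) before the acid peak
  at 32 h, then sigmoidal to ~12.5 g/L; acids pulse to their peak at the
  onset and are re-assimilated; pH falls 6.8→4.3, bumps to ~4.45 at onset,
  drifts to 4.0. Measurement noise is off by default so shape tests are
  exact; optional log-normal noise is seeded.
* **Metabolome**: 4 sampling times (24/48/60/80 h) × 5 replicates × 97
  metabolites. Log-scale replicate noise SD 0.2 (~20% CV, a realistic
  GC-MS figure). Planted effects at 3 × noise SD: 10 growth-positive-only,
  10 butanol-negative-only, 5 dual metabolites; effects act on the true
  relative abundance (peak areas are reconstructed as
  `R · DCW · A_s`) so that planting is on the modeled quantity and the
  biomass trend does not contaminate null metabolites. Per-metabolite RNG
  substreams make the table extensible without reshuffling.
* **Pathway library**: 12 pathways, sizes 5–10; one planted pathway per
  response-level ground-truth class (all growth-favoring metabolites; all
  butanol-opposing metabolites) drawing 80% of members from its class
  (the generator enforces ≥ 60%); graphs are random DAGs (chain backbone
  plus forward edges), so out-degree totals are always positive.

An important emergent feature: μ and q are strongly anticorrelated across
the four sampling times (growth precedes the solvent switch), so a
metabolite planted only on μ genuinely becomes significant for q with the
opposite sign. Recovery is therefore defined per planted response, and
most planted metabolites legitimately land in the dual type. The
generator does **not** emulate retention-time drift, missing peaks,
batch effects, censored low-intensity values or metabolite–metabolite
correlation beyond the shared phenotype — a green recovery test says the
estimator chain works under the stated noise model, not that it survives
real GC-MS pathologies.

## Numerical choices

* NIPALS rank exhaustion is detected at `1e-12` relative tolerance and
  truncates with a warning; a singular `P'W` raises a collinearity error.
* `ora_fisher` sums in log-space via log-sum-exp and clamps at 1; it is
  exact against rational enumeration for all configurations with N ≤ 30.
* Enrichment ties are ordered p ascending, impact descending, then
  pathway id, making every output table deterministic.
* Rows with non-positive internal standard or DCW are rejected with a
  named diagnostic rather than propagating non-finite abundances.

## Known limitations

* Printed μ/q magnitudes depend on the OD→DCW factor; only their profile
  across times is biologically meaningful here.
* The typewise raw-p union inflates neutral-pathway admission (above);
  users wanting strict control should filter on the emitted FDR column.
* The 9-type rule table is threshold-based; metabolites near VIP = 1 can
  change type between seeds — by design, since that is how the published
  scheme behaves.
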