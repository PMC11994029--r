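---
title: "Methods: invasion-criterion estimates of community stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invasion-criterion estimates of community stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinvade)
```

## The question and the statistic

A community of coexisting species should be *mutually invasible*: any member
driven to low density should recover, because a rare species escapes
intraspecific competition while its competitors remain self-limited. The
standard microbial assay invades a focal species from rare (here, 100-fold
below the residents) into the remainder of the community and measures the
**relative invader growth rate**

$$\mathrm{RGR} = \frac{m_\text{focal}}{m_\text{community}}, \qquad
  m = \frac{\ln(N_1 / N_0)}{t},$$

where $m$ is the realized Malthusian parameter over the assay ($N_0$, $N_1$
the starting and final CFU densities, $t$ the assay time — one week
throughout this package, so rates are per week). The community rate pools
**summed densities** of every non-focal population — residents *and*
co-invaders — never an average of per-species rates. RGR > 1 is negative
frequency dependence: the rare species gains ground, the signature of
niche-stabilized coexistence.

`coinvade` implements the full workflow around this statistic for both
assay families:

* **single invasion** — one focal invader, residents of richness 1–4
  (`design_single_invasion()`, 75 treatments over five species);
* **co-invasion** — total richness fixed at the pool size, with 2–4 species
  simultaneously invading from rare and each invader in turn treated as
  focal (`design_co_invasion()`, $\sum_k k\binom{5}{k} = 70$ treatments,
  14 per focal species).

Treatments are paired across families on (focal, resident set)
(`pair_by_residents()`), which is what makes "does a single invasion
predict the co-invasion outcome?" a well-posed comparison.

## The synthetic community

No raw plate counts ship with the package; a generative model with the same
statistical structure stands in for them, so every stage is testable.

**Dynamics.** Batch growth follows a generalized Lotka–Volterra model,

$$\frac{dN_i}{dt} = N_i\Big(r_i + \sum_j \alpha_{ij} N_j\Big),$$

integrated over one uninterrupted 7-day batch (no serial transfer) with
`deSolve::ode` (lsoda). gLV is the minimal model able to express the
community's qualitative interaction structure — mostly pairwise
competition, with one facilitated species — which is all the experimental
literature on this community constrains; nothing mechanistic (resource
explicit, lag phases) is claimed.

**Presets.** Interaction magnitudes are not experimentally constrained, so
the three bundled presets are qualitative regimes with fixed, documented
constants (nothing is drawn at random; presets are fully deterministic):

| preset | r (per day) | alpha | regime |
|---|---|---|---|
| `neutral` | 1.0 all | all entries −2e−9 | all species identical; every RGR is exactly 1 |
| `stabilized` | 1.2, 1.0, 1.3, 0.9, 1.1 (A, O, P, S, V) | diagonal −1e−8, off-diagonal −2e−9 | self-limitation dominates; mutual invasibility |
| `paper_like` | as stabilized | as stabilized, but V gains +8e−10 from A, O, P and 0 from S | competitive community with one facilitated member |

The magnitudes were fixed once by two physical requirements: a
single-species carrying capacity $K = -r/\alpha_{ii} \approx 10^8$ CFU
(a dilute medium at roughly $2\times10^7$ CFU/ml in 6 ml), and a neutral
whole-community capacity ($r/|\alpha| = 5\times10^8$ CFU) well above the
$1.616\times10^7$ CFU total inoculum — without the second property a
freshly inoculated community would *shrink* over the week, the pooled
community rate would go negative and the RGR would be undefined, which is
not how a batch culture behaves.

**Inoculation** (`inoculation_scheme()`): residents 16×10⁶ CFU total,
invaders 16×10⁴ CFU total (the 100-fold rarity that defines "invading from
rare"), each group's total split equally among its members.

**Observation** (`observation_model()`): colony counting at an effective
sampling fraction $f$ (default 10⁻⁴) is modelled as
$\hat N = \mathrm{Poisson}(N f)/f$, so count noise scales the way plate
counts do. Observations below the detection limit (default 10³ CFU
whole-culture, about one colony at the default dilution; the true plating
dilutions are not published, so this is configurable) are recorded as 0 and
flagged. Each treatment × replicate gets its own seed from a stable
polynomial hash of (master seed, treatment id, replicate)
(`replicate_seed()`), so datasets are byte-identical across runs and
independent of enumeration order.

**What the generator does not emulate:** evolution during the assay,
spatial structure, phage/predator layers, serial transfer, pipetting error
beyond Poisson counting, species misidentification on plates, and any
quantitative match to the real community's interaction strengths. Passing
tests therefore validate the *machinery* (enumeration, estimators, error
control) under a plausible data-generating process; they do not reproduce
the wet-lab study's data-bound numbers, which depend on its raw counts.

## Estimation policies

* **Below-detection focal finals.** A plate count of zero does not mean
  extinction. The default policy imputes $N_1$ at the detection limit —
  keeping the replicate and yielding a strongly negative $m_\text{focal}$,
  i.e. a conservative RGR — and flags it `focal_below_detection,imputed`.
  `drop_replicate` and `impute_half_limit` are selectable alternatives;
  the original analyses never state their handling, so the choice is
  explicit rather than hidden.
* **Non-growing community.** If $m_\text{community} \le 0$ the ratio no
  longer measures frequency dependence (dividing by a non-positive rate
  flips or explodes the sign), so the estimate is recorded as missing with
  flag `community_decline` rather than as a signed number.
* **Time units.** $t$ travels per-row in the counts table (`assay_days`),
  rates are reported per week, and the RGR is invariant to the shared time
  unit.

## Statistical analysis

* **Stability per treatment** (`classify_stability()`): a two-sided
  one-sample t-test of mean RGR against 1 per (focal × resident community
  × invasion type) group, Benjamini–Hochberg adjustment across all groups
  in the invocation (the family size is recorded in the output attributes
  and the run log; with the default design that family is the 70
  co-invasion tests), verdict *stable* iff mean > 1 **and** adjusted
  p < α (default 0.05 — the conventional level, as the significance
  language of such analyses implies). Direction is read from the mean: a
  significantly *low* mean is a failed invasion. Groups with fewer than two
  defined values or zero variance are reported `untestable`, never silently
  dropped, so row counts always match the design.
* **Rank correlation per species** (`correlate_by_species()`): Spearman's
  rho on paired treatment means with average ranks on ties; the p-value
  uses the asymptotic t-approximation under the null of independence
  (`stats::cor.test(..., exact = FALSE)`), FDR-adjusted across the five
  species.
* **Cross-assay linear model** (`fit_rgr_comparison()`): OLS of co-invasion
  means on single-invasion means × species. Nested-model F-tests on
  residual sums of squares test the interaction (full vs additive), then
  the common slope and the species intercepts from the additive model —
  for Gaussian OLS the F-test is the exact finite-sample form of the
  likelihood-ratio comparison; a χ² LRT is available via `test = "LRT"`.
  With 70 paired means and 5 species the degrees of freedom are
  (4, 60), (1, 64) and (4, 64).
* **Within-treatment contrasts** (`within_treatment_contrasts()`): the
  replicate-level factorial model RGR ~ treatment × invasion type
  (140 cells for the default paired design; interaction df 69, 700), then
  one co-minus-single contrast per treatment using the model's pooled
  residual variance. A Tukey studentized-range family over all 140 cells is
  not fully determined by the published description, so the package instead
  adjusts the 70 *planned* pairwise contrasts by Benjamini–Hochberg
  (Bonferroni selectable) — a deliberate, documented substitution.

## Numerical choices

* Integration in scaled units of 10⁶ CFU with rtol = 1e−10 and
  atol = 1e−10 (10⁻⁴ CFU — far below one cell), so the neutral-community
  identity RGR ≡ 1 holds to ~10⁻¹⁵ against the 10⁻⁶ contract. Species
  inoculated at exactly 0 have identically zero derivative and stay at 0;
  trajectories are clamped non-negative inside the right-hand side, and
  non-finite or absurdly large states (> 10¹² scaled) abort with a
  dynamics-divergence error naming the parameters.
* Per-treatment finals are deterministic, so the generator integrates each
  distinct inoculum once and reuses it across replicates.
* CSV outputs format doubles at 10 significant digits, making reruns under
  the same config byte-identical.
* Zero-variance groups, constant correlation inputs, rank-deficient model
  matrices and unpaired contrasts all have explicit, tested behaviours
  (untestable flag, `constant_input` note, collinearity error naming the
  aliased terms, warning naming the excluded treatment).

## Design decisions on open points

* The historical single-invasion design is reported inconsistently in the
  literature (75 vs 70 treatments); the enumerator exposes the
  resident-richness range (1–4 gives 75) and takes no side.
* Treatment ids are `"<focal>_into_<residents>[_with_<co-invaders>]"` with
  sets concatenated in pool order (`"V_into_AP_with_OS"`), matching the
  field's first-letter convention. Concatenated sets require
  single-character labels; multi-character pools work everywhere except
  this serialization.
* Replicate count lives on each design row (default 6) so mixed designs
  are expressible.
* The co-invasion design hard-codes residents = pool ∖ invaders (total
  richness fixed at the pool size); partial-community co-invasion is out
  of scope.

## Problem sizes used by the test suite

The suite exercises the full 70-treatment × 6-replicate design for the
neutral-oracle, stabilized-regime and classification checks; type-I error
control uses 1000 datasets of the 20-treatment reduced design (invader
richness 2) with fresh Poisson observations per dataset, the brute-force
oracle comparisons use 2×10⁴ random p-vectors, 10⁴ t-samples, 2×10³
tied Spearman cases and 100 random CFU tables. `scripts/acceptance.R`
repeats the headline quantities end to end (300 type-I datasets) from a
fresh seed.

## Limitations

Because interaction magnitudes are qualitative stand-ins, simulated
stabilized communities are *more* regular than real ones: every invasion
succeeds, cross-assay correlations are near 1 and most within-treatment
contrasts are significant only because replicate noise is small. Analyses
of real plate-count exports (ingested via `counts_co`/`counts_single`
config paths or `rgr_table()` directly) inherit none of these properties.
The pipeline assumes simultaneous inoculation (no priority effects from
staggered arrival), a closed batch (no transfers) and a single trophic
level.
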