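---
title: "Methods: comparing lime and fertilizer on acid soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing lime and fertilizer on acid soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limeval)
```

`limeval` compares two ways of buying cereal yield on acid soils: a
one-off application of agricultural lime that raises soil pH toward its
agronomic optimum, and the annual nitrogen fertilizer a farmer would
otherwise apply to compensate. This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

## 1. Soil chemistry: from pH deficit to lime tonnage

Lime requirement is not proportional to the pH deficit alone: the same
correction takes more lime on a strongly buffered (high-CEC) soil. The
package uses the classic base-saturation formulation

$$L \;=\; \mathrm{CEC}\cdot
  \frac{BS_t - BS_o}{2\,(1 - BS_o)}\cdot
  \frac{TD}{6}\cdot \mathrm{CCE}\cdot F,$$

with $L$ in metric tons per acre, converted to per-hectare by the factor
2.4710 and finally scaled by a calibration constant $k$. The $/2$ term is
the buffering factor of the formulation and $TD/6$ normalises to a
six-inch tillage depth; both are implemented exactly as written, and the
mt/ac → mt/ha conversion is explicit and unit-tested.

The pH → base-saturation relationship is soil-specific and not available
as a closed form, so it is represented by configurable piecewise-linear
anchors. Defaults:

| pH  | base saturation |
|-----|-----------------|
| 4.5 | 0.25 |
| 5.5 | 0.40 |
| 6.5 | 0.70 |
| 7.0 | 0.85 |

These anchors place the steepest buffering in the agronomically relevant
5.5–6.5 band. The single scalar $k$ is then calibrated — once, at package
level — so that the reference correction (pH 5.5 → 6.5 on a soil of
CEC 10 cmol(+)/kg with pure, fine lime at 6-inch tillage) requires
exactly 3.12 mt/ha, the published Ethiopian rate for that one-unit
correction. Only this single input–output pair is anchored by published
data; the reference CEC of 10 cmol(+)/kg is a config value, chosen as a
round mid-range value for highland cultivated soils. Everything lives in
`base_saturation_model()` / `lime_spec()`, nothing is hard-coded.

Acidity classes follow the convention used throughout: pH ≤ 5.5 "highly"
acidic (closed boundary), 5.5 < pH ≤ 6 "moderately", above 6 non-acidic.
Soils at or above the target pH have a lime requirement of exactly zero;
the requirement is continuous and non-decreasing as pH falls.

## 2. The yield response surface

`yield_response()` fits, separately per crop, ordinary least squares of
yield (mt/ha) on:

* orthogonal polynomial expansions $p(x, 1),\dots,p(x, k_x)$ of the
  continuous covariates (pH, fertilizer, CEC, SOC, sand, PDSI, elevation,
  extension/improved-seed/irrigated/damaged shares, market distance);
* the policy dummies (PSNP, AGP);
* year and agro-ecological-zone fixed effects.

Orthogonal bases (rather than raw powers) keep high-order fits
numerically stable and make the order-selection tests independent of
affine rescalings of a covariate, a property the test suite checks. The
orthogonalisation constants of every basis are frozen inside the fitted
object (and its JSON serialisation), so the training design — and hence
every prediction — is reproducible from the object alone to machine
precision.

**Order selection.** For each continuous covariate independently, with
all other covariates held at first order, the polynomial order grows
forward from 1: order $k+1$ is kept only while the nested F-test against
order $k$ rejects at level $\alpha$ (default 0.05, `max_order` 4). The
per-covariate-independent convention was chosen over a joint/sequential
search because it is deterministic, order-independent across covariates,
and cheap; a joint search would be equally defensible. Note the forward
test over-selects with probability $\approx\alpha$ when the true order
has been reached, so at $\alpha = 0.05$ the expected exact-recovery rate
sits at 95% by construction; the acceptance simulation therefore runs
its low-noise order-recovery check at $\alpha = 0.01$, where the
expected rate is ~99%.

**Standard errors** are classical OLS; the sampling design gives no
clustering instruction, and repeated observations of a sub-kebele across
years are treated as exchangeable given the fixed effects. This likely
understates uncertainty in real survey data (a known limitation).

**Marginal quantities.** Curves and gains hold all other covariates at
their training means, with fixed effects at a reference cell (default:
the most populous year × zone, configurable). Because fixed effects
cancel in a difference, the absolute gain
$\Delta Y(\mathrm{pH}_0 \to \mathrm{pH}_1)$ does not depend on that
choice; the *percentage* gain does, through its baseline. The package
reports percentages against the "average hectare" baseline — fixed-effect
dummies averaged at their sample shares — since the cost comparison is
framed for the average sub-kebele hectare, while curves use the
reference-cell convention so they correspond to a realisable covariate
profile. Grid points outside the training support produce an
extrapolation warning rather than an error.

**Fertilizer equivalence.** The fertilizer quantity matching a lime
gain is the smallest $\Delta f \ge 0$ whose predicted response at the
given pH reaches the target, found by a 512-point bracket plus bisection
to $10^{-3}$ kg/ha. The search is capped (default: the training 99th
percentile of fertilizer use) because the fitted response is concave and
extrapolating it far beyond observed applications is meaningless: gains
beyond the cap are flagged "unattainable" and reported with the maximum
achievable gain, and downstream cost ratios computed at the cap are
marked as lower bounds.

## 3. Delivered lime prices

Travel time from the nearest crusher is computed by exact multi-source
Dijkstra on the 8-connected cell graph of a friction raster. A cell's
traversal time is $\text{cellsize}/\text{speed} \times
(1 + c \cdot \text{slope\%})$; moving between adjacent cells costs the
mean of their times, $\times\sqrt2$ on diagonals. Choices made here:

* **8-connectivity with octile metric** — standard accessibility
  practice; 4-connectivity would overstate diagonal distances by up to
  41%.
* **Multiplicative-linear slope penalty** with default $c = 0.02$ (a 50%
  slope doubles traversal time); the steepness discount is a convention,
  recorded in `friction_params()`, not hard-coded.
* **Default speeds**: 60 / 30 km/h for primary/secondary roads,
  10 km/h off-road.

Delivered price is affine in time:
$\text{price} = \text{gate} + \text{loading} + v \cdot t$ with defaults
750 + 100 + 60 ETB/mt/hr. The defaults are only loosely calibrated, but
they reproduce all seven published town-level distributor costs from
their printed travel times to within ±6 ETB — exactly the residual
explained by the printed times being rounded to 0.1 hr. Each location is
served by its time-minimising crusher and inherits that crusher's gate
price. Last-mile transport and field application costs are excluded
throughout.

## 4. Present values and the x cost of lime

Fertilizer is an annual cost: each year's outlay grows with inflation
(default 13.4%/yr) and is discounted (8%/yr) over the horizon (5 years,
matching the assumed lime re-application interval). The default annuity
factor is $\sum_{t=0}^{4}(1.134/1.08)^t = 5.5256$. Payments default to
the start of each year — the first fertilizer purchase is concurrent
with the lime alternative — because this makes the lime present value
equal its one-shot cost; an end-of-year convention is available behind
the `timing` flag since the choice cannot be pinned down externally.
Lime is paid once, up front, undiscounted.

The **x cost of lime** is $|PV_{fert}| / |PV_{lime}|$ for the same yield
gain; above 1, lime is cheaper. Savings $|PV_{fert}| - |PV_{lime}|$ are
also expressed as a share of annual agricultural household income
(default 8,176 ETB ≈ \$370 at the December-2016 rate of 22.07 ETB/\$).
Yield revenue is deliberately *not* monetised: the comparison is
cost-for-equal-gain. A single blended Urea/NPS price of 11.5 ETB/kg is
used; the two products were priced identically in the reference period.
Ratios and percentages are rounded (1 d.p., nearest %) only at report
time.

## 5. What the synthetic generator emulates — and what it does not

`generate_panel()` produces one row per sub-kebele × year × crop with
the full covariate set and a yield computed from a *known planted
response* plus Gaussian noise (sd 0.35 mt/ha), truncated below at zero.
The planted response is the package's reference study condition:

* concave quadratic in pH peaking at 6.5, with amplitudes 0.30 (wheat)
  and 0.20 (barley) mt/ha — so the planted gain of the 5.5 → 6.5
  correction equals the amplitude exactly;
* linear + quadratic fertilizer terms giving diminishing returns of
  0.16 / 0.24 mt/ha (wheat/barley) per additional 100 kg/ha at the mean
  application rate of ~150 kg/ha;
* crop intercepts (1.006 / 0.472 mt/ha) set so those gains are ~21.5%
  and ~18.5% of the predicted yield at pH 5.5 for the average hectare;
* four regions with distinct pH distributions — including one (Tigray)
  whose sample contains essentially no moderately acidic soil, so that
  class × region aggregation exercises empty-cell handling — and a
  planted within-region fertilizer–pH slope of −45.8 kg/ha per pH unit
  in Amhara;
* small linear effects for the remaining covariates, a 0.02 mt/ha/yr
  time trend, and zone offsets spanning ±0.1 mt/ha.

pH draws are clipped to [4.2, 8.5], which keeps the planted yield
positive except in a vanishing tail (well under 0.1% of rows), so the
zero-truncation does not measurably bias parameter recovery.

The generator deliberately does **not** emulate: spatial autocorrelation
of soils or weather (covariates are independent across sub-kebeles),
survey weighting or the household-to-sub-kebele aggregation rule,
measurement error in the soil rasters, or any real geography (the
landscape is an abstract planar grid; road corridors are straight lines;
crushers sit on roads). Passing recovery tests therefore demonstrates
that the estimators are consistent and correctly implemented under the
assumed data-generating structure — not that the published real-data
coefficients are reproducible, which would require the original survey
and soil data. For the same reason the per-class, per-region *median*
gains and regional cost-ratio ranges — which hinge on the empirical pH
distribution — are not treated as recoverable quantities.

## 6. Numerical conventions and problem sizes

* One master seed; the panel and landscape streams are derived from it
  by fixed offsets, and generation restores the caller's RNG state.
* Manifest determinism: `run_all()` hashes every artifact (MD5) and
  stores no timestamps, so equal seeds give byte-identical manifests.
* The test suite fits panels of 1–2 thousand rows for unit checks;
  coverage of the planted pH gain is verified over 100 seed replicates
  of ~5,000-row single-crop panels, and order recovery over 50 low-noise
  replicates. The acceptance script uses a ~40,000-row panel
  (2,860 sub-kebeles × 7 years × 2 crops), at which size the fitted
  fertilizer-response contrast has a standard error comfortably below
  the reporting tolerance.
* Travel-time correctness is checked against an independent fixed-point
  relaxation oracle on random grids up to 7 × 7; the fertilizer
  inversion against an exhaustive 0.01 kg/ha grid scan.

## 7. Known limitations

The pH–yield relationship is estimated from spatial variation in
observed pH, not from experimental lime application, so it is an
associational proxy for the causal liming effect; micronutrient and
toxicity-reduction benefits of lime are not modelled, which biases the
comparison *against* lime. Classical standard errors ignore possible
within-sub-kebele correlation. The five-year horizon is conservative:
lime carryover can last a decade. Delivered prices stop at distribution
centres — last-mile costs would shift both interventions. None of these
caveats affect the arithmetic identities or the parameter-recovery
guarantees the package is tested on.
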