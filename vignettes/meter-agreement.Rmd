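---
title: "Validating point-of-care glucose and ketone meters: the statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating point-of-care glucose and ketone meters: the statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocagree)
```

## The problem

Handheld point-of-care (POC) meters read glucose (mg/dL) and
β-hydroxybutyrate (β-HB, mmol/L) from a drop of whole blood or plasma in
seconds. Before such a meter can be trusted in a clinical or field setting —
here, health assessment of stingrays, whose preferred oxidative fuel is the
ketone body β-HB rather than glucose — its readings must be compared against
a reference laboratory analyzer on paired samples. `pocagree` implements the
complete agreement workbench for such a validation study: replicate
precision, percent bias, observed total error, relative-error zoning,
Bland–Altman limits of agreement, Passing–Bablok rank regression, and a
mixed-model screen for covariates that drive disagreement. A synthetic-study
generator with the same design (4 species, 28 animals, 3 meters, 2 specimen
matrices) makes every stage runnable and testable at desk scale.

Throughout, the *reference* analyzer measures plasma only, while each POC
meter measures both heparinized whole blood and plasma; every statistic is
computed per (meter, analyte, matrix) against the reference plasma value of
the same animal.

## Handling readings below the limit of quantification

Meters report values below their lower limit of quantification (LLOQ) as a
censoring token (`"<20"` for a 20 mg/dL glucose LLOQ). `impute_lloq()`
substitutes half the LLOQ (20 → 10 mg/dL), the constant-substitution rule
with the least bias among single-imputation approaches. The censored flag is
kept so that reports can print a censored minimum as `"< 20"` and count how
many values were imputed. Imputation is a genuine distortion of the low
tail: summary means, bias percentages and regression fits computed on
heavily censored combinations (low-range glucose on a 20 mg/dL-LLOQ meter)
inherit it, which is why the coverage checks below use an uncensored
device/analyte combination.

## Error metrics

For five replicate readings of the same sample,

$$\mathrm{CV\%} = \frac{\mathrm{SD}}{\mathrm{mean}} \times 100$$

with the sample (n − 1) standard deviation (the denominator convention is
ours; at n = 5 the distinction is visible, and the sample form is the
standard unbiased-variance choice). When several animals carry replicate
runs, the per-animal CVs are averaged. Mean-level inaccuracy is

$$\mathrm{Bias\%} = \frac{\overline{x}_{\mathrm{ref}} -
\overline{x}_{\mathrm{POC}}}{\overline{x}_{\mathrm{ref}}} \times 100,$$

signed, with reference minus POC in the numerator — a meter that reads high
has *negative* bias under this convention. The Westgard-style combined
metric is

$$\mathrm{TE_{obs}\%} = 2 \times \mathrm{CV\%} + \mathrm{Bias\%}.$$

Because TE is a magnitude-style quality figure and published tables print it
positive, `total_error_observed()` uses |Bias| by default and exposes a
signed variant. Per-pair accuracy uses

$$\mathrm{RE\%} = \frac{x_{\mathrm{POC}} - x_{\mathrm{ref}}}{x_{\mathrm{ref}}}
\times 100,$$

and `zone_proportions()` reports the percentage of pairs with |RE| strictly
below 12, 15 and 20% — the FDA human-glucometer accuracy bands. Strict
inequality and the absolute value are our reading; proportions are only
meaningful on |RE|, and the boundary case is measure-zero for continuous
data.

## Bland–Altman agreement

On differences $d_i = x_{\mathrm{POC},i} - x_{\mathrm{ref},i}$:

* mean bias $\bar d$, limits of agreement $\bar d \pm 1.96\, s_d$;
* bias CI: $\bar d \pm t_{1-\alpha/2,\,n-1}\, s_d/\sqrt n$;
* each LoA CI: $\mathrm{LoA} \pm t_{1-\alpha/2,\,n-1}\, s_d \sqrt{3/n}$,
  the classical large-sample approximation $\mathrm{Var(LoA)} \approx
  3 s_d^2 / n$ from the original method paper.

Bias is flagged significant when the bias CI excludes 0. Two deliberate
quantile choices: the LoA multiplier is the fixed normal 1.96 (a population
95% band on individual differences), while the CIs use t quantiles with
df = n − 1; `ci_quantile = "z"` is exposed for users who want the pure
normal version, since published tables rarely state which was used. The
upper LoA always equals $2\bar d - \mathrm{LoA}_{\mathrm{lower}}$ exactly —
a structural identity the test suite asserts, and which holds for published
tables only up to print rounding.

## Passing–Bablok regression

The rank-based structural regression of POC on reference. All pairwise
slopes $S_{ij} = (y_j - y_i)/(x_j - x_i)$, $i < j$, are formed with the
method's degenerate-pair rules, pinned explicitly here because published
applications delegate them to the original procedure:

* pairs identical in both coordinates contribute nothing;
* vertical pairs ($x_i = x_j$, $y_i \ne y_j$) contribute a signed infinite
  slope;
* slopes exactly −1 are dropped;
* $K$ = number of remaining slopes < −1.

The slope is the $K$-shifted median of the sorted slopes (for even $N$ the
mean of the two central order statistics); the intercept is
$\mathrm{median}(y - b x)$. The CI uses the rank statistic
$C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}$, $M_1 =
\mathrm{round}((N - C)/2)$, $M_2 = N - M_1 + 1$, giving slope bounds
$(S_{(M_1+K)}, S_{(M_2+K)})$; the intercept bounds re-fit the intercept at
the opposite slope bounds. *Rounding rule:* the method papers say "rounded
to the nearest integer" without a half rule; we use round-half-away-from-zero
and the brute-force oracle (`pb_oracle()`, an independent double-loop code
path) applies the same rule, so the equality test between the two paths is
exact, not approximate. Constant bias is declared when the intercept CI
excludes 0; proportional bias when the slope CI excludes 1. No cusum
linearity test is provided. Below n = 10 the fit warns; when the rank
indices fall outside the slope multiset the CI is refused rather than
clamped.

Two structural caveats the tests respect:

* exact scale equivariance holds on positively associated data (all
  pairwise slopes positive); the −1 exclusion and the $K$ offset live on
  the slope scale, so arbitrary-sign data is only approximately equivariant;
* like any method assuming comparable error in both methods (the implicit
  error-variance ratio is the squared slope), the estimator acquires an
  upward slope bias when the reference is nearly error-free and the test
  method is noisy. At the noise levels of this study's meters (replicate
  CVs of 0–12%, mostly ≤ 3%) the effect is negligible, but users comparing
  a very noisy method against a gold standard should prefer a regression
  that models the error ratio explicitly.

## The mixed-model covariate screen

For each meter and analyte, the difference $d = x_{\mathrm{POC}} -
x_{\mathrm{ref}}$ (one row per animal × matrix) is modelled with sex
(F = 0, M = 1), centred weight/PCV/buffy coat, and matrix (plasma = 0,
whole blood = 1) as fixed effects, and random intercepts for species and
individual (individuals are nested in species by id construction; coding
them as crossed is equivalent). Centring the continuous covariates is our
choice — it affects only the intercept and improves conditioning; the
scale of the covariates is untouched.

Fitting is by REML through `lmerTest` with Satterthwaite degrees of
freedom — the exact tool a practitioner would use for this model, and the
package treats it as infrastructure rather than re-deriving it. What the
package adds is validation: the test suite pins the fit against two
closed-form oracles (ordinary least squares when both group variances are
estimated at the zero boundary, tolerance 10⁻⁶ relative; the balanced
one-way ANOVA estimators $\hat\sigma^2_e = \mathrm{MSE}$,
$\hat\sigma^2_g = (\mathrm{MSB} - \mathrm{MSE})/m$ when interior) and
verifies the matrix test's type-I error at the study's design size (500
null simulations, 5% ± 2.5%). Boundary variance estimates are legitimate
REML solutions and are flagged (`boundary`), not errored. Animals missing a
fixed-effect covariate are dropped from this model only — never from the
agreement statistics — with a warning naming them.

## The synthetic-study generator

`simulate_study()` emulates the validation study's design so the entire
pipeline can be exercised without data:

* **Population**: 28 animals in 4 species (10 Atlantic, 6 cownose, 4
  southern, 8 yellow stingrays), printed weight ranges, sex Bernoulli(1/2),
  PCV ~ U(11, 32)%, buffy coat ~ U(0, 4)%, total solids ~ U(4.4, 8.1) g/dL.
* **True analyte values**: species-specific lognormals parameterised from
  the published per-species medians and ranges (glucose medians 26–48
  mg/dL; β-HB medians 0.22–0.31 mmol/L), chosen for positivity and right
  skew; no distribution is published, only ranges. Yellow stingrays carry a
  1/8 probability of a ×10 β-HB outlier, emulating the single extreme
  ketosis individual the study observed.
* **Measurement model**: a meter reads $\alpha + \beta\,t +
  \gamma\,\mathbb{1}[\mathrm{WB}] + \varepsilon$, $\varepsilon \sim
  N(0, (\sigma_0 + \sigma_1 t)^2)$ — constant plus proportional bias with
  heteroscedastic noise, which is exactly the structure Passing–Bablok and
  Bland–Altman are designed to detect. Default $(\alpha, \beta)$ per device
  emulate the published regression magnitudes; $(\sigma_0, \sigma_1)$ are
  sized from the published replicate CV column (0–11% by device and
  analyte). Readings below the device LLOQ (20 mg/dL glucose on all three
  meters; 0.1 mmol/L β-HB on two, none on the third) become censored
  records; negative draws truncate at 0 and are counted in metadata. The
  reference analyzer reads plasma only, with 2% CV multiplicative noise and
  its own 20 mg/dL glucose LLOQ.
* **Replicates**: 2 yellow stingrays re-measured 5 times per meter,
  analyte and matrix, sharing the truth across draws.
* **Determinism**: one study seed; sub-streams are derived per
  (stage, device, analyte) by a documented string hash, so adding or
  removing a device never perturbs any other draw — a property the test
  suite asserts.

What the generator does *not* emulate: meter read-out discretisation (the
published 0% CVs arise from 0.1 mmol/L resolution; we model continuous
noise sized to the same magnitude), anesthesia or venipuncture-site
physiology, sample-handling decay, and any matrix-specific noise change.
Passing the recovery tests therefore shows the statistics are computed
correctly under the declared error model, not that any particular real
meter is accurate.

## Verification choices and problem sizes

The suite verifies each stage against an independent oracle: hand-computed
constants for CV/bias/TE/RE, brute-force counting for zone proportions, a
literal-enumeration Passing–Bablok oracle (equality asserted on 1000 random
instances, n ∈ [10, 60], ties and verticals included), closed-form OLS and
ANOVA limits for the mixed model, and published worked examples for the
TE identity, the half-LLOQ rule and LoA symmetry. Distributional checks
use the study's design size: Passing–Bablok CI coverage of the generator's
$(\alpha, \beta)$ over 500 seeded studies at n = 28 (run on the β-HB meter
without an LLOQ, because half-LLOQ imputation deliberately shifts the
censored low tail and would change the estimand); Bland–Altman bias-CI
coverage over 2000 runs of $d \sim N(\mu, \sigma)$ at n = 28 — the model
under which the t interval is exact; mixed-model type-I error over 500 null
fits. Larger asymptotic checks (LoA convergence at n = 10⁵, censoring
fraction against its normal-CDF prediction at n = 10⁴) pin the generator
itself. These sizes are the package's verification design; they keep the
full suite within a coffee break on a laptop.

## Reporting conventions

All statistics are carried at full precision; rounding happens only at
render time (`render_*_table()`, `write_agreement_report()`): glucose in
whole mg/dL, β-HB and percents to one decimal, censored minima printed as
`"< LLOQ"`, significance stars on CI-excludes-null flags. `report.json`
keeps full precision alongside provenance (input MD5, seed, imputation
count, package version, timestamp). Animals may be excluded from
Bland–Altman/Passing–Bablok *plot data* (mirroring outlier handling in
published figures); statistics always use all pairs, and exclusions are
logged in provenance.

## Known limitations

* Half-LLOQ substitution is a single-imputation heuristic; maximum
  likelihood or multiple imputation for left-censored data is out of scope.
* Passing–Bablok here has no cusum linearity diagnostic, and its slope is
  sensitive to the error-variance-ratio assumption (above).
* The mixed model offers random intercepts only — no random slopes,
  likelihood-ratio comparisons, or Kenward–Roger correction.
* No clinical error-grid analysis (Clarke/Parkes): there is no consensus
  on hypoglycemia/ketonemia thresholds for elasmobranchs, so the grids'
  clinical zones are undefined for these data.
* No serum/plasma distinction and no mg/dL ↔ mmol/L glucose conversion.
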