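---
title: "Radiobiological plan evaluation from DVHs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiobiological plan evaluation from DVHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvhbio)
```

## Scope and data model

`dvhbio` evaluates radiotherapy plans purely at the dose-volume-histogram
level: the input to every model is, per structure, a set of fractional
volumes $v_i$ (summing to 1) at bin-center doses $D_i$. Nothing in the
package touches 3-D dose grids or DICOM; DVHs arrive through a CSV schema,
a treatment-planning-system text-export reader, or the synthetic generator.

Two bin conventions are fixed throughout and matter for reproducibility:
differential volumes attach to half-open bins $[e_i, e_{i+1})$ and are
evaluated at bin centers, and minimum/maximum dose are reported at bin-edge
resolution (the lower/upper edge of the extreme nonzero bin), with no
extrapolation beyond recorded bins. Cumulative and differential modes
convert exactly into each other at shared edges (reverse cumulative sum and
successive differences), and `dose_at_volume()` / `volume_at_dose()`
interpolate the cumulative curve linearly; on a flat cumulative segment the
highest qualifying dose is returned, which makes $D_{95\%}$ of a
normalized plan equal to the prescription dose rather than 0.

## Fractionation correction

All dose-response parameters in the registry are defined on the
2-Gy-per-fraction equivalent scale, so every DVH is first corrected with
the linear-quadratic conversion

$$\mathrm{EQD2} = D\,\frac{1 + d/(\alpha/\beta)}{1 + 2/(\alpha/\beta)},$$

where $D$ is cumulative dose and $d$ dose per fraction. Two readings of
$d$ coexist and both are deliberate:

* correcting a **DVH**, each bin's dose is taken as delivered evenly over
  all fractions, $d_i = D_i / n_{\mathrm{fractions}}$ — the per-bin
  correction a biological-evaluation module applies;
* correcting a **scalar dose difference** between two plans (e.g. a
  $\Delta D_{95\%}$ of 6.5 Gy), the nominal prescription fraction dose is
  the physically meaningful $d$ (12 Gy for a 60 Gy / 5-fraction scheme),
  giving `eqd2(6.5, 12, 10)` $= 11.9$ Gy. A per-bin reading would be wrong
  here: the difference is not itself a delivered course.

The correction maps the dose axis monotonically and leaves volumes
untouched, so the output grid is non-uniform; all downstream metrics accept
that. No high-dose LQ modifications (LQ-L, universal survival curve) are
implemented: at SBRT fraction doses the plain LQ conversion is itself an
acknowledged approximation, and we keep it explicit rather than stacking a
second model on top.

## Tumor control probability

The per-dose response is the Poisson linear-quadratic sigmoid in the
Källman parameterization,

$$P(D) = 2^{-\exp\!\big(e\,\gamma\,(1 - D/D_{50})\big)},$$

chosen because its two parameters are exactly the quantities the bundled
fits report: $P(D_{50}) = 0.5$ by construction and $\gamma$ is the
normalized slope at the steepest point. A DVH aggregates under the
voxel-independence assumption,

$$\mathrm{TCP} = \prod_i P(D_i)^{\,v_i},$$

the standard Poisson product rule. Because commercial modules do not
document their aggregation, an EUD-based reduction (response evaluated at
the $n = 1$ generalized mean) is provided as `tcp_method = "eud"`; the
product rule is the default and is what the tests oracle against
brute-force per-voxel products.

Bundled tumor sets (tumor $\alpha/\beta$ = 10 Gy): Willner 24-month
($D_{50}$ 74.5 Gy, $\gamma$ 3.5), Martel 24-month (72.0, 2.0) and Martel
30-month (84.5, 1.5) local control for NSCLC.

## Normal tissue complication probability

Two architectures are implemented.

**LKB**: probit response on the generalized equivalent uniform dose,
$\mathrm{NTCP} = \Phi\big((\mathrm{EUD} - D_{50})/(m D_{50})\big)$ with
$\mathrm{EUD} = (\sum_i v_i D_i^{1/n})^n$. The printed form of the EUD in
some sources parenthesizes the exponent ambiguously; the standard
generalized-mean reading (exponent $1/n$ inside the sum, $n$ outside) is
used, since any other reading loses the defining properties ($n = 1$ mean
dose, uniform-dose fixed point, $n \to 0$ max dose). $\Phi$ is evaluated in
closed form (`pnorm`); the test suite cross-checks it against numerical
quadrature of the probit integrand to $10^{-7}$ over $t \in [-6, 6]$.

**Relative seriality**: $\mathrm{NTCP} = [1 - \prod_i (1 -
P(D_i)^s)^{v_i}]^{1/s}$ with the same Poisson-LQ $P$ and seriality $s$;
at uniform $D_{50}$ it returns 0.5 for any $s$, and at $s = 1$, uniform
dose, it collapses to $P(D)$.

Each NTCP parameter set carries its own $\alpha/\beta$ (lung 1.3 Gy by
default, with a 3 Gy variant; esophagus LKB 10 Gy; heart 2.5 Gy; the
seriality sets 3 Gy), and the pipeline EQD2-corrects the organ's DVH
separately per set — parameter fits and fractionation scale are a package
deal and must not be mixed.

## Numerical choices

* Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs and
  products. This only becomes visible below roughly 8 Gy EQD2 for the
  tumor sets, where the response is physically negligible anyway; oracle
  tests therefore sample voxel doses above 10 Gy so the clip is inert.
* EUD is computed in log-scaled form (doses normalized by their maximum
  before exponentiation), so small $n$ (large exponents $1/n$) cannot
  overflow; zero-dose bins contribute zero.
* Degenerate inputs are defined, not errors, where a definition exists:
  Kruskal-Wallis on identical values returns $H = 0$, $p = 1$; a constant
  covariate yields an explicitly "undefined" correlation.
* Constraint inequalities are strict (`<`), so a measured value exactly at
  a limit fails; a missing structure yields "not evaluable", never a pass.

## Cohort comparison

Paired deltas are defined reference − recalculated, so positive values
mean the reference plan reports more dose or higher probability. Cohort
summaries are medians with (min, max) ranges, stratified by tumor
location. Between-role p-values use the Kruskal-Wallis rank test as an
*unpaired* comparison — mirroring how such studies typically cite it — and
this is statistically questionable for paired data, which is why the
package reports it as a descriptive echo and offers the paired deltas
themselves as the primary quantities. For small samples (pooled $n \le
10$) the p-value switches to the exact permutation distribution of $H$.
Trend screens use Spearman rank correlation with a seeded 10 000-draw
permutation p-value and make no model-based significance claims.

## The synthetic cohort generator

No patient DVHs are available to this package, so `generate_cohort()`
produces a cohort with the *statistical structure* the analysis assumes,
not with realistic DVH shapes:

* Reference PTV: a smooth monotone cumulative curve from a drawn minimum
  dose (51.2–57.1 Gy) to a drawn maximum (63.7–73.2 Gy), shaped as a
  power-law quantile pinned so that $D_{95\%}$ is exactly the 60 Gy
  prescription — the normalization every reference plan carries.
* Recalculated PTV: a monotone, volume-conserving dose-axis remap that
  lowers $D_{95\%}$ by a per-patient $\delta$ drawn uniformly from the
  per-location ranges (peripheral 0.3–6.5 Gy, central 0.6–4.4 Gy). Uniform
  is the minimal assumption given only a median and range; a triangular
  option peaked at the configured median (1.7 / 1.0 Gy) is available. The
  drop is applied fully at doses at or below the prescription (tapering to
  zero below 20 Gy so the axis stays non-negative) and tapers to
  $0.2\delta$ at the maximum dose, so the mean drops less than $D_{95\%}$
  — the pattern paired dose-engine recalculations show.
* OARs: exponentially decaying cumulative curves scaled to a drawn mean
  dose and truncated below each organ's maximum-point-dose criterion, so
  generated plans satisfy the bundled constraints by construction; the
  recalculated partner differs by one multiplicative dose perturbation
  within ±2 %. The mean-lung-dose range of 3–8 Gy is **invented** (no lung
  DVH summaries exist to match); the other organs' mean ranges are fixed
  plausible values. PTV volumes are drawn from the per-location ranges
  15.3–107.3 cc (peripheral) and 19.0–144.9 cc (central); the default
  cohort is 28 patients, 19 peripheral / 9 central.
* Reproducibility: each patient's draws are seeded from the cohort seed
  plus the patient counter, so cohorts are bit-identical across runs and
  insensitive to evaluation order; written cohorts round-trip bytewise.

What passing tests on this cohort do show: the pipeline's plumbing, the
monotone coupling between coverage loss and TCP loss, and the insensitivity
of low-value lung NTCP to small dose perturbations. What they cannot show:
anything about real DVH shapes, dose-engine physics (lateral scatter in
low-density lung), or the actual magnitudes of clinical TCP/NTCP — the
generator emulates consequences, not causes.

## Problem sizes and defaults

DVHs use a 0.1 Gy default bin width (configurable); the default scheme is
60 Gy in 5 fractions. The test suite exercises voxel-list oracles up to
100 voxels, property suites over 10–20 random DVHs per invariant, and one
full 28-patient cohort end to end; the whole suite runs in well under a
minute on one CPU.

## Known limitations

* LQ-based EQD2 at 12 Gy per fraction extrapolates the model beyond the
  fraction sizes most parameter fits used; results at such doses are
  model-consistent, not validated predictions.
* The TCP aggregation rule of commercial biological-evaluation modules is
  undocumented; the product rule is an assumption (the EUD alternative is
  provided for sensitivity checks).
* Minimum/maximum dose depend on the recorded bin resolution by design.
* The Kruskal-Wallis echo treats paired samples as independent (see
  above).
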