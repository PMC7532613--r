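---
title: "Modelling secondary cancer risk from dose-volume histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary cancer risk from dose-volume histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrisk)
```

## The problem

Modern external-beam radiotherapy for left-sided breast cancer with nodal
involvement gives patients a long life expectancy, which makes the small but
real probability of a radiation-induced second malignancy — in the lungs and
the contralateral breast — a clinically relevant planning consideration,
especially for younger patients. Different techniques distribute the
out-of-field dose very differently: pencil-beam-scanning proton therapy (PT)
confines dose tightly around the target, tangential 3D-CRT leaks a modest
scatter dose, and VMAT trades conformity in the target for an extended
low-to-intermediate dose bath across the thorax. `scrisk` quantifies what
those dose baths mean in terms of expected second cancers, and compares
techniques at cohort level.

## The risk model

The package implements the organ-equivalent-dose (OED) formalism. Two organs
are taken to carry the same second-cancer risk whenever their dose
distributions would induce the same cancer incidence; the OED is the uniform
dose with that property. Given a differential dose-volume histogram (DVH)
with per-bin volume fractions $v_i$ at representative doses $D_i$, the three
supported dose-response assumptions give

$$
\mathrm{OED}_{\text{linear}} = \sum_i v_i D_i, \qquad
\mathrm{OED}_{\text{lin-exp}} = \sum_i v_i D_i e^{-\alpha D_i}, \qquad
\mathrm{OED}_{\text{lin-plat}} = \frac{1}{\delta}\sum_i v_i \left(1 - e^{-\delta D_i}\right),
$$

with defaults $\alpha = 0.044\,\mathrm{Gy}^{-1}$ and $\delta =
0.139\,\mathrm{Gy}^{-1}$ estimated from combined atomic-bomb and
Hodgkin-lymphoma survivor data. The linear model assumes risk keeps growing
with dose and is known to overestimate risk beyond a few Gy; the
linear-exponential (bell-shaped) model assumes no repair or repopulation of
sterilised cells, and the linear-plateau model assumes full repair. The two
non-linear models bracket the plausible biology, which is why all three are
computed; results under the linear model should be read as a reference
ceiling. Useful analytic facts, all verified in the test suite: linear OED
is exactly the mean dose; both non-linear OEDs are strictly below it
whenever any dose is positive; the plateau model is bounded by $1/\delta
\approx 7.19$ Gy; a uniform dose maximises the linear-exponential response
at $D = 1/\alpha \approx 22.7$ Gy.

Excess absolute risk (EAR) then follows by direct proportionality,

$$ \mathrm{EAR} = \mathrm{EAR}_0 \cdot \mathrm{OED}, $$

where $\mathrm{EAR}_0$ is the organ-, sex- and age-dependent low-dose risk
coefficient in cases per 10,000 persons per year per Gy, taken from
atomic-bomb survivor analyses for females at attained age 70: 7.5 (lung) and
9.2 (breast) for exposure at age 30, changing to 7.8 and 3.7 for exposure at
age 50. The steep drop of the breast coefficient with exposure age — a
reduction of $1 - 3.7/9.2 \approx 60\%$ — is what drives the
age-at-exposure difference $\Delta\mathrm{EAR} = \mathrm{EAR}_{30\text{--}70}
- \mathrm{EAR}_{50\text{--}70}$ reported by `delta_ear()` and the report
tables; the lung coefficients barely move, so lungs contribute little to it.
A cumulative EAR per patient is the plain sum of the organ EARs, which is
well-defined because the formalism is linear in the baseline coefficients.
Attained ages other than 70 are rejected unless the user supplies extended
coefficient entries, because extrapolating the published coefficients would
be silent guesswork. Confidence intervals on $\mathrm{EAR}_0$ are propagated
multiplicatively to EAR bounds with no added distributional assumption; they
are reported, never combined across organs.

No fractionation or dose-rate correction is applied: the OED sums above are
used exactly as written, so results describe the 2 Gy-per-fraction regime
they were fitted in. Proton doses are stored as constant-RBE-weighted
Gy(RBE); the `rbe_weighted` flag is bookkeeping and never triggers a
conversion.

## DVH conventions and numerical choices

DVHs are stored as bin edges plus either differential volume fractions (one
per bin) or cumulative fractions (one per edge, starting at 1). Validation
(`validate_dvh()`) reports every broken invariant — normalisation within
$10^{-9}$, monotonicity, edge ordering — rather than repairing anything
silently; computations refuse invalid input with a classed error.

* **Representative dose is the bin centre, for every bin.** This is
  unbiased when dose is roughly uniform within a bin and makes the binned
  OED agree with a brute-force per-voxel evaluation to within half a bin
  width (the test suite checks this for all three response functions at
  $10^4$ voxels). The first bin of a grid starting at 0 is treated no
  differently: a truly unirradiated organ is therefore reported with a mean
  of half a bin width (0.025 Gy at the default grid), a deliberate trade
  against biasing genuinely low-dose organs whose mass sits in that bin.
* **Default bin width is 0.05 Gy**, giving discretisation errors orders of
  magnitude below the inter-patient spread at prescription-level doses while
  keeping a 50 Gy DVH at 1,000 bins.
* **Conversion** between the two forms is the exact finite-difference /
  reverse-cumulation pair, an identity round trip to $10^{-12}$.
* **Rebinning** moves each source bin's volume as a point mass at its
  centre into the destination grid: volume is conserved exactly, a
  uniform-dose spike stays a spike under refinement, and the mean moves by
  at most half the destination bin width. The original clinical analyses'
  export binning is unknowable from published material, so this
  bin-refinement invariance is what bounds the associated uncertainty.
* `uniform_dvh()` centres a single bin exactly on the requested dose so
  closed-form expectations hold to machine precision in tests and in the
  published-arithmetic reproduction.

## Cohort statistics

`summarize_cohort()` averages per-organ EAR over patients and reports both
SD and SEM ($= \mathrm{SD}/\sqrt{n}$), because the source tables the
package reproduces mix the two conventions (dose tables use SEM, EAR tables
SD); the reporting convention is a configuration choice, never a change to
the numbers. Cumulative EAR is summed per patient and then averaged, which
by linearity equals the sum of organ means — asserted to $10^{-9}$ in the
tests. Cohorts need at least two patients; dispersion of a singleton is
undefined and refused rather than returned as `NA`.

Technique comparisons report **two** relative-factor conventions: the ratio
of cohort mean cumulative EARs (the headline value, which reproduces the
published factors arithmetically from the table rows) and the mean ± SEM of
per-patient ratios. The published "±" on factors is not defined precisely
in the source material, so both are emitted and neither is asserted to be
"the" published convention. Significance uses two-tailed paired Student t
tests at 0.05 via `stats::t.test()`; a zero-variance difference vector
(identical or uniformly shifted cohorts, common with synthetic data)
returns $p = 1$ with a `degenerate` flag instead of an exception. No
multiple-testing correction is applied; reports record how many tests were
run so readers can apply their own.

## The synthetic cohort generator

No per-patient clinical DVHs are publicly available for the study design
the package reproduces (two five-patient groups, 50 Gy prescription, PT vs
tangential 3D-CRT for supraclavicular-node targets and PT vs VMAT when
internal mammary nodes are included, free breathing and breath hold).
`generate_cohort()` therefore emulates them from published summary
statistics:

* Each organ's DVH is a **two-component mixture**: a target-adjacent
  high-dose component (beta distribution scaled to $[0, 50]$ Gy) holding
  volume fraction $f_h$, plus an exponential low-dose bath truncated at the
  prescription dose. Published cumulative DVH morphology motivates the
  family: photon plans show long low-dose tails in contralateral organs
  (bath means of 1.5–2 Gy), proton plans a near-step behaviour (bath means
  below 0.1 Gy contralaterally). Only cohort mean doses are published, so
  the component shapes are free parameters; $f_h$ is solved per patient so
  the **discretised** mixture mean equals the patient's drawn mean dose
  exactly. Draws below the discretised bath mean switch to a pure bath
  whose rate is re-solved by `uniroot`; draws outside the representable
  range $[w/2, \bar D_{\text{high}}]$ are clamped to it; a *profile* mean
  above the high component's mean is a configuration error.
* **Inter-patient spread** is lognormal around the arm's published mean
  dose with CV = published SEM $\times \sqrt{5}$ / mean, winsorised at the
  0.1%/99.9% normal quantiles — a planning cohort's spread is bounded, and
  an unbounded tail would let a single extreme draw dominate cohort means
  at the highest CVs. Sampling is Latin-hypercube stratified (one normal
  stratum per patient with uniform jitter), so cohort means converge at
  $O(1/n)$ while a five-patient cohort still shows realistic spread.
* **Pairing.** The stratum draw for patient $i$ and organ $o$ depends only
  on the master seed, $i$ and $o$ — not on the technique — so two cohorts
  generated with the same seed represent the same anatomies planned twice,
  exactly the paired design the t tests assume. Large organs receive more
  dose under both techniques, which is the correlation that gives the
  paired test its power.
* Outputs are **byte-reproducible** for a fixed configuration: numbers are
  written with 17 significant digits and every random draw comes from a
  deterministic substream of the master seed.

What the generator does *not* emulate, and what passing tests therefore do
not show about clinical data: anatomical dose gradients and organ geometry,
covariance between organs beyond the single shared anatomy factor,
systematic planning differences between centres, heart dose, and the true
patient-level dispersions of the clinical cohorts (the published
per-patient DVHs not being available, only dispersions *of the same order*
as the printed SEMs are claimed). Reproduction of the published per-organ
EAR tables from synthetic cohorts is accurate to roughly the printed
standard deviations, not to the digit.

## Verification problem sizes

The shipped tests exercise: closed-form OED agreement to $10^{-12}$ on a
0–60 Gy grid; model orderings on 1,000 random DVHs; voxel-oracle
equivalence at $10^4$ voxels; conversion/rebinning invariants on 100 random
DVHs; generator calibration at $n = 200$ patients (cohort organ means
within 1% of the configured means for the free-breathing Group 2 arms,
whose CVs make that check statistically meaningful); and paired-test power
over 100 master seeds of five-patient VMAT-vs-PT cohorts, where the
ipsilateral-lung comparison rejects at 0.05 in at least 95 of 100 seeds.
These sizes were chosen to keep each property's Monte-Carlo error well
below the asserted tolerance at desk scale.

## Known limitations

* The formalism is incidence-only: no mortality conversion, no lifetime
  attributable risk, no population transfer of coefficients.
* $\mathrm{EAR}_0$ coefficients carry wide confidence intervals; absolute
  EARs inherit them. Relative technique comparisons are far more robust
  than absolute risks, and that is the intended use.
* Neutron dose (relevant to proton delivery), variable proton RBE, imaging
  dose, fractionation corrections and heart/oesophagus/thyroid endpoints
  are all out of scope.
* The default coefficient table covers female lung and breast at attained
  age 70 with exposure at 30 or 50; anything else must be supplied
  explicitly through the risk configuration.
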