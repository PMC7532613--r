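# scrisk — secondary cancer risk from dose-volume histograms

`scrisk` estimates the risk of radiation-induced second malignancies after
external-beam radiotherapy, and compares treatment techniques on that
basis. It is aimed at medical physicists and modelling researchers who have
per-organ dose-volume histograms (DVHs) exported from a treatment planning
system and want organ-equivalent doses, excess absolute risks and paired
cohort comparisons — for example pencil-beam-scanning proton therapy versus
tangential 3D-CRT or VMAT in left-sided breast cancer with nodal
involvement.

## The model

A DVH with per-bin volume fractions $v_i$ at bin-centre doses $D_i$ is
reduced to an organ equivalent dose (OED) — the uniform dose carrying the
same cancer-induction risk — under three dose-response assumptions:

$$
\mathrm{OED}_{\text{linear}} = \sum_i v_i D_i
\qquad
\mathrm{OED}_{\text{lin-exp}} = \sum_i v_i D_i e^{-\alpha D_i}
\qquad
\mathrm{OED}_{\text{lin-plat}} = \frac{1}{\delta} \sum_i v_i (1 - e^{-\delta D_i})
$$

with $\alpha = 0.044\,\mathrm{Gy}^{-1}$, $\delta = 0.139\,\mathrm{Gy}^{-1}$.
Excess absolute risk follows by proportionality,
$\mathrm{EAR} = \mathrm{EAR}_0 \cdot \mathrm{OED}$, with baseline
coefficients $\mathrm{EAR}_0$ (cases per 10,000 persons per year per Gy,
attained age 70) from atomic-bomb survivor analyses: lung 7.5, breast 9.2
for exposure at age 30; lung 7.8, breast 3.7 for exposure at age 50.
Per-patient cumulative EAR is the sum over organs; cohorts are compared by
relative factors on cumulative EAR and two-tailed paired Student t tests.
A calibrated synthetic cohort generator (two-component mixture DVHs:
target-adjacent high-dose component plus exponential low-dose bath)
reproduces the study conditions — five-patient groups, 50 Gy prescription,
published mean organ doses — so the whole pipeline runs without clinical
data. See the methods vignette (`vignettes/secondary-cancer-risk.Rmd`) for
assumptions, parameter choices and limitations.

## Worked example

Generate paired synthetic cohorts (same seed = same anatomies planned with
both techniques) for the group with internal-mammary-node involvement, then
summarise and compare under the linear-exponential model:

```r
library(scrisk)

vmat <- generate_cohort(synthetic_cohort_config(group = 2, technique = "VMAT",
                                                setup = "FB", seed = 2020))
pt   <- generate_cohort(synthetic_cohort_config(group = 2, technique = "PT",
                                                setup = "FB", seed = 2020))

summarize_cohort(vmat, model = "linear_exponential")
#> <cohort_summary> 2-VMAT-FB, model linear_exponential, exposure age 30, n = 5
#>                 organ mean_ear  sd sem
#>      ipsilateral_lung       32 5.3 2.4
#>    contralateral_lung       31 5.2 2.3
#>  contralateral_breast       27 2.4 1.1
#> cumulative EAR: 90 (SD 12.8, SEM 5.7) cases per 10,000 person-years

summarize_cohort(pt, model = "linear_exponential")
#> <cohort_summary> 2-PT-FB, model linear_exponential, exposure age 30, n = 5
#>                 organ mean_ear  sd sem
#>      ipsilateral_lung       16 1.2 0.5
#>    contralateral_lung        2 1.4 0.6
#>  contralateral_breast        1 0.2 0.1
#> cumulative EAR: 19 (SD 2.8, SEM 1.2) cases per 10,000 person-years

relative_factor(summarize_cohort(vmat, model = "linear_exponential"),
                summarize_cohort(pt,   model = "linear_exponential"))
#> relative EAR factor: 4.85 (ratio of means); 4.86 +/- 0.02 (mean of per-patient ratios, SEM); p = 9.091e-05
```

Reading the output: under VMAT each of the three organs contributes
comparably (roughly a third each) to an expected ~90 extra cancer cases per
10,000 person-years, driven by the extended low-dose bath; under proton
therapy nearly all residual risk sits in the ipsilateral lung and the total
is ~19. The relative factor near 5 with p < 0.001 mirrors the roughly
five-fold risk increase of VMAT over protons for this target complexity.
EARs are displayed as rounded integers; full precision is kept in the
returned objects and in every CSV the pipeline writes.

The same pipeline is scriptable from a shell via the thin driver
`inst/cli/scrisk.R` (`simulate`, `compute`, `compare`, `report`
subcommands; exit codes 0/2/3 for success, validation failure,
configuration error).

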