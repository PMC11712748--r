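# hnplanr

Desk-scale tools for studying **automated head-and-neck IMRT treatment
planning** and its commissioning, entirely on synthetic data.

Automated planning platforms for head-and-neck radiotherapy chain together
several distinct pieces of machinery: template-plan automation (isocenter
placement, a standard 9-beam gantry layout, per-beam collimator jaw
fitting), beam's-eye-view (BEV) anatomical projections feeding a fluence-map
predictor with selectable parotid/target tradeoff profiles, dose computation
with prescription normalization, dose-volume endpoints, gamma-index
delivery QA, and a paired statistical comparison against reference plans.
Validating such a platform requires exercising every one of those stages.
`hnplanr` implements the full chain in R so that each stage - and the
pipeline end to end - can be tested against analytic and brute-force
references, with no clinical data, trained weights, or commercial planning
system involved. It is aimed at medical-physics researchers and developers
who need a transparent, reproducible desk model of the workflow.

## The core quantities

For a prescription dose $R_x$ (44 Gy here, covering 95% of the PTV after
normalization):

* **Conformity index** $\mathrm{CI} = V_{PR} / V_{PTV}$, the prescription
  isodose volume over the PTV volume (1.0 is perfectly conformal).
* **Heterogeneity index** $\mathrm{HI} = (D_{2\%} - D_{98\%}) / R_x$,
  reported x100 (0 for a perfectly uniform target).
* **$D_{x\%}$ / $D_{cc}$ / $D_{median}$**: minimum dose to the hottest x%
  (or cc) of a structure, by interpolated DVH inversion.
* **Gamma index** $\gamma = \min_r \sqrt{(\Delta d / \delta_D)^2 +
  (\Delta r / \delta_r)^2}$ with criteria like 3%/2 mm; the passing rate
  GPR is the percentage of points with $\gamma \le 1$.
* **Paired Wilcoxon signed-rank tests** with Bonferroni correction compare
  endpoint distributions between plan types at $\alpha = 0.05$; exact
  enumeration is used for $n \le 12$ pairs.

Six tradeoff profiles (BP, BO, LP, LO, RP, RO) pair a parotid-sparing
preference (**B**oth / **L**eft / **R**ight) with a priority for **P**TV
coverage or **O**AR sparing.

## Worked example

```r
library(hnplanr)

# a bilateral head-and-neck phantom with 15% PTV-parotid overlap
ph  <- generate_phantom(phantom_spec(overlap_fraction = 0.15, seed = 1))

# template automation + projections + baseline prediction + dose + endpoints
res <- plan_case(ph, profile = "BP")
res$template
#> <beam_template> 9 beams, SAD 1000 mm, isocenter ( 1.25, 11.25, 31.25) mm
#>   gantry: 180, 140, 100, 60, 20, 340, 300, 260, 220
res$endpoints
#> # A tibble: 12 x 4
#>    plan  endpoint              structure  value
#>  1 BP    PTV CI                PTV         1.05
#>  2 BP    PTV HI                PTV        34.9
#>  6 BP    Parotid_L Dmedian_Gy  Parotid_L  29.0
#>  7 BP    Parotid_R Dmedian_Gy  Parotid_R  29.2
#> # ... (BODY/brainstem/cord hot spots, remaining OAR medians, MU proxy)
```

The nine beams sit at exact 40-degree spacing starting from 180; the
isocenter is the PTV centroid rounded to 5 mm. CI of 1.05 means the
44 Gy isodose volume is 5% larger than the PTV; after normalization,
exactly 95% of the PTV receives at least 44 Gy. Switching the profile to
`"LP"` drops the left-parotid median dose (29.0 to 22.4 Gy on this phantom)
at the cost of the right parotid - the designed tradeoff.

The statistics layer works the same way on its own:

```r
paired_wilcoxon(c(1.20, 1.15, 1.31, 1.22, 1.18, 1.25),
                c(1.09, 1.11, 1.16, 1.10, 1.07, 1.13))
#> <paired_wilcoxon> V = 21, n = 6, p = 0.03125 (exact enumeration)
```

`autoplot()` methods cover DVH curves, DVH bands, fluence maps and gamma
maps; `tidy()`/`glance()` methods cover structure sets, test results, QA
reports and commissioning reports. A thin CLI mirroring the three-step
plan/predict/review workflow ships in `inst/cli/hnplan`.

## Scope

The fluence predictor is a deterministic conformal baseline behind a
pluggable registry (trained models can be registered without touching the
pipeline), and the dose engine is a simplified attenuation + scatter model,
clearly labelled as such: comparisons are meaningful within the engine, not
against clinical dosimetry. See the methods vignette
(`vignettes/hnplanr-methods.Rmd`) for the full model description, parameter
rationale and known limitations.
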