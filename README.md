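# aorta4d

Aortic biomechanics from time-resolved 3D segmentations.

Aortic diameter is the main criterion guiding prophylactic aortic surgery in
connective-tissue disease (e.g. Marfan syndrome), yet dissections occur below
the diameter threshold — which motivates functional stiffness markers.
`aorta4d` computes such markers from 4D cine segmentations of the thoracic
aortic lumen (one binary mask per cardiac phase, typically 30 phases at
~1 mm isotropic resolution), for imaging scientists and cardiovascular
researchers working with segmentation-based cine MRI:

* **3D distensibility** per segment (ascending: annulus → brachiocephalic
  trunk; descending: left subclavian artery → diaphragm):
  `D3D = (max_t V(t) − V_ED) / (V_ED · PP)`, in 1e-3/mmHg, with `PP` the
  brachial pulse pressure;
* **motion-corrected 2D distensibility** of tracked mid-ascending and
  mid-descending cross-sections: `D2D = (max_t A(t) − A_ED) / (A_ED · PP)`;
* **longitudinal strain** of the ascending aorta:
  `ε = 100 · (max_t L(t) − L_ED) / L_ED` (%), with `L` the annulus→BCT
  centerline length;
* **peak mean surface displacement** at four anatomical planes, from
  non-rigid (coherent point drift) registration of the end-diastolic lumen
  surface to every phase;
* **aortic tortuosity index**: arc/chord ratio of the centerline from the
  sinotubular junction to the diaphragm.

The package also provides a deforming-aorta phantom generator with fully
analytic ground truth (radial dilation, longitudinal stretch, weighted root
displacement on a realistic arch geometry), a cohort simulator calibrated to
published group summaries, and the cohort statistics stage (one-way ANOVA
with a 0.005 significance gate, Tukey HSD, univariate→multivariate linear
regression with VIF screening, Pearson correlation). The methods vignette
(`vignettes/aorta4d-methods.Rmd`) documents the models, parameter choices
and validation design.

## Worked example

Build a phantom with 10% radial dilation, 12% longitudinal strain and 8 mm
root displacement, then run the full measurement pipeline:

```r
library(aorta4d)

spec <- phantom_spec(spacing_mm = 1.5, n_phases = 10,
                     radial_amplitude_asc = 0.10, radial_amplitude_desc = 0.08,
                     strain_amplitude = 0.12, root_displacement_mm = 8)
phantom <- build_phantom(spec)

bp <- blood_pressure(128, 80)          # 128/80 mmHg -> pulse pressure 48
subject <- compute_subject(phantom$series, phantom_landmarks(spec), bp)
subject
#> <aorta_subject>
#>   3D distensibility AAo 7.154 / DAo 3.368 (1e-3/mmHg)
#>   2D distensibility mid-AAo 4.323 / mid-DAo 3.569 (1e-3/mmHg)
#>   longitudinal strain 12.34 % (phase 2)
#>   peak plane displacement: STJ 8.61, mid-AAo 3.41, mid-DAo 1.34, diaphragm 1.05 mm
#>   ATI 2.006, PP 48 mmHg
```

Reading the numbers: the ascending 3D distensibility (7.15) reflects the
combined radial (`(1+0.10)^2`) and longitudinal (`×1.12`) expansion over
pulse pressure; the analytic peak value for this spec is 7.40 and the small
shortfall is the 10-phase waveform grid not exactly hitting the systolic
peak. Strain recovers the generated 12%. The sinotubular-junction
displacement (8.61 mm) combines the weighted root translation at that level
(6.7 mm closed form) with coherent annulus motion that the large strain mode
pushes into the band — the vignette discusses when these mix — and decays to
~1 mm at the descending planes, as generated.
`analytic_metrics(spec, bp)` returns the closed-form
ground truth for any spec; `autoplot(subject)` plots the per-phase volume,
area, strain and displacement curves.

Real data enter through `read_series()` (4D NIfTI-1, or per-phase 3D files),
a landmark JSON and a `blood_pressure()`; `validate_series()` gates series
quality (one connected component per phase, clean margins). A thin
command-line front-end (`exec/aorta4d`, subcommands `phantom`, `metrics`,
`cohort`) wraps the same functions for shell pipelines.

Cohort-level analysis:

```r
cohort <- simulate_cohort(cohort_spec(seed = 1))
anova_oneway(cohort, dist3d_aao, group)      # F test across the 3 groups
tukey_hsd(cohort, dist3d_aao, group)         # pairwise contrasts
regress(cohort[cohort$group == "native", ], "dist3d_aao",
        c("age", "sex_male", "bsa", "root_diameter", "ati"))
```

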