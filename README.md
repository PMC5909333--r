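# nfquant

Quantification of myocardial infarction (MI) and its no-flow core on
contrast-enhanced cardiac MRI, with a ground-truth digital phantom for
validating every stage.

## The problem

On inversion-recovery gadolinium-enhanced (early/late gadolinium
enhancement, EGE/LGE) short-axis images, acute infarct appears bright
against nulled normal myocardium, while a hypoperfused core inside the
infarct — the *no-flow region* (NF), often called microvascular
obstruction — stays dark because contrast agent barely reaches it. Its
size carries prognostic weight, and it shrinks during the post-contrast
period as agent slowly diffuses in, so *when* you measure matters as much
as *how*. `nfquant` implements the full measurement chain for researchers
working with serial post-contrast acquisitions:

- **Threshold segmentation.** Remote (normal) myocardium is sampled with a
  ≥ 100-pixel ROI; a myocardial pixel is *enhanced* when its signal
  exceeds `mean_remote + k · SD_remote` (default `k = 5`).
- **Indirect NF measurement.** The NF is a sub-threshold island fully
  enclosed by enhanced tissue. Total MI = enhanced ∪ NF, and
  `NF = area(total MI) − area(enhanced)` — the indirect measurement that
  works even when the core shows no enhancement at all.
- **Volumes, mass, fractions.** Pixel counting × voxel size;
  LVM = myocardial volume × 1.05 g/ml; MI fraction (%LVM), NF fraction
  (%LVM and %MI).
- **Pixel-wise T2 mapping.** Two-parameter least-squares fit of
  `SI = SI₀ · exp(−TE/T2)` over a multi-echo series (vectorised
  Levenberg–Marquardt across all pixels), with regional mean ± SD.
- **Serial kinetics.** One-way repeated-measures ANOVA over post-contrast
  timepoints and Holm-corrected paired comparisons against the early
  (2-min) reference, returning the earliest timepoint from which the NF is
  significantly reduced "and thereafter".
- **Digital phantom.** A parametric LV annulus with a transmural infarct
  sector and a shrinking NF core, rendered through the same signal
  equations (mono-exponential T2 decay, magnitude IR `|1 − 2e^(−TI/T1)|`,
  Rician noise), with *exact* voxel-level ground truth for every region at
  every timepoint.

## Worked example

```r
library(nfquant)

spec  <- phantom_spec("reperfused", matrix_size = c(128L, 128L),
                      n_slices = 2L, seed = 20L)
truth <- build_phantom(spec)
truth
#> <phantom_truth> reperfused group
#>   myocardium 66.80 ml (LVM 70.14 g) | MI 17.08 ml
#>   NF (ml): 2'=7.69 10'=7.69 15'=7.69 20'=6.04 25'=4.78 30'=3.74 35'=2.97 40'=2.31 45'=1.81

ege <- render_lge_series(truth, 2)          # 2-min early acquisition
seg <- segment_series(ege, truth$contours)  # mean + 5 SD threshold
quantify_masks(seg, truth$pixel_spacing_mm, truth$slice_thickness_mm)
#> <quant_result>
#>   LV myocardium 66.80 ml (LVM 70.14 g)
#>   MI 17.08 ml (MIF 25.6 %LVM) | NF 7.69 ml (NFF 11.5 %LVM, 45.0 %MI)

t2map <- compute_t2_map(render_t2_series(truth), truth$masks$myocardium)
region_t2(t2map, truth$masks$myocardium & !truth$masks$mi)
#> remote T2: 57.8 +/- 4.5 ms over 905 pixels
```

The segmentation recovers the generator's configured volumes (17.1 ml MI,
7.7 ml NF at 2 min) to within the rasterisation granularity, and the
fitted remote T2 matches the configured 57 ms within the noise-induced
bias discussed in the methods vignette.

A one-command end-to-end run (phantom → T2 map → serial segmentation →
quantification → kinetics decision, with CSV/JSON/NIfTI outputs):

```sh
Rscript scripts/nfquant-pipeline.R --out out/demo --seed 1234
```

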