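# ivimhsi

Unsupervised breast-lesion detection and quantification for
multi-b-value IVIM diffusion-weighted MRI, treating the b-value stack
as a hyperspectral image cube.

## What it does

A diffusion-weighted acquisition with B weightings yields B co-registered
band images of the same slice; every pixel is then a length-B spectral
vector whose shape follows the bi-exponential intravoxel incoherent
motion (IVIM) model

    S_b / S_0 = (1 − PF)·exp(−b·D) + PF·exp(−b·D*)

with pure diffusion coefficient D, pseudo-diffusion coefficient D* of
capillary perfusion, and perfusion fraction PF. Lesions decay
differently from parenchyma, so their spectra are separable — which
turns lesion detection into hyperspectral subpixel target detection.
The package provides:

- **Detectors** — constrained energy minimization (CEM,
  `w = R⁻¹d / dᵀR⁻¹d`), its iterative (I-CEM) and RBF-kernel (K-CEM)
  variants seeded automatically by ATGP + spectral-angle pooling, and
  K-means / fuzzy C-means clustering with ATGP lesion-cluster
  identification; all binarized by Otsu's method.
- **Band expansion (BEP)** — squares and pairwise products grow 13
  bands into 104 (13 + 13 + 78), exposing second-order statistics to
  the linear filters.
- **Preprocessing** — polynomial log-domain bias-field correction,
  exhaustive integer-translation band registration, Otsu-based
  breast-region extraction.
- **Quantification** — ADC (log-linear through the origin), linear
  signal-decay slope, and segmented + Levenberg–Marquardt
  bi-exponential fits of D, D*, PF on ROI-mean decay curves.
- **Evaluation** — Dice, Jaccard, and confusion-matrix rates against
  ground truth.
- **A digital phantom** — label maps (compact mass or scattered
  non-mass lesions), per-class bi-exponential signal with literature
  lesion presets, Rician noise, a smooth bias field, and per-band
  shifts, with the ground truth carried alongside so the whole chain
  is testable end to end.

## Worked example

```r
library(ivimhsi)

# A 64x64 phantom: mass lesion, 2% Rician noise, 0.3-amplitude bias
# field, random +-3 px per-band shifts.
ph <- ivim_phantom(noise_sigma = 0.02, bias_amplitude = 0.3,
                   shifts = "random", seed = 3)

pp  <- preprocess_cube(ph$cube)                      # bias -> register -> mask
det <- detect_tumor(pp$cube, pp$breast_mask, method = "icem", seed = 3)

dice(det$mask, ph$truth_mask)
#> [1] 1

quantify_detection(pp$cube, det$mask, method = "icem")$params
#>   method          ADC   decay_slope       Dstar            D        PF refined
#> 1   icem 0.0009869072 -0.0003720053 0.005974277 0.0008233119 0.2444413    TRUE
```

The detected lesion's fitted parameters sit next to the phantom's mass
preset (D = 0.84e-3 mm²/s, D* = 6.10e-3 mm²/s, PF = 23%): D is
recovered within ~2%, D* within ~2%, and PF within ~1.5 points; ADC
lands between D and D* as perfusion inflates the apparent coefficient.

The same chain is scriptable from a shell:

```sh
Rscript exec/ivimhsi simulate --out phantom --seed 3 --bias 0.3 --shifts
Rscript exec/ivimhsi detect --cube phantom/cube.nii.gz --bvals phantom/bvals.txt \
        --out run --method icem,kcem,kmeans,fcm --seed 3
Rscript exec/ivimhsi evaluate --pred run/mask_icem.nii.gz --truth phantom/truth_mask.nii.gz
#> {"dice":1,"jaccard":1,"precision":1,"accuracy":1,"recall":1}
```

Cubes are NIfTI (H×W×1×B) with a plain-text b-value side-car; masks are
NIfTI; reports are CSV/JSON.

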