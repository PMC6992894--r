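# crpen

Quantifying how fast an alkaline buffer penetrates resin-embedded tissue
during **chemical reactivation (CR)** of quenched fluorophores.

In serial block-face imaging, resin embedding protonates and quenches GFP or
FITC; an alkaline buffer dropped on the block face restores fluorescence as
hydroxyl ions diffuse in. The reactivated depth at any moment sets how thick
a slice can be imaged and cut, so the penetration rate is the key system
parameter. `crpen` estimates it from time series of 3-D fluorescence stacks
and predicts reactivated thickness for any embedding resin.

## The model

Penetration is one-dimensional diffusion into a semi-infinite medium
(depth z in µm, time t in s, diffusion coefficient D in µm²/s):

    C(t, z) = erfc( z / (2 sqrt(D t)) )

Fluorescence saturates above a concentration threshold set by the
saturation coefficient K ≥ 1:

    I_f(t, z) = min{ 1, K · C(t, z) }

The depth of any isointensity contour grows as `Z_p(t) = s_p sqrt(t)` with
slope `s_p = 2 sqrt(D) · erfcinv(p / K)`. Measuring two contour slopes
(conventionally at levels 0.5 and 0.9) therefore determines both D and K:
`crpen` eliminates K through the erfc ratio, root-finds the remaining
scalar equation, and back-substitutes.

## Worked example

Solving the two-level system for the classic FITC-in-resin standard sample,
whose measured contour slopes are 0.642 and 0.441 µm/√s at levels 0.5 and
0.9:

```r
library(crpen)
params <- solve_DK(0.642, 0.5, 0.441, 0.9, sample = "FITC standard")
params
#> Penetration model parameters [FITC standard]
#>   D = 0.1396639 um^2/s
#>   K = 2.227459   (saturation threshold 1/K = 0.4489)
```

D ≈ 0.14 µm²/s is the hydroxyl diffusion coefficient through the resin
micropores; 1/K ≈ 0.45 means fluorescence is fully saturated wherever the
penetrated concentration exceeds 45% of its surface value.

The same estimate can be produced from images alone. Here the synthetic
generator stands in for the confocal stacks (64×64×50 voxels, four time
points, 2% Gaussian noise, truth D = 0.138, K = 2.233):

```r
spec <- synthetic_preset("standard", gaussian_sigma = 0.02, seed = 1)
gen <- generate_series(spec)
profiles <- lapply(seq_along(spec$times), function(i)
  normalize_profile(mean_profile(gen$series, i)))
report <- fit_penetration(profiles, sample = "synthetic standard")
report
#> Penetration model fit
#> Penetration model parameters [synthetic standard]
#>   D = 0.1382848 um^2/s
#>   K = 2.232666   (saturation threshold 1/K = 0.4479)
#>   Slope fit at level 0.5: 0.6395 um/sqrt(s) (R^2 = 1, n = 4)
#>   Slope fit at level 0.9: 0.4397 um/sqrt(s) (R^2 = 1, n = 4)
```

The recovered parameters sit within a fraction of a percent of the
generative truth. Forward prediction then gives the reactivated thickness —
the depths above which fluorescence exceeds 50% and 100%:

```r
cr_thickness_curves(report$params, levels = c(0.5, 1), times = c(60, 300, 1200))
#>   time_s level  depth_um
#> 1     60   0.5  4.953892
#> 2    300   0.5 11.077240
#> 3   1200   0.5 22.154479
#> 4     60   1.0  3.091570
#> 5    300   1.0  6.912961
#> 6   1200   1.0 13.825921
```

`resin_params()` ships fitted coefficients for GMA, LR white and Lowicryl
HM20 embedded mouse brain for the same forward predictions.

A thin command-line front end wrapping the same functions
(`simulate`, `extract`, `fit`, `predict`, `verify`) is installed at
`system.file("cli", "crpen.R", package = "crpen")`.

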