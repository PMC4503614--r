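# laserquad

Photogrammetric scaling of oblique seafloor still images from two parallel
laser lines.

## The problem

Quantitative seafloor surveys — benthic ecology, litter and geology
transects — need the ground area covered by each video frame or still. On
ROVs and towed platforms the camera looks at the seabed obliquely and moves
constantly, so no fixed image-to-ground scale exists, and the camera's
height, pan and tilt are rarely known well enough to compute one. A common
rig, however, carries two parallel sheet lasers fixed to the vehicle frame,
drawing two green lines of known separation *l* on the seabed.

`laserquad` implements the closed-form geometry that turns pixel
measurements of those two lines in a **single image** into ground length,
area, camera pose, camera altitude, seabed slope, and maximal first-order
uncertainties for all of them. The only calibration inputs are *l* (with
its tolerance) and the camera's horizontal and vertical angles of view
α<sub>H</sub>, α<sub>V</sub>; the physical sensor size cancels everywhere.

## The method in brief

Seven pixel quantities are read off the image (manually, from an
annotation file, or with the built-in sub-pixel line detector): the line
separations *n′*, *n″* at a near and a far reference row, the left line
position *n*₀ and the near-row offset *m*₀, and the line slopes *n*₁/*m*,
*n*₂/*m* relative to the vanishing point V′ of the two lines. Because the
lasers are fixed to the vehicle, V′ encodes the camera pose:

    tan λ = [m0/M − 1/2 + n′/(n1+n2) · m/M] · 2 tan(αV/2)
    tan γ = [1/2 − n0/N − n1/(n1+n2) · n′/N] · 2 tan(αH/2) · cos λ

and the footprint and altitude follow as

    L = (n′/n″ − 1) · (N/n′) · l / (2 tan(αH/2) cos λ cos γ),   S = L·l
    h = cos λ cos γ · l / (cot θ1 + cot θ2),
        cot θi = (ni/N)(M/m) · tan(αH/2)/tan(αV/2)

Maximal (absolute-sum, not quadrature) first-order uncertainty bounds ΔL,
ΔS, Δh are propagated from one-pixel reading errors and Δl. Over sloping
ground the recovered tilt is apparent tilt; with an external tilt reading
λ₀ the slope is α = λ − λ₀. An exact pinhole forward model doubles as
simulation oracle and synthetic-image generator, and an equal-ground-area
grid overlay adapts the Canadian-grid idea to the vanishing point. See
`vignette("laserquad-methods")` for derivation notes, conventions and
limitations.

## Worked example

The shipped example is a deep-sea ROV still (1280 × 800 px,
α<sub>H</sub> = 50.43°, α<sub>V</sub> = 29.67°, lasers 67 ± 0.5 cm apart)
with measured pixel quantities n′ = 312, n″ = 232, n₀ = 465, n₁ = 52,
n₂ = 29, m₀ = 367, m = 143:

```r
library(laserquad)
cam  <- camera_intrinsics(alpha_h = 50.43, alpha_v = 29.67,
                          width = 1280, height = 800)
rig  <- laser_rig(l = 67, delta_l = 0.5)
meas <- image_measurements(n_prime = 312, n_dprime = 232, n0 = 465,
                           n1 = 52, n2 = 29, m0 = 367, m = 143)
laser_estimate(meas, cam, rig, true_tilt_deg = 18.9)
#> <laser_estimate>
#>   tilt  lambda =  18.93 deg   pan gamma =  -1.01 deg
#>   length L = 106.4 +/- 5.5 cm
#>   area   S = 7130 +/- 425 cm^2
#>   height h = 100.7 +/- 5.8 cm
#>   seabed slope = 0.03 deg (true tilt 18.90 deg)
```

Reading: the camera was pitched ~19° down and panned ~1° left of the laser
direction; the trapezoid between the two reference rows spans
106.4 ± 5.5 cm along the seabed, i.e. 7130 ± 425 cm² between the lasers,
and the camera flew 100.7 ± 5.8 cm above the bottom. For this frame the
deployed reference object measured 108 ± 3 cm (7236 cm² with l = 67 cm) at
a surveyed camera height of 113 cm — an area error of about 1.5% and a
height error of about 11%, the latter dominated by residual laser
alignment, to which the height (but hardly the area) is sensitive.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/laserquad measure --config rig.yaml \
    --measurements still42.csv --out still42_report.json
```

with subcommands `measure`, `simulate`, `detect` and `grid`.

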