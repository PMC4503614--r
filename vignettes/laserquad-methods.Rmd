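---
title: "Laser-line photogrammetry of oblique seafloor imagery: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laser-line photogrammetry of oblique seafloor imagery: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laserquad)
```

## The measurement problem

Quantitative work on towed-camera and ROV imagery — densities of benthic
organisms, litter counts, geological mapping — needs the ground area seen in
each frame. Survey cameras view the seabed obliquely and move constantly, so
a fixed image-to-ground scale does not exist. A classical remedy is a pair
of parallel sheet lasers rigidly mounted to the vehicle frame (not to the
camera), drawing two green lines of known separation $l$ on the seabed.
`laserquad` turns pixel measurements of those two lines in a *single* still
image into:

* the ground length $L$ and area $S = L\,l$ of the trapezoid bounded by the
  lines and two reference image rows,
* the camera's downward tilt $\lambda$ and signed pan $\gamma$ relative to
  the laser direction, via the vanishing point of the lines,
* the camera height $h$ above the seabed,
* the seabed slope, when an external tilt sensor reading is supplied,
* maximal first-order uncertainties for all of the above.

The only calibration inputs are the laser separation $l$ (with tolerance
$\Delta l$, typically $0.5$ cm) and the camera's horizontal and vertical
angles of view $\alpha_H, \alpha_V$. The physical sensor width cancels from
every formula; all equations use ratios of pixel counts.

## Image model and conventions

The model is an ideal pinhole: negligible lens distortion, uncropped image,
principal point at the image centre, zero camera roll. Raster coordinates
have their origin at the top-left corner, $u$ rightward, $v$ downward,
real-valued at pixel centres; the image is $N \times M$ pixels. A pixel
column/row maps to tangent coordinates through the scales
$N / (2\tan(\alpha_H/2))$ and $M / (2\tan(\alpha_V/2))$.

Seven pixel quantities are read off one image (by hand in any image-analysis
tool, from an annotation file, or from the built-in detector):

* $n'$, $n''$ — horizontal separation of the two lines at the near (lower)
  and far (upper) reference row;
* $n_0$ — horizontal position of the left line at the near row;
* $m_0$ — vertical distance of the near row **from the bottom image edge**;
* $n_1$, $n_2$ — horizontal distances from the vertical through the
  vanishing point to the left and right line, at a row $m$ pixels below the
  vanishing point.

Only the ratios $n_1/m$ and $n_2/m$ — the line slopes — enter the
estimators, so the slope triple may be measured at any row; the package's
annotation extractor uses the near reference row, which has the largest
lever arm from the vanishing point and hence the smallest relative reading
error. The uncertainty formulas do inherit the chosen row.

The bottom-edge convention for $m_0$ deserves a note: with it, the tilt
bracket $m_0/M - 1/2 + \frac{n'}{n_1+n_2}\frac{m}{M}$ equals the vertical
vanishing-point offset in units of $M$ for *every* row position, which makes
the tilt estimator an exact inverse of the projection model. Measured from
the top edge instead, the bracket is exact only for a row through the image
centre. The package's forward model verifies this identity numerically in
the test suite.

## Pose from the vanishing point

Because the lasers are fixed to the vehicle, panning or tilting the camera
moves the vanishing point $V'$ of the two projected lines away from the
image centre: tilting down moves it up; panning right moves it left (the
world-fixed laser direction shifts opposite to the camera rotation). The
closed forms are

$$\tan\lambda = \Big[\tfrac{m_0}{M} - \tfrac12 +
\tfrac{n'}{n_1+n_2}\tfrac{m}{M}\Big]\,2\tan\tfrac{\alpha_V}{2},
\qquad
\tan\gamma = \Big[\tfrac12 - \tfrac{n_0}{N} -
\tfrac{n_1}{n_1+n_2}\tfrac{n'}{N}\Big]\,
2\tan\tfrac{\alpha_H}{2}\cos\lambda,$$

and the vanishing point sits at offsets
$\big({-}\tfrac{N}{2}\tan\gamma/(\tan\tfrac{\alpha_H}{2}\cos\lambda),\;
\tfrac{M}{2}\tan\lambda/\tan\tfrac{\alpha_V}{2}\big)$ from the centre
(rightward, upward). For a horizontal, laser-aligned camera $V'$ is the
image centre. Both equations, and the equality of the vanishing point with
the pixel-space intersection of the two lines, are exact inverses of the
pinhole model; the test suite checks the round trip to $10^{-6}$ over a
thousand random scenes.

## Footprint and height

$$L = \Big(\frac{n'}{n''}-1\Big)\,\frac{N}{n'}\,
\frac{l}{2\tan(\alpha_H/2)\,\cos\lambda\,\cos\gamma}, \qquad S = L\,l,$$

$$h = \frac{\cos\lambda\,\cos\gamma\;l}{\cot\theta_1+\cot\theta_2},
\qquad
\cot\theta_i = \frac{n_i}{N}\,\frac{M}{m}\,
\frac{\tan(\alpha_H/2)}{\tan(\alpha_V/2)}.$$

The perspective cotangents are the slopes of the lines in the physically
scaled image plane, where angles are true; their sum obeys
$\cot\theta_1+\cot\theta_2 = l\cos\lambda/(h\cos\gamma)$ exactly. At zero
pose these forms reduce to the elementary special cases
($L = (n'/n''-1)(N/n')\,l/(2\tan\tfrac{\alpha_H}{2})$ and
$h = (-z_{A'}/l')\,l$), implemented separately as
`ground_length_simple()`, `ground_area_simple()` and
`camera_height_simple()`.

### Exact second-order pan behaviour

Tested against the exact forward model, the plain closed forms have a
precise meaning under nonzero pan: the length equation returns the
perpendicular separation of the two reference ground lines — the along-laser
side of the ground parallelogram times $\cos\gamma$ — and the height
equation returns $h\cos^2\gamma$. Both deviations are second order in
$\gamma$: at the survey-typical pans of a few degrees they are orders of
magnitude below the measurement uncertainty (at $\gamma = 1^\circ$, 0.03%).
The estimators therefore keep the plain forms as defaults, and expose
`pan_exact = TRUE` variants (an extra $1/\cos\gamma$ on $L$, and
$\cos\gamma \to 1/\cos\gamma$ in $h$) that invert the projection model
exactly at any pan; the round-trip tests use those. Reported uncertainties
are unaffected by the choice.

## Maximal uncertainties

Uncertainty propagation is *maximal* (first-order absolute-sum of error
contributions), not statistical quadrature: each pixel quantity is assumed
read to within one pixel (configurable via `measurement_errors()`), and the
laser separation to within $\Delta l$. The relative bounds are

$$\frac{\Delta L}{L} = \Big(\frac{n''}{n'}+\frac{n'}{n''}\Big)
\frac{1}{n'-n''} + \frac{\Delta\cos\gamma}{\cos\gamma}
+ \frac{\Delta\cos\lambda}{\cos\lambda} + \frac{\Delta l}{l},
\qquad
\frac{\Delta S}{S} = \frac{\Delta L}{L} + \frac{\Delta l}{l},$$

$$\frac{\Delta h}{h} = \frac1m + \frac{2}{n_1+n_2}
+ \frac{\Delta\cos\gamma}{\cos\gamma}
+ \frac{\Delta\cos\lambda}{\cos\lambda} + \frac{\Delta l}{l},$$

with the cosine terms given by their own absolute-sum closed forms
(`rel_unc_cos_tilt()`, `rel_unc_cos_pan()`, the pan one nesting the tilt
one). The $L$, $S$ and $h$ bounds are exactly the absolute-sum first-order
propagation of the corresponding closed forms; the test suite verifies them
against an independent finite-difference oracle to 5%. All bounds grow as
the image resolution drops — the coarse-graining penalty of working with
ratios of small pixel counts — and the suite checks that monotonicity.
Integer-pixel quantization keeps the true error inside the $\Delta L$ and
$\Delta h$ bounds in essentially all simulated scenes (the acceptance test
requires at least 90% of 1000).

## Seabed slope

Over ground sloping by $\alpha$ along the laser direction, the imagery
yields the *apparent* tilt $\lambda = \lambda_0 + \alpha$, where $\lambda_0$
is the camera's true tilt. Given an attitude-sensor reading of $\lambda_0$,
`seabed_slope()` returns $\alpha = \lambda - \lambda_0$. In that geometry
the recovered height is the perpendicular distance to the sloping plane
($h\cos\alpha$ for a camera at vertical height $h$), and $L$ is measured
along the slope — both verified exactly in the forward-model tests. Angles
are degrees at every interface and radians internally; lengths are cm,
areas cm².

## The forward model and what the synthetic data do (not) show

`forward_scene()` implements the exact pinhole projection of the rig:
camera panned about the vertical, then tilted about its own horizontal
axis (this order reproduces the vanishing-point equations; with zero roll
the two plausible orders give the same image geometry). It generates
synthesized measurement sets (`synthesize_measurements()`, optionally
quantized to integer pixels with seeded dithering of exact halves) and
rendered PNG stills (`render_synthetic_image()`) with anti-aliased
Gaussian-profile green lines over flat, gradient or speckle backgrounds.

The generator emulates the *geometry* of real stills faithfully — pose,
perspective, resolution, quantization — and, for the detector, moderate
background noise. It does not emulate water-column effects (turbidity,
attenuation, flicker), laser-line curvature from uneven terrain, lens
distortion, or miscalibrated (non-parallel) lasers. Passing tests therefore
demonstrate correctness of the geometry and of the error propagation, not
robustness to those field effects; the published in-situ validation of the
method itself is the single worked example the acceptance values reproduce.
Defaults used in the simulated studies: the validation camera
($\alpha_H = 50.43^\circ$, $\alpha_V = 29.67^\circ$, $1280 \times 800$ px),
$l = 67$ cm, $\Delta l = 0.5$ cm; random scenes draw
$\lambda \in [2, 45]^\circ$, $\gamma \in [-20, 20]^\circ$,
$h \in [50, 400]$ cm (narrowed to $\lambda \in [10,30]^\circ$,
$\gamma \in [-5,5]^\circ$, $h \in [80,200]$ cm for the "paper-like"
quantization and detection studies); property sweeps use 1000 scenes and
the detection study 200 rendered stills.

## Detection

`detect_laser_lines()` scores pixels by normalised green excess
$G - (R+B)/2$, thresholds (default 0.25 of the maximum), clusters each
row's surviving pixels into at most two horizontal runs, takes
intensity-weighted centroids, and fits one straight line per side by
iterative reweighting, discarding residuals beyond 2.5 median absolute
deviations (default 20 iterations). Per-row centroids give sub-pixel
positions with no accumulator binning to tune; on rendered stills the fit
is accurate to well under 0.3 px RMS and the downstream area lands within
1% of truth. Rows whose cluster count is not exactly two are ignored; if
fewer than half the signal-bearing rows (default) survive, detection fails
with diagnostic counts. The module is an extension hook: it is tuned on
synthetic imagery only and makes no claim about turbid, real footage.

## Grid overlay

`ground_grid_overlay()` adapts the Canadian-grid idea with the vanishing
point in place of the optical centre: virtual laser lines through $V'$ at
ground offsets $k \cdot$`lateral_spacing` (their image slope is affine in
ground offset — exact for a pinhole, verified against the forward model),
and transversal rows placed so that successive ground separations, from
inverting the length equation, all equal `axial_spacing`; the reciprocal
row distance from $V'$ is affine in ground distance, so the rows follow in
closed form. Rows stepped toward the camera beyond the ground half-plane
are dropped; rows stepped away exist for any distance, crowding toward the
horizon.

## Numerical choices and degenerate inputs

* $|n' - n''| < 0.5$ px: length refused (rows too close to resolve).
* Annotated lines parallel within $10^{-12}$ rad: vanishing point at
  infinity; the error message points to the zero-pose simple-case forms.
* $n_1 + n_2 \le 0$ or $m \le 0$: pose undefined, rejected at
  construction. $n_1$ or $n_2$ individually may be negative (vanishing
  vertical outside the line pair under strong pan).
* Annotation coordinates are kept unrounded; left/right line identity is
  assigned by position at the near row, never by file order.
* Quantization rounds half-integers by seeded random dithering, avoiding a
  systematic half-pixel bias in simulation studies.
* Reference rows are horizontal raster rows. For a pinhole camera with
  zero roll every horizontal image row corresponds to a ground line
  parallel to the camera's horizontal axis, so this choice is not an
  approximation; it fixes what $L$ means under pan (see above).

## Known limitations

One image in, one estimate out: no multi-frame averaging or filtering
(batch use is a thin loop over stills). Camera roll is assumed zero; lens
calibration and distortion correction are out of scope, as are real-footage
detection robustness and video tracking. Height is the most sensitive
output — it depends directly on the two line slopes, so residual
non-parallelism of the lasers degrades $h$ faster than $S$; where height
matters, an altimeter is the better instrument, and the imagery value is a
cross-check.
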