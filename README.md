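# otoseg

Multispectral otoscopy phantoms and localized active-contour segmentation
of the tympanic membrane (TM).

## What this is for

Automatic delineation of the eardrum in otoendoscopic images is difficult
under white light: the TM, the surrounding ear-canal wall and the malleus
handle are similar in brightness, and blood vessels cross both regions.
Under narrow-band red (~630 nm) illumination, haemoglobin absorption is
minimal — vessels disappear, the canal wall becomes homogeneous — while the
collagen-rich TM stays bright, so the TM/background contrast is strong.
`otoseg` turns that observation into a reproducible simulation study for
people developing or evaluating eardrum segmentation:

* **`phantom`** — a seeded generator of synthetic multispectral eardrum
  image sets (white/red/green/blue channels) with ground-truth masks:
  elliptical TM, malleus-handle strip, cone of light, curvilinear vessels
  that vanish under red light, noisy dim blue channel.
* **`msio`** — image I/O (PNG/TIFF), grayscale and jet-colormap
  conversion, region histograms, histogram overlap, and line profiles
  with analytic ellipse-crossing marks.
* **`snake`** — a localized region-based active contour as a narrow-band
  level set: smoothed Heaviside/Dirac band functions, exact signed
  distance fields, local interior/exterior means, curvature-regularized
  evolution (single-scale and coarse-to-fine).
* **`metrics`** — Dice similarity coefficient on masks and maximum
  Hausdorff distance on boundary pixel sets, both validated against
  brute-force oracles.
* **`pipeline`** — the full experiment: cohort generation, common
  elliptical initialization per set, per-channel segmentation, metric
  aggregation and channel ranking.

The model: a contour $C$ is the zero level set of a signed distance
function $\varphi$ (negative inside). The interior indicator is the
smoothed Heaviside $\mathcal{H}(\varphi)$ with band half-width
$\varepsilon$, the band selector is the smoothed Dirac
$\delta(\varphi) = |\mathcal{H}'(\varphi)|$, and each band pixel moves
under the localized mean-separation force
$F = (I-u_{in})^2 - (I-u_{ex})^2$ (local means over a window of radius
$r$) plus curvature $\alpha\kappa$. Agreement is scored with
$\mathrm{Dice} = 2|A\cap B|/(|A|+|B|)$ and
$\mathrm{HD}(A,B) = \max\{h(A,B),\,h(B,A)\}$,
$h(A,B) = \max_{a\in A}\min_{b\in B}\lVert a-b\rVert$ on boundary pixels.

## Worked example

```r
library(otoseg)

report <- run_experiment(default_phantom_spec(), 12, 42)
report
#> <experiment_report> 12 phantoms x 4 channels, master seed 42
#>  channel  n mean_dice      sd_dice mean_max_hd sd_max_hd
#>     blue 12 0.9684784 0.0095406063   16.883100  2.962355
#>    green 12 0.9728060 0.0102413688   15.255791  3.815399
#>      red 12 0.9985392 0.0005449839    8.384194  3.611390
#>    white 12 0.9739461 0.0144252811   14.791616  4.791065
#> ranking by mean Dice   : red > white > green > blue
#> ranking by mean max HD : red < white < green < blue
```

Twelve synthetic eardrum sets are generated at 976 × 494 px, every channel
is segmented from the same covering-ellipse initialization, and each
result is scored against the set's ground-truth TM mask (ellipse plus
malleus strip). The red channel wins on both metrics — near-perfect
overlap (mean Dice 0.999) and a worst-case boundary error of ~8 px —
while white/green/blue contours stall or wander in their low-contrast,
vessel-crossed terrain. That is the channel ranking the underlying optics
predicts: segmentation quality tracks the inside/outside histogram
separation, which is greatest under red illumination (check it with
`region_histogram()` / `histogram_overlap()`).

Single pieces are usable on their own:

```r
set <- generate_phantom(default_phantom_spec(), seed = 7)
init <- make_init_mask(set, jitter_seed = 1)
seg <- evolve_contour_pyramid(set$channels$red, init$mask)
evaluate(seg$mask, set$gt_tm_mask, "red", 7)
#>   phantom_id channel      dice   max_hd n_pred_pixels n_truth_pixels valid
#> 1          7     red 0.9984459 9.219544        119486         119233  TRUE
```

A thin CLI over the same functions lives at `inst/cli/otoseg`
(`generate`, `segment`, `evaluate`, `run`).

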