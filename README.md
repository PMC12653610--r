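# rubbergrade

Automated colorimetric grading of natural rubber specimens from
calibrated camera images.

Natural rubber is traded in visually graded classes — **white crepe**
(premium, near-white), **STR5** / **STR5L** (Standard Thai Rubber,
strongly yellow; 5L with a green undertone), and the ribbed smoked
sheets **RSS3** / **RSS5** (progressively darker). `rubbergrade`
replaces subjective visual grading with an imaging measurement chain:

```
frames ── average ── quality gates ── flat-field ── denoise ── segment
                                                                  │
         grade ◀── decision tree ◀── (YI, L*, a*) ◀── mean RGB ◀──┘
```

* **Radiometry** — dark/white-reference flat-field correction,
  Gaussian denoising, and quality gates (blur-referenced focus score,
  illumination-uniformity CV, saturation fraction, SNR).
* **Segmentation** — hand-rolled Otsu threshold (exhaustive
  between-class-variance scan, with diagnostics), morphological
  refinement, 8-connected labelling, and geometric ROI validation
  (area 620–630 mm², circularity > 0.85, central position).
* **Colorimetry** — dual-path RGB→XYZ (raw-linear for the yellowness
  index, sRGB-piecewise-linearized for CIELAB per CIE 15:2004), D65
  white point, yellowness index with two coefficient presets
  (grading-consistent and ASTM E313 D65), CIE76 ΔE\*ab. Every XYZ value
  carries its path as an attribute.
* **Classification** — a five-leaf decision tree on (YI, L\*, a\*) with
  at most five strict comparisons, calibrated per-grade mean ± 2 SD
  ranges, and an `"unclassified"` escape hatch instead of forced leaves.
* **Statistics** — one-way ANOVA, Tukey HSD, ISO 5725-style
  repeatability/reproducibility, Monte-Carlo uncertainty propagation of
  RGB noise into YI, and ΔE calibration reports.
* **Synthetic data** — a seeded, bit-reproducible scene generator
  (specimen + vignetting + sensor noise + reference frames) so the full
  pipeline is testable without the imaging rig.

See `vignette("grading-pipeline")` for the methods and the reasoning
behind the design choices.

## Quick start

```r
library(rubbergrade)

# colorimetric vector from an 8-bit mean RGB measurement
cv <- color_vector(c(129.0, 107.6, 43.2), id = "example STR5")
cv
#> <color_vector>  id: example STR5
#>   RGB  :  129.0  107.6   43.2
#>   L*a*b*:  46.29   0.59  38.18   (sRGB-linearized path)
#>   YI   :  62.85 (grading)    91.19 (ASTM/linearized)

assign_grade(cv)$grade
#> [1] "STR5"

# full pipeline on a synthetic acquisition
sc <- make_scene(scene_config(grade = "STR5L", seed = 101))
run_specimen(sc)
#> <specimen_result> status: ok
#>   grade: STR5L  (YI 64.33, L* 46.91, a* -0.91)

# batches, with accuracy/confusion when ground truth is known
scenes <- make_scene_batch(n_per_grade = 2, seed = 7)
run_batch(scenes)
```

The per-grade reference colorimetry (means and SDs of RGB, CIELAB and
YI) that anchors the thresholds is available as
`rubber_reference_colors()`.

A thin command-line front end lives at `inst/cli/rubbergrade.R`
(subcommands `synth`, `measure`, `classify`, `batch`; exit code 0 ok,
2 reacquisition required, 3 input error).

## Tests

```r
testthat::test_dir("tests/testthat", package = "rubbergrade",
                   load_package = "installed")
```

The suite (≈500 assertions) checks the numerics against independent
brute-force oracles: Otsu via exhaustive variance scan, ANOVA via raw
sums of squares, Gaussian smoothing via explicit kernels, classifier
recall via analytic Gaussian tail probabilities, and the colorimetric
constants against the frozen reference table.

## License

MIT (see `LICENSE`).
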