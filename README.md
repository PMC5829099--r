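# retinalca

Why don't we see the blue–yellow fringes that the eye's own optics
paint on every luminance edge? The eye's refractive power changes by
about two diopters across the visible spectrum (longitudinal chromatic
aberration, LCA), so when the 550–580 nm band is in focus the
short-wavelength image feeding the S cones is badly defocused.
`retinalca` implements a retinal model of the compensation: adapted
cone signals feed the color-coding ganglion cells — spatially
antagonistic type-I L/M cells (differences of Gaussians) and the
spatially coextensive type-II S/(L+M) small-bistratified cell — and an
inverse transformation reconstructs the perceived image from those
opponent responses. Because the coextensive channel cancels the
achromatic component inside its receptive field and low-passes what
remains, the reconstruction re-attaches only a smoothed chromatic
residue to the sharp L/M carrier: fringes collapse, and the same
mechanism predicts assimilative color shifts on S-cone ring patterns.

The package is aimed at computational visual neuroscientists and
vision students: every stage (optics, adaptation, receptive fields,
inverse transform, metrics) is an exported, documented function, with
synthetic stimulus generators and an end-to-end pipeline.

## Model in brief

With `*` denoting convolution by unit-sum Gaussians `f_c` (ρ = 1 px)
and `f_s` (ρ = 3 px):

```
adapted  = photo/(photo + σ) · (photo + remote),  σ = a·photo + b + c·remote
L+M−     = (L_ad * f_c) − (M_ad * f_s)            (type I, and M+L− mirrored)
S+LM−    = (S_ad − (L_ad + M_ad)/2) * f_s         (type II, coextensive)

perceive: solve  L+M− = L_per − M_per * f_s ,  M+L− = M_per − L_per * f_s
then     S_per = S+LM− + (L_per + M_per)/2
```

Defaults: a = 1, b = 3, c = 1, remote annulus 35 px; S-channel defocus
1.2 D through a 3 mm pupil at 64 px/deg (σ_S ≈ 3.8 px); Jacobi-style
descent with dt = 0.1, tolerance 1e-6. See the vignette
(`vignettes/lca-compensation.Rmd`) for derivations and conventions.

## Worked example

Fringe compensation on the achromatic grid:

```r
library(retinalca)
res <- fringe_reduction(stimulus_spec("grid"), run_config())
res$retinal    # 3.636  max |B/(R+G) − 1| near edges, retinal image
res$perceived  # 0.991  same measure after the model
res$reduction  # 0.727  fractional drop
```

The retinal image's blue–yellow contrast swings to 3.6× the achromatic
reference next to the square borders (the LCA fringe); in the model's
perceived image the worst deviation within 9 px of an edge is 0.99 —
a 73% reduction, i.e. the fringes essentially vanish while the grid
itself stays sharp.

Chromatic induction on the S-cone ring pattern (two variants whose
test ring is pixel-identical):

```r
rep <- predict_induction(stimulus_spec("rings"), run_config())
#> <induction_report: S/(L+M) test-ring contrast 0.7639 (A) vs 0.3224 (B), shift 0.4415>
```

The test ring's predicted S/(L+M) chromatic contrast is higher when
its neighbours are the high-S "purple" inducers (variant A) than when
they are the low-S "lime" inducers — an assimilative shift toward the
adjacent ring's chromaticity, of magnitude ≈ 0.44 for the package's
default (documented, approximate) stimulus chromaticities.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/retinalca.R fixtures grid --out grid.png
Rscript inst/cli/retinalca.R run --input grid.png --out-dir out --profile-row 32
Rscript inst/cli/retinalca.R induction
```

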