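---
title: "A retinal opponent-channel model of chromatic-aberration compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A retinal opponent-channel model of chromatic-aberration compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinalca)
```

## The problem

The optical power of the eye varies by roughly two diopters across the
visible spectrum (longitudinal chromatic aberration, LCA). With the
lens focused near 550–580 nm — where solar irradiance, luminance
sensitivity and the L/M cones all peak — the short-wavelength image
that drives the S cones is strongly defocused. Geometrically this
should paint every luminance edge with a blue–yellow fringe: bluish on
the dark side (defocused short-wavelength light leaks outward), yellowish
on the bright side (short-wavelength light is missing). Yet we do not
see such fringes. This package implements a retinal explanation: the
spatio-chromatic structure of the color-coding ganglion cells,
combined with an inverse transformation from their responses back to
an image, removes the fringes without any learned correction — and, as
a by-product, predicts the striking assimilative color shifts induced
by S-cone ring patterns.

## Model

The pipeline has five stages, each an exported function.

### 1. Cone sampling (`rgb_to_cones`)

Input images are linear-light RGB. A fixed, invertible 3×3 transform
(Hunt–Pointer–Estévez fundamentals applied to the linear-sRGB
primaries, row-normalized) maps RGB to L, M, S cone excitations. The
row normalization makes achromatic closure exact: an equal-RGB pixel
yields L = M = S, so every chromatically opponent stage below is
silenced by neutral surfaces. Any fixed invertible transform with this
property would serve; colorimetric fidelity to a particular display is
not the point of the model.

### 2. Optics (`build_psfs`, `simulate_retina`)

Each cone plane is blurred by a Gaussian point-spread function of
width

σ (px) = k · defocus (D) · pupil (mm) · pixels-per-degree / 60.

A defocus of ΔD diopters through a pupil of d mm subtends a geometric
blur circle of ΔD·d mrad ≈ 3.44·ΔD·d arcmin; taking σ as roughly a
quarter of that diameter gives the calibration constant k = 1, kept
explicit and configurable. Defaults: L and M in focus (0 D), S at 1.2 D
(0.6 of the 2 D spectral span, the distance from the focus plane to
the short-wavelength end weighted toward the S-cone band), pupil 3 mm,
64 px/deg. At these values σ_S ≈ 3.8 px. A full wavefront-optics
simulation is deliberately out of scope: the model under test only
needs a realistic, controllable S-channel blur.

### 3. Adaptation (`adapt_image`)

Each ganglion-cell input is gain-controlled by local and remote
signals (the curve-shifting form of Naka–Rushton adaptation):

σ(x,y) = a·photo + b + c·remote,
adapted = photo/(photo + σ) · (photo + remote),

with a = 1, c = 1 (equal local and remote strength) and b = 3. The
remote signal is a weighted mean of the same cone plane over an
annulus of diameter 35 px surrounding the whole receptive field
(decaying-exponential weights, renormalized to unit sum over the
annulus so a uniform field is a fixed point). The annulus inner radius
(9 px, three surround space constants — just outside the classical RF)
and weight decay (8.75 px, a quarter diameter) are not fixed by the
reference parameter set and are exposed as configuration. The printed
source for the adapted-response expression is typographically
ambiguous; the reading above is isolated in `adapt_channel()`, and a
pure Naka–Rushton alternative (`form = "naka_rushton"`, response =
photo/(photo+σ)) can be selected — both preserve achromatic closure,
which is all the downstream stages rely on.

### 4. Opponent receptive fields (`opponent_maps`)

Type-I cells are differences of Gaussians with chromatic opponency:

L+M−(x,y) = (L_ad ∗ f_c) − (M_ad ∗ f_s),
M+L−(x,y) = (M_ad ∗ f_c) − (L_ad ∗ f_s),

with center decay ρ_cen = 1 px and surround decay ρ_sur = 3 px (the
surround weight function three times larger than the center's). The
type-II small-bistratified cell is spatially coextensive — chromatic
but not spatial opponency:

S+LM−(x,y) = (S_ad − (L_ad + M_ad)/2) ∗ f_s,

a single-signed Gaussian integral of the pointwise blue–yellow
difference. Because the achromatic component cancels *inside* the
integrand, this channel gives a null response to any achromatic
pattern, and its response to an achromatic edge whose S plane has been
optically blurred is a small, spatially low-passed transient — the
quantity the reconstruction stage will treat as chromaticity, not
form. All discrete kernels are renormalized to unit sum (the printed
continuous normalization 1/(πρ) is dimensionally inconsistent with
exp(−r²/ρ²); unit total weight is what guarantees null responses on
uniform fields). Kernels are truncated at 3ρ, which keeps >98% of the
Gaussian mass. The coextensive RF's decay ρ_s_rf defaults to ρ_sur;
the source text is ambiguous about whether the S cell carries its own
radius, so it is a separate configurable parameter.

### 5. Inverse transformation (`solve_perceived`)

The perceived L/M planes are defined implicitly by

L+M− = L_per − (M_per ∗ f_s),   M+L− = M_per − (L_per ∗ f_s),

the same opponent equations read in the perceived domain. They are
solved by minimizing the total squared residual E. The iterative
solver descends E with the surround cross-term of the gradient
collapsed to its central tap f_s(0,0) (a Jacobi-style approximation;
the update direction differs from the exact gradient only at order
f_s(0,0) ≈ 0.04, and the true solution remains the unique fixed
point). The step size dt = 0.1 is halved automatically whenever a
proposed step would increase E, so accepted energies are
non-increasing; iteration stops when the largest per-pixel update
falls below 10⁻⁶ or after 5000 iterations (non-convergence is flagged
on the result, never raised). Because f_s has unit weight, adding one
common constant to both planes leaves the equations unchanged; that
null mode is pinned by the achromatic initialization
L⁰ = M⁰ = S⁰ = (L_ad + M_ad)/2, and solver steps are projected off it.
Over the iterations chromaticity "fills in" from the opponent
responses. A direct solver (`solve_perceived_direct`) assembles the
2N×2N sparse system with the reflective-boundary surround operator and
solves the ridge-regularized (10⁻⁹) normal equations; it is exact and
serves as the oracle for the iterative path on small images.

Finally the perceived S plane is pointwise

S_per = S+LM− + (L_per + M_per)/2:

the coextensive channel contributes chromaticity only; perceived
brightness is carried entirely by L_per and M_per (rendering gain in
`render_perceived` therefore normalizes on (L_per+M_per)/2).

Why this removes fringes: for an achromatic scene the type-I channels
see no chromatic contrast (L and M are equally sharp), so
L_per = M_per reconstructs the achromatic pattern at full resolution,
while the only chromatic signal — the S-cone fringe — enters through
S+LM−, where it has been (i) differenced against the sharp achromatic
carrier inside the integrand and (ii) spatially low-passed by the
coextensive RF. The reconstruction re-attaches that smoothed, small
chromatic residue to the sharp carrier, and the fringe's peak contrast
collapses.

## Numerical choices

* **Convolutions.** All RF integrals are discrete correlations with
  symmetric unit-sum kernels under symmetric (edge-repeating)
  reflection, evaluated via FFT on a reflectively padded grid; this is
  exact (no wrap-around) and matches a nested-loop reference to
  10⁻¹², which the test suite asserts. Reflection avoids spurious
  fringes at image borders and conserves each channel's total flux
  exactly for symmetric kernels.
* **Solver stability.** The Jacobi/gradient step is stable for
  dt below a kernel-dependent bound; detecting instability at run time
  (energy increase → halve dt and retry) is cheaper and more robust
  than deriving the bound.
* **Degenerate inputs.** Zero photoreceptor signal ⇒ zero adapted
  response (the 0/0 gain is defined as 0). Zero-denominator pixels in
  the B/(R+G) profile are flagged, not dropped or made infinite.
  `rho → 0` kernels collapse to the unit impulse.
* **Conventions.** Blue–yellow contrast is B/((R+G)/2), so the
  achromatic reference is exactly 1; S-cone chromatic contrast is
  S/(L+M) with the sum in the denominator (a `"mean"` switch exists,
  since the bracket notation is ambiguous). Fringes are measured as
  max |contrast − 1| within 9 px (3ρ_sur) of a known fixture edge.

## Synthetic stimuli and what they do (and do not) show

`make_grid()` produces the achromatic grid of equal-energy squares
(256×256, 64-px squares, levels 0.8/0.1 in linear light) used for the
fringe-compensation demonstration; sizes are chosen so the 35-px
remote annulus fits comfortably inside a square.

`make_ring_pattern()` approximates the Shevell–Monnier S-cone
pattern: 15 concentric rings of width 8 px (≈7.5 arcmin at 64 px/deg)
in a 256×256 field, the middle ring being the test. The published
stimulus chromaticities are not tabulated, so the defaults are chosen
once, in cone space, to preserve the stimulus's defining structure:
every ring has the same L and M excitation (0.40) and the rings differ
only in S — test 0.40, "purple" inducer 0.70, "lime" inducer 0.15.
The two variants swap the inducer alternation phase, leaving the test
ring pixel-identical. The predicted shift magnitude scales with the
(unknown) inducer S-contrast, which is why the induction prediction
should be read as order-of-magnitude with the correct, assimilative
sign rather than as a calibrated psychophysical match.

These fixtures are piecewise-constant, noise-free and perfectly
achromatic where intended; natural images are none of those things.
Passing tests on them demonstrates the mechanism (null responses,
fringe collapse, assimilation sign) but does not establish performance
on natural scenes, photon noise, or chromatic edges co-located with
luminance edges.

## Known limitations

* The optics stage is a per-cone-channel Gaussian defocus, not a
  wavefront model: no Zernike aberrations, no Stiles–Crawford effect,
  no transverse chromatic aberration.
* One receptive-field size per cell class; no eccentricity scaling,
  no midget/parasol distinction, no S-OFF pathway.
* The inverse transformation is run to numerical convergence; no claim
  is made about the biological time course of filling-in.
* Rendering of perceived images requires a global brightness gain
  (adapted signals are compressed); chromatic ratios are invariant to
  it, but absolute rendered intensities are conventional.

## Problem sizes

The test suite exercises oracles on 8×8–32×32 images, where
brute-force references and dense/sparse linear algebra are exact and
fast, and runs the full pipeline at 96×96–256×256. The two headline
analyses (`fringe_reduction()`, `predict_induction()`) use the default
256×256 fixtures.
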