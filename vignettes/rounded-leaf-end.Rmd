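---
title: "Rounded leaf ends: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rounded leaf ends: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcedge)
```

## The model

A single-focused multileaf collimator shapes the beam with tungsten leaves
that translate perpendicular to the beam axis. Because the leaves do not
pivot about the source, their tips are machined as circular arcs of radius
$R$ so that a usable edge is presented at every field position. This package
models one leaf pair in the $x$–$z$ plane:

* origin at the isocenter, $z$ increasing toward the source at $(0, \mathrm{SAD})$;
* the leaf slab spans $z \in [\mathrm{SAD} - \mathrm{SCD} - lh/2,\;
  \mathrm{SAD} - \mathrm{SCD} + lh/2]$, where SCD is measured to the leaf
  *middle* plane — the only reading that makes the mechanical back-projection
  $x_E = x_N \cdot \mathrm{SCD}/\mathrm{SAD}$ exact;
* a leaf cross-section is the circular-arc tip (center $C = (x_E + R,
  \mathrm{SAD} - \mathrm{SCD})$, the arc spanning the full leaf height), flat
  top and bottom faces, and a finite body behind the tip.

Three positions on the scoring plane $z = 0$ are computed per configuration:

* **nominal** $x_N$: the uncalibrated projection of the mechanical tip;
* **geometric** $x_G = x_T \cdot \mathrm{SAD}/(\mathrm{SAD} - z_T)$, where
  $T$ is the point where a ray from the source grazes the outline. $T$ is
  the arc tangency satisfying $\vec{CT} \cdot \vec{ST} = 0$ with
  $x_T < x_C$ when that tangency lies inside the slab; it clamps to the
  proximal corner $U$ when the tangency falls above the slab (or the source
  lies inside the arc circle) and to the distal corner $V$ when it falls
  below;
* **physical** $x_P$: the scoring intercept of the secant through the source
  whose in-leaf chord equals the half-value layer $L = -\ln(0.5)/\mu$, so
  primary transmission along it is exactly 50%.

The offsets are reported in millimetres: $\mathrm{LPO} = x_G - x_N$,
$\mathrm{RFO} = x_P - x_G$, $\mathrm{PNO} = \mathrm{LPO} + \mathrm{RFO}$
(the identity is enforced exactly by computing PNO as the sum).

## Solving the half-value-layer secant

With both secant endpoints $A$ (proximal) and $B$ (distal) on the arc, the
stacked system — two circle memberships, collinearity with the source, chord
length $L$ — is polished by damped Newton iteration from a closed-form
initialisation: the secant must lie at perpendicular distance
$h = \sqrt{R^2 - (L/2)^2}$ from $C$, which is a tangent-line construction to
the concentric circle of radius $h$. Convergence tolerance is $10^{-12}$ on
the residual, at most 100 iterations.

For large radii and off-axis positions the arc chord leaves the leaf slab
and a secant endpoint must move onto a flat face: if the arc–arc solution has
$z_A > z_{top}$ (or the source is inside the arc circle), $A$ moves to the
proximal flat face ($z_A = z_{top}$, one fewer unknown); if $z_B < z_{bottom}$,
$B$ moves to the distal flat face. Spurious Newton branches (endpoints off
the field-facing arc or outside the slab) are rejected and re-seeded from an
arc point half a chord inside the slab. Every solution is verified post hoc
against the exact analytic path length of the secant ray; a residual above
$10^{-6}$ cm raises an error rather than returning a silently wrong edge.
Both flat branches are exercised in the test grid (R = 25 cm at nominal
±20 cm).

## The primary-fluence ray tracer

The simulator replaces full Monte Carlo transport with the weighted beam
integral of the exponential attenuation law:

$$\Phi(x) = \int w(s)\, e^{-\mu\,[p_{\mathrm{leaf}}(s, x) +
  p_{\mathrm{opp}}(s, x)]}\, ds ,$$

where $s$ is the focal-spot abscissa (Gaussian weight $w$, truncated at
$\pm 4\sigma$, $\sigma = \mathrm{FWHM}/2.35482$), and the in-leaf path
lengths $p$ are exact circle–line intersections clipped to the slab and body
extent. Deliberately excluded: Compton scatter, energy spectra and angular
source distributions (the study conditions use a monoenergetic beam with a
single $\mu = 0.96\ \mathrm{cm}^{-1}$), electron transport, inverse-square
and divergence weighting (they cancel under normalisation over the ±3 cm
analysis window), and the 3-D leaf structure (tongue-and-groove, interleaf
leakage). Consequently simulated *penumbra widths* are narrower than
measured dose penumbras, which include scatter; the *edge positions* and
offsets, which are ratios of primary fluence, are the quantities the model
is built to reproduce.

Numerical choices:

* **Kink-split panel quadrature.** For fixed scoring position the integrand
  is only piecewise smooth in $s$: its derivative jumps where a ray becomes
  tangent to the arc or sweeps an outline corner. Plain Gauss–Legendre on
  the full interval stalls near $10^{-3}$ accuracy; splitting the interval
  at the (analytically known) tangency and corner abscissae and applying
  Gauss–Legendre per panel restores spectral accuracy — doubling the default
  201 nodes changes no profile value by more than $10^{-6}$.
* **Monte Carlo mode** samples the focal spot instead (seeded, with a
  per-point standard-error estimate) to emulate the noise character of a
  stochastic transport run at desk scale; it agrees with quadrature within
  three standard errors at $10^5$ histories.
* **Default grid**: 0.01 cm spacing over the nominal edge ±3 cm. Grids may
  extend up to 3 cm beyond the maximum half field so that edges of leaves
  parked at the field limit can be analysed.
* The opposing leaf is the mirror image of the studied leaf with its nominal
  edge a configurable `gap` (default 10 cm) away; its transmission tail is
  negligible in the analysis window but is traced anyway.
* The leaf body extends 20 cm behind the tip; the transmission floor
  $e^{-\mu \cdot lh} \approx 4.6 \cdot 10^{-4}$ makes the exact extent
  irrelevant beyond a few centimetres.

## Profile analysis

Profiles are normalised so the open-field plateau maps to 1. The plateau
level is the *median* of the samples within 5% of the 99th-percentile value:
a rank-based mean of the top values would average only the upper noise tail
and bias the level upward (we measured a ~0.025 mm edge bias on noisy
fixtures from that estimator), while the median is exact on noiseless
profiles and unbiased under symmetric noise.

The field edge is the 50% relative-intensity crossing, the penumbra width
the distance between the 20% and 80% crossings (reported in mm). Two routes
are provided:

* **interpolation** — monotone piecewise-linear interpolation of the raw
  samples; exact to grid curvature for smooth deterministic profiles, and
  the default for quadrature-mode sweeps;
* **fit** — an $n$-peak Gaussian mixture $f(x) = \sum_i a_i
  e^{-((x - b_i)/c_i)^2}$ fitted by Levenberg–Marquardt, the route suited to
  noisy stochastic profiles. The default is $n = 3$ (the precedent set by
  the bundled reference fit); an `"auto"` option picks $n \in \{1, 2, 3\}$,
  keeping an extra peak only for a >1% RMSE improvement, since the choice of
  $n$ is otherwise unconstrained.

The mixture decays on both sides and cannot represent the plateau, so it is
fitted and evaluated only on the *edge window*: the region with relative
intensity in (0.02, 0.98), widened by 0.3 cm on each side. Initialisation
spreads the peak centers across the window with widths of one sixth of the
window; ten seeded, jittered restarts guard against local minima. If noise
produces several crossings of a level, the one nearest the steepest-descent
point is used.

On 100 seeded Gaussian-blurred-step fixtures (blur 0.3–2 mm, noise sd
0.005) the fitted 50% edges recover the ground truth with |bias| < 0.01 mm
and sd < 0.05 mm; the test suite recomputes this.

## Study conditions and defaults

The generator and sweep defaults are the study conditions themselves:
SAD 100 cm, SCD 46 cm, leaf height 8 cm, $\mu = 0.96\ \mathrm{cm}^{-1}$,
maximum half field 20 cm; leaf-end radii $\{4, 6, 8, 10, 15, 20, 25\}$ cm;
focal spots 0.5–3 mm FWHM; nominal positions −20…20 cm in 1 cm steps; a
10 cm gap to the opposing leaf. The single "analytic RFO" summary value is
the mean over the nominal positions — the curve is flat to ~0.013 mm for
R = 15 cm, so mean, central value and plateau read-off agree to ~0.01 mm and
the choice of reduction is immaterial.

Problem sizes in the tests are chosen for quick desk-scale runs: sweep
properties use 5 cm nominal steps (the U-shape and optimal-radius
comparisons are insensitive to the step), and the full 1 cm grid is used
where a mean over positions is the quantity of interest.

## Known limitations

* Primary fluence only: no scatter, spectrum or electron transport, so
  absolute penumbra widths underestimate measured dose penumbras; offsets
  are the robust outputs.
* 2-D single-leaf-pair geometry: no dosimetric leaf gap between opposing
  rounded ends, no tongue-and-groove or interleaf effects, no diaphragms.
* The half-value-layer rule itself underestimates the radiation field
  offset for extended sources — that bias is a *finding* the package
  reproduces and bounds (`chord_sagitta()`, `three_part_intensity()`,
  `underestimation_check()`), not a defect of the implementation; a
  weighted-ray corrected analytic RFO is out of scope.
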