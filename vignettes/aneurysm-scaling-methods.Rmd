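---
title: "Methods: aneurysm size ratio and height-graded sac scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aneurysm size ratio and height-graded sac scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneumorph)
```

## The problem

Rupture risk of an intracranial aneurysm correlates with its shape, and a
widely used shape index is the ratio of sac height to neck size. Projection
based measurements of the neck depend on the viewing angle of the 3D image,
so this package uses a rotation-independent variant, the **aneurysm size
ratio (ASR)**: the perpendicular height $h$ of the sac above the neck
cutting plane, divided by the *average neck diameter* $D$ derived from the
neck perimeter $P$,

$$\mathrm{ASR} = \frac{h}{D}, \qquad D = \frac{P}{\pi}.$$

To study how hemodynamics change as an aneurysm grows, one wants a
*longitudinal* series of geometries from a single patient vessel: the sac
inflated or deflated to prescribed ASR values while the parent artery and
the neck are kept exactly constant. That virtual growth operation, its
morphometric bookkeeping, and a synthetic phantom with closed-form ground
truth are what this package implements.

## The neck frame

All measurement and scaling happens in the *neck frame*: a rigid
transformation takes the user-chosen neck cutting plane (a clinical
clip-plane, given as point + normal or three points; never auto-detected)
to a horizontal plane $\{z = d\}$ with the sac on the $+z$ side.

The transform is parameterised as
$T(p,q,r)\,R_z(\Phi)\,R_y(\omega)\,R_x(\theta)$, with each elemental block
in clockwise (transposed-CCW) form. `build_neck_frame()` uses the *minimal
geodesic rotation* taking the plane normal onto $+z$, with zero
translation, and sets $d$ to the plane's signed distance from the origin.
The in-plane rotation is under-determined by "make the plane horizontal";
the geodesic choice is deterministic, treats no horizontal direction as
special, and reduces to the identity when the model is already aligned.
(The decomposed $\Phi, \omega, \theta$ of that rotation are recorded on the
transform object; $\Phi$ is generally not zero — fixing $\Phi = 0$ and
using the geodesic rotation are two different resolutions of the same
under-determination, and we chose the geodesic one.)

The **neck curve** is the mesh–plane cross-section: crossing triangles
contribute segments, chained through shared mesh edges (never by matching
floating-point endpoints) into closed loops; an open chain means the cut is
not watertight and is an error that names the gap location. Among multiple
loops (a curved vessel can also cross the plane), the loop enclosing the
sac-side reference point is kept. Its perimeter is the summed segment
length, and the neck's "geometric center" — the anchor of the scaling
transform — is the *arc-length-weighted* centroid of the polyline, which
is robust to non-uniform tessellation (a plain vertex mean is not).

Sac membership is decided by **seeded connectivity**, not height: faces
strictly above the plane are split into connected components and only the
component holding the apex seed is the sac. A curved parent artery that
arches above the neck plane therefore keeps its label and is never
deformed. Vertices on the plane (within $10^{-6}$ mm, matching the STL
weld tolerance) are labelled `neck`.

## The height-graded scaling transformation

With neck centroid $(x_m, y_m, z_m)$ ($z_m = d$) and sac height $h$, a sac
point with $z > z_m$ maps to

$$
\begin{aligned}
x_t - x_m &= \Big[1 + a\,\tfrac{(z - z_m)(k-1)}{h}\Big](x - x_m),\\
y_t - y_m &= \Big[1 + b\,\tfrac{(z - z_m)(k-1)}{h}\Big](y - y_m),\\
z_t - z_m &= \Big[1 + c\,\tfrac{(z - z_m)(k-1)}{h}\Big](z - z_m),
\end{aligned}
$$

with gradation coefficients $(a, b, c) = (2, 2, 1)$ by default and height
factor $k > 0$. The deformation vanishes at the neck plane and grows
linearly with height — emulating the clinical observation that expansion
rate increases from neck to fundus — so the neck curve and every vertex at
or below the plane are untouched *exactly*, and with $c = 1$ the apex maps
to height $k h$ exactly. Consequently

$$\mathrm{ASR}(k) = \big(1 + c(k-1)\big)\,\mathrm{ASR}(1),$$

and `solve_k()` inverts this in closed form,
$k = 1 + (\mathrm{ASR}_\text{target}/\mathrm{ASR}_\text{current} - 1)/c$,
which is simply the ratio of ASRs for $c = 1$. Series generation applies
the solved $k$ to the *original* model per schedule entry (never chained),
so entries are order-independent and each re-measured ASR matches its
target to floating-point accuracy.

### Feasibility and stepwise mode

The map is only injective while every factor stays positive. At the apex
the lateral factors are $1 + a(k-1)$ and $1 + b(k-1)$, and the derivative
of the z-map has minimum $\min(1,\, 1 + 2c(k-1))$ over the sac height.
With the defaults, any $k \le 0.5$ drives the apex lateral factor to zero
or below: the mesh would invert. This is a real gap in the stated method —
shrinking a sac of ASR 0.5-ish straight to ASR $\approx 0.25$ is
infeasible in one step — handled two ways:

* **strict** mode (default): `validate_params()` is consulted and an
  infeasible $k$ is an error naming the failing factor;
* **stepwise** mode: $k$ is split into the minimal number of equal
  geometric steps $k^{1/n}$ whose per-step factors all exceed a 0.05
  margin, re-measuring $h$ and the anchors between steps. The vertical
  composition is exact ($c = 1$ heights multiply), so the target ASR is
  still met; the lateral profile differs from the (non-existent)
  single-step map, which is the price of reaching any positive target.

No re-tessellation or smoothing is performed after scaling: vertex
correspondence is what makes the exactness properties testable, and
validity (watertightness, optional self-intersection scan) is *reported*,
never silently repaired. The self-intersection scan is a grid-pruned
edge-versus-triangle test; exactly coplanar overlaps are its known blind
spot.

## The phantom

`make_phantom()` builds the synthetic stand-in for a patient model — a
watertight straight tube carrying a sac with closed-form morphometry:

* the sac is an exact half-ellipsoid (base semi-axes $r, r_y$; polar
  semi-axis = `sac_height`, apex vertex exact), so the analytic ASR is
  $h/(P/\pi)$ with $P$ the base-ellipse perimeter — $h/2r$ for circular
  necks; a hemisphere gives ASR $0.5$ exactly;
* the sac sits on a short collar whose top ring lies exactly *on* the
  neck plane: the cut at $z=0$ is therefore the exact base polygon
  (perimeter $2nr\sin(\pi/n)$ at tessellation $n$, increasing
  monotonically to $2\pi r$), and no mesh face is coplanar with the
  cutting plane, which keeps the cross-section machinery transversal;
* the vessel is a tube of elliptical cross-section (vertical semi-axis =
  `vessel_radius`, default half of the 3.478 mm inlet diameter typical of
  the relevant arteries) with a flat platform under the sac, closed by
  end caps; the platform-with-hole is triangulated by an angular zipper.

`make_curved_phantom()` additionally lifts the tube beyond the sac
platform along a circular arc so that vessel surface genuinely rises above
the neck plane far from the sac — the fixture for the seeded-connectivity
rule. Optional seeded vertex jitter exists for robustness tests and is off
by default because the exact assertions depend on the pristine geometry.

**What a green test does and does not establish.** The phantom has a
planar, convex neck, a single-lobed sac, and an analytically flat platform;
real 3DRA reconstructions have none of these luxuries. Green tests
establish that the measurement and scaling operators implement their
definitions exactly and behave correctly under rigid motion, refinement,
and the feasibility boundary — not that neck-plane choice or segmentation
noise on patient data are handled, which are out of scope here.

## Statistics

The correlation stage is deliberately decoupled from any flow solver:
hemodynamic fields arrive as CSV point samples, `plane_average()` bins
them onto the three measurement planes — P3 on the neck plane, P2 at
$d + h/3$, P1 at $d + 2h/3$, the two interior cut planes of three equal
height intervals, each sample accepted within a half-spacing band of
$h/6$ — and `pearson_r()` is the plain product-moment coefficient (no
p-values; r is what is reported in this line of work). The grand mean is
the mean of plane means; per-plane and unassigned counts are returned so a
pooled mean can be formed instead. The headline patient-data correlations
(r ≈ −0.94 velocity–ASR, −0.93 WSS–ASR) require a commercial FSI solver
and are not reproduced here; this module makes the statistical stage
reusable and testable.

## Numerical choices

| quantity | value | why |
|---|---|---|
| STL weld tolerance | $10^{-6}$ mm | STL stores float32; fuses duplicated facet corners at clinical (mm) scale without welding features |
| "on plane" tolerance | $10^{-6}$ mm | matches the weld tolerance |
| cut snap | $10^{-9}$ mm | signed distances below this are pushed to the positive side, so every face is strictly classified and vertices on the plane never produce degenerate segments |
| feasibility margin (stepwise) | 0.05 | keeps per-step factors safely away from the fold-over boundary |
| rotation orthonormality | $10^{-9}$ | construction tolerance for `rigid_from_matrix()` |

Degenerate inputs error early with typed conditions (`aneumorph_io_error`,
`aneumorph_validation_error`, `aneumorph_infeasible_error`) that the CLI
maps to distinct exit codes (2, 3, 4).

## Worked example

```{r example, eval = FALSE}
ph <- make_phantom(tess = 128)                 # hemisphere sac, ASR 0.5
fr <- analyze_aneurysm(ph$mesh, ph$plane, ph$apex_seed)
measure_sac(fr)
#> <sac_morphometry: h = 2 mm, neck perimeter = 12.5651 mm,
#>  D = 3.9996 mm, ASR = 0.50005, aspect ratio = 0.5>

series <- generate_series(fr)                  # the eight-value schedule
series$manifest[, c("target_asr", "k", "measured_asr", "watertight")]
```

Every number above is reproduced by the test suite
(`tests/testthat/test-acceptance.R`) and the acceptance script
(`scripts/acceptance.R`); the vignette states no result they do not
compute.

## Known limitations

* No automatic neck-plane detection; multi-lobed sacs with several necks
  are out of scope.
* Vertex jitter breaks the exact-planarity assumptions mildly; it is for
  robustness probing, not for emulating segmentation noise statistics.
* The self-intersection scan misses exactly coplanar overlaps.
* Scaled surfaces are not re-meshed; extreme lateral factors can produce
  poorly shaped (though valid) triangles that a downstream volume mesher
  may dislike.
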