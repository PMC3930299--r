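# aneumorph

Morphometry and virtual growth of intracranial aneurysm surface models.

Intracranial aneurysms are sac-like dilatations of cerebral arteries, and
the ratio of sac height to neck size is a standard index of their shape.
`aneumorph` works on triangulated vascular surfaces (STL) and a clinically
chosen neck cutting plane, and provides:

* **Measurement** — the aneurysm size ratio
  `ASR = h / D`, where `h` is the perpendicular height from the neck plane
  to the sac apex and `D = P / π` is the average neck diameter derived from
  the neck perimeter `P` (rotation-independent, unlike projection-based
  aspect-ratio readings); plus the classical aspect ratio and the three
  measurement planes P1/P2/P3 that divide the sac height into equal thirds.
* **Virtual growth** — a height-graded anisotropic scaling of the sac
  alone. In the neck frame (neck plane at `z = d`, neck centroid
  `(x_m, y_m, z_m)`, sac height `h`), a sac point maps by

  ```
  x_t − x_m = [1 + a (z − z_m)(k − 1)/h] (x − x_m)
  y_t − y_m = [1 + b (z − z_m)(k − 1)/h] (y − y_m)
  z_t − z_m = [1 + c (z − z_m)(k − 1)/h] (z − z_m)
  ```

  with `(a, b, c) = (2, 2, 1)` by default. The deformation vanishes at the
  neck, so parent vessel and neck stay exactly constant while the ASR
  scales by `1 + c(k − 1)`; `generate_series()` produces a longitudinal
  series at the growth schedule 0.3, 0.5, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0.
  A feasibility guard rejects (or, in stepwise mode, decomposes) factors
  that would fold the mesh over.
* **A synthetic phantom** — watertight vessel + half-ellipsoid sac with
  closed-form morphometry (hemisphere ⇒ ASR exactly 0.5), standing in for
  patient 3DRA reconstructions in every test.
* **Statistics** — plane-averaging of externally computed hemodynamic
  samples (velocity, WSS) and Pearson correlation against ASR. No flow is
  solved here.

## Worked example

```r
library(aneumorph)

ph <- make_phantom(tess = 128)      # hemisphere sac (r = 2 mm) on a vessel
fr <- analyze_aneurysm(ph$mesh, ph$plane, ph$apex_seed)
measure_sac(fr)
#> <sac_morphometry: h = 2 mm, neck perimeter = 12.5651 mm, D = 3.9996 mm,
#>  ASR = 0.50005, aspect ratio = 0.5>
```

The measured ASR is 0.50005, not 0.5: the mesh's neck polygon is inscribed
in the true circle, so its perimeter `2 n r sin(π/n)` is slightly short at
tessellation `n = 128`; the error shrinks monotonically under refinement.
Scaling the sac to the full growth schedule:

```r
series <- generate_series(fr)
series$manifest
#>   target_asr         k steps measured_asr watertight self_intersecting
#> 1        0.3 0.5999398     1          0.3       TRUE             FALSE
#> 2        0.5 0.9998996     1          0.5       TRUE             FALSE
#> 3        0.7 1.3998594     1          0.7       TRUE             FALSE
#> 4        1.0 1.9997992     1          1.0       TRUE             FALSE
#> 5        1.3 2.5997390     1          1.3       TRUE             FALSE
#> 6        1.5 2.9996988     1          1.5       TRUE             FALSE
#> 7        1.7 3.3996587     1          1.7       TRUE             FALSE
#> 8        2.0 3.9995984     1          2.0       TRUE             FALSE
```

Each entry is produced independently from the original model; `k` is the
solved height factor (`target / current` for `c = 1` — the current ASR is
0.50005, hence `k` just under the round ratios), and the re-measured ASR
hits every target to better than 1e−6 while the neck curve is bitwise
unchanged.

## Command line

An `aneumorph` script is installed under `inst/cli/` (all logic is in
`run_cli()`):

```sh
aneumorph phantom --out ph.stl --plane-out plane.json --tess 128
aneumorph measure --mesh ph.stl --plane plane.json
# {"h_mm":2,"perimeter_mm":12.5651...,"D_mm":3.9996...,"ASR":0.50005...,"aspect_ratio":0.5}
aneumorph scale   --mesh ph.stl --plane plane.json --target-asr 1.3 --out s.stl
aneumorph series  --mesh ph.stl --plane plane.json --outdir series/
aneumorph correlate --table summaries.csv --y mean_velocity
```

The plane JSON is `{"point":[x,y,z],"normal":[nx,ny,nz]}` or
`{"three_points":[[...],[...],[...]],"sac_point":[...]}`; units are
millimetres throughout (STL carries no unit metadata). Exit codes: 0 ok,
64 usage, 2 I/O, 3 validation, 4 infeasible scaling.

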