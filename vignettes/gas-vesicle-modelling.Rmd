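---
title: "Modelling gas vesicle shells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gas vesicle shells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvshell)
```

# The shell model and its assumptions

A gas vesicle wall is a two-dimensional protein crystal wrapped into a
cylinder with conical caps. `gvshell` treats it as a one-dimensional
object: a space curve (the rib midline) decorated with rigid monomer
copies. The curve has constant pitch `P` in both the cylindrical and the
conical region, a constant radius `r_max` over `t_cyl` turns, and a
radius decreasing linearly to zero over `t_cap = r_max/(P sin α)` further
turns, where `α` is the cone semi-angle. This is deliberately the
simplest geometry consistent with a helical lattice transitioning into a
cone; it is known to break down at the very tip (the last placements
crowd and clash), which is why the builder omits a configurable number of
tip points (default 4) and why `clash_report()` exists to quantify the
residual overlap rather than hide it.

A useful identity: on the cone the curve speed is
`sqrt((2πr)² + (P cos α)² + (r_max/t_cap)²)`, and because
`r_max/t_cap = P sin α` this collapses to `sqrt((2πr)² + P²)` — the same
form as on the cylinder. The closed-form arc length used as the test
oracle follows directly; the package itself integrates numerically
(adaptive quadrature, relative tolerance 1e-9) and inverts arc length by
bisection to 1e-10 turns, so the two routes stay independent.

## Placement-count convention

Monomers sit at arc positions `0, s, 2s, …`. The number that fits is
taken as `floor(L/s)` where `L` is the total curve length — i.e. the
number of spacing-length segments the curve accommodates, with the point
at `t = 0` included and no point closer to the tip than one full spacing.
At the default parameters `L = 10 497.8 Å` and `s = 12.07 Å`, giving 869
points, minus 4 omitted tip points: 865 per half, 1 730 for the complete
vesicle. This convention also makes a curve of exactly ten spacings carry
exactly ten points. The count is always computed, never assumed.

## Frames, seed orientation and corrections

The local frame at `t` maps the template's local x to the outward wall
normal, local z to the in-wall "up" direction (approximately the cylinder
axis) and local y to the reversed curve tangent; it is the unique proper
rotation with those properties once the radial axis is orthogonalised
against the tangent (needed on the cone, where the tangent acquires a
radial component). The seed monomer is expected pre-oriented in this
frame with its placement pivot — the midpoint of the residue-28 and
residue-42 carbonyl oxygens — at the origin; `align_curve_to_pivot()`
reduces any z-offset/azimuth mismatch by a pure z-shift and z-rotation,
and the builder re-centres the pivot exactly.

Four correction rotations adapt monomers to the cone. Their axes are
computed from the monomer's own landmarks (least-squares plane normals
via SVD; a collinear landmark set is an error, not a silent fallback).
The helix-angle correction is analytic: the in-surface winding angle
`atan(P/(2πr))` minus its cylindrical reference. We use the in-surface
angle rather than the tangent elevation above the equatorial plane
because the latter is discontinuous at the cylinder/cone junction while
the winding angle is continuous and monotone — this is the angle that
"steepens" toward the tip. The other three corrections (monomer tilt,
β-hairpin tilt, N-terminal tilt) were hand-tuned against image data in
the source study and are not tabulated anywhere; they therefore remain
user parameters. The shipped schedule shape is zero on the cylinder, a
linear ramp over the first `tip_frac` (default 0.8) of the cone, then a
constant hold — qualitatively the published curve shapes. Corrections are
applied in template-local coordinates in the fixed order helix-angle,
monomer tilt, β tilt, N-terminal tilt, then the copy is mapped rigidly
into the frame; applying them about the mapped axes in global
coordinates would be equivalent.

## Tunable parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `r_max` | Å | 178.4 | cylinder radius of the reference polymorph |
| `pitch` | Å | 48.8 | helical pitch, identical in cylinder and cone |
| `alpha` | deg | 25 | cone semi-angle |
| `t_cyl` | turns | 5 | cylindrical turns per half shell |
| `spacing` | Å | 12.07 | arc spacing between monomers (`√((2πr)²+P²)/ut`) |
| `n_omit_tip` | – | 4 | tip points omitted per half |
| `tip_frac` | – | 0.8 | fraction of the cone over which manual corrections ramp |
| grid `spacing` (pore) | Å | 0.25 | clearance-grid step |
| `n_boot` | – | 50 | bootstrap resamples for `p0` |

# Image analyses

Projections are sums of per-atom Gaussians (σ default 3 Å, roughly a
class-average-scale blur of ~1.3 Å/px data), binned at sub-pixel centres
and convolved with a normalised kernel, so integrated density equals the
sum of atom weights for every view axis.

**Width profiles.** The image is averaged along the tube axis; local
maxima above 50% of the profile maximum are refined by parabolic
interpolation and the outermost pair taken as the rims. The peak rule is
our documented choice — the source procedure never states one. Blurring
the asymmetric rim of a projected thin shell pulls the peaks inward by
≈1.55 σ in total, independent of tube radius in the regime of interest;
this constant was calibrated once on noiseless synthetic cylinders
(σ between 1.5 and 4 Å, residual < 0.2 Å) and is applied when the image
carries a known blur, with the raw peak distance also reported. Polymorph
assignment snaps a measured rim distance onto the diameter ladder with
increment `spacing/π` (3.82 Å for 12 Å lateral spacing) anchored at the
solved reference (35.6 nm ↔ 92.93 monomers per turn). Diameter-to-count
conversion scales proportionally against that reference because this
reproduces all four published conversions (145 ± 19 and 227 ± 18); the
naive `πD/s` mode is available but is the inference we did not adopt as
default.

**Layer lines.** Segments are rotated in-plane (bilinear interpolation),
mean-subtracted, and their centred power spectra summed — computational
fibre diffraction. The first layer line is read as the strongest
off-equatorial axial-frequency row (excluding ±2 equatorial bins); on
synthetic lattices this recovers the generating pitch within one Fourier
bin, the resolution limit of the box.

# Pore bottlenecks

The bottleneck is a max-min optimisation: over all 26-connected paths on
a clearance grid (clearance = distance to nearest atom surface), maximise
the minimum clearance; the bottleneck diameter is twice that value. The
implementation binary-searches the connectivity threshold over the sorted
node clearances — this returns exactly the same optimum as a
priority-first (bottleneck Dijkstra) search, deterministically, and is
easier to vectorise in R; one realising path is then extracted by BFS on
the thresholded subgraph. Grid axes are centred on the scene box so that
symmetric analytic scenes have nodes on their symmetry planes. This is a
functional stand-in for Voronoi-diagram tunnel tools, validated against
analytic slit and ring scenes and exhaustive max-min relaxation on small
grids; it does not reproduce any particular tool's tunnel surfaces, and
start/end points on real structures are the user's choice. Van der Waals
radii default to Bondi-style values (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å).

# Collapse-pressure fitting

OD₅₀₀ series are normalised per measurement to [0, 1] and fitted with
`OD = 1/(1 + exp(k(p − p0)))` by bounded least squares (`k > 0`):
L-BFGS-B from a deterministic initialisation — `p0` from the first
downward 0.5 crossing by linear interpolation, `k` from 4 divided by the
0.75-to-0.25 crossing span, fallback 1 — followed by a damped
Gauss–Newton polish to machine precision (the quasi-Newton step alone
stops ~1e-5 short). With ≥2 replicates per pressure, replicate standard
deviations enter as inverse-variance weights; both weighted and
unweighted modes exist because the source description is ambiguous on
this point. Uncertainty is the mean/SD of `p0` over 50 n-of-n resamples
with replacement at the (pressure, OD) pair level, with an explicit seed;
failed refits are counted and more than 50% failures is an error. The
coverage check in the acceptance suite uses the conventional 95%
bootstrap interval (`p̂0 ± 1.96 sd`), chosen before measurement as the
standard reading of "the bootstrap SD covers the truth". Note that
min-max normalisation of a finite pressure window is itself a (small)
model violation — noiseless data normalised this way are recovered to
~5e-5 bar, exact model-class data to 1e-6.

# The synthetic world

`make_toy_monomer()` builds a backbone-level (Cα/Cβ/carbonyl-O)
monomer with the coil–α–β–β–α–coil region layout (N-arm 1–7, α1 8–22,
hairpin 23–49 with the turn at 36, α2 50–66), every landmark the
corrections reference, a −36° hairpin tilt, a ~46 Å hairpin span within
the ~50 Å footprint, and 7 052 Da mass (consistent with a 1 730-monomer,
12.2 MDa vesicle). Three choices make the toy lattice pack like the real
one at backbone resolution: α1 sits on the luminal layer, the N-arm
crosses *under* the neighbouring hairpins on the deepest layer, and the
whole template is pre-bent to the reference wall curvature (a straight
feature running circumferentially would otherwise poke outward by
`y²/2r` and collide with the outer layer two neighbours away). With
these, the cylindrical lattice is clash-free at a 2.0 Å main-chain
cutoff while the uncorrected tip still clashes — the qualitative
behaviour the full model is expected to show.

What the generators do **not** emulate: side chains and sequence,
detector/ice noise statistics (noise is plain Gaussian), CTF and dose
effects in images, and instrument drift in pressure series. A green test
therefore establishes the correctness of the geometry, search and
fitting machinery on data from the stated model classes — not
performance on real micrographs.

Collapse curves are sampled on a 0–12 bar grid in 0.5-bar steps (the
instrument increment; the upper end chosen so midpoints up to 8 bar are
well bracketed), default noise SD 0.05 on the normalised scale and
triplicate replicates, matching the measurement design the fitting
module expects. Canonical seeds 0/1/2 appear throughout the suite.

# Numerical choices and degenerate inputs

* Arc-length quadrature 1e-9 relative; inversion bisection 1e-10 turns.
* Rounding of monomers-per-turn: half away from zero (base R's
  `round()` is half-to-even).
* Plane fits reject collinear landmark sets (second singular value
  below 1e-8 of the first).
* The tip singularity (`r → 0`) takes the radial axis from its limiting
  direction; the frame stays orthonormal.
* `duplicate_d1()` refuses already-complete models; `write_pdb()`
  refuses >99 999 atoms or multi-character chains instead of truncating
  (complete vesicles are always mmCIF).
* Flat images, constant OD series, impassable slits and disconnected
  pore grids raise errors naming the condition.

# Known limitations

* The three manual correction schedules are user parameters; no claim is
  made that the defaults reproduce the published tip geometry beyond its
  qualitative shape.
* The constant-pitch cone is wrong at the very tip by construction; the
  model reports its clashes rather than resolving them.
* The rim-bias calibration (1.55 σ) was established for thin-shell
  projections with σ in 1.5–4 Å and is applied only when the blur is
  known (synthetic images and in-package projections; images read from
  plain MRC default to no correction).
* PNG output is not provided (no PNG writer in the dependency budget);
  images are exchanged as MRC mode 2 or TSV.
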