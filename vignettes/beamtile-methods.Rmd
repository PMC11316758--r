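---
title: "beamtile: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{beamtile: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
assumptions those computations rest on, and where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. The acquisition scheme being modelled

A beam-deflection TEM (bdTEM) uses the microscope's deflectors to shift the
illumination to a pattern of positions adjacent to the optic axis and to
de-scan each image back onto the camera. One mechanical stage position
therefore yields a grid of overlapping camera frames — a *supertile* — and a
section-scale montage is a grid of overlapping supertiles. The reference
operating point modelled throughout is a 3 × 3 grid of 6000 × 6000-px
subtiles with 15% subtile overlap (900 px), 600 px overlap between
supertiles, at 3 nm per pixel.

### Tiling arithmetic

All coordinates are 0-based, origin at the region-of-interest top-left,
`x` = column, `y` = row, pixel intervals half-open `[x, x + w)`. With `n`
tiles of side `T` overlapping by `v` px, the stitched extent per axis is
`n·T − (n−1)·v`. The subtile overlap in pixels is `round(frac · T)`; the
section pixel extent is `ceiling(nm / nm_per_px)`; the supertile grid count
per axis is `max(1, ceiling((section − extent)/step) + 1)`. The ceilings
make the montage *overshoot* the requested region rather than undershoot it;
this convention reproduces the published 484 (3 nm) and 324 (3.6 nm)
supertile counts exactly, which an undershooting convention does not.

The inter-supertile overlap defaults to 600 px. The literature on this
instrument quotes both "10%" (which would be 1620 px) and 600 px; only
600 px is consistent with the published supertile counts, so the package
follows it.

### Deflection order

Acquisition starts at the undeflected centre subtile — the best-quality
frame — and spirals outward ring by ring. Within each square
(Chebyshev-radius) ring the order starts at offset `(+1, 0)` (east) and
proceeds counter-clockwise. The chirality and starting spoke are not fixed
by any physical constraint; they are fixed here by convention so that the
order is reproducible. For even grid dimensions the "centre" is the tile at
index `floor(dim/2)` and rings clip at the grid edge.

### Beam-boundary capacity

Deflection range is limited by a circular boundary; the package models a
tile as *fitting* iff all four of its corners lie inside (or on) the circle,
with the subtile grid anchored so one tile is centred on the optic axis.
Both capacity searches (largest contiguous rectangle; all fitting tiles,
the "cruciform") are validated against an exhaustive corner-test oracle. A
consequence of the centred-circle model worth knowing: the fitting set is
symmetric, so a maximal rectangle always has odd extent per axis. Published
packings such as 6 × 5 therefore cannot arise under this idealized model —
they indicate a physically off-centre boundary — and the capacity
operations are deliberately validated against the oracle, not against any
published packing count.

## 2. Throughput model

The per-section time model is linear in its event counts:

```
t_imaging = N_t (t_exp + t_acq) + N_st (t_move + t_settle) + N_defl t_defl
t_total   = t_imaging + t_transition
```

with `N_defl = (tiles_per_supertile − 1) · N_st` (the centre subtile needs
no deflection settle) and one stage step charged per supertile, including
the first. Defaults: 37 ms stage motion (mean of the published 34 ms x-axis
and 40 ms y-axis times) plus 10 ms added settle; 2.2 min transition; 120 ms
exposure. The per-tile acquisition-software overhead `t_acq` is the one
constant not published anywhere; `fit_acq_overhead()` back-solves it from an
observed imaging time (~31 ms/tile for the published 11.7-minute section).

Rates: burst = pixels/exposure; montage = all acquired pixels over imaging
time; net = same over total time; effective = overlap-deduplicated pixels
over total time. The duty cycle numerator counts **exposure only** — not
readout or software overhead — which is the definition that reproduces the
published 32.9% / 31% figures. Displayed rates round half-away-from-zero to
integer MPix/s; sections/day floors and days-per-volume ceils (the only
combination that reproduces the published 103 sections/day and 54 days
simultaneously). Volume projections assume 1 mm² sections at 45 nm
thickness.

One published cell is not exactly recoverable from printed inputs: the
40 ms montage rate prints as 397 MPix/s but recomputes as 396 from the
rounded printed times (6.6 min); the discrepancy is rounding in the source,
not in the model.

## 3. The simulator and its stated world

### Specimen texture

`make_specimen()` emulates heavy-metal-stained neural tissue *at the texture
level only*: dark curvilinear ridges (membranes), dark soft disks
(vesicle/mitochondria cross-sections), and a band-limited background
(cytoplasm). Defaults: 40 membranes/Mpix, thickness 2–6 px, tortuosity
0.12 rad/step; 350 blobs/Mpix of radius 3–14 px; background level 0.55,
fluctuation s.d. 0.04, correlation length 4 px. The densities were chosen to
make the texture feature-rich and isotropic the way micrographs are at
3 nm/px. An early sparser draft (30 membranes + 60 blobs/Mpix, nearly
straight membranes) was visibly unlike tissue and produced a diagnostic
artefact: block matching on it suffered an aperture problem (displacement
poorly constrained along the few straight edges). Density and curvature
were revised once, for realism, and are not tuned further.

What the generator does **not** emulate: section folds/cracks, knife marks,
charging, staining gradients, beam-induced pre-irradiation deformation, and
real ultrastructure (no closed cells, no synapse geometry). A green test on
simulated data therefore establishes that the *algorithms* behave as
specified on textured, ground-truth-known input — not that the instrument
achieves any particular quality on tissue.

### Optics and noise

Per subtile at deflection-radius `r` (Euclidean norm of the offset index, so
corner subtiles at `r = √2` degrade more than edge subtiles at `r = 1`):

* **Distortion** — a 2nd-order 2-D polynomial displacement field plus a
  radial (barrel) term, coefficients drawn deterministically from the tile
  seed, rescaled so the maximum displacement equals `distortion_scale · r`.
  The exact coefficients and scale are stored in the truth manifest, so the
  applied field is reconstructable bit-for-bit (`distortion_field()`).
  The real instrument shows distinct smooth per-subtile fields; no
  functional form is published, so a low-order polynomial was chosen as the
  simplest family with the right qualitative behaviour.
* **Contrast falloff** — multiplicative attenuation `(1 − snr_falloff)^r`
  about the tile mean. Quality loss with deflection is attributed in the
  source literature to defocus, aberration, or reduced dose without
  quantification; the falloff is a free knob, not calibrated to any
  published curve.
* **Noise** — expected counts `dose_per_ms · exposure_ms · intensity`,
  Poisson-sampled, plus Gaussian read noise (s.d. in intensity units).
  In-memory rasters stay in intensity units `[0, 1]` (counts divided by
  dose), so the ideal-detector limit (`dose_per_ms = Inf`) returns the scene
  crop exactly; quantization to 16 bits happens only at TIFF export.
* **Boundary** — pixels whose deflected position exceeds
  `boundary_radius_px` from the optic axis are replaced by the in-boundary
  mean and the tile is flagged `clipped`.
* **Stage jitter** — optional Gaussian perturbation of each supertile
  origin (default 0). The scene must include a `4·sd` margin per side so
  jittered edge tiles stay inside it.

The "mild noise" level used by the end-to-end acceptance run is
`dose_per_ms = 10`, `read_noise_sd = 0.01`: ~1200 detected electrons per
pixel at the 120 ms exposure and 1% additive read noise, a realistic
electron budget for stained-section TEM imaging. It was fixed once when the
acceptance world was defined.

## 4. Quality-control metrics

* **Radial power spectrum** — mean-subtract, Hann taper (the taper choice
  is recorded in the output; the source methods are silent on windowing),
  2-D FFT, squared modulus, radial bins `round(r/0.5 · n_bins)` clamped to
  `[1, n_bins]`, DC excluded. Default `n_bins` is Nyquist in integer radius
  steps. Binned power sums exactly to the total non-DC power.
* **Spectral SNR** — `SNR(f) = max(0, (P_img − P̄_noise)/P̄_noise)` against
  the mean spectrum of one or more noise images acquired identically
  (physically: beam blanked; in simulation: zero-signal acquisitions). Bins
  with zero noise power are flagged invalid and excluded. The scalar
  spectral-SNR is the trapezoidal integral over the band. Clamping at zero
  and the bin count are defaults, not claims about the original
  implementation.
* **Focus score** — fraction of non-DC spectral power above
  `cutoff_frac × Nyquist`; higher is sharper.
* **Displacement fields** — evenly spaced grid; per point the integer
  offset maximizing NCC within the search radius, refined by 1-D quadratic
  fits along each axis. Ties break toward the smaller displacement; a
  perfect peak (NCC = 1) skips refinement so bit-identical input yields
  exactly zero vectors. Peak NCC < 0.2 flags a point invalid; blocks that
  would leave the image are skipped, not errors. For a pull-back warp
  `warped(x) = ref(x + d(x))` the measured vector satisfies the fixed point
  `s + d(q + s) = 0`; tests use that exact relation as the oracle.

## 5. Stitching

Translation-only: one `(x, y)` per tile. Pairwise offsets come from NCC
matching of a central block of the nominal overlap (capped at 256 px for
speed; pairs overlapping < 64 px are flagged unusable). Global positions
minimize the confidence-weighted sum of squared pair disagreements with the
anchor — the centre subtile of the first supertile, the undeflected
best-quality frame — fixed at its nominal position; x and y decouple and
are solved via the normal equations of the weighted graph Laplacian.
Compositing renders at an integer canvas with linear feather blending
(ramp = tile/8 by default) or first-wins.

Two caveats are inherent and documented rather than hidden. First, the
global translation of the solution is unobservable: if the anchor's own
stage-jitter draw is `ε`, every solved position is off by exactly `ε`.
Accuracy against ground truth is therefore evaluated after removing the
best-fit global translation. Second, rendering at integer positions leaves
up to half a pixel of placement error per tile; with low noise this — not
the registration — can dominate the composite-versus-scene residual.
Elastic (mesh-based) refinement, which production pipelines apply after
translation stitching, is out of scope.

## 6. Numerical and degenerate-input choices

* Constant rasters: zero power spectrum (not an error); NCC returns `NA`
  with an invalid flag; constant overlap blocks give a low-confidence pair.
* `ssnr` is invariant to a common positive gain on image and noise.
* A disconnected pair graph is an error naming the unreachable tiles.
* Tile seeds derive deterministically from `(montage seed, supertile,
  subtile)` and stay below 2³¹, so any tile is reproducible in isolation and
  the caller's RNG stream is never disturbed.
* The JSON plan/manifest round-trips exactly (section extent is stored in
  pixels and re-derived multiplicatively).

## 7. File formats

Tiles are single-page uncompressed baseline TIFF, single-channel, 16-bit
(8-bit accepted on read, widened with a warning; RGB, compressed and
multi-page files rejected). The codec is implemented in the package because
the supported R environment provides no TIFF reader; it covers exactly the
subset the tool emits. Configs are JSON validated against a fixed key
schema (unknown keys rejected) — JSON rather than TOML because no TOML
parser is available in the supported environment. Manifests embed the
package version and all seeds.

## 8. Known limitations

* No electron-optical physics: no defocus PSF, coma, charging, or
  pre-irradiation deformation; the deflection-quality model is a
  phenomenological falloff.
* Capacity modelling assumes a centred circular boundary (see §1).
* The stitcher is translation-only by design; distortion-enabled
  simulations stitch with residuals reflecting the injected fields.
* Block matching needs feature-rich texture; on nearly 1-D texture the
  aperture problem inflates along-edge uncertainty (flagged only via lower
  peak confidence).
* Throughput projections inherit the published constants; filament life,
  vacuum events, re-imaging and QC overheads are not modelled.
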