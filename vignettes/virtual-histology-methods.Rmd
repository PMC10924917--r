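---
title: "Methods: simulating propagation-based phase-contrast micro-CT virtual histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating propagation-based phase-contrast micro-CT virtual histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vhisto)
```

## The problem

Histology reads a ~5 micrometre stained section — about one-thousandth of a
~5 mm paraffin block. Propagation-based phase-contrast micro-CT (PhC
micro-CT) images the whole block non-destructively at micrometre pixel
sizes: the real refractive-index decrement delta of soft tissue is roughly
three orders of magnitude larger than the absorption index beta at ~20 keV,
so letting the beam propagate a few hundred millimetres after the sample
turns invisible soft-tissue boundaries into measurable edge fringes. A
single-distance TIE-Hom (Paganin) filter then converts the fringed
projections back into maps proportional to the linear attenuation
coefficient, and filtered back projection (FBP) reconstructs the volume,
which can be virtually sliced along any plane and registered against real
sections.

`vhisto` implements that whole chain as testable code: a seeded procedural
breast-tissue phantom plays the role of the specimen, a Fresnel forward
model plays the role of the beamline, and quantitative image-quality
metrics (CNR, edge FWHM, ring and cupping scores) replace qualitative
visibility assessment.

## Physical model and conventions

The complex refractive index is `n = 1 - delta + i*beta`. Per projection
angle the phantom is line-integrated (parallel beam, rotation about the
central vertical axis, bilinear interpolation along rays), giving the exit
phase `phi = -(2*pi/lambda) * integral(delta)` and absorbance
`B = (2*pi/lambda) * integral(beta)`. The wavefield `exp(i*phi - B)` is
propagated with the paraxial Fresnel transfer function
`exp(-i*pi*lambda*z*f^2)` after replicate padding to twice the lateral
size; intensity is its squared modulus. The protocol presets follow the
beamline settings: 4 um pixels at z = 500 mm, 2.5 um at 250 mm, 1 um at
150 mm, 20 keV effective energy, 1800 evenly spaced projections over 180
degrees on a 2048-pixel-wide detector (desk-scale runs reduce the grid and
angle count, never the physics).

Monochromatic 20 keV replaces the filtered polychromatic beam; the
magnification at 22.3 m source distance and <= 0.5 m propagation is at most
1.023 and is ignored (parallel-beam, M = 1). An optional quadratic
attenuation bias (`detector_model(beam_hardening=)`, `B -> B*(1 - c*B)`)
emulates the residual beam-hardening cupping that the de-trending stage is
designed to remove.

All arrays are indexed `[row, column, slice]`, 1-based, pixel centres at
integer coordinates. Angles are degrees counterclockwise from the +x axis.

## Material constants

`build_material_table()` computes delta and beta per material from a frozen
per-element table (Z, A, imaginary scattering factor f2 at 20 keV) and
ICRU-44-style mass compositions (paraffin CH2 at 0.90 g/cm3; adipose 0.95;
glandular 1.04; dense stroma as glandular at 1.10; blood 1.06;
hydroxyapatite 3.18). beta includes an incoherent (Compton) term so that it
is consistent with the *total* linear attenuation a reconstruction
measures; `mu = 4*pi*beta/lambda`. Air is treated as vacuum. Away from
20 keV, delta scales exactly as `1/E^2`; f2 is scaled as `(20/E)^2`, a
documented approximation adequate across the allowed 5-100 keV range for
these low-Z materials.

The retrieval filter ratio delta/beta = 350 is the protocol's operational
choice for the glandular/fat interface and is stored as the pipeline
default. It is deliberately *not* derived from the table: the tabulated
glandular/adipose interface ratio is ~1400, and soft-tissue/air interfaces
reach ~4300. Retrieving with one global 350 therefore under-smooths most
interfaces, which preserves sharp edges (the visual appeal of the
technique) at the cost of residual fringe halos — see "Known limitations".

## The phantom generator

`phantom_spec()` + `generate_phantom()` build a labeled voxel map:

* a cylindrical paraffin block (`block_radius_frac`, default 0.96 of the
  half-width) with **air outside**, so a full-field scan is laterally
  complete; truncation is produced deliberately by choosing a detector
  window narrower than the block;
* a tissue cylinder (default 0.78) of glandular background, optionally
  textured with thresholded correlated Gaussian noise into dense stroma
  (`stroma_fraction`, correlation length `stroma_corr_um`);
* adipocytes as non-overlapping spheres (radii in micrometres), either a
  fixed count or grown until a target adipose area fraction is reached;
* duct/TDLU-like units: a glandular-walled annulus with paraffin lumen and
  a ring of small acini; microcalcifications (hydroxyapatite, strictly
  disjoint so component counts equal requested counts); optional blood
  vessels; air bubbles in the paraffin margin.

Both cylinders get small seeded centre offsets (<= 4% and <= 1% of the
half-width). A perfectly centred cylinder would put its edge in the same
detector columns at every angle — indistinguishable from a ring artifact
and unrealistic for a mounted specimen.

One integer seed drives everything through per-class sub-streams, so a
spec is a pure function: identical specs give bit-identical phantoms.
Placement uses bounded rejection sampling and errors naming the class that
does not fit.

`labels_to_refractive()` converts labels to (delta, beta) maps by exact
per-voxel lookup; `edge_sigma_px` optionally smooths the maps by ~1 px to
emulate partial-volume softness of biological interfaces. The study
configurations use 1 px: mathematically sharp single-pixel edges produce
unrealistically broadband phase fringes whose mismatch residuals dominate
every artifact metric.

### What the generator does and does not emulate

It reproduces the *geometry statistics* that matter to the pipeline:
compartment contrasts, object scales from tens of micrometres
(calcifications, acini) to millimetres (the block), interfaces of very
different delta/beta ratio, and through-depth variation in thin 3D stacks.
It does not attempt cellular realism, vascular trees, fibre anisotropy or
stain-specific appearance. Consequently, passing tests demonstrate the
correctness and artifact behaviour of the *processing chain*, not
diagnostic equivalence on real tissue.

## Detector model and ring artifacts

`detect()` applies `counts = blur(ideal * n0 * gain) + dark`, Poisson
noise when enabled, Gaussian dark noise, and synthesises flat and dark
frames. Defaults used in the study configurations: n0 = 5000 photons per
pixel per projection, 20 flats/darks, 0.6 px Gaussian PSF (standing in for
the scintillator/optics blur), 1% static column gain spread.

Static column gains cancel exactly in flat-fielding, because the flats see
the same gains. What survives — and what ring removal exists for — is
column structure that changes between the flats and the scan. The model
exposes this as `gain_drift_sigma`, a per-column multiplicative drift
applied to sample projections only. The study value, 2% RMS, aggregates
every flat-field-invalidating effect at a real beamline (scintillator
inhomogeneity and radiation damage, beam and monochromator drift), and is
sized so the simulated data show the clearly visible rings that motivate a
ring-removal stage: the delta/beta = 350 retrieval filter alone attenuates
single-column errors by ~500x at the Nyquist frequency, so sub-percent
drift would produce data that never needed ring correction.

`remove_rings()` subtracts from each sinogram column the high-frequency
part of its angle-averaged profile (moving median window, default 9
columns), re-centred so the sinogram mean is exactly preserved; it is
near-idempotent and near-identity on ring-free data.

## Retrieval, reconstruction, enhancement

`retrieve()` applies `H(f) = 1/(1 + pi*lambda*z*(delta/beta)*f^2)` to the
replicate-padded transmittance and returns `-log` of the result; sinograms
are filtered per angle in 1D, full projections in 2D. At `z = 0` or
`delta/beta -> 0` this is exactly `-log(T)`.

`fbp()` zero-pads each projection to the next power of two at least four
times the width, applies the Shepp-Logan kernel
`H(f) = |f| * sinc(f/(2*f_N))`, and back-projects with linear
interpolation, scaling by `pi/n_proj`. The generous padding keeps the DC
deficit of the frequency-sampled ramp (which biases wide uniform regions)
at the ~1% level; at 2x padding the bias on a uniform disk is ~4%. Working
in per-pixel frequency units makes a `-log(T)` sinogram reconstruct to
`mu * voxel_size` — "proportional to the linear attenuation coefficient".

`pad_local_sinogram()` extends truncated (local-area) sinograms with a
half-cosine taper from the edge value to a target level before FBP. The
default target is zero — modelling the object plausibly ending outside the
field of view — which on a uniform wide block reduced the centre-to-edge
truncation bowl ~8x (pad = half the window width), versus ~2.7x for
tapering to the row mean; the row-mean and constant-edge variants remain
available.

`detrend()` fits a full second-order 2D polynomial to a reference mask,
subtracts it everywhere and restores the reference median. The mask must
be spatially distributed: in a full-field block scan the paraffin is a
thin annulus, and a quadratic fitted to an annulus alone is unconstrained
over the interior — its extrapolation can exceed the soft-tissue contrast
several-fold. The pipeline therefore fits on the paraffin background plus
the eroded glandular compartment (`detrend_reference_mask()`), the two
nominally homogeneous regions, which anchors the trend across the field
of view while leaving compartment contrasts intact. `unsharp_mask()` is
the standard `in + a*(in - G_sigma(in))` with defaults a = 1,
sigma = 2 px.

## Quality metrics

* `cnr()`: pooled-sigma contrast-to-noise,
  `|m_a - m_b| / sqrt((v_a + v_b)/2)` — fixed project-wide since no single
  definition is canonical.
* `edge_fwhm()`: edge-spread profile sampled at 0.25 px along a segment,
  lightly smoothed, differentiated; FWHM of the line-spread function in
  micrometres.
* `ring_score()`: variance of the narrow radial spikes of the angular-mean
  polar profile (after moving-median baseline removal, so smooth object
  structure does not count), normalised by the slice variance; measured
  inside 35% of the half-width by default to exclude the block-edge
  circle.
* `cupping_score()`: magnitude of the fitted `a + b*r^2` radial trend of
  the background (r normalised to the half-width), in intensity units.

The headline property of the whole chain is the trade the protocol makes:
on the same seeded noisy scan, phase retrieval at delta/beta = 350
multiplies the glandular/adipose CNR by roughly an order of magnitude
relative to the attenuation-only reconstruction (measured factors 7-16
across seeds under the study conditions), while edge FWHM grows by a
bounded factor. The resolution
half of that statement is measured on a noise-free twin of the scan:
resolution is deterministic, and at realistic flux the attenuation-only
image simply has no detectable soft-tissue edge above the noise — which is
the technique's premise.

## Virtual slicing and registration

`extract_slice()` samples arbitrary planes (orthonormal in-plane basis,
trilinear interpolation; out-of-volume samples are NA and counted).
`simulate_section()` turns a stored slice into a histology stand-in:
thickness averaging, a rigid pose (`rigid_transform_2d`: rotation about
the image centre, then translation, optional isotropic scale), affine
intensity remap, and seeded dropout holes emulating tissue lost in
sectioning. `register_2d()` maximises normalized cross-correlation — NCC
is invariant to affine intensity remaps, appropriate because the stand-ins
share the CT contrast mechanism — over a coarse rotation grid with
FFT-based translation search, two rounds of 5x rotation refinement and
parabolic sub-pixel peak interpolation. `find_best_plane()` repeats this
over candidate depths and returns the argmax, the automated counterpart of
a pathologist matching a stained section to its position in the stack.
Sections are generated at CT pixel size; registration of images smaller
than ~150 px with little texture can prefer the unrotated pose, because
the interpolation loss of rotating back outweighs a small angular
misalignment — the desk-scale demo shows this, the study-scale checks do
not. Mutual information was considered and left out: with shared contrast
mechanisms NCC is sufficient and has no histogram-binning parameters.

## Problem sizes and numerical choices

The bundled configurations use: 512^2 phantoms with 800 projections for
the end-to-end quantitative checks; a 320^2 block with a 192-px window for
truncation; 128-160 px images for registration properties; a 128^2
pipeline demo. These sizes put every structure well above the resolution
limit while keeping a full run in minutes on one CPU core.

Other fixed choices: transmittance floor 1e-6 before logarithms;
interior regions for recovery statistics erode 16 px from every label
boundary (the measured extent of mismatch halos at delta/beta = 350);
"interior RMSE" is reported relative to the phantom's full ground-truth
attenuation dynamic range, the same normalisation as the unit-disk oracle;
end-to-end recovery is evaluated on piecewise-constant phantoms (stroma
texture off), since textured regions have no plateaus to recover.

## Known limitations

* **Single-ratio retrieval is not quantitative near interfaces.** With
  physically tabulated constants, the glandular/adipose interface ratio is
  ~1400 and paraffin/air ~4300; filtering at 350 leaves oscillatory halos
  extending tens of micrometres whose amplitude is comparable to the
  soft-tissue contrast itself. Plateau values far from boundaries are
  correct (the filter passes DC exactly), but soft-tissue-contrast-level
  accuracy within a halo length of an interface should not be expected.
  Per-region retrieval is out of scope.
* TIE-Hom linearises the propagation; very sharp, high-contrast edges
  (calcifications, air bubbles) violate its validity regardless of the
  ratio chosen.
* The forward model is 2D slice-wise (each detector row independent),
  exact only for objects invariant along the rotation axis over the row
  spacing; partial coherence, scatter and detector nonlinearity are not
  modelled.
* Interior (local-area) tomography recovers absolute values only up to the
  low-frequency component the padding heuristic supplies; de-trending
  absorbs the remainder but is a correction, not a reconstruction.
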