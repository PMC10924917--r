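# vhisto

Simulation and analysis of **propagation-based phase-contrast micro-CT
(PhC µCT) virtual histology** of paraffin-embedded breast-tissue blocks.

A stained histology section is ~5 µm thick — about one-thousandth of a
~5 mm paraffin block. Synchrotron PhC µCT images the whole block
non-destructively at micrometre pixel sizes: at ~20 keV the refractive
decrement δ of soft tissue exceeds the absorption index β by ~3 orders of
magnitude, so a few hundred millimetres of free-space propagation turn
otherwise invisible soft-tissue boundaries into measurable edge fringes.
Single-distance TIE-Hom (Paganin) retrieval with filter
`H(f) = 1/(1 + πλz(δ/β)f²)` followed by `-log` converts the fringed,
flat-fielded projections into maps of the projected attenuation `µ·t`, and
Shepp-Logan filtered back projection (`H(f) = |f|·sinc(f/2f_N)`)
reconstructs a volume proportional to µ that can be virtually sliced along
any plane and co-registered with real stained sections.

`vhisto` implements the complete chain as tested R code, for imaging
scientists and methodologists who need a controlled, fully seeded testbed
for this class of pipeline:

* **phantom** — procedural labeled breast-tissue-block phantoms
  (adipocytes, duct/TDLU-like units, dense-stroma texture,
  microcalcifications, air bubbles, paraffin block) and conversion to
  δ/β maps from a frozen scattering-factor material table;
* **forward optics** — parallel-beam line integrals, Fresnel propagation,
  and a detector model with flats, darks, Poisson noise, PSF blur,
  column-gain structure and beam-hardening bias;
* **preprocess** — flat-field correction `T = (I-D̄)/(F̄-D̄)` and
  ring-artifact suppression;
* **phase retrieval** — TIE-Hom at a configurable δ/β (protocol default
  350 for the glandular/fat interface);
* **recon** — Shepp-Logan FBP with local-area (truncated) sinogram
  padding;
* **enhance + metrics** — de-trending, unsharp masking, CNR, edge FWHM,
  ring score, cupping score;
* **virtual slicing** — arbitrary-plane extraction, histology-like section
  synthesis, rigid NCC registration and best-plane search;
* **pipeline** — one YAML config drives phantom → scan → reconstruction →
  report → registration, bit-reproducibly (`run_pipeline()`, plus a thin
  `inst/cli/vhisto` wrapper).

## Worked example

```r
library(vhisto)

out <- run_pipeline(system.file("extdata", "demo_config.yaml", package = "vhisto"),
                    "demo_out",
                    stages = c("simulate", "reconstruct", "report", "register"))
print(out$report)
#> quality_report
#>   CNR glandular_vs_adipose   1.360
#>   edge FWHM   8.48 um
#>   ring score  8.432e-05
#>   cupping     0.0001564
```

The demo scans a 128² phantom under the 4 µm / 500 mm / 20 keV protocol
preset (200 projections): the glandular/adipose contrast-to-noise ratio of
1.36 is reached at soft-tissue contrasts that are essentially invisible in
the attenuation-only reconstruction of the same data; the edge width of
8.5 µm (2.1 pixels) shows the resolution cost of retrieval plus detector
blur; ring and cupping scores near zero confirm the ring-removal and
de-trending stages did their job. `demo_out/` then contains the raw TIFF
stack (`raw/tomo_0000.tif`…), the reconstructed slices (`recon/`), the
report JSON, and a `overlay.tif` fusing the reconstructed slice with a
synthesized degraded section re-registered onto it.

At study scale (512² phantom, 800 projections, noise on) the same pipeline
yields a glandular/adipose CNR ~7× the attenuation-only value, recovers
piecewise-constant interiors to ~2.6% of the attenuation dynamic range,
and its ring removal / de-trending / local-area padding reduce the
corresponding artifact scores 5–8×; see the methods vignette
(`vignettes/virtual-histology-methods.Rmd`) for the model, parameter
choices and known limitations.

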