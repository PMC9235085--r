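---
title: "Virtual reconstruction of bony midfacial defects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual reconstruction of bony midfacial defects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bony midfacial defects — from tumour resection, trauma or congenital
deformity — need a reconstruction target before surgery. The classic
reference is *mirror technology*: reflect the intact contralateral bone
across the facial midsagittal plane. It fails for midspan and bilateral
defects and is biased by natural craniofacial asymmetry. An alternative is
to learn the shape of the normal midface from a cohort of CT scans and
inpaint the defect region slice by slice with a conditional generative
adversarial network (GAN): the generator receives the defect image and
proposes the missing bone; accuracy is then quantified against a reference
by cosine similarity of the 8-bit slice images and by the mean surface
error (mm) between registered bone surfaces.

`midfacer` implements that pipeline end to end, *including* the data: no
public CT cohort exists for this task, so the package generates
procedural head phantoms on which every stage — defect construction, GAN
training, mirror references, metrics, statistics — is exercisable and
testable.

## Pipeline overview

1. **Volumes** (`volume()`, `read_volume()`, `write_dicom_series()`): 3D
   HU-intensity arrays `[slice, row, column]` with mm spacing. The DICOM
   codec is deliberately narrow: explicit-VR little-endian, single-frame
   axial CT, 16-bit pixels. Integer-HU volumes round-trip bit-exactly.
2. **Phantoms** (`generate_head_phantom()`): an ellipsoidal vault shell
   plus an anterior midfacial block with paired cavities (orbits,
   maxillary and frontal sinuses) and a midline nasal corridor, divided
   into five axial subunit bands labelled I (frontal sinus–frontal bone)
   down to V (residual maxilla). Landmarks (glabella, nasion, anterior
   nasal spine, basion) sit exactly on the midsagittal plane.
3. **Defects** (`sample_defect_spec()`, `carve_defect()`): sphere, cuboid
   or semi-cylinder phantoms carved out of bone within a chosen subunit;
   `make_slice_pairs()` emits aligned (truth, defect, mask) 8-bit triples.
4. **GAN** (`train_gan()`): residual encoder + upsampling decoder
   generator G(x, z), 3-convolution-layer conditional discriminator
   D(x, y), trained with a non-saturating adversarial loss plus L1
   reconstruction (1:100), Adam at learning rate 0.002.
5. **Evaluation** (`evaluate_reconstruction()`): per-slice cosine
   similarity over mask-intersecting slices; marching-tetrahedra surface
   extraction; point-to-plane rigid ICP; symmetric mean surface error;
   `mirror_reference()` for the mirror-technology baseline.
6. **Statistics** (`mann_whitney_u()`, `compare_groups()`,
   `render_tables()`): mean ± SD group summaries, Mann–Whitney U
   comparison of artificial vs clinical accuracy, per-subunit and
   per-case report tables.

## What the phantoms emulate — and what they do not

The phantoms reproduce the *structural* properties the pipeline's
correctness depends on: a thin bone shell with internal cavities, five
non-empty labelled subunits in anatomical order, exact mirror symmetry
about a configurable midsagittal plane, and controllable left–right
asymmetry. They are geometric primitives, not anatomy: no trabecular
texture, no soft-tissue gradients, no CT noise physics (optional additive
Gaussian noise only), no inter-subject shape statistics beyond simple
scale jitter. Tests passing on phantoms therefore validate the *plumbing
and the mathematics* — carving, compositing, registration, metrics,
statistics — and the GAN's ability to learn structured inpainting at desk
scale. They do not certify clinical accuracy on real CT data, which
requires the original cohort scale (hundreds of cases at 512×512).

Key defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| grid | 96×128×128 at 1 mm (64³ in tests) | desk-scale, 1 mm slice spacing typical of craniofacial CT |
| bone / soft / background HU | 700 / 40 / −1000 | cortical bone, soft tissue, air |
| bone threshold | 300 HU | common cortical segmentation threshold |
| grayscale window | (−1000, 2000) HU | air black, dense bone near white |
| shell thickness | 3 mm | calvarial cortical scale |
| defect extent | 10–30 mm | subunit-scale defects |
| split rule | test = ⌊0.2·n⌋ | the only rounding consistent with 518 → 415/103 |

## The asymmetry construction

Asymmetry is implemented as an *outward inflation* of the vault shell on
the left side: both the outer and inner ellipsoid surfaces are offset
outward by the amplitude `a`, ramped smoothly to zero near the midplane.
An offset along the surface normal leaves the local surface-to-surface
distance equal to `a` (exactly so for a sphere, and to first order on the
lateral cap of a mildly eccentric ellipsoid), so the mirror reference of
such a phantom must disagree with the true surface by ≈ `a` on the
perturbed cap — an analytically checkable oracle. Two practical caveats
drive the test configuration:

* the error is measured on the lateral cap only
  (`asymmetric_region()`), where the inflation is at full amplitude and
  normals are near-lateral;
* the shell must be thicker than about twice the amplitude. Otherwise
  the closest point to an offset *outer* surface is the opposing *inner*
  sheet of the thin shell, and the measured distance collapses to
  `shell − a`. The asymmetry checks therefore use an 8 mm shell with a
  2 mm amplitude.

With a zero amplitude the voxel grid itself is mirror-symmetric
(the midplane lies exactly between voxel centers), so the reflected
surface coincides with the original up to triangulation differences —
measured below 0.01 mm — which is the null case for the mirror pipeline.

## Surface extraction and registration

No marching-cubes implementation is available among the package's
dependencies, so `extract_surface()` implements marching tetrahedra over
the 6-tetrahedron (Kuhn) decomposition of each grid cube, at level 0.5 on
the binary mask pre-smoothed with a small Gaussian (σ = 1.2 voxels). The
smoothing provides sub-voxel vertex placement (digital-ball surface area
within 0.5 % of the analytic sphere); when smoothing would erase a tiny
component (e.g. a single voxel) the raw binary field is used so every
non-empty mask yields a closed mesh. The volume border is padded, so
meshes are watertight by construction; degenerate triangles are dropped.

`register_rigid()` is ICP with point-to-triangle correspondences and a
linearized *point-to-plane* update (Rodrigues-composed each iteration).
Point-to-plane was chosen after observing the classic behaviour of
point-to-point updates: tangential sliding is penalized, giving linear
convergence too slow for sub-0.01 mm recovery in 100 iterations, whereas
the point-to-plane update recovers 5 mm translations and 10° rotations to
numerical precision in fewer than ten iterations on phantom meshes. The
moving vertex set is capped at 2000 evenly-spaced vertices (dense meshes
add correspondences, not information). Iteration stops on relative MSE
improvement < 1e−6, an absolute MSE floor of 1e−14 mm², or 100
iterations, returning the best iterate with a convergence flag.

`mean_surface_error()` is the symmetric mean of unsigned point-to-triangle
distances (A-vertices→B averaged with B-vertices→A); a one-sided mode
matches deviation tools that measure a test surface against a reference.
Distances are point-to-triangle, not point-to-vertex, to avoid
mesh-resolution bias.

## GAN design

The training objective is the pix2pix convention: non-saturating
adversarial loss plus λ·L1 to the truth slice with λ = 100, Adam with
learning rate 0.002 and β = (0.5, 0.999). The generator encoder follows
residual-network presets (18 and 34 with basic blocks, 101 with
bottleneck blocks); tests and the acceptance experiments use depth 18 at
base width 8 and 64×64 resolution — training at full scale (depth 101,
512×512, optionally starting from natural-image-pretrained weights) is
configurationally supported but not exercised in the test suite. The noise input z enters as a broadcast
channel concatenated to the defect image and mask channels; z = 0 gives
deterministic inference and is the reconstruction-time default. The
defect mask is an explicit input channel: the defect region is known in
this workflow (the surgeon delineates it), and compositing in
`reconstruct_volume()` keeps generator output only inside the mask, so
intact anatomy is bit-identical by construction.

The augmentation factors — horizontal flip (p = 0.5), scaling in
[0.8, 1.2], rotation up to 11°, additive Gaussian noise — apply one shared
geometric transform to the (truth, defect, mask) triple, bilinear for
intensity images and nearest-neighbour for the mask. Interpolation blends
intensities across the mask boundary, so augmented pairs are exempt from
the strict `defect == truth` identity that freshly carved pairs satisfy.

The whole engine (conv2d via im2col/GEMM in compiled code, batch norm,
leaky ReLU 0.2, nearest upsampling, Adam) is implemented in the package;
the hand-written reverse-mode gradients are pinned by finite-difference
checks in the test suite. Determinism is promised per platform: seeded
runs reproduce loss histories and weights bitwise on one machine/BLAS,
not across BLAS implementations.

At desk scale the headline check is an *improvement* property, not an
accuracy claim: training the depth-18 generator on 20 synthetic 64×64
slice pairs for 30 epochs reduces the held-out masked-region mean
absolute 8-bit error below that of the random-weight generator (median
over three seeds). The accuracy reported for the original clinical-scale
system is not reproducible without its 518-case cohort and trained
weights; what the package pins exactly are the in-table aggregations
(the published per-case table averages to 0.96 / 0.48 mm) and the 8:2
split arithmetic (518 → 415/103).

## Statistics

`mann_whitney_u()` computes U from midrank sums and reports
`min(U1, U2)` for two-sided tests. The p value is exact (via the null
distribution of U) when `n1·n2 ≤ 400` and the pooled data are tie-free —
the regime where the test suite checks it against exhaustive enumeration
of all C(n1+n2, n1) labelings — and otherwise a normal approximation with
tie and continuity corrections, whose type-I error at the study's group
sizes (15 vs 103) calibrates to 0.05 within Monte-Carlo tolerance.
Group summaries report the sample SD (n−1) and also the population SD,
since published mean ± SD tables do not always state the convention;
aggregation targets pin only means, which are denominator-independent.
Display rounding is half-up to two decimals, applied only at report time.

## Numerical choices and degenerate inputs

* 8-bit quantization: linear window map, clip, round half-up (127.5 → 128).
* Cosine similarity rejects all-zero images (undefined angle); it is
  invariant to positive rescaling to 1e−12.
* Voxel membership for carving is a pure voxel-center-in-shape test with
  closed boundaries (≤), exactly reproducible by brute-force enumeration;
  a sub-half-voxel sphere between voxel centers carves nothing and
  returns the volume unchanged.
* Empty defect masks are legal everywhere downstream: no slice pairs, a
  no-op reconstruction, and an error only where a value is undefined
  (cosine aggregation over zero slices).
* DICOM slice-spacing consistency is enforced to 1 % of the median gap;
  the offending slice is named in the error.

## Limitations

Phantom realism as discussed above; 2D slice-wise inpainting (no 3D
convolutions or inter-slice consistency loss); rigid registration only —
no deformable refinement; single defect per case; the one-sided
deviation convention of commercial inspection software and the
mask-area-weighted cosine aggregation are
provided as modes but the defaults (symmetric error, unweighted slice
mean) are used throughout the reported checks. Desk-scale problem sizes
(64³ phantoms, depth-18/width-8 generator, 30-epoch runs, 2000-point ICP
subsets) were chosen so the full suite runs comfortably on one CPU; all
are configuration, not architecture.
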