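# midfacer

Virtual reconstruction of bony midfacial defects with a conditional GAN,
end to end in R: synthetic skull phantoms with five labelled midfacial
subunits, parametric artificial defect carving on CT-like volumes,
per-slice adversarial inpainting, mirror-symmetry reference surfaces, and
quantitative accuracy evaluation with Mann–Whitney group comparison.

## Who this is for

Researchers in craniomaxillofacial virtual surgical planning who want a
fully reproducible, dependency-light testbed for GAN-based defect
inpainting pipelines — every stage from DICOM I/O to the statistics table
runs on procedurally generated phantoms, so no patient data is required
to develop or validate the machinery.

## The method

The bony midface is divided into five subunit regions (I frontal
sinus–frontal bone, II naso-orbital-ethmoid, III infraorbital
margin–maxillary sinus, IV zygomatic complex, V residual maxilla).
Artificial defects — spheres, cuboids, semi-cylinders — are carved out of
bone within a subunit, giving aligned (normal, defect, mask) slice
triples. A conditional GAN is trained on them:

* generator **G(x, z)**: residual encoder (depth 18/34/101 presets) +
  upsampling decoder; inputs are the defect slice *x*, the defect mask
  and a broadcast noise channel *z*; output is the inpainted slice,
* discriminator **D(x, y)**: 3 convolution layers (kernel 3, batch norm,
  leaky ReLU) scoring the conditional pair,
* loss: non-saturating adversarial + 100·L1 (pix2pix convention), Adam
  with learning rate 0.002.

Reconstruction accuracy is measured per case by

* **cosine similarity** `a·b / (‖a‖‖b‖)` between the reconstructed and
  normal 8-bit slice images, averaged over mask-intersecting slices, and
* **mean surface error (mm)**: symmetric mean point-to-triangle distance
  between the reconstructed and reference bone surfaces (marching
  tetrahedra at 0.5 on the 300 HU bone mask) after point-to-plane rigid
  ICP.

For unilateral defects the reference is **mirror technology**: least
squares plane through midsagittal landmarks, reflection of the bone
surface, ICP refinement restricted to intact regions. Group accuracy
(artificial vs clinical defects) is compared with the Mann–Whitney U
test; results render as per-subunit and per-case tables.

## Worked example

```r
library(midfacer)

# a 64^3 phantom with labelled subunits and midsagittal landmarks
ph <- generate_head_phantom(head_phantom_config(grid = c(64, 64, 64)))
bone <- segment_bone(ph$volume, threshold = 300)

# carve a seeded defect in subunit III and build training slices
spec <- sample_defect_spec(ph, subunit = 3, size_bounds = c(10, 20), seed = 7)
cd <- carve_defect(ph$volume, bone, spec)
pairs <- make_slice_pairs(ph$volume, cd$volume, cd$mask, case_id = "demo")
length(pairs)   # one pair per mask-intersecting slice: 14

# train a small inpainting GAN and reconstruct the defect volume
fit <- train_gan(pairs, gan_config(epochs = 10, batch_size = 4, seed = 1))
print(fit)
#> <gan_fit> depth-18 generator, 10 epochs
#>   final losses: D 0.9914, G 10.1651 (adv 0.9452, L1 0.0922)
recon <- predict(fit, cd$volume, mask3d = cd$mask)

# evaluate against the known truth
ev <- evaluate_reconstruction(ph$volume, recon, cd$mask)
print(ev)
#> <similarity_result> case (artificial): cosine 0.9989, mean error 0.0000 mm
```

The cosine similarity is the per-slice image agreement (1 = identical
direction); the mean error is the registered bone-surface deviation in mm
(0 = surfaces coincide — here the inpainted intensities cross the 300 HU
bone threshold exactly where the true bone does, so the extracted
surfaces match; on harder defects this is a fraction of a millimetre).
A mirror-technology reference for the same phantom:

```r
surf <- extract_surface(bone)
mir  <- mirror_reference(surf, ph$landmarks, refine = FALSE)
mean_surface_error(mir, surf)   # 0.008 mm: the phantom is symmetric
```

The published per-case accuracy table for 15 unilateral clinical
reconstructions ships with the package and aggregates to its printed
averages:

```r
t2 <- render_tables(case_results = clinical_cases())$table2
tail(t2, 1)
#>    case cause cosine_similarity mean_error_mm
#> 16 average   -              0.96          0.48
```

## Command-line interface

A thin CLI over the package functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/midface-recon", package="midfacer"))') \
    report --cases cases.csv --out report/
```

Subcommands: `train` (slice-pair directory → checkpoint), `reconstruct`
(DICOM defect volume + mask → DICOM), `report` (per-case CSV → table1/
table2 CSV + stats.json).

## Package layout

* `R/volume.R`, `R/dicom.R` — volume container, minimal axial-CT DICOM
  codec, 8-bit windowing, dataset splitting
* `R/phantom.R` — head-phantom generator (subunits, landmarks, asymmetry)
* `R/defect.R`, `R/augment.R` — defect carving, slice pairs, training
  augmentation
* `R/nn.R`, `R/gan.R`, `src/conv_ops.cpp` — conv-net engine with
  hand-written backprop, GAN training/reconstruction
* `R/mesh.R`, `R/register.R`, `src/mesh_ops.cpp` — marching tetrahedra,
  STL/PLY, point-to-plane ICP
* `R/metrics.R`, `R/stats.R`, `R/report.R` — accuracy metrics, mirror
  reference, Mann–Whitney, tables

See `vignettes/midface-reconstruction.Rmd` for the full methods account:
model assumptions, parameter defaults, numerical choices and limitations.
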