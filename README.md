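# monorient

Orientation of sub-diffraction, fluorescently double-tagged collagen
monomers from epifluorescence images.

## The problem

Collagen's molecular unit is a ~300 nm × 1.5 nm triple helix. Tagged with
one or two AF488 fluorophores it can be located under an epifluorescence
microscope, but it is smaller than the diffraction limit: a single tag
images as an Airy spot of diameter `1.22 λ / NA ≈ 446 nm` (530 nm emission,
NA 1.45), and a double-tagged monomer images as two such spots 150–300 nm
apart — unresolved, so the image is approximately an ellipse whose major
axis is the monomer's orientation. Estimating that axis non-destructively,
frame by frame, is what this package is for; it matters because how free
monomers orient while docking onto growing collagen fibrils is an open
question in fibrillogenesis.

`monorient` provides:

* **`photon_budget()`** — a radiometric chain from LED radiance through
  filter passbands, absorption cross-section, quantum yield/lifetime
  saturation (`PER = (Ω/4π)·φ·(1/γ + t_fl)⁻¹`), collection solid angle
  (`Ω = 2π(1 − √(1 − NA²/n²))`), emission filters and camera QE to detected
  electrons per fluorophore and background electrons per pixel.
* **`generate_dataset()`** — a simulator rendering one monomer per
  25×25-pixel patch (107.5 nm/px) on a 10× supersampled grid with an Airy
  PSF, mean background, Poisson shot noise and read noise; labels are 12
  axial 15° orientation bins plus a single-tag class (13 classes).
* **`classify_gabor()` / `classify_dataset_gabor()`** — a 175-count /
  7-pixel area gate separating single from double tags, denoising, and a
  12-orientation wavelength-5 complex Gabor bank whose feature-magnitude
  maximum gives the orientation through the perpendicular convention.
* **`cnn_build()` / `cnn_train()` / `cnn_predict()`** — a two-convolutional-
  layer softmax-13 network (54,141 parameters, categorical cross-entropy,
  Adam, batch 32, 3 epochs, 70/30 split), implemented in compiled C++ and
  trained purely on simulated data.
* **Evaluation tools** — confusion matrices, accuracy and per-class recall,
  adjacent-bin error, sequential-frame orientation dispersion (naive and
  axial), photobleaching drift, track building from TIFF stacks, and
  report rendering.

## A worked example

```r
library(monorient)

photon_budget()
#> Photon budget
#>   solid angle           3.9656 sr
#>   absorbed photon rate  2110 photons/s
#>   collected emission    612.5 photons/s
#>   signal electrons      1063 e-/fluorophore
#>   background/pixel      100.3 e- (scatter 1.81e-10, dark 0.25, extra 100)
```

The chain collects 3.97 sr of the emission sphere, absorbs 2110 photons/s
per fluorophore, and detects ~1063 signal electrons per 5-s exposure over a
~100-electron background whose scatter-leakage component is negligible
(the emission path blocks the excitation wavelengths by ~20 orders of
magnitude across its two elements).

```r
ds <- generate_dataset(1300, sim_config(), seed = 1)   # balanced 13 classes
gab <- classify_dataset_gabor(ds)
cm_accuracy(confusion_matrix(ds$labels, gab$label))$accuracy
#> [1] 0.9730769

r <- classify_gabor(get_image(ds, 4))
r
#> <orientation_result: label 6, orientation 0.0 deg, gate double>
ds$labels[4]
#> [1] 6
```

The training-free Gabor pipeline classifies 97.3% of this corpus correctly;
image 4 is a double-tagged monomer whose reported orientation, 0° (bin 6),
matches its ground truth. The CNN, by contrast, needs its full training
protocol before it is competitive:

```r
model <- cnn_train(ds, training_config(n_samples = 1300, seed = 1))
model
#> <cnn_model: 25x25 input, 2 conv layers, 13 classes, 54141 parameters, trained>
val <- generate_dataset(650, sim_config(), seed = 2)
mean(cnn_predict(model, val)$labels == val$labels)
#> [1] 0.2261538
```

Three epochs over 910 training images are nowhere near enough (22.6%);
the full 26,000-sample protocol below reaches ~87–91% held-out accuracy.

A thin command-line wrapper over the same functions lives at
`inst/cli/monorient.R` (subcommands `simulate`, `budget`, `train`,
`classify`, `evaluate`, `track`).

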