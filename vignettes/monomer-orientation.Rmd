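---
title: "Simulating and classifying the orientation of double-tagged collagen monomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and classifying the orientation of double-tagged collagen monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monorient)
```

## The problem

A collagen monomer is a triple-helical molecule about 300 nm long and 1.5 nm
in diameter. Labeled with one or two fluorophores, it can be located by
epifluorescence microscopy, but it is far smaller than the diffraction
limit: a single tag images as an Airy spot of about 450 nm, and a
double-tagged monomer images as the incoherent sum of two such spots
separated by 150–300 nm — less than the resolution. The resulting blob is
approximately an ellipse whose major axis carries the monomer's axial
orientation. `monorient` simulates these images from radiometric first
principles and classifies them into twelve 15° orientation bins plus a
13th "single-tag" class, with two independent classifiers: a Gabor filter
bank and a compact convolutional network trained purely on simulated data.

Orientations are axial angles in degrees on $[-90, 90)$, measured
counter-clockwise from the horizontal image axis; $-90°$ and $+90°$ denote
the same physical axis, which matters for binning and for dispersion
statistics.

## The photon budget

The simulator's count scale is anchored in an explicit radiometric chain
(`photon_budget()`):

1. **Source and excitation path.** The LED radiance spectrum is multiplied
   by the excitation-filter transmission and the dichroic reflection, then
   converted to photon spectral irradiance with the photon energy
   $hc/\lambda$ and the collection solid angle
   $\Omega = 2\pi\left(1-\sqrt{1-\mathrm{NA}^2/n^2}\right)$
   (3.97 sr for NA 1.45 in $n = 1.56$ glass).
2. **Absorption.** The absorbed-photon rate is
   $\gamma = \sigma_{\mathrm{abs}} \int E_\lambda \, d\lambda$ with
   $\sigma_{\mathrm{abs}} = 1.212\times10^{-20}\,\mathrm{m^2}$ for AF488.
3. **Emission.** The collected emission rate uses the saturation-corrected
   form $\mathrm{PER} = \frac{\Omega}{4\pi}\,\phi\,(1/\gamma + t_{fl})^{-1}$,
   which reduces to $\frac{\Omega}{4\pi}\phi\gamma$ far from saturation and
   plateaus at the lifetime limit. (The alternative $(1/\gamma -
   t_{fl})^{-1}$ reading of this formula is exposed as the
   `saturation_form` switch; the default is the physically bounded form.)
4. **Detection.** Signal electrons are
   $N_e = t_{\mathrm{exp}} \int \mathrm{PER}\cdot S_{em}(\lambda)\,
   T_{em} T_{dich} \mathrm{QE} \, d\lambda$. Background electrons per pixel
   sum a scatter-leakage chain (the large elastic scattering cross-section
   $1.1\times10^{-13}\,\mathrm{m^2}$ at the *source* wavelength, blocked by
   the out-of-band floor of the emission path), dark current, and a
   configurable extra term for out-of-focus fluorophores and
   autofluorescence.

Manufacturer spectra are not tabulated in public sources, so the defaults
are honest parametric models, all replaceable by tabulated CSV curves:
Gaussian LED radiance centered at 470 nm (FWHM 25 nm, peak
1000 W m⁻² sr⁻¹ nm⁻¹), ideal top-hat passbands (465–495 nm excitation,
515–555 nm emission) with a flat $10^{-10}$ blocked-side floor per element,
flat QE 0.6 over 450–650 nm, and a skewed-Gaussian AF488 emission spectrum
peaked at 520 nm. Quantum yield 0.92 and lifetime 4.1 ns are documented
typical AF488 values. Spectral integrals use the trapezoid rule on a 1-nm
grid; $h$ and $c$ are CODATA constants. Under these defaults the chain
yields 1062.97 signal electrons per fluorophore per 5-s exposure, frozen as
a regression value and cross-checked in the test suite against an
independent trapezoid oracle to $10^{-6}$ relative tolerance.

Because the absolute LED radiance is the one genuinely unknowable input,
the simulator takes a direct `signal_electrons` override rather than
forcing every user through the chain. Its default is 2000 electrons per
fluorophore, chosen so that the peak background-subtracted pixel of a
single tag (~510 counts) sits comfortably above the 175-count detection
threshold and the 7-pixel area gate behaves as designed: singles put about
5 pixels above threshold, doubles 7 or more. This calibration was fixed
before any classifier accuracy was measured and not revisited afterwards
(see *Known limitations*).

## The image simulator

`generate_dataset()` renders one monomer per 25 × 25-pixel patch
(107.5 nm/pixel — the 6.45-µm camera pitch demagnified by 60×) on a grid
supersampled 10×. Tags are unit impulses convolved with a unit-sum Airy
kernel (first dark ring 445.9 nm from $1.22\lambda/\mathrm{NA}$ at 530 nm,
truncated at the third dark ring; a Gaussian switch exists for speed),
bin-summed to camera resolution, offset by the mean background
(100 e⁻/pixel by default), Poisson-corrupted per pixel, and optionally
given rounded Gaussian read noise (6 e⁻ RMS). Stored counts have the mean
background subtracted and clipped at zero — exactly what the classifiers
see — while raw frames are retained. The 25-pixel field with the monomer
anchored in its central third holds the full truncated PSF support around
any admissible tag pair, keeping expected-electron conservation losses
under 1%.

Double-tag separations are uniform on 150–300 nm. Orientations are drawn
on the 15° grid $\{-90, -75, \dots, 75\}$ in the default `"discrete"` mode;
the 13 grid values collapse to 12 classes by identifying $-90°$ with
$+90°$. A `"continuous"` mode draws uniformly within each bin for
robustness studies. Datasets are pure functions of `(config, seed)`.

What the simulator deliberately does **not** emulate: out-of-focus
emitters, autofluorescence texture (only a flat mean background),
photobleaching kinetics, multiple interacting monomers per frame, and
polarization/vectorial PSF effects. Tests passing on these synthetic data
therefore certify the algorithms under shot-noise-limited, single-monomer
conditions — not performance on arbitrary experimental frames.

## The Gabor classifier

`classify_gabor()` runs three stages:

1. **Area gate.** Pixels above 175 counts (applied to the pre-denoise,
   background-subtracted image, keeping the threshold in physical electron
   units) form the candidate mask: an empty mask is "no monomer detected",
   fewer than 7 pixels is the single-tag class, otherwise the image
   proceeds to the filter bank. The gate exists because a single tag's
   circularly symmetric spot would otherwise hand the bank an essentially
   random orientation.
2. **Denoising.** The reference method for this stage is collaborative
   block-matching 3D transform-domain filtering; the backend is pluggable
   and this package's default is an edge-renormalized Gaussian of
   $\sigma = 1$ px (flat regions are fixed points). The backend actually
   used is recorded in every result.
3. **Filter bank.** Twelve complex Gabor filters at 15° steps, carrier
   wavelength 5 px. Parameters the method leaves open are set by standard
   conventions: $\sigma = 0.56\lambda$ (one-octave bandwidth), aspect
   ratio 0.5, phase 0, kernel size $\approx 4\sigma$ (11 px). The feature
   is the magnitude of the same-size cross-correlation; the reported
   orientation is the bank orientation of the global feature maximum plus
   90°, wrapped to $[-90, 90)$ — an unresolved elongated spot is *narrow*
   across its long axis, so the filter whose wave vector is perpendicular
   to that axis responds most. Ties break deterministically to the lowest
   bank angle.

## The CNN classifier

`cnn_build()` defines conv(8 @ 3×3) + ReLU + 2×2 max-pool,
conv(48 @ 3×3) + ReLU, flatten, dense softmax over 13 classes — exactly two
convolutional layers with categorical cross-entropy, 54,141 parameters
(reported in the architecture descriptor; the parameter budget, not
accuracy, fixed the filter counts, which is why the second pooling stage
was dropped in favour of a wide dense layer). Inputs are standardized per
image to zero mean and unit variance. `cnn_train()` splits the corpus
70/30, shuffles minibatches of 32, and runs 3 epochs of Adam at the
conventional $10^{-3}$ rate; initialization, split and shuffles all derive
from the config seed, so training is bit-reproducible. The forward and
backward passes are implemented in compiled C++ — the network is small
enough that explicit loops train the full 26,000-sample protocol in under
a minute on one CPU. Validation sets are always generated with a seed
disjoint from the training seed.

## Evaluation machinery

`confusion_matrix()` (truth × prediction over the 13 classes, with an
extra column for missed detections), `cm_accuracy()` (normalized trace and
per-class recall, with and without the single-tag class),
`adjacent_bin_error()` (fraction of misclassified double-tag samples whose
prediction is an axial neighbour of the truth; predictions of "single"
count as non-adjacent errors), `orientation_dispersion()` (per-track
standard deviation over double-tag frames, reported both as the naive
linear SD and as the axial circular SD — angles doubled, circular mean,
residuals wrapped to $(-90, 90]$, linear SD — because the naive form
explodes across the ±90° wrap: the two-point track $\{+85°, -85°\}$ has
naive SD 120.2° but axial SD $10/\sqrt{2} \approx 7.07°$), and
`photobleach_drift()` (mean and SD of pixelwise consecutive-frame
differences; for pure shot noise the SD is $\sqrt{2\times\text{rate}}$).
`track_monomers()` links above-threshold connected components across
frames by nearest centroid within 3 pixels — a rule this package had to
choose, as the method's description does not give one — and classifies a
25-pixel patch per detection with either classifier.

## Numerical and design choices

* 0-based (row, col) pixel geometry, origin top-left, angles
  counter-clockwise positive; R matrices handed to users remain 1-based.
* Airy kernel truncated at the third dark ring and renormalized to unit
  sum; supersample factor 10.
* The 175-count gate threshold applies to background-subtracted counts
  (the subtraction is a constant shift, so this is a pure convention, but
  it keeps the threshold in the same units as the stored images).
* Poisson noise is applied to the full expected image including the mean
  background; the subtraction happens afterwards, so background shot noise
  survives in the stored counts, as it should.
* Class histogram of a generated corpus is uniform within rounding; the
  single-tag class is one of the 13.
* `read_frames()` accepts 8/16-bit grayscale TIFF stacks and rejects color
  or float samples; counts above 65,535 are rejected at write.
* Degenerate inputs: empty gate masks return a distinct "none" outcome;
  dispersion with fewer than two double-tag frames and adjacent-bin error
  with zero errors return NA with an explanatory attribute flag.

## Problem sizes used by the test suite

The shipped tests exercise the full protocol: a 26,000-sample training
corpus (70/30 split, batch 32, 3 epochs), a disjoint 6,500-sample balanced
validation set, 10,000-draw sampling-law checks, and 1,000-replicate
Monte-Carlo convergence checks — the corpus sizes of the underlying study,
which run in about two minutes total here. Unit properties use smaller
fixtures (13–650 samples) chosen to keep each check sharp.

## Known limitations

* With the gate-calibrated default signal level (2000 e⁻/fluorophore), the
  Gabor pipeline reaches ~98% accuracy on the default validation set and
  thereby *outperforms* the CNN (~87–91%), whose accuracy matches the
  headline figure usually quoted for this protocol. Sweeping the signal
  shows the Gabor pipeline is a steep function of SNR (≈7% at 400 e⁻, ≈70%
  at 700 e⁻, ≥97% from 1000 e⁻ up); accuracies near 55% occur only at
  signal levels where the printed 175-count/7-pixel gate semantics
  simultaneously degenerate. The defaults were frozen from the gate
  calibration alone and deliberately not re-tuned toward any published
  accuracy; consequently the package reproduces the CNN operating point
  and the mechanistic gate behaviour, but not a mid-50s Gabor accuracy.
* At the default SNR the few remaining Gabor errors are mostly
  150-nm-separation doubles gated as singles, so "errors sit one bin off
  the diagonal" holds in the noisier regimes (demonstrated at a
  700-electron fixture in the tests) rather than at the defaults.
* The CNN agrees with the second-moment oracle on noiseless 300-nm
  fixtures at roughly its overall skill (~90%), not above it.
* Absolute radiometry depends on manufacturer curves modeled
  parametrically here; replace the spectra with tabulated CSVs for
  quantitative radiometric work.
* Sequential-frame dispersion and photobleaching numbers from real
  monomer recordings require the original frames, which are not
  distributed; those operations are instead validated against closed-form
  oracles.

## A worked example

```{r example, eval = FALSE}
library(monorient)

# photon budget under the default configuration
photon_budget()

# a labeled corpus and the two classifiers
ds <- generate_dataset(1300, sim_config(), seed = 1)
gab <- classify_dataset_gabor(ds)
cm <- confusion_matrix(ds$labels, gab$label)
cm_accuracy(cm)$accuracy

model <- cnn_train(ds, training_config(n_samples = 1300, seed = 1))
val <- generate_dataset(650, sim_config(), seed = 2)
mean(cnn_predict(model, val)$labels == val$labels)
```

The README shows this example with the numbers it prints; the
`scripts/acceptance.R` entry point reruns the full 26,000/6,500-sample
protocol from scratch.
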