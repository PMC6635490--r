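---
title: "Voxel-level internal dosimetry: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level internal dosimetry: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxdose)
```

# The problem

Internal dosimetry estimates the radiation absorbed dose (Gy = J/kg)
delivered to tissue by a radionuclide administered inside the body. For a
positron emitter such as ⁶⁸Ga imaged by quantitative PET/CT, three voxel
dose-rate estimators of increasing fidelity are in use:

1. **Voxel S-value (VSV) kernel convolution** — the dose to voxel $j$ per
   unit time-integrated activity in voxel $i$, tabulated once in a uniform
   water medium and applied by 3D convolution:
   $$D_j = \sum_i \tilde A_i \, \mathrm{VSV}(j \leftarrow i).$$
   Fast, but blind to tissue heterogeneity: the same water kernel is used
   inside lung (ρ ≈ 0.26 g/cm³), bone and air cavities.
2. **Direct Monte Carlo** — stochastic particle transport through the
   patient-specific voxelized density map. The accuracy reference, but
   orders of magnitude slower.
3. **A learned estimator** — a 3D U-net that maps co-registered PET and CT
   patches to the Monte-Carlo dose-rate patch, recovering most of the
   heterogeneity correction at convolution-like speed.

`voxdose` implements all three, plus the synthetic phantoms, patch
machinery, time integration and error statistics needed to exercise them
end to end without patient data.

# Synthetic phantoms

Phantoms are lists of geometric primitives (ellipsoids/cuboids) with a
material tag, a uniform activity concentration (Bq/mL, the PET image
semantic) and an effective clearance half-time. Voxels are assigned
wholly to the last-listed covering organ — the same convention a
voxelized-phantom import uses — so labels, CT numbers and densities are
exactly consistent by construction. The material table is deliberately
small and auditable (air, lung, adipose, soft tissue, bone); CT-to-density
conversion is the piecewise-linear interpolation through those five
nominal (HU, ρ) points, with soft tissue pinned to 1.000 g/cm³ at HU 0 so
water defines the scale. Real CT calibration curves have more segments;
five classes are enough to drive the density-dependent physics that
matters here (lung/bone/air contrast).

Dynamic behaviour is mono-exponential per organ
($C(t) = C_0\,2^{-t/T_\mathrm{eff}}$), with the background following the
physical half-life (67.71 min for ⁶⁸Ga). The default frame schedule is
the eight-point dynamic acquisition at 1, 4, 7, 10, 15, 30, 46, 62 min.

The `demo_phantom_spec("torso")` preset emulates a thorax: a soft-tissue
body containing two large lungs (a real chest is roughly a third lung by
volume), a high-uptake liver-like organ, a heart and a spine block, with
organ centres and uptakes jittered by the seed so different seeds give
structurally similar but distinct subjects. What these phantoms do *not*
model: PET image formation (noise, partial volume, reconstruction
artifacts such as the bladder hot-spot streaks seen clinically), realistic
organ shapes, intra-organ uptake texture, or respiratory motion. Passing
tests on these phantoms therefore demonstrates the *mechanics and physics
plumbing* of the three estimators, not clinical accuracy.

# The Monte Carlo engine

The engine (`simulate_dose`) is a deliberately simplified voxel transport
code — the desk-scale stand-in for a full Geant4/GATE "dose actor":

* **Decay sampling.** Per-voxel multinomial over the activity
  distribution, emission point uniform within the voxel. Implemented as
  sequential conditional binomials (the exact multinomial), with a
  seeded 64-bit Mersenne Twister: a fixed seed gives bit-identical
  tallies.
* **Positrons.** Deposited locally in the source voxel. The ⁶⁸Ga mean
  positron range in tissue (~mm) is below the 2.67–5 mm voxel size, so
  local deposition is the engine's chief — and quantitatively mild —
  simplification. This is also why the VSV kernel's central voxel
  dominates.
* **Photons.** Two back-to-back 0.511 MeV annihilation photons per
  positron plus the 1.077 MeV gamma (3.2% yield). Woodcock (delta)
  tracking across the grid avoids per-voxel boundary arithmetic; the
  majorant is the maximum-density water attenuation at the current
  energy. Compton scattering is sampled from the Klein–Nishina
  distribution (the standard composition–rejection sampler), and the
  Compton cross-section used for flight sampling is the *analytic*
  Klein–Nishina total, so sampler and cross-section cannot disagree.
  Photoelectric absorption uses an embedded NIST XCOM water table
  (log–log interpolated). No coherent scattering, no element-wise
  composition — all media are density-scaled water. Photons below 10 keV
  deposit locally.
* **Tally.** Energy per voxel per batch (default 10 batches), converted
  to Gy with the voxel mass; relative uncertainty is the batch-mean
  standard error. Energy deposited into a zero-density voxel is re-routed
  to the last voxel with mass along the track. The tally satisfies
  deposited + escaped = emitted to floating precision, and in a
  quasi-infinite water phantom the deposited/emitted ratio exceeds 0.995
  at 10⁶ histories (an acceptance check).

Out of scope by design: electron transport, coherent scattering,
composition-dependent cross-sections, variance reduction.

# The VSV kernel and its failure mode

`generate_vsv_kernel` runs the same engine with a single-voxel source at
the centre of uniform water (kernel extent plus a margin for
backscatter) and normalizes to Gy per MBq·s. The default kernel matrix is
49×49×25 — the odd-sized analogue of the 48×48×24 patch geometry, since a
convolution kernel needs a central voxel; the source study never states
its kernel matrix size, only that it shares the PET voxel size. A kernel
that captures less than 95% of the non-escaping energy triggers a warning
to enlarge it.

Convolution (`convolve_vsv`) zero-pads outside the volume (no activity
outside the body) and runs in the Fourier domain above a size threshold,
by direct summation below; both routes agree with a brute-force double
sum to 10⁻¹⁰ relative (acceptance check). The per-frame reading
`vsv_dose_rate` treats an activity frame (MBq per voxel) as MBq·s per
second, yielding Gy/s.

Because the kernel assumes water everywhere, dose in lung is
underestimated by roughly the density ratio: deposited energy per unit
mass scales as 1/ρ for the locally dominated part, so lung
(ρ = 0.26 g/cm³) receives ~3.8× the water-kernel prediction. The
acceptance suite checks both sides of this coin: agreement with Monte
Carlo within 5% in uniform water, and a lung-label error at least 5× the
soft-tissue error (with the correct underestimation sign) on a thorax
phantom.

`density_corrected_dose_rate` applies exactly this first-order 1/ρ
correction to the convolution output. It serves as the fast, noise-free
"kernel-generated" ground-truth surrogate for network training
experiments — the same role the literature assigns to multi-kernel VSV
labels as a cheaper alternative to Monte Carlo ground truth. It is a
surrogate: it inherits the water kernel's spatial spread and corrects
only the local mass scaling, which is the dominant but not the only
heterogeneity effect.

# Patch pipeline

Training patches of 48×48×24 voxels are enumerated at fixed offsets
(7 transverse, 5 axial), in lexicographic corner order with 0-based
inclusive-start coordinates; patches with less than 1/8 of their voxels
inside the body mask are excluded. "Body" is defined by CT thresholding
at −900 HU (between air and inflated lung, so lungs are body) plus
largest connected component. On the full 256×256×165 grid this grid
yields 26,100 candidate positions; the per-image budget of 5,000 is a
seeded uniform subsample, and 8 subjects × 8 frames × 5,000 patches
reproduces the 320,000-patch training-set bookkeeping (acceptance
checks). Overlapping predictions are reassembled by uniform averaging per
covering patch; a coverage map is emitted and uncovered body voxels are
reported. At inference the enumeration is augmented with flush patches at
the far boundaries so the whole volume is covered — the training-data
description fixes only the offsets, so inference stride is a free choice.

# The dose-prediction U-net

The network maps 2-channel (PET, CT) patches to 1-channel dose-rate
patches. Contracting path: per level one 3×3×3 convolution + batch
normalization + ReLU, then 2×2×2 max pooling; features start at
`base_features` (reference value 14) and double per level. Expanding
path: stride-2 2×2×2 transposed convolution + ReLU, skip concatenation,
3×3×3 convolution + ReLU; batch normalization is used in the contracting
path only (a literal reading of the architecture description, and
configurable). A final 1×1×1 linear convolution produces the output.
Design points left open by the source description, fixed here with
documented defaults: number of levels (4; three poolings exhaust the
axial factor of 24), learning rate (ADAM, 10⁻³), He weight
initialization, and input/target normalization (PET divided by the
training set's 99.9th percentile, CT mapped HU/1000, dose-rate targets
divided by their 99.9th percentile; all three constants persist with the
model). Normalization is required because un-normalized Gy/s spans
decades; the constants-ride-with-the-model rule makes prediction
self-contained.

Everything — forward, backward, ADAM, L1 loss — is implemented in this
package (Rcpp kernels for the convolution/pooling primitives), and the
backward pass is verified against numeric differentiation in the test
suite. Training is seed-deterministic: shuffling and initialization use
isolated RNG streams, so a fixed seed reproduces the loss history
bit-for-bit.

The desk-scale training profile used by the tests and the acceptance
script is the package's own choice: 32×32×16 phantoms, 16×16×8 patches at
offsets 3/3/2 capped at 170 per image (510 patches from three training
subjects), base 8 / depth 3 (~40k parameters), batch 16, 24 epochs. On a
held-out thorax phantom with kernel-surrogate ground truth this small
network reaches a lower whole-body mean voxel error than the water-kernel
baseline, with the margin concentrated in the lung — the direction, not
the magnitude, of the full-scale result it mirrors. Five-fold
cross-validation (`crossvalidate_unet`) partitions subjects into equal
seeded test folds (8 train / 2 test at ten subjects; leave-one-out when
k equals the subject count).

# Absorbed dose and reporting

`integrate_series` integrates dose-rate frames per voxel: trapezoid from
the first to the last frame, the first-frame rate held constant back to
t = 0 (alternative: zero head), and an analytic exponential tail
$R_\mathrm{last}/\lambda$ after the last frame. The default tail constant
is physical ⁶⁸Ga decay — the conservative standard when kinetics beyond
the last frame are unknown — and is configurable. Sampled at the
eight-frame schedule, a pure-exponential rate integrates to within 3% of
the closed form $r_0/\lambda$ (acceptance check).

Organ doses are mass-weighted means over the label volume; the
reference-mass correction rescales by patient mass over the ORNL stylized
adult phantom mass (packaged, editable table). The published description
does not print the correction's direction; the implemented reading
(patient/reference) is labelled and swappable (`correction = "none"`).

Voxel-level error is $\overline{|m - r|/r}\times 100$ over mask voxels
whose reference exceeds 0.1% of the reference maximum (the ratio is
unstable at near-zero dose; the floor is reported with every metric).
The statistic is deliberately asymmetric — the reference is always the
Monte Carlo map. Organ-level differences average per organ across
subjects, with the cross-organ mean reported both with and without a
named outlier organ (conventionally the pancreas, whose near-zero
reference dose makes its percentage error explode in organ-based
dosimetry). Paired two-sided t-tests with Bonferroni-adjusted thresholds
(α/m) flag significance; zero-variance differences return a degenerate
status rather than a fabricated p-value.

# Numerical and engineering notes

* Grid equality (dims + voxel size to 10⁻⁶ mm) is checked on every
  multi-volume operation; volumes carry mandatory unit tags, and a
  dose/activity volume without units cannot be read back in.
* Voxel-size mismatch between kernel and map is a hard error — no silent
  resampling. Explicit resampling (`resample_to`) uses trilinear
  interpolation for continuous volumes and nearest-neighbour for labels.
* FFT convolution results are clipped at zero (round-off can produce
  ~−10⁻¹⁸ values) and agree with direct summation to 10⁻¹⁰ relative.
* Monte-Carlo problem sizes in the tests (10⁶–6×10⁶ histories,
  24³–48³ grids) were chosen so each check completes in seconds on one
  core while leaving per-voxel noise well inside the asserted tolerances;
  the uncertainty machinery (batch SE, 1/√n scaling) is itself under
  test.
* The synthetic study conditions (organ activities ~300–2500 Bq/mL,
  clearance half-times 40–70 min, eight-frame schedule) were fixed once
  from typical ⁶⁸Ga-peptide uptake patterns and are not tuned per test.

# Known limitations

* Density-scaled water physics: no composition effects, so bone dose is
  approximate at the few-percent level typical of that simplification.
* Local positron deposition slightly sharpens dose gradients at organ
  boundaries relative to explicit electron transport.
* The kernel-surrogate ground truth corrects only local mass scaling;
  networks trained on it learn that correction, not full transport.
* Phantoms are geometric; conclusions about clinical PET/CT data require
  the full-scale study this package mirrors at desk scale.
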