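---
title: "Masked classification with residual signal subtraction: models and methods"
author: "cryofocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked classification with residual signal subtraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-particle cryo-EM data sets of flexible complexes are mixtures: a
small part of the molecule (a transmembrane helix, a peripheral subunit)
adopts several conformations while the bulk is rigid.  A consensus 3D
refinement against one reference averages the mixture away and leaves
fuzzy density in the variable region.  Conventional multi-reference
classification struggles to separate such states because the signal that
differs between them is a tiny fraction of the total particle signal,
while all of the noise — and all of the signal from the invariant bulk
that is misassigned by the reference mask — still enters the class
assignment.

`cryofocus` implements the two-step remedy this package is built around:

1. **Residual signal subtraction.**  After a consensus refinement has
   fixed each particle's orientation `(rot, tilt, psi)`, in-plane offsets
   and CTF, the part of the consensus map *outside* the region of
   interest (`V1`) is projected at each particle's orientation, multiplied
   by its CTF, shifted to the particle frame, and subtracted from the
   particle image:

   `D_i'  =  D_i − CTF_i · P_{r_i}(V1)`

   What remains is, up to noise, the CTF-affected projection of the
   region of interest (`V2`) alone.

2. **Masked classification without alignment.**  The subtracted images
   are classified against K references that are multiplied by a soft mask
   around the region of interest, with orientations held fixed at the
   consensus values (no alignment search).  Only the focus region drives
   the class assignment; the subtracted bulk no longer acts as an
   additional noise source.

## The statistical model

Classification is maximum-likelihood with a shell-wise Gaussian noise
model in Fourier space.  For particle `i` and class `k`,

```
ln L_ik = − Σ_f |D_i(f) − CTF_i(f) · P_{r_i}(V_k)(f)|² / (2 σ²(ν(f)))
          − Σ_s (m_s / 2) ln(2 π σ²_s)
```

summed over Fourier components up to the classification resolution limit
(`m_s` components in shell `s`).  Responsibilities are the softmax of
`ln π_k + ln L_ik` over classes.  Expectation-maximization updates, in
order: the responsibilities (E-step); then the noise spectrum `σ²(ν)`
from the responsibility-weighted residuals, the class fractions `π_k`,
and the references `V_k` by responsibility-weighted direct Fourier
reconstruction followed by re-application of the focus mask (M-step).
Each update is a coordinate-ascent step on the expected complete-data
log-likelihood at the point where it is applied, so the per-iteration
mean log-evidence recorded in the run history is non-decreasing up to the
approximations discussed below.

Assumptions worth stating: noise is independent between particles and
Fourier components, with a variance that depends only on frequency
magnitude (colored but isotropic); orientations, offsets and CTFs from
the consensus refinement are treated as exact; and the mixture is over a
finite set of discrete states.

## Projection, reconstruction and their numerical choices

The projector extracts a central slice from the 2×-oversampled
(zero-padded) 3D Fourier transform of the reference by trilinear
interpolation (Fourier-slice theorem), applies the in-plane offsets as
phase shifts, and multiplies by the CTF.  Image frequencies outside the
Nyquist ball (radius `N/2 − 1` pixels) are zeroed so every interpolation
cell stays inside the padded cube.

Two deliberate choices differ from some other implementations:

* **No gridding pre-correction in the projector.**  With trilinear
  interpolation at pad factor 2, dividing the real-space map by the
  kernel transform (`sinc²`) before projection improves off-lattice
  accuracy but destroys the exactness of on-lattice orientations.  We
  keep the projector uncorrected: at the identity orientation the
  projection equals the z-axis voxel sum to rounding, mass is conserved,
  and the backprojector is the exact adjoint.  For band-limited maps
  (Gaussian blobs of σ ≥ 1.5 px; realistic density maps are band-limited)
  the off-lattice error is 1–2 % RMS, which the test suite checks against
  exact-rotation oracles.

* **Gridding correction on the reconstruction side only — and only for
  human-facing maps.**  `reconstruct()` divides the final map by the
  trilinear-kernel transform to undo the spreading blur
  (`grid_correct = TRUE`, the default).  Inside the EM loop the
  references skip this division (`grid_correct = FALSE`): the classifier
  compares data to *projections of the reconstruction*, and projecting an
  uncorrected reconstruction reproduces the accumulated slices
  self-consistently.  Correcting inside the loop systematically sharpens
  the model relative to the data and degrades both the likelihood and
  the classification.

Reconstruction itself is Wiener-style direct Fourier inversion: the
numerator accumulates `w · CTF · D` and the denominator `w · CTF²` along
each particle's central plane, and the map is
`num / (den + ε)` with `ε = 10⁻³ ×` the mean nonzero denominator by
default.  Accumulating CTF² across a realistic defocus spread fills the
zeros of individual CTFs.  A strictly positive `ε` keeps cells with
vanishing aggregate CTF² finite; it makes the reference update a slightly
shrunken version of the exact least-squares step, which together with the
mask re-application is the reason the EM objective is guaranteed
non-decreasing only approximately.  In practice the history is monotone
at the study scales the package documents (hundreds of particles per
class and up); in severely noise-dominated, small-n runs transient dips
of order 10⁻⁵ relative can occur, and symmetry breaking from a random
start can fail altogether — the honest signature that the data cannot
support the split.

## The CTF convention

`CTF(f) = −( √(1−Q²) sin γ + Q cos γ )` with
`γ = π λ Δz(θ) |f|² − (π/2) Cs λ³ |f|⁴ + phase shift`, underfocus
positive, so that `CTF(0) = −Q` and projected protein density appears as
dark contrast.  The simulator, the subtractor and the classifier share
this one convention; subtraction consistency depends only on that
sharing, not on the sign choice itself.  No envelope function is applied
at simulation time — spectral decay is the job of the noise/signal
spectra, and a detector MTF can be applied or divided out afterwards as a
tabulated radial filter.

## Masks

Soft masks are built the standard way: binarize at a threshold, dilate by
`extend_px` (3 by default), add a raised-cosine edge over `soft_edge_px`
(6 by default) of Euclidean distance.  The defaults are stated rather
than inherited from any particular data set because mask parameters for
focused classification are rarely reported; every workflow in this
package passes them explicitly.  Masks combine by clipped subtraction
(`whole − part`), which is how the "everything but the focus region"
subtraction mask is made.  Gaussian pseudo-atom rendering
(`pseudo_atoms_to_map()`, σ = radius/2) stands in for atomic-model-to-map
conversion; it is labelled as such and is not a scattering-factor model.

## The simulator and what it does (not) emulate

`simulate_particles()` draws uniform SO(3) orientations (area-correct:
`tilt = acos(U(−1,1))`), defocus uniform in a stated range, projects the
phantom of each particle's class through its CTF, and adds Gaussian noise
shaped shell-by-shell to a stated spectrum (flat by default, tabulated if
supplied).  The exact noise realization of every particle is retained, so
downstream identities — e.g. that the subtraction residual minus the
focus projection *is* the stored noise — are testable to rounding rather
than statistically.

Emulated: orientation dispersion, defocus spread, CTF oscillations,
frequency-dependent SNR, class imbalance if requested.  Not emulated:
ice/solvent background, beam-induced motion, radiation damage, detector
MTF in the forward model, orientation/offset errors from the consensus
refinement, and non-discrete (continuous) heterogeneity.  Passing tests
therefore show the method's behavior under its own model assumptions;
they do not certify performance on real micrographs where those
assumptions are violated.

## The study conditions

The headline experiment (`run_simulation_study()`, reproduced by
`scripts/acceptance.R`) is a desk-scale analog of classifying a small
mobile element: two 64-voxel phantoms at 2.8 Å/px, identical except for a
~30 Å rod of pseudo-atoms inside a spherical focus region; 2,000
particles per class; defocus 0.7–3.2 μm at 300 kV, amplitude contrast
0.1; flat noise of sd 1.0, which puts the per-pixel image SNR near 0.01 —
the canonical single-particle contrast level.  The pipeline runs
end-to-end: consensus reconstruction from all 4,000 particles, soft mask
of the whole complex (threshold 20 % of the map maximum), spherical focus
mask, clipped mask subtraction, projection subtraction of the masked
consensus, and K = 2 masked classification for 25 iterations without
alignment.  Accuracy is the best label-to-class bijection of the hard
assignments.

Problem sizes elsewhere were chosen so that each property is tested in
the regime where it is expected to hold and the whole suite stays quick:
the classifier property checks run at box 32 with 150–250 particles per
class (where EM is reliably monotone and symmetry breaking succeeds), the
SNR sweep spans noise sd 0.25–4 (from saturated accuracy to chance), and
the K = 8 negative control uses 800 homogeneous particles with class maps
compared after a 12 Å low-pass — class maps differ by per-class
reconstruction noise beyond the resolution the per-class particle count
supports, exactly as in practice.

## Validation tools

FSC curves are shell-wise normalized cross-correlations; resolution is
the first downward crossing of a threshold (0.143 for independent
halves), linearly interpolated between shells.  Gold-standard halves are
assigned by a seeded shuffle recorded in the `random_subset` column.
Mask-induced FSC inflation is measured and removed by high-resolution
noise substitution: phases beyond the randomization frequency (default:
where the unmasked FSC first drops below 0.8) are randomized with a
Hermitian-symmetric phase field, the masked FSC of the randomized maps is
taken as the pure mask contribution, and
`(FSC_t − FSC_n) / (1 − FSC_n)` is reported beyond that frequency.
Shells where `FSC_n` reaches 1 are flagged invalid rather than divided
through.

## Known limitations

* Orientations are never refined; the method inherits whatever errors the
  consensus alignment made, and the simulator does not model them.
* The Gaussian noise model ignores the correlation between Fourier
  components that Hermitian symmetry induces (the classic factor-of-two
  bookkeeping); since the simulator and classifier share the convention,
  this does not affect any reported comparison.
* The `ε` regularizer is a single global constant, not a per-shell
  signal-to-noise-derived filter; class maps at very high resolution are
  accordingly conservative.
* C1 symmetry only; no anisotropic magnification; single optics group.
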