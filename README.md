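# cryofocus

Masked (focused) 3D classification with residual signal subtraction for
single-particle cryo-EM, as a self-contained R toolkit with a forward
simulator.

## The problem and who this is for

Cryo-EM data sets of flexible complexes mix several conformations of a
small region — a transmembrane helix, a peripheral subunit — on top of a
rigid bulk.  A consensus refinement averages the states into fuzzy
density, and ordinary 3D classification often fails to separate them:
the signal that distinguishes the states is a small fraction of each
particle image, while the bulk signal and all of the noise still enter
the comparison.  This package is for structural biologists and methods
developers who want to study, teach, or prototype the focused-
classification remedy without a cluster or experimental data.

## The method

Given per-particle orientations `r_i = (rot, tilt, psi)`, offsets and CTFs
from a consensus refinement, and a consensus map split by soft masks into
a focus region `V2` and everything else `V1`:

1. **Subtraction** — replace every particle image by

   `D_i' = D_i − CTF_i · P_{r_i}(V1)`

   where `P` is Fourier-slice projection (central-slice extraction from
   the 2×-oversampled transform).  Up to noise, `D_i'` contains only the
   CTF-affected projection of the focus region.

2. **Masked classification, no alignment** — run K-reference
   maximum-likelihood EM on the subtracted images with orientations held
   fixed and references multiplied by the focus mask.  Responsibilities
   are `softmax_k( ln π_k − Σ_f |D_i'(f) − CTF_i(f) P_{r_i}(V_k)(f)|² /
   (2σ²(ν)) )` with a shell-wise noise spectrum `σ²(ν)` re-estimated each
   iteration.

The package also provides MRC2014 and STAR input/output, soft-mask
construction, Wiener-filtered direct Fourier reconstruction, FSC
validation with high-resolution noise substitution, a forward simulator
with exact ground-truth bookkeeping, and a command-line interface.

## Worked example

A scaled-down version of the package's headline experiment: two phantoms
that differ by one rod inside the focus region, 150 noisy CTF-affected
particles per class, full pipeline (consensus reconstruction, mask
construction, subtraction, K = 2 masked classification):

```r
library(cryofocus)
study <- run_simulation_study(n_per_class = 150, box = 32, noise_sd = 1.0,
                              rod_length = 25, rod_offset = 10,
                              n_iter = 10, seed = 1)
study$accuracy
#> [1] 1
study$run$model
#> <class_model> K = 2, iteration 10, fractions: 0.500 0.500
head(study$run$history[, 1:4], 4)
#>   iteration mean_log_evidence fraction_1 fraction_2
#> 1         0         -3258.958  0.5000000  0.5000000
#> 2         1         -3258.555  0.5164407  0.4835593
#> 3         2         -3258.005  0.5146007  0.4853993
#> 4         3         -3256.615  0.5293138  0.4706862
```

Every simulated particle is assigned to its generating class
(`accuracy = 1`), the two classes keep the generating 50/50 proportions,
and the mean log-evidence rises monotonically across EM iterations.  The
same data classified **without** the subtraction step show why the method
exists — the bulk signal overlapping the focus region acts as extra
noise:

```r
control <- run_simulation_study(n_per_class = 150, box = 32, noise_sd = 1.0,
                                rod_length = 25, rod_offset = 10,
                                n_iter = 10, seed = 1, subtract = FALSE)
control$accuracy
#> [1] 0.7
```

A shell version of the same workflow is available through the installed
executable (`system.file("exec", "cryofocus", package = "cryofocus")`)
with subcommands `simulate`, `makemask`, `subtract`, `classify`,
`reconstruct`, `fsc` and `report`; each writes a JSON manifest recording
its inputs, flags and seed.

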