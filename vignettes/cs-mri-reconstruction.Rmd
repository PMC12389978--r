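---
title: "Sparse-transform and compressed-sensing MRI reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-transform and compressed-sensing MRI reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmri)
```

## The problem

MRI scanners acquire data in k-space (the spatial-frequency domain), and scan
time is proportional to the number of samples acquired. Compressed sensing
(CS) exploits the fact that magnitude MR images are *sparse* — well
approximated by few coefficients — in transform domains such as the wavelet or
cosine basis, to reconstruct diagnostic-quality images from far fewer samples
than the Nyquist count. `csmri` implements and benchmarks four reconstruction
strategies for grayscale images under a common metric framework:

1. **Zero-filled Haar wavelet** (`run_dwt_pipeline`): level-1 orthonormal Haar
   decomposition; a uniformly random subset of `round(rate * M)` coefficients
   is kept, the rest set to zero, and the image re-synthesized.
2. **Zero-filled FFT** (`run_fft_pipeline`): the same random-retention scheme
   in the 2-D DFT domain, with the real part taken after the inverse
   transform.
3. **Top-magnitude DCT** (`run_dct_pipeline`): the `floor(rate * M)`
   largest-magnitude coefficients of the orthonormal 2-D DCT are kept — the
   best possible `N`-term approximation in an orthonormal basis, and fully
   deterministic.
4. **Basis pursuit** (`run_bp_pipeline`): the only pipeline that models an
   actual acquisition operator. The image `x` (resized to `size`², floored at
   0.1, unit-normalized) is observed through `m = round(n * rate)` Gaussian
   random measurements `y = Φx`; the sparse DCT representation `s` is
   recovered by equality-constrained L1 minimization

   $$\min_s \|s\|_1 \quad \text{s.t.} \quad \Theta s = y, \qquad
     \Theta = \Phi\,\Psi^{-1},$$

   where `Ψ⁻¹` is the orthogonal inverse-DCT dictionary
   (`idct_dictionary()`), and the image is the inverse DCT of `s`.

The wavelet and DCT pipelines subsample coefficients the reconstruction
algorithm could never observe in a real scan; they are labelled
`"simulation-only"` in every result and serve as sparsity benchmarks. The FFT
pipeline (Fourier samples) and the basis-pursuit pipeline (random linear
measurements) are labelled `"measurement-model-consistent"`.

## The solver

`solve_bp()` is a primal–dual interior-point method on the linear-program
reformulation `min 1'u` subject to `s − u ≤ 0`, `−s − u ≤ 0`, `Θs = y`.
Design choices, all following the published defaults of the classical
equality-constrained L1 solver family:

* **Surrogate duality gap** `η = −(f₁'λ₁ + f₂'λ₂)` as the termination
  measure; it upper-bounds the suboptimality of the current objective, so
  `tol` has the interpretation "certified distance from the optimal L1 norm".
  Defaults `tol = 1e-6`, `max_iter = 26` — the settings all pipeline runs
  use. Hitting the cap is a warning and a `"max_iter"` status, not an error:
  on dense natural images the cap is the normal operating regime.
* **Barrier update** μ = 10; **backtracking line search** with α = 0.01,
  β = 0.5, at most 32 halvings.
* **Newton system** reduced to the m×m dual system
  `(Θ D Θᵀ) dv = rhs`, solved by Cholesky with a dense-LU fallback. Two
  numerical refinements matter in practice:
  * the diagonal scaling is computed in product form
    `σₓ = 4(λ₁/f₁)(λ₂/f₂)/σ₁` rather than the textbook difference
    `σ₁ − σ₂²/σ₁`, which cancels catastrophically near convergence; the
    product form is algebraically identical and strictly positive;
  * `Θ D Θᵀ` is assembled as a symmetric rank-k update (`crossprod` of
    `sqrt(1/σₓ) Θᵀ`), halving the dominant cost per iteration.
* **Initialization**: the conventional zero starting vector is infeasible for
  `y ≠ 0`; it is silently replaced by the minimum-L2-norm feasible point
  `Θᵀ(ΘΘᵀ)⁻¹y` (`feasible_init()`). With a feasible start, every Newton step
  stays on the measurement manifold, so feasibility is maintained to
  roundoff throughout.

`bp_lp_oracle()` provides an independent cross-check: the same problem posed
as a plain LP via the nonnegative split `s = p − q` and handed to
`boot::simplex()`. The solver and the oracle are two genuinely different
algorithms sharing no code path; their agreement (tested to 1e-5 in objective
and 1e-4 in solution on random instances) is the package's primary
correctness evidence for the solver.

## Transforms

* **DCT**: orthonormal type-II, separable. Orthonormality is what makes
  "compression efficiency = 1 at full retention" and "top-N retention is
  L2-optimal" true statements, and both are tested.
* **FFT**: plain DFT, negative exponent forward, `1/(MN)` on the inverse;
  Parseval holds with factor `√(MN)`.
* **Haar**: level-1 only (the only level the wavelet pipeline uses;
  multi-level trees are out of scope), orthonormal `1/√2` taps, periodic
  extension so the coefficient count equals the pixel count on even-sided
  images. Odd sides are zero-padded and cropped on synthesis. The coefficient
  vector is laid out `[approx | horizontal | vertical | diagonal]` with
  explicit sub-band bookkeeping, mirroring the flat-vector convention of
  classic wavelet toolboxes. The detail-band sign convention is
  `(even − odd)/√2`; tests that must be convention-independent check
  magnitudes or round trips.

## Sampling rules

Two rounding conventions coexist deliberately: the random-mask pipelines use
round-half-away-from-zero (`round(M * rate)`) while the top-magnitude DCT
pipeline uses `floor(rate * M)`. These match the respective algorithm
conventions this package replicates, which genuinely differ between the
pipelines. Ties in the magnitude sort are broken by lower position first, so
top-N selection is deterministic across platforms. Every stochastic operation
takes an explicit integer seed, drives a locally scoped RNG, and restores the
caller's RNG state.

The Gaussian sensing matrix uses the `1/m` entry scaling of the basis-pursuit
pipeline's specification. The conventional CS normalization is `1/√m`
(unit-norm columns in expectation); since the choice only rescales `y` and
`Θ` jointly, the recovered `s` is identical in exact arithmetic, but the
conventional scaling is available via `scale = "1/sqrt(m)"`. The `1e-6`
diagonal perturbation is applied to the leading m×m block (the natural
reading of a square-identity perturbation on a wide matrix). The measurement
`y` is taken with the perturbed matrix, so `Θs = y` is exactly consistent
with the measured image; this is required for the full-sampling (`rate = 1`)
exactness guarantee, which is tested at 1e-8.

## Metrics

RMSE is defined as `√MSE` (the square root is occasionally dropped in
informal write-ups; the magnitudes of all reported tables are only consistent
with the rooted definition, which is the one implemented). PSNR uses peak 1
because all pipelines normalize to [0, 1]; identical images report an
explicit `Inf` sentinel, serialized as `"inf"` in CSV reports. Data loss is
`100·‖x − x₁‖₂/‖x‖₂`.

SSIM has two window modes because the windowless textbook formula and the
practical estimator differ:

* `"gaussian"` (default): 11×11 Gaussian window, σ = 1.5, unit exponents,
  valid-region convolution — the classic mean-SSIM estimator;
* `"global"`: a single uniform window with population moments, which makes
  tiny examples hand-checkable (the complementary 2×2 checkerboards evaluate
  to −0.99641, a frozen test value).

Compression efficiency is `‖retained coefficients‖₂ / ‖original signal‖₂`
(moduli for complex FFT coefficients). Note one quirk inherited from the
replicated definition: for the basis-pursuit pipeline the "retained
coefficients" are the measurements `y = Φx`, whose norm scales like `1/√m`
under the `1/m` matrix scaling, so the BP efficiency figure is not
commensurable with the transform pipelines' (which lie in (0, 1] by
Parseval). It is reported as defined.

Time and peak memory (`resource_probe()`, VmHWM on Linux) are informational
only — they are never asserted against, since they are hardware-bound.

## The phantom and synthetic fixtures

No reference image ships with the package; all experiments run on synthetic
inputs generated in code:

* `shepp_logan_phantom()` renders the standard ten-ellipse head phantom
  (modified-intensity variant) — piecewise-constant, strongly compressible in
  the DCT and wavelet domains, with a zero background exceeding 30% of the
  field of view. That reproduces the *qualitative* structure of a magnitude
  MR slice: sharp anatomical boundaries enclosing smooth regions. It does
  **not** reproduce Rician noise, coil-sensitivity shading, partial-volume
  effects, or soft-tissue texture, so passing benchmarks demonstrate
  correct algorithmic behaviour on compressible piecewise-smooth images, not
  clinical performance. An optional seeded low-frequency texture can break
  exact piecewise constancy.
* `sparse_dct_image()` and `ksparse_vector()` plant exactly-K-sparse ground
  truths for solver validation (uniform magnitudes in [0.5, 1.5], random
  signs, uniformly random support).
* `write_dicom_fixture()` writes minimal explicit-VR little-endian
  single-frame grayscale DICOM files (8 or 16 bit) so the reader can be
  tested without any downloaded data; the files also parse with independent
  DICOM implementations.

`read_dicom()` covers the subset of DICOM a single-frame grayscale image
needs: explicit- and implicit-VR little endian, rescale slope/intercept,
MONOCHROME1 inversion, and rejection of color and multi-frame files.
Pre-processing follows the pipelines' convention: min–max normalization to
[0, 1] (a constant image maps to zeros with a warning rather than a division
by zero), bicubic resize (Keys kernel, a = −0.5, antialiased when
downscaling, clipped to [0, 1] after the overshoot-prone cubic), and a hard
intensity floor using a strict `< t` comparison.

## Problem sizes and runtime envelope

The package's own verification runs at desk scale, chosen so the whole suite
completes in about a minute while still exercising every regime:

* transform round trips on 100 random images of sizes 2–64;
* solver-vs-oracle agreement on 50 instances at n = 64, m = 32;
* exact-recovery success counting over 100 trials at n = 128, K = 4, m = 64;
* phantom benchmarks at 64×64 (n = 4096, m up to 2867 measurements for basis
  pursuit), rates 35%, 50% and 70%.

The basis-pursuit pipeline defaults to `size = 128` (n = 16384) for
standalone use; a single solve at that size is minutes-scale on one core and
is therefore not part of the routine test runs.

## Known limitations

* Dense linear algebra throughout the solver: no implicit/functional
  operators, so n beyond ~128² is impractical.
* Basis-pursuit only — no noise-tolerant variants (BPDN), greedy methods, or
  nonconvex penalties.
* Level-1 Haar only; no other wavelet families.
* Uniform random masks only; no variable-density or Poisson-disc k-space
  sampling.
* The benchmarking reports orderings and trends on synthetic phantoms; the
  absolute metric values of any particular clinical image depend on that
  image and are not reproduced here.
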