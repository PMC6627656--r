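---
title: "Reverse anisotropic diffusion unsharp masking: model, discretization, and validation"
author: "radusm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse anisotropic diffusion unsharp masking: model, discretization, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radusm)
```

## The problem

Portable chest radiographs acquired in intensive care are low-contrast
images in which thin line structures — endotracheal, feeding and
nasogastric tubes, catheters — must be located reliably. Classical unsharp
masking (USM) enhances such structures by adding a high-frequency mask back
onto the image,

$$I_{en}(x,y) = I(x,y) + \alpha_{usm}\,\bigl(I(x,y) - I_{sm}(x,y)\bigr),$$

where $I_{sm}$ is a smoothed companion image. When $I_{sm}$ comes from a
Gaussian filter the mask $I - I_{sm}$ contains everything the filter
removed — edges *and* noise — so the enhancement amplifies noise in
exactly the flat regions where tubes must be traced, and the mask's
negative excursions produce dark halos along edges.

## Reverse anisotropic diffusion

The idea implemented here is to build $I_{sm}$ with a diffusion process
whose diffusivity *increases* with the gradient magnitude,

$$\frac{\partial I}{\partial t} = \operatorname{div}\!\bigl(\|\nabla I\|^{\beta}\,\nabla I\bigr),
\qquad \beta \ge 1,$$

the reverse of Perona–Malik diffusion (which uses a *decreasing*
diffusivity to remove noise while keeping edges). Under a gradient-grown
diffusivity, strong edges diffuse quickly while flat and mildly noisy
regions barely move; the mask $I - I_{sm}$ therefore contains mostly edge
structure and little noise. Decomposed along the local gradient direction,
a diffusivity $g(\|\nabla I\|)$ produces flow $g\,I_{\xi\xi} +
\varphi'\,I_{\eta\eta}$ with $\varphi(s) = s\,g(s)$; a monotonically
increasing $g$ puts the stronger diffusion across the edge, the weaker
along it, which is exactly the wanted behaviour.

Rather than integrating the flow explicitly, the smoothed image is defined
variationally: minimize a fidelity term plus the diffusion energy with
weight $\alpha_{diff}$. One lagged-diffusivity step of the resulting
Euler–Lagrange equation is the linear system

$$\bigl[D + \alpha_{diff}\,L(I^{(m)})\bigr]\, I^{(m+1)} = I_{input},$$

where $D$ is the identity and $L(I^{(m)})$ the diffusion operator with
coefficients frozen at the current iterate ($I^{(0)} = I_{input}$). Each
outer iteration is one sparse symmetric positive definite solve.

## Discretization

The operator is discretized on half-pixel faces with central tangential
differences. For the face between $(x,y)$ and $(x\!-\!1,y)$ the squared
gradient estimate is

$$G_1 = \bigl(I_{x,y}-I_{x-1,y}\bigr)^2 +
\tfrac14\bigl(I_{x-1,y+1}-I_{x-1,y-1}\bigr)^2,$$

and analogously $G_2, G_3, G_4$ for the faces towards $x\!+\!1$, $y\!-\!1$,
$y\!+\!1$. The face diffusivity is

$$c_k = \bigl(\sqrt{G_k} + \varepsilon\bigr)^{\beta},$$

the discrete form of $g(\|\nabla I\|) = \|\nabla I\|^{\beta}$ with a small
floor $\varepsilon$ (default $10^{-3}$) that keeps the diffusivity strictly
positive in flat regions. With $s = c_1+c_2+c_3+c_4$, one application of
$A = D + \alpha_{diff} L$ reads, per pixel,

$$ (Av)_{x,y} = v_{x,y} + \alpha_{diff}\bigl(s\,v_{x,y} - c_1 v_{x-1,y}
 - c_2 v_{x+1,y} - c_3 v_{x,y-1} - c_4 v_{x,y+1}\bigr). $$

Out-of-bounds neighbours are reflected (homogeneous Neumann), the standard
choice for diffusion filtering of images. Three structural facts follow
and are enforced by tests:

* **Symmetry.** The same two pixel values and the same tangential
  difference enter $c_2$ at $(x\!-\!1,y)$ and $c_1$ at $(x,y)$, so the two
  coupling coefficients across any face are *identical floating-point
  numbers* and the assembled matrix is exactly symmetric.
* **Zero row sums of $L$.** $s$ is defined as the sum of the four face
  coefficients, so constants are fixed points and the mean intensity is
  conserved by the solve.
* **M-matrix structure.** The diagonal exceeds the absolute off-diagonal
  row sum by exactly 1, so $A$ is strictly diagonally dominant, the solve
  is well posed at every $\alpha_{diff} \ge 0$, and the output obeys a
  discrete maximum principle (no over/undershoot).

## The linear solver

The system is solved matrix-free — at radiograph sizes ($2048\times 2048$
and larger) a materialized matrix is out of the question, while one
operator application is a handful of vectorized grid operations. The
Krylov method is the preconditioned bi-conjugate gradient (PBCG) with the
Jacobi (diagonal) preconditioner $1 + \alpha_{diff}\,s$:

* PBCG is implemented in its standard textbook recurrence with paired
  residuals and directions and an explicit transpose operator, so it is
  correct for general nonsymmetric systems; since the RAD operator is
  symmetric positive definite, the iterates coincide with preconditioned
  CG — the suite checks this agreement per iterate to $10^{-10}$ on small
  systems, a strong internal consistency check.
* The initial guess is the right-hand side ($A \approx D$ for small
  $\alpha_{diff}$, so $x_0 = b$ starts near the solution); it is
  overridable.
* Iteration stops on the relative residual $\|b - Ax\|/\|b\|$ (absolute
  floor $10^{-30}$ guards $b=0$); the reported final residual is
  recomputed from scratch, never trusted from the recurrence. Breakdown of
  either inner product raises a structured error naming the iteration;
  non-convergence is returned as a diagnosable result and escalated to an
  error by `rad_smooth()`.
* At boundary pixels the true assembled diagonal folds the reflected
  neighbour in, so the Jacobi diagonal $1+\alpha s$ is an upper bound
  there; this only perturbs the preconditioner's constants, never the
  fixed point, and the suite verifies that preconditioned and
  unpreconditioned solves agree to $10\times$ the tolerance while the
  preconditioned one never needs more iterations.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha_diff` | 0.02 | diffusion weight; 0.001 barely moves edges, 0.2 smooths aggressively and thickens contours. 0.02 is the operating point used throughout. |
| `beta` | 1 | exponent of the gradient-grown diffusivity. |
| `grad_eps` | 0.001 | flat-region diffusivity floor; also the only regularization of the gradient magnitude. |
| `outer_iters` | 1 | lagged-diffusivity iterations; one solve already produces the edge-selective behaviour, and the parameter is exposed for users who want a tighter fixed point. |
| `solver_tol` | 1e-8 | relative residual of the inner PBCG solve. |
| `alpha_usm` | 1.0 | mask weight of the USM step (the mask is added at full strength); distinct from `alpha_diff` — the two weights play entirely different roles. |
| `range_policy` | clip | out-of-range handling after enhancement: clipping is the minimal fix for the classical USM halo/overflow defect; `rescale` and `none` are available. |
| Gaussian `kernel_size` | 15 (also 19, 23 conventionally) | baseline USM smoother; `sigma = kernel_size/6` so the kernel is truncated at $3\sigma$ and the size determines the scale. |
| Perona–Malik `kappa`, `step`, `n_steps` | 30, 0.2, 10 | baseline only; `kappa` sits above the phantom's noise gradients and below its edge gradients, `step` respects the explicit-scheme stability bound 0.25. |
| EMEE `block_h x block_w`, `c` | 40 x 40, 30 | contrast metric blocks and the stabilizing constant added to each block minimum (zero-intensity pixels are common in radiographs). |

EMEE uses the natural logarithm; the base uniformly rescales all values,
so comparisons and trends are unaffected, but absolute EMEE values are
only comparable between implementations with the same base. Partial blocks
at the right/bottom edges are included as-is so every pixel contributes
(typical radiograph sizes are not multiples of 40). The term
$r\,\ln r$ is continued by $0\ln 0 := 0$ for all-zero blocks. The `snr()`
helper (mean of a signal rectangle over the sample standard deviation of a
noise rectangle) is this package's own documented definition; no claim is
made that it reproduces any published radiograph SNR protocol.

## The phantom: what it emulates, and what it does not

All tests run without external data on a reproducible phantom: a smooth
background with a vertical gradient (base 1500, span 400 of the 12-bit
range), five smooth sinusoidal "rib" bands (amplitude 200), two curved
bright tubes (width 3 px, contrast +600) rendered as flat-topped bands
along natural splines, i.i.d. Gaussian noise ($\sigma = 20$), and sparse
impulse pixels (+400, exact count `round(0.005 * npixels)` chosen by a
seeded draw so tests can assert counts; impulse pixels replace, rather
than add to, the Gaussian noise at their location so the ground-truth
masks are exact). The standard preset is $256\times 256$ with seed
20190424, frozen in code.

The phantom reproduces the *geometry* that matters to the method — thin
high-contrast curvilinear structures over smooth anatomy with low-level
noise — but none of the physics of radiography (beam hardening, scatter,
anatomical texture, detector MTF). Passing tests therefore demonstrate the
mathematical behaviour of the filter (selectivity, conservation,
convergence, metric trends), not clinical image quality.

Two empirical regimes deserve explicit statement, because they shape what
the validation can and cannot show:

* **Selectivity is amplitude-relative.** RAD attenuates every structure
  roughly in proportion to its own gradient, so "smooth edges, keep
  noise" holds when noise amplitude is well below edge contrast — the
  regime of a 12-bit radiograph. The selectivity fixture therefore uses a
  step edge of contrast 100 with impulses of amplitude 20; there RAD
  attenuates the across-edge contrast by a clearly larger factor than the
  impulse amplitude, while Gaussian and Perona–Malik smoothing show the
  opposite ordering.
* **Mask-energy concentration is contrast-dominated.** On the standard
  phantom the tube band (contrast 600) carries most of the energy of
  *any* unsharp mask: the RAD mask concentrates about 79% of its energy
  within 2 px of tube pixels and the Gaussian mask about 77% — the RAD
  mask is the more concentrated, as expected, but the Gaussian fraction
  cannot drop far while tube contrast dominates noise by a factor of 30.
  A phantom with weaker tubes or stronger noise would separate the two
  fractions much further; the preset is kept as frozen.

## Numerical choices and degenerate inputs

* `alpha_diff = 0` returns the input bit-identically (no solve is run);
  constant images are fixed points to within the solver tolerance.
* Gaussian smoothing uses half-sample mirror padding, under which a
  symmetric normalized kernel conserves total intensity exactly; the
  explicit Perona–Malik scheme conserves the mean by face-flux pairing.
* Images are carried as real-valued matrices throughout; quantization to
  integers happens only at write time (writers reject out-of-range values
  instead of clipping silently, so range policy stays an explicit caller
  decision).
* The 16-bit grayscale PNG writer is built into the package (filter-0
  scanlines, zlib via `memCompress`, hand CRC32) because no installed R
  package writes 16-bit PNG; round-trips are verified against
  `png::readPNG` as an independent reader. TIFF goes through the `tiff`
  package; the raw 2048x2048 big-endian JSRT layout has a paired
  reader/writer.
* Problem sizes in the suite are chosen so every claim has an affordable
  independent oracle: dense assembly and direct solves up to
  $16\times16$ grids (21 seeded systems across
  $\alpha_{diff}\in\{0.001, 0.02, 0.2\}$, agreement $\le 10^{-6}$
  relative), per-iterate CG comparison on $6\times6$, and the full
  pipeline on the $256\times256$ phantom, which enhances in about a
  second.
* With coefficients frozen to a constant field $c$, one implicit step is
  the low-pass filter $1/(1+\alpha c\,k^2)$, i.e. a Gaussian blur of
  standard deviation $\sqrt{2\alpha c}$ up to $O((\alpha c k^2)^2)$; the
  suite verifies 2% agreement on a smooth test image — the diffusion ⇔
  Gaussian-convolution limit that also motivates the Gaussian baseline.

## Known limitations

* One outer iteration is the default; the full nonlinear fixed point may
  need several, at proportional cost.
* `alpha_diff` is global; spatially adaptive weighting is out of scope.
* No DICOM input, no display window/level handling, no multi-frame images.
* EMEE is sensitive to noise through the per-block extrema; on very noisy
  images a larger block `c` or pre-filtering may be warranted.
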