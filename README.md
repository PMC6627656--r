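# radusm — reverse anisotropic diffusion unsharp masking for radiographs

`radusm` enhances thin line structures — endotracheal, feeding and
nasogastric tubes, catheters — in low-contrast grayscale radiographs such as
portable ICU chest X-rays. It implements unsharp masking built on **reverse
anisotropic diffusion (RAD)**: a diffusion filter whose diffusivity
*increases* with the gradient magnitude,

    ∂I/∂t = div( ‖∇I‖^β ∇I ),        β ≥ 1,

so edges are smoothed while flat and mildly noisy regions are left nearly
untouched — the reverse of Perona–Malik diffusion. Subtracting the
RAD-smoothed image from the original gives an unsharp mask that contains
edge structure with little noise; adding it back,

    I_en = I + α_usm (I − I_sm),

enhances tubes and contours without the noise amplification and halo
defects of Gaussian-based USM.

Each smoothing step solves the implicit lagged-diffusivity system
`[D + α_diff L(I)] I_sm = I` with half-pixel face diffusivities
`c_k = (√G_k + ε)^β`, matrix-free, using a Jacobi-preconditioned
bi-conjugate gradient solver. The package also provides the Gaussian and
Perona–Malik baselines, the EMEE block-entropy contrast metric, an ROI SNR,
readers/writers for 16-bit PNG/TIFF and the raw 2048×2048 JSRT layout, a
reproducible chest-like phantom generator, and a command line.

## Worked example

```r
library(radusm)

ph <- make_phantom(phantom_spec())   # standard 256x256 chest-like phantom
ph$img
#> <image2d> 256 x 256, 12-bit, intensities [1106.1, 2757.97]

fit <- rad_usm(ph$img, diffusion_params(alpha_diff = 0.02), usm_params())
fit
#> <rad_usm> 256 x 256 image, alpha_diff=0.02, alpha_usm=1 (clip)
#>   mask range [-344.5, 682.2], EMEE 0.8197 -> 1.623
plot(fit)   # original / smoothed / mask / enhanced panels
```

The printed summary says: the RAD smoothing produced an unsharp mask
ranging from −344 to +682 gray levels (concentrated on the tube and rib
edges), and adding it raised the EMEE contrast metric of the phantom from
0.820 to 1.623 — roughly a doubling of blockwise entropy-weighted contrast.
Sweeping the diffusion weight shows the expected monotone trend:

```r
sapply(c(0.001, 0.02, 0.2), function(a)
  emee(rad_usm(ph$img, diffusion_params(alpha_diff = a))$enhanced))
#> [1] 1.273558 1.623347 1.699094
```

For real data:

```r
img <- read_image("portable_cxr.png", bit_depth_hint = 12)   # or read_jsrt_raw("case.IMG")
fit <- rad_usm(img)
write_image(fit$enhanced, "portable_cxr_enhanced.png")
```

Command line (`inst/cli/radusm.R`):

```sh
Rscript inst/cli/radusm.R enhance --method rad-usm --alpha-diff 0.02 \
    --out-dir out --emit-intermediates chest1.png chest2.png
Rscript inst/cli/radusm.R emee --block-h 40 --block-w 40 out/chest1_enhanced.png
Rscript inst/cli/radusm.R phantom --out-dir phantom_out
```

`enhance` writes the enhanced image (plus smoothed image and mask with
`--emit-intermediates`) and appends one JSON record per input — parameters,
EMEE before/after, runtime — to `run_log.jsonl`.

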