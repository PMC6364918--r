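# dwiframelet

Edge-preserving denoising of diffusion-weighted (DW) MR images with
undecimated B-spline tight wavelet frames (framelets) and a group
ℓ0 sparsity penalty.

DW images are intrinsically noisy — their contrast comes from signal
*attenuation* — and multi-coil magnitude reconstruction makes the noise
noncentral-chi (nc-χ), signal-dependent, with an elevated floor in dark
regions. Total-variation denoising staircases smoothly varying
anatomy. This package instead penalizes sparsity of tight-frame
coefficients, which act as difference operators of several orders, and
it denoises channels acquired at angularly neighboring gradient
directions *collaboratively*: for each channel `g` it minimizes

    Φ(u) = ‖u − f‖² + Σ_{i,g,l,r} λ_{g,l,r} ‖ Σ_m w_{g,m}² (W_{l,r} u⁽ᵐ⁾)_i² ‖₀

where `W_{l,r}` are the subbands of a UEP-derived B-spline framelet
system (Haar / piecewise linear / piecewise cubic; Parseval, so
`WᵀW = I`), and `w_{g,m} = exp(κ[(νₘᵀν_g)² − 1])` are Watson angular
weights gated at θ = 30°. The objective is minimized by penalty
decomposition: each iteration is a *group hard threshold* of the
coefficients (keep a whole weighted group at a voxel/band iff its
energy `h ≥ 2λ_{g,l,r}/μ`) plus a *pointwise division*, with the
penalty factor μ grown geometrically. An ℓ1 (group soft threshold)
variant is included. After denoising, the nc-χ signal bias is removed
by second-moment inversion `η̂ = sqrt(max(û² − 2Nσ², 0))`, with σ
estimated from the image background if unknown.

Intended users: diffusion-MRI methods researchers who want a
self-contained, fully testable implementation — including an nc-χ noise
simulator, a synthetic spiral phantom with ground truth, and
PSNR/SSIM/RMSE evaluation — with no downloads required.

## Worked example

Simulate a scaled spiral phantom, corrupt it with 32-coil nc-χ noise at
σ = 5, denoise, debias, and evaluate:

```r
library(dwiframelet)

ph    <- makeSpiralPhantom(spiralPhantomSpec(
           dim = c(32, 32, 8), nDirections = 24, turns = 2, r0 = 2,
           rGrowth = 5, tubeRadius = 2, seed = 1))
noisy <- addNcChiNoise(ph$stack, ncChiModel(sigma = 5, nCoils = 32, seed = 1))

fit <- dwiDenoise(noisy, frame = "linear", levels = 2, penalty = "l0",
                  lambda = 1, debias = TRUE, sigma = 5)

clean <- dwiData(ph$stack)
cat(sprintf("noisy:           %5.2f dB\n", psnr(clean, dwiData(noisy))))
cat(sprintf("debiased only:   %5.2f dB\n",
            psnr(clean, debiasNcChi(dwiData(noisy), 5, 32))))
cat(sprintf("denoise+debias:  %5.2f dB\n", psnr(clean, dwiData(denoised(fit)))))
```

```
noisy:            8.83 dB
debiased only:   19.37 dB
denoise+debias:  25.45 dB
```

The raw-noisy PSNR is dominated by the nc-χ bias (with 32 coils the
background floor is 8σ = 40 against a baseline signal of 150), so
debiasing alone recovers ~10 dB; the framelet ℓ0 denoiser contributes
a further ~6 dB on top. `solverTrace(fit)` shows the outer μ schedule
and objective; `bcdObjectiveTrace(fit)` the per-sweep augmented
objective of every inner run (non-increasing by construction).
`evaluateDenoising(ph$stack, denoised(fit))` adds per-channel PSNR,
SSIM and an RMSE map. `lambdaGridSearch()` reproduces the PSNR grid
search used to select λ.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/framelet-denoise.R simulate --out noisy.nii.gz --sigma 5 --seed 1
Rscript inst/cli/framelet-denoise.R run --in noisy.nii.gz --bvec noisy.bvec \
        --bval noisy.bval --out denoised.nii.gz --penalty l0 --lambda 4
Rscript inst/cli/framelet-denoise.R evaluate --ref clean.nii.gz --test denoised.nii.gz
```

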