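# srrecon

Super-resolution reconstruction (SRR) of an isotropic 3D MR volume from
multiple anisotropic 2D multi-slice stacks.

Clinical single-shot T2-weighted series (as used in upper abdominal /
MR cholangiopancreatography studies) have fine in-plane resolution
(~0.78 mm) but thick slices (~5 mm), so ducts and vessels are degraded by
partial-volume averaging, and every breath-hold series is displaced by
subject motion. `srrecon` estimates one high-resolution volume from several
such stacks acquired in axial, coronal, sagittal and oblique orientations,
for researchers studying acquisition-protocol and motion-correction choices
for thick-slice SRR.

## The model

Each slice pixel is a point-spread-function-weighted average of the unknown
high-resolution volume `x`:

    y_si(j) = A_si(j, x) + n_si(j)

with a slice-aligned 3D Gaussian PSF of covariance
`diag((1.2 s1)^2, (1.2 s2)^2, s3^2) / (8 ln 2)` (in-plane spacings `s1, s2`,
thickness `s3`). The reconstruction solves the non-negative, Tikhonov-
regularized least-squares problem

    x* = argmin_{x >= 0}  sum_{s,i} 1/2 ||y_si - A_si x||^2 + alpha/2 ||grad x||^2

by matrix-free conjugate-gradient least squares. Motion is handled by rigid
slice-to-volume registration (normalized cross-correlation through the PSF
forward model) inside an iterative two-step registration–reconstruction
loop with outlier rejection: at iteration `k`, only slices with
`NCC(y_si, A_si x^{k-1}) >= sigma_k` (defaults 0.6, 0.65, 0.7) enter the
solve. A reference-guided variant registers slices to a separately acquired
high-resolution volume instead, optionally with an in-plane B-spline
deformation step. A seeded digital phantom and an evaluation harness
(self-consistency, ground-truth similarity, experiment grids over
acquisition configurations) make every pipeline testable without scan data.

## Worked example

```r
library(srrecon)

# ground-truth phantom: nested ellipsoids + bright 1-2 voxel ducts,
# 48^3 voxels at 0.78 mm
phantom <- make_phantom(dims = 48, spacing = 0.78, seed = 2)

# simulate the six-stack protocol (axial+coronal+sagittal+3 obliques),
# 5 mm slices, per-slice rigid motion up to 3 mm / 3 deg, noise sd 0.01
sim <- simulate_protocol(phantom, "a+c+s+3obl",
                         motion_t = 3, motion_r = 3, noise_sd = 0.01,
                         seed = 42)

grid <- roi_grid(phantom)         # 0.78 mm isotropic lattice over the ROI
rob  <- reconstruct_outlier_robust(sim$stacks, grid = grid, alpha = 0.01,
                                   seed = 42)
sta  <- reconstruct_static(sim$stacks, grid = grid, alpha = 0.01)

ground_truth_similarity(rob, phantom, metrics = "ncc")$ncc$value
#> [1] 0.8216695
ground_truth_similarity(sta, phantom, metrics = "ncc")$ncc$value
#> [1] 0.6000845
rob$rejected_count
#> [1] 6 6 6
summary(motion_errors(rob, sim$motions)$trans_mm)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.07275 0.21300 0.27370 0.46518 0.46148 2.94599
```

The motion-corrected reconstruction agrees with the ground truth
(NCC 0.82 inside the phantom mask) substantially better than the
no-motion-correction baseline (0.60); six low-agreement slices per
iteration were excluded by the outlier rule, and the median slice
translation error after correction is about a third of a reconstruction
voxel. `write_image()` stores any volume as NIfTI; a command-line front end
(`inst/scripts/srr`) wraps simulation, reconstruction and evaluation for
shell use.

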