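# hermiteflow

Dense 2D and 3D+t optical flow built on the **steered Hermite transform**:
a differential, multiresolution motion estimator for volumetric image
sequences such as cardiac CT, where wall contraction and dilation must be
quantified in all three spatial directions.

## Who this is for

Researchers in biomedical image analysis who need a dense per-voxel
displacement field between consecutive volumes (or 2D frames), a way to
*validate* that field when no ground-truth motion exists (interpolation
errors), and reproducible synthetic phantoms for testing motion-estimation
pipelines.

## The model

The Hermite transform decomposes a signal under overlapping Gaussian
windows into polynomials orthonormal to the window — equivalently, into
responses of Gaussian-derivative filters, a classical model of receptive
fields in early human vision. Coefficients `L_{l,m,n}` up to total order
`N` are computed by separable convolution; *steering* rotates each order's
coefficient block onto the local orientation of maximal energy
`(θ, φ)`, compacting oriented structure into a 1D profile along the
orientation.

The flow field `w = (u, v, w)` minimizes a Horn–Schunck-family energy in
which brightness constancy acts on the order-0 coefficient and is augmented
by constancy of the on-axis steered coefficients:

    E = ∫ (L0(x+w, t+1) − L0(x, t))²
        + γ Σ_{n=1..N−1} (l_n(x+w, t+1) − l_n(x, t))²
        + α |∇w|² dx

solved coarse-to-fine with symmetric (midpoint) warping, per-voxel 3×3
solves under the neighbor-average smoothness coupling, and the order-raising
property supplying the coefficient derivatives. `γ = 0` gives a
multiresolution Horn–Schunck baseline in the identical scaffold. Estimated
flows are validated by forward reconstruction: the interpolation error (IE,
RMS intensity units) and the gradient-normalized interpolation error (NE,
dimensionless) between the true and reconstructed next volume.

## Worked example

Estimate the motion of a beating ellipsoidal-shell phantom (a synthetic
"left ventricle" with analytic ground truth) across one cardiac-phase
transition, and validate it by forward reconstruction:

```r
library(hermiteflow)

spec <- phantom_spec("beating_ellipsoid", shape = c(32, 32, 32),
                     phases = 10, seed = 7)
ph <- generate_phantom(spec)

params <- flow_params()            # alpha = 10, gamma = 100, N = 4,
params                             # window 5, 5 levels, 50 iterations
#> flow_params: alpha=10 gamma=100 N=4 window=5 levels=5 iters=50 warps=3

fl <- estimate_flow(ph$volumes[[2]], ph$volumes[[3]], params)
fl
#> flow_field (3D, 32x32x32): |w| mean 1.011, max 3.152 voxels

evaluate_pair(ph$volumes[[2]], ph$volumes[[3]], fl)
#> error_report: IE = 1.7296, NE = 0.054447 (epsilon = 1, forward)

gt  <- ph$flows[[2]]
msk <- phantom_shell_mask(spec, phase = 2)
epe <- sqrt((fl$u - gt$u)^2 + (fl$v - gt$v)^2 + (fl$w - gt$w)^2)
mean(epe[msk])
#> [1] 0.3776
```

The phantom contracts between phases 2 and 3 (about one voxel of radial
motion at the shell). The estimated field reconstructs the next volume with
an RMS error of 1.73 intensity units (against 18.2 for assuming no motion)
and a normalized error of 0.054, inside the < 0.1 quality regime; the mean
endpoint error on the shell is 0.38 voxels. `write_vtk_flow()` exports the
field for glyph rendering, `plot_flow()` draws a quiver over a slice, and
`evaluate_sequence()` tabulates IE/NE over a whole cycle (optionally under
a left-ventricle mask).

A thin command-line driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hof.R", package = "hermiteflow"))')" \
    synth --out phantom --kind beating_ellipsoid --shape 32,32,32 --phases 10
```

with subcommands `estimate`, `evaluate`, `synth` and `benchmark-middlebury`.

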