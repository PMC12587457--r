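---
title: "Finite-element photon modeling for diffuse optics: models, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-element photon modeling for diffuse optics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonfem)
```

## The forward problem

Near-infrared light in highly scattering tissue is well described by the
diffusion approximation. In the frequency domain the fluence rate
$\Phi(r,\omega)$ obeys

$$-\nabla\cdot(\kappa(r)\nabla\Phi) + \mu_a(r)\Phi +
  \frac{i\omega}{c(r)}\Phi = q(r,\omega),$$

with absorption $\mu_a$ (mm$^{-1}$), reduced scattering $\mu_s'$
(mm$^{-1}$), diffusion coefficient $\kappa = 1/(3(\mu_a+\mu_s'))$ and
medium light speed $c = c_0/n$. At the tissue-air interface the Robin
(partial-current) condition $\Phi + 2\beta\kappa\,\partial\Phi/\partial\nu
= 0$ models internal reflection; the scalar $\beta$ encodes the
refractive-index mismatch and can be computed three ways
(`boundary_beta()`): exact Fresnel integrals, a two-step closed-form
approximation, and Groenhuis's empirical cubic. The empirical method is the
assembly default because it is closed-form and accurate to roughly 10%
of the exact integrals over the tissue range — and, crucially, the *same*
$\beta$ feeds both the FEM boundary term and the analytical
extrapolated-boundary offset $z_b = 2\beta\kappa$, so validation
comparisons are internally consistent.

P1 (linear) finite elements on triangles/tetrahedra turn the PDE into the
sparse symmetric system $(A + i\omega B)\Phi = Q$ with
$A = K(\kappa) + M(\mu_a) + \tfrac{1}{2\beta}M_\Gamma$ and $B = M(1/c)$
(`assemble_standard()`). Weighted integrals use the element mean of the
nodal coefficient — the natural lowest-order choice for P1 accuracy; for
the homogeneous phantom studies in this package it is exact. Three problem
families reduce to this one linear form:

* **standard** — one wavelength, CW ($\omega=0$) or frequency-domain;
* **fluorescence** — a coupled pair of standard problems: the excitation
  field drives a re-emission source $\gamma\Phi^x/(1+i\omega\tau)$, with
  lumped yield $\gamma = \eta\mu_{af}$ and lifetime $\tau$, applied through
  the basis-overlap matrix $U$ ($U_{ik}=\int u_i u_k$). The product rule
  behind that nodal approximation requires the excitation field to vary
  slowly over an element, which holds in diffuse optics away from the
  immediate source vicinity;
* **DCS** — the electric-field autocorrelation $G_1(r,\tau)$ obeys the same
  equation with delay-dependent extra absorption
  $2\alpha D_b \mu_s' k_0^2 \tau$; `assemble_dcs()` caches the static
  operator and the dynamic mass matrix so a delay sweep costs one sparse
  add per $\tau$.

## Solvers

All systems are solved with Krylov methods preconditioned by a factorized
sparse approximate inverse (FSAI): a sparse lower-triangular $G$ with
$M^{-1}=G^TG\approx A^{-1}$, applied as two sparse matrix-vector products
(`build_fsai()`). Row patterns follow the solver: BiCGStab uses the three
largest-magnitude entries of each lower row; CG uses the diagonal plus the
four largest strictly-lower entries; the complete lower triangle reproduces
the exact inverse-Cholesky factor and serves as a testing limit.
"Largest" is by absolute value (FEM off-diagonals are negative), ties break
toward the smaller column index, and the diagonal is always forced into the
pattern since the row solve normalizes by it. `choose_solver()` implements
the selection rule: frequency-domain problems (complex symmetric operators)
get BiCGStab; every real problem — CW, time stepping, moments, DCS — gets
the cheaper conjugate gradient. The complex operator is carried as a
(real, imaginary) pair of real sparse matrices and the preconditioner is
built from the real part only: at 100 MHz the imaginary part, a scaled mass
matrix, is a small perturbation of $A$, and a real $G$ keeps the
two-triangular-product application. Default termination is a true relative
residual of $10^{-12}$, verified against re-computed residuals in the
tests.

## Time-resolved data: stepping versus direct moments

The temporal point spread function (TPSF) is computed by $\theta$-scheme
stepping of $B\,\partial\Phi/\partial t + A\Phi = 0$
(`femdata_tpsf_standard()`), default Crank-Nicolson ($\theta = 1/2$),
with $\theta = 1$ available for positivity-critical early-time work since
Crank-Nicolson can produce small oscillations around the sharp launch.
The impulse is injected as the mass-consistent delta $B\Phi_0 = Q$, which
preserves the defining identity $\int_0^\infty f(t)\,dt = \Phi_{CW}$ up to
discretization error (tested at 2%). One FSAI of the constant step operator
is built once and reused for every step, and each solve warm-starts from
the previous field — stepping a 2000-node disk through 1000 steps takes a
few seconds. Fluorescence stepping drives the emission field with a running
exponential convolution $w_{k+1} = w_k e^{-\Delta t/\tau} +
(\gamma\Phi^x_{k+1})(1-e^{-\Delta t/\tau})$ (exact for piecewise-constant
excitation; $\tau = 0$ degenerates cleanly to instantaneous re-emission).

When only moments of the TPSF are needed, the Mellin-transform recursion is
far cheaper: $m_0 = A^{-1}Q$ (the CW solve) and $m_n = n\,A^{-1}(B\,m_{n-1})$
— one linear solve per order instead of one per time step. The coupled
fluorescence recursion adds the source ladder $s_n = \gamma\odot m_n^x +
n(\tau\odot s_{n-1})$, $m_n^m = (A^m)^{-1}(n B^m m_{n-1}^m + U s_n)$.
Normalized moments $\langle t^n\rangle = m_n/m_0$ are formed per channel
after interpolating the Mellin fields at the detector points. The tests
verify both that the recursion satisfies its defining linear relations and
that TPSF-integrated moments agree with the direct ones to a fraction of a
percent on the disk phantoms.

## Optodes, voxel grids and Jacobians

Only point sources are supported: each source is projected onto the nearest
boundary point and moved inward one scattering length $1/\mu_s'$ (the
isotropic-source depth; $1/\mu_{sx}'$ for fluorescence), detectors are
projected but not moved, and boundary data are barycentric interpolations
of the nodal field at the projected detector point. The inward direction at
a projection is the negated area-weighted average of the adjacent boundary
face normals, which stays well-defined on edges and corners.

For reconstruction work, nodal fields are interpolated once onto a uniform
voxel grid through a sparse mapping whose rows are barycentric weights —
a partition of unity, exact for affine fields, independent of grid
resolution at any fixed location. Adjoint Jacobians are then elementwise
products of direct and adjoint voxel fields times the voxel volume: the
$\mu_a$ block is $-\Phi\odot\Psi\,V_{vox}$, the $\mu_s'$ block applies
$d\kappa/d\mu_s' = -3\kappa^2$ to the per-element gradient product
$\nabla\Phi\cdot\nabla\Psi$ sampled at voxel centers, fluorescence yields
$\Phi^x\odot\Psi^m$ (Born-ratio normalized by default), and DCS scales the
$\mu_a$-type product by $2\mu_s'k_0^2\tau$ per delay (zero at $\tau = 0$
by construction). Adjoint fields are detector injections *without* the
scattering-length displacement, mirroring the source/detector asymmetry.
Every block is validated against finite-difference perturbation oracles at
5%. Frequency-domain Jacobians interleave real and imaginary rows per
channel; CW fluorescence returns only the real $\gamma$ block because the
imaginary derivative vanishes identically at $\omega = 0$.

`tikhonov_reconstruct()` implements the underdetermined form
$\hat{x} = J^T(JJ^T + \lambda\,\max\operatorname{diag}(JJ^T)\,I)^{-1}y$.
Scaling $\lambda$ by the largest diagonal makes the conventional
$\lambda = 10$ scale-free across grid resolutions — without it the same
numeric value would mean different things on different voxel sizes.

## Synthetic meshes: what they emulate

No external dataset is needed: two generators reproduce the geometries the
validation studies use.

* `make_disk_mesh()` — a 2D disk (default 43 mm radius, ~2000 nodes) from
  concentric rings of nodes triangulated by a deterministic angular merge,
  with the standard single-source, 15-detector circumferential layout.
  Ring spacing makes near-equilateral triangles; the polygonal boundary
  area converges to $\pi r^2$ under refinement (tested monotonically).
* `make_slab_mesh()` — a rectilinear tensor-product lattice split into six
  tetrahedra per cell (Kuhn split, conforming across cells, volume exact).
  Plane spacings may be uniform, per-axis, or fully graded via
  `graded_planes()`.

The slab studies (time-resolved moments and DCS at 20 mm source-detector
separation on a 120 x 120 x 60 mm slab, $\mu_a = 0.01$, $\mu_s' = 1$,
$n = 1.37$) use a graded lattice: 0.8 mm planes in a band around the
optode line (x 54-86 mm, y 54-66 mm, z 0-6 mm), stretched geometrically
(ratio 1.3) to a 4 mm cap far away, about 91k nodes. The grading emulates
the adaptive refinement an unstructured mesher provides around sources and
detectors, where the point-source near-field dominates the discretization
error; uniform lattices at the same node budget leave several-percent
moment errors (a spacing sweep is how we chose this layout), while the
graded lattice brings the first three normalized moments within about one
percent of the semi-infinite analytical solution. These phantoms are
homogeneous with matched internal refractive index; passing them validates
the operators, solvers, moment recursions and boundary handling, but says
nothing about heterogeneous media, internal index mismatches, or
low-scattering regions where the diffusion approximation itself fails.

## Analytical oracles

`semi_infinite_fd/tr/dcs()` implement the homogeneous semi-infinite
solutions used for validation: image-source Green's functions under zero
(ZBC), extrapolated (EBC, $z_b = 2\beta\kappa$) and partial-current (PCB)
boundary conditions, the time-domain kernels and the hybrid-flux boundary
reflectance, and the DCS curve by the absorption substitution
$\mu_a \to \mu_a + 2\alpha D_b\mu_s'k_0^2\tau$ (static $\kappa$ and source
depth). The frequency-domain wavenumber is
$k = \sqrt{(\mu_a c - i\omega)/(c\kappa)}$, fixed by dimensional analysis
and the CW limit $\sqrt{\mu_a/\kappa}$; the PCB reflectance uses the
standard complementary error function. PCB integrals use adaptive
quadrature truncated at $40 z_b$, where the integrand's envelope is
$e^{-40}$ of its peak.

One subtlety matters when validating FEM boundary data: the *detected*
time-resolved quantity corresponds to the EBC boundary **reflectance**
(the hybrid-flux expression), not the fluence sampled at $z = 0$. The two
differ by a non-constant factor worth 1-3% in the first three normalized
moments — the same offset that separates the EBC and partial-current
fluences. The Robin-BC FEM converges to the reflectance-based moments
(and to the PCB fluence), so the moment validation compares against the
reflectance curve; both curves are returned.

## Numerical choices and degenerate inputs

* Element orientation is normalized to positive signed volume at
  construction; degenerate (zero-volume) elements are rejected.
* Surface projection distance ties break toward the lowest face index;
  point location accepts barycentric weights down to a small negative
  tolerance so surface detectors land in an adjacent element
  deterministically.
* A displaced source that would exit a thin mesh falls back to the deepest
  interior point along the normal, with a warning.
* FSAI rows with numerically singular local systems drop to diagonal-only
  (warned, counted); a zero right-hand side returns a zero solution in zero
  iterations; BiCGStab restarts once from the current iterate on a
  $\rho$-breakdown before raising an error.
* The DCS delay sweep warm-starts each solve from the previous delay's
  field and rebuilds the (cheap, C++-assembled) preconditioner per delay,
  since the operator's diagonal grows with $\tau$.
* $\tau = 0$ in the fluorescence lifetime kernels is handled exactly
  ($e^{-\Delta t/0} = 0$), not by epsilon-guards.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script run entirely on synthetic
fixtures: disks of a few hundred to ~2000 nodes for operator, solver,
Jacobian and reconstruction properties; the graded ~91k-node slab for the
moment and DCS comparisons (10 ns / 10 ps TPSF spans on the standard disk,
15 ns for fluorescence; 51 log-spaced correlation delays up to 1 ms).
These sizes were chosen as the smallest at which the discretization
error of each quantity is at or below the agreement levels being verified.

## Known limitations

The diffusion model is inaccurate for early photons, low-scattering or
strongly anisotropic media, and near-field measurements; internal
refractive-index mismatches are not modeled (one global boundary $\beta$
from the modal boundary index). Only point sources/detectors are
supported. Higher-order elements, frequency sweeps, noise models and
nonlinear reconstruction are out of scope; `tikhonov_reconstruct()` is a
single linear update intended for difference imaging.
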