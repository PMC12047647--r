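---
title: "Models and methods behind nibsim"
author: "nibsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nibsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nibsim is a desk-scale modeling chain for non-invasive brain stimulation
(NIBS): it builds a synthetic volume-conductor head phantom, solves the
electroquasistatic field problem for scalp electrode montages, plans
temporal-interference (tTIS) exposures by multi-objective optimization,
couples the fields into a Jansen-Rit whole-brain network, projects the
simulated sources to virtual EEG through a reciprocity lead field, and
characterizes the resulting dynamics with dynamic functional connectivity
(DFC) state analysis. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical choices, in the
order the pipeline runs them.

## The synthetic phantom and what it emulates

All inputs are generated by the phantom factory, so no imaging data are
needed. `buildSpherePhantom()` produces nested concentric shells —
scalp, skull, CSF, gray matter, white matter by default — on a
rectilinear voxel grid (right-handed RAS, millimetres, world = origin +
index × spacing at voxel centres). The default radii are 92/86/80/78/70
mm with low-frequency conductivities 0.4, 0.01, 1.8, 0.3 and 0.15 S/m:
representative database-style values with the two dominant contrasts of
the head (resistive skull, highly conductive CSF). The conductivity
table is an input the user can replace, not a result.

Four scalp landmarks (nasion, inion, two pre-auricular points) anchor
`placeElectrodes1010()`. Cz is the crossing of the nasion–inion and
pre-auricular geodesics; the midline and coronal chains subdivide those
geodesics in 10% arc-length steps, the outer ring carries the
Fp1/AF7/…/O1 chain, and intermediate rows interpolate along great-circle
arcs between ring and midline. Because the in-scope phantoms are
spheres, the geodesics are computed in closed form in the
landmark-derived frame; this is exact where a surface-graph shortest
path would only approximate, and is the reason we did not implement a
Dijkstra construction. Electrode pads default to circular 3 cm²
(radius ≈ 9.77 mm) Dirichlet patches.

`tessellateCortex()` places an icosphere (vertex counts 12, 42, 162,
642, 2562, …; requests are rounded up to the next level) on the mid-GM
sphere with outward radial normals. Vertices are assigned to regions by
nearest-seed sectorization with area-uniform seed directions per
hemisphere; `synthConnectome()` uses the same seed directions as region
centroids, so mesh regions and connectome regions coincide by
construction. Connectome weights decay exponentially with Euclidean
centroid distance (`decayMm`, default 40 mm — a typical structural
connectivity decay length), cross-hemisphere connections are scaled by
`interhemisphericScale` (default 0.5), multiplicative log-normal jitter
(sdlog 0.5) adds dispersion, and the matrix is symmetrized, zeroed on
the diagonal and rescaled to unit mean row sum so that the global
coupling constant G is the single knob controlling network input.
Tract lengths are the Euclidean centroid distances.

What the phantom does **not** emulate: gyrified anatomy, tissue
inhomogeneity within a shell, realistic skull layering, and
tractography-derived connection topology. Tests passing on the phantom
therefore validate the algorithms and their couplings, not anatomical
realism.

## Conductivity tensors from diffusion data

`dtiToConductivity()` maps a diffusion-tensor field to conductivity
keeping the eigenvectors and reassigning eigenvalues, either by linear
scaling σᵢ = k·dᵢ (k defaults to 844 S·s/(m·mm²), surfaced in the
configuration and logs rather than hard-coded as truth) or by the
axial/radial database mode (largest eigenvalue → axial σ, the other two
→ radial σ). `clampTensorEigenvalues()` then applies the two-step rule:
(i) eigenvalues above 2 S/m are clamped to 2 S/m; (ii) any eigenvalue
still above c = 3 times the smallest is clamped to that threshold. The
second step uses the minimum found after step (i) and is applied once,
not iterated; clamping to exactly c·min makes the operation idempotent,
which a property test verifies together with rotation equivariance.
`synthFiberTensors()` provides radially oriented prolate test tensors in
the WM shell.

## The electroquasistatic solver

At tES frequencies conduction currents dominate, so the potential obeys
∇·(σ∇φ) = 0 with Dirichlet equipotential electrode patches and zero
normal flux elsewhere. The discretization is a finite-volume scheme on
the voxel grid: two-point fluxes with harmonic-mean face conductivities
for the tensor diagonal (the classical 7-point stencil, an M-matrix for
isotropic σ), plus a symmetric corner-coupling stencil for tensor
off-diagonals obtained as the Hessian of the central-difference
cross-energy σₚq ∂ₚφ ∂qφ. The corner terms are dropped for cells whose
four in-plane neighbours are not all conducting (one cell layer at the
domain boundary); linear potentials in homogeneous anisotropic media are
reproduced exactly away from that layer, which the tests check against
a random SPD tensor. The assembled matrix is symmetric positive
definite and is solved with Jacobi-preconditioned conjugate gradients
(C++, tolerance 1e-8 relative, deterministic). Injected currents are
read off as discrete residual fluxes over the patch cells, which makes
the two patch currents balance to numerical tolerance.

"Floating PEC" electrodes are not implemented: for two-terminal drives,
Dirichlet patches followed by post-hoc rescaling to 1 mA injected
current are equivalent, and that is exactly how `computeFieldBasis()`
normalizes each electrode-vs-reference solve. Pair fields follow by
superposition, `basisField(basis, a, b)`.

`leadFieldReciprocity()` converts the basis into an EEG lead field: one
row per sensing electrode, one column per mesh vertex with a
normal-constrained unit dipole (a free-orientation variant would use
three columns; normal-constrained matches the cortical source model
used by the network). By Green reciprocity, with the basis convention
"electrode driven positive against the reference", the potential read at
electrode e for a dipole p is V = −p·E_e(r)/I_e; the minus sign is part
of the stated convention and is pinned down by an independent oracle in
the test suite: a discrete dipole (two opposite monopoles in adjacent
voxels, pure-Neumann solve gauged by pinning one cell) whose electrode
readings must agree with the reciprocal prediction within 2%.

## Temporal-interference planning

Two sinusoidal channels at nearby kHz frequencies produce a field
sin(ω₁t)E₁(r) + sin(ω₂t)E₂(r) whose low-frequency envelope modulation
is what tTIS exploits. The per-voxel quantity of interest is the
modulation envelope magnitude (MEM): the largest, over spatial
directions n, envelope modulation of the projected two-tone signal,
which has the closed form 2|e₂| if |e₂| ≤ |e₁|cosα, else
2|e₂×(e₁−e₂)|/|e₁−e₂| (after relabeling so |e₁| ≥ |e₂| and flipping e₂
when the angle is obtuse — the MEM is sign-invariant).
`memBruteForce()` is a deliberately independent oracle: it samples unit
directions on a Fibonacci lattice, evaluates the envelope numerically
over a dense grid of beat phases, and polishes the best direction with
Nelder-Mead; closed form and oracle agree to 1e-3 relative on a
thousand random pairs.

`exposureMetrics()` scores a configuration by three objectives:
M1 (strength) — the p-th linear-interpolation percentile (default
p = 50, the median) of the QoI in the target; M2 (selectivity) — mean
target QoI over mean QoI in all non-target brain voxels (we read
"off-target regions" as all non-target brain, consistent with M3's
wording); M3 (collateral) — the fraction of non-target brain above a
threshold, by default the configuration's own M1 ("auto"), with a fixed
global threshold available since either reading is defensible.
`paretoFront()` marks the non-dominated set (maximize M1, M2; minimize
M3; identical triples all stay on the front) and `weightedRank()` scores
configurations with min–max-normalized weighted sums while always
ranking front members above dominated ones — so interactive reweighting
can never promote a dominated montage. `steerCurrents()` redistributes
a fixed total current across the two channels over a ratio grid that
always includes 0.5; the winner therefore never scores below the 50/50
split. For tACS (single channel) the same metrics run on |E|.

## The Jansen-Rit network

Each node is a Jansen-Rit neural mass: three interacting populations
(pyramidal, excitatory and inhibitory interneurons) with second-order
synaptic kinetics and the sigmoid S(v) = 2e₀/(1+exp(r(v₀−v))). The six
states integrate

    y0' = y3;  y3' = A a S(y1−y2+s) − 2a y3 − a² y0
    y1' = y4;  y4' = A a (p(t) + C2 S(C1 y0) + coupling) − 2a y4 − a² y1
    y2' = y5;  y5' = B b C4 S(C3 y0) − 2b y5 − b² y2

with the standard parameters A = 3.25 mV, B = 22 mV, a = 100 s⁻¹,
b = 50 s⁻¹, C1 = 135, C2 = 0.8C1, C3 = C4 = 0.25C1, v₀ = 5.52 mV,
e₀ = 2.5 s⁻¹, r = 0.56 mV⁻¹. The pyramidal potential v_pyr = y1 − y2 is
the model's EEG-generating quantity.

Coupling and noise definitions (these are package conventions, stated
because the plain numbers G = 7 and noise 10⁻⁷ only acquire meaning
under them):

* long-range input = G · Σⱼ wᵢⱼ S(v_pyr,j(t − τᵢⱼ)), delays
  τ = length / conduction speed (3 mm/ms default, configurable),
  rounded to integration steps; the transmitted signal is the firing
  rate S(v_pyr), with the connectome normalized to unit mean row sum;
* surface mode adds an undelayed Gaussian local kernel
  (width 10 mm, amplitude 1, cutoff 20 mm) on great-circle distances,
  while long-range coupling acts at region granularity (region-mean
  rates, region-pair delays);
* additive noise of intensity `noiseSigma` enters the excitatory PSP
  rate state y4 as a per-step increment of standard deviation
  √(2·noiseSigma·dt) in TVB-like mV/ms units, with the same Wiener
  increment used in the predictor and corrector of the stochastic Heun
  ("modified trapezoidal") scheme;
* the mean background pulse density `pMean` defaults to 250 s⁻¹. This
  value is not printed anywhere and had to be fixed once: with the
  v₀ = 5.52 mV sigmoid midpoint the model's input range splits into a
  slow large-amplitude spiking regime (roughly 110–240 s⁻¹, ~3–7 Hz)
  and the characteristic alpha regime above it; 250 s⁻¹ puts the
  uncoupled node at a ~10 Hz limit cycle, which is the α-band baseline
  operating point the chain is documented to reproduce. The tests treat
  the α-band location of the baseline spectrum as the arbiter of this
  convention.

Stimulation couples in as λ·E: the field component along the cortical
normal (the assumed orthodromic axis), scaled by the effective membrane
space constant λ (mm), perturbs the pyramidal membrane potential — the
term s above is added inside every sigmoid that takes v_pyr, both in
the node's own dynamics and in the rate it transmits. Units work out to
1 mV per V/m per mm of λ. Interneuron coupling is deliberately absent
(λ terms for interneurons would be straightforward to add but default
to zero); λ itself is a placeholder of order 1 mm that must be tuned
against measured data for quantitative work, so demonstrations state
their λ explicitly (the tACS demo uses 5 mm to obtain mV-scale
perturbations on the phantom).

Integration uses dt = 0.5 ms by default; the package's convergence test
checks that halving dt changes the 30 s average log-PSD (1–40 Hz) by
less than 5% RMS, mirroring the convergence-based step choice. The
delayed coupling is held over each step (evaluated at the step start
for both Heun stages), a standard simplification that is second-order
in the smooth terms and first-order in the delayed term; the
convergence test bounds its practical effect. Noise draws use R's RNG,
so a seed fully reproduces a run. The first second is discarded as
burn-in. Degenerate inputs fail loudly: non-finite states abort with
the offending step, delays must be nonnegative, and a zero-amplitude
drive is bitwise identical to no drive.

## Virtual EEG and spectra

`projectEEG()` multiplies the lead field into the pyramidal potentials
(region-mode simulations pair with `aggregateLeadField()`, which
averages member-vertex columns). The record is average-referenced by
default — the reference convention is otherwise arbitrary — and the
source scale is a single global constant logged in the output (absolute
EEG magnitudes are not meaningful until λ and the dipole scale are
calibrated). Spectra use a Welch estimator written on `stats::fft`
(Hann window, 2 s segments, 50% overlap, per-segment mean removal,
density scaling): none of the installed packages provides one, and the
estimator is validated by sinusoid-localization and Parseval tests. The
spectrogram is the same periodogram slid over the record, and band
topographies integrate the per-channel PSD over a band (default α,
8–12 Hz) for display against the montage positions.

## DFC state analysis

`slidingFC()` computes Pearson-correlation FC matrices over sliding
windows (10 s, 50% overlap by default; window count
floor((T−L)/(L(1−overlap))) + 1) on the raw pyramidal output — no
band-pass by default, configurable upstream. Constant signals in a
window are an error by design: they carry no correlation information.
`clusterStates()` runs seeded multi-restart k-means on the
upper-triangle vectors (k is the user's choice; `silhouetteScore()`
helps pick it, but no automatic selection is claimed), and
`pcaProject()` gives the mean-centred PCA whose component loadings
reshape back to symmetric FC-space matrices (`pcLoadingMatrix()`) for
interpretation against the connectome's hemispheric block structure.
Fluidity has no canonical formula, so the package reports two proxies:
the state-transition rate per second (primary) and the variance of
pairwise window-FC correlations (secondary).

In the package's baseline demonstration (region mode, fluid-regime time
constants a = 60 s⁻¹, b = 30 s⁻¹, G = 7, noise 10⁻⁷), windowed FC
fluctuates between more and less hemisphere-synchronized patterns, and
the leading two PC loadings weigh cross-hemisphere node pairs more than
a hemisphere-label-permuted null (permutation test, p < 0.05). Only
this block-structure property is asserted: the clean circular PC-space
manifold seen with some template connectomes is tied to their specific
topology and is not expected from the synthetic connectome.

## Problem sizes and design choices in the shipped checks

The shipped tests and the acceptance script choose desk-scale sizes:
slab oracles on ~20×10×10 grids at 2 mm; reciprocity on a 33³ uniform
ball at 4 mm; steering, α-band and tACS checks on a four-shell phantom
at 4 mm with icosphere meshes of 162 vertices; the baseline DFC
demonstration simulates 300 s of the 84-region network (downsampled to
200 Hz for windowing); the acceptance script runs the full default
pipeline (2 mm phantom, 21 electrodes, 84 regions, 30 s analyzed after
burn-in). These sizes are the package's reproducibility compromise:
large enough for the asserted properties to be stable across seeds,
small enough to rerun routinely.

Known limitations, beyond those noted above: spherical geometry only in
the generators (user-supplied NIfTI volumes are accepted but the 10-10
construction assumes sphere-like scalps); no capacitive effects, TMS,
or multi-channel/phase-modulated TI optimization; no plasticity or
BOLD/SEEG forward models; region-granular delays in surface mode; and
the EEG contains projected neural sources only, not the stimulation
artifact itself.
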