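---
title: "Convergence and plasticity diagnostics: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence and plasticity diagnostics: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdconverge)
```

This vignette documents the statistical model behind `mdconverge`, the
meaning and defaults of every tunable parameter, what the synthetic
generators do and do not emulate, and the numerical decisions that shape
the results. It is the reference for anyone interpreting the package's
output or extending it.

## 1. The analysis model

A trajectory is an array of Cartesian coordinates
$x_t \in \mathbb{R}^{n \times 3}$, $t = 1, \dots, T$, over a fixed
topology (atom table plus segment annotation: chain, residue range,
`helix`/`loop` kind). All analyses operate on an `AtomSelection` resolved
against the topology; the default selection is C$\alpha$ atoms in helix
segments, the conventional choice because loop coordinates are noisy and
inflate every RMSD-derived quantity.

The package treats conformational sampling as a hidden-state problem: the
system visits a finite set of metastable basins, and the question
"converged?" becomes "has the cumulative count of discovered basins
$c(t)$ plateaued?". Everything else — RMSD matrices, PCA, RMSF, tICA,
gauges — characterizes the geometry and kinetics of those basins.

### 1.1 Superposition

Rigid-body alignment uses the Kabsch algorithm: with centred mobile and
reference coordinates $A$, $B$ and SVD $A^\top B = U \Sigma V^\top$, the
optimal proper rotation is $R = U \,\mathrm{diag}(1, 1, d)\, V^\top$ with
$d = \mathrm{sign}(\det U \det V)$. The determinant correction excludes
reflections, which are rigid motions mathematically but not physically:
a mirror image of a protein is a different molecule.

`kabsch()` refuses inputs with fewer than 3 atoms or with collinear
selections, where the rotation is not identifiable. RMSD is always
computed by explicitly applying the fitted transform, never from the
singular values, so the same code path serves superposed and
non-superposed (`superpose = FALSE`) distances.

### 1.2 Leader (sequential) cluster counting

Frames are scanned in time order. Frame $t$ is compared against the
current cluster representatives; it joins the *nearest* representative at
superposed RMSD $\le$ `cutoff`, otherwise it founds a new cluster and
becomes that cluster's representative forever. Design points:

* **Nearest, not first-within-cutoff.** First-match assignment depends on
  cluster founding order in a way that has no physical meaning.
* **Representatives never update.** This keeps the pass $O(T \cdot c)$
  and makes $c(t)$ monotone by construction, which is what a discovery
  curve must be.
* **Comparisons are `<=`**, so a frame exactly at the cutoff joins.
* **Plateau time** is the *time stamp* (in ns, from the trajectory's
  `times`) of the frame that founded the last cluster — the moment after
  which nothing new was seen. A single-cluster trajectory plateaus at its
  first frame's time.

The default `cutoff` of 2.0 Å is the community convention for backbone
RMSD sub-state resolution; it is a scientific choice, and the report
records it in its provenance block.

### 1.3 GROMOS (neighbour) clustering

Given the all-to-all RMSD matrix, repeatedly take the frame with the most
neighbours within the cutoff (ties broken toward the lowest frame index,
which makes the algorithm deterministic), remove it and its neighbours as
one cluster, and continue. Unlike leader counting this is retrospective
and order-free, so the two methods cross-check each other: on
well-separated basins they agree on the count.

The all-to-all matrix is $O(T^2)$ in memory; `allToAllRmsd()` refuses
more than `maxFrames` (20,000) frames unless `force = TRUE`, and the
error message suggests `stride`. Strided computation subsamples frames
*before* the pairwise pass, so `values(allToAllRmsd(x, stride = 2))` is
exactly a submatrix of the full matrix.

### 1.4 Cartesian PCA

Coordinates are aligned to the *mean structure* with a two-pass scheme
(align every frame to frame 1, average, re-align every frame to that
average) — a single fixed-frame reference biases the covariance toward
that frame's pose. Aligned frames are flattened to $3n$-vectors in
$(x_1, y_1, z_1, x_2, \dots)$ order, centred, and the *population*
covariance $C = X^\top X / T$ is diagonalized with `eigen(symmetric =
TRUE)`. Consequences of the $1/T$ convention:

* eigenvalues are variances in Å$^2$ and the projection variances match
  them exactly;
* the trace identity $\sum_k \lambda_k = \mathrm{tr}\,C$ holds to
  round-off over the full spectrum, which the test suite asserts at
  $10^{-8}$ relative error.

Each eigenvector's sign is fixed by making its largest-magnitude
coefficient positive, so results are reproducible across LAPACK builds.
Superposition removes 6 rigid-body degrees of freedom, so at least 6
eigenvalues are numerically zero; asking for components beyond the
numerical rank sets `rankDeficient` and warns rather than failing.

### 1.5 RMSF

After the same two-pass mean alignment,
$\mathrm{RMSF}_i = \sqrt{\langle \lVert r_i(t) - \langle r_i \rangle
\rVert^2 \rangle_t}$ per selected atom. For iid isotropic Gaussian
displacement of per-coordinate standard deviation $\sigma$ the exact
value is $\sigma\sqrt{3}$, which is the closed form the harmonic
generator is validated against. `meanRmsfByChain()` averages the profile
within each chain — the single number used when comparing the floppiness
of two variants.

### 1.6 Dihedral tICA

Internal motions are featurized as backbone dihedrals — C$\alpha$
pseudo-dihedrals over sliding windows of four consecutive C$\alpha$
atoms within a segment (`ca_pseudo`, the default, appropriate for
C$\alpha$-only models) or $\phi/\psi$ when N/CA/C backbone atoms exist
(`phi_psi`). Each angle $\theta$ enters as the pair
$(\sin\theta, \cos\theta)$: angles live on a circle, and the embedding
removes the $\pm 180°$ wrap discontinuity that would otherwise dominate
the covariance.

With mean-free features $y_t$, tICA solves the generalized symmetric
eigenproblem
$$\bar C_\tau v = \lambda C_0 v, \qquad
  \bar C_\tau = \tfrac{1}{2}(C_\tau + C_\tau^\top),$$
via whitening: eigendecompose $C_0$, form
$K = C_0^{-1/2} \bar C_\tau C_0^{-1/2}$, and diagonalize the symmetric
$K$. Three choices matter:

* **Symmetrization** of $C_\tau$ enforces real eigenvalues bounded by 1
  in magnitude (detailed-balance estimator). The degenerate check: a
  lag-periodic signal yields eigenvalues exactly 1.
* **$C_0$ averaged over head and tail** frame windows
  ($t \le T-\tau$ and $t > \tau$), the standard finite-sample
  symmetrized estimator.
* **Ridge regularization** `regularization * I` added to $C_0$, default
  $10^{-6}\,\mathrm{tr}(C_0)/p$. The $(\sin, \cos)$ embedding is locally
  rank-deficient for small-amplitude angles, so $C_0$ is routinely
  near-singular; the ridge is scale-aware (proportional to the average
  feature variance) and small enough not to move well-conditioned
  eigenvalues. Exact-invariance tests (remixing features by a random
  invertible matrix must not change eigenvalues) set
  `regularization = 0`.

Eigenvalues are lag-$\tau$ autocorrelations of the corresponding
independent components, so a planted Ornstein–Uhlenbeck mode with
timescale $\tau_0$ appears as $\lambda_1 \approx e^{-\tau/\tau_0}$, and
for pure white noise all $|\lambda|$ are $O(1/\sqrt{T})$. There is no
default lag: the lag *is* the scientific question ("slower than what?"),
so `AnalysisConfig(ticaLag = NA)` makes the report skip the tICA stage
explicitly rather than guess.

### 1.7 k-means in tICA space

States in the slow subspace are found with k-means: k-means++ seeding
(deterministic given `seed`), Lloyd iterations to a relative-inertia
tolerance, and a documented empty-cluster rule — an emptied cluster is
re-seeded at the point farthest from its current centroid assignment.
The inertia history is recorded and must be non-increasing. Each
cluster's *representative* is the real frame nearest its centroid — a
genuine structure from the trajectory, never a synthetic average —
and `extractRepresentatives()` returns those frames aligned to the first
for inspection as a multi-model PDB.

### 1.8 Gauges

A gauge is a scalar observable: the distance between two named atoms
(`"chain:resid:name"`), computed in raw coordinates *without*
superposition — inter-atomic distances are rigid-motion invariant by
construction, and superposing first would only add numerical noise.
`bimodalitySummary()` splits the series at a threshold (`>` is "above")
and reports occupancies and conditional means; `fractionBelow` is
computed as `1 - fractionAbove` so the two sum to one exactly.

### 1.9 The report

`runReport()` runs the seven stages (RMSD series, RMSD matrix, leader
clustering, PCA, RMSF, tICA + k-means, gauges) under one
`AnalysisConfig`, collects a summary, and `writeReport()` serializes
everything: one CSV per stage, representative structures as PDB, and a
schema-validated `report.json` with a provenance block (package version,
seed, config, selection, frame/atom counts and a coordinate checksum).
No timestamps are written, so two runs with identical inputs, config and
seed produce byte-identical output — the property `compareReports()` and
the test suite rely on. A stage can be skipped only explicitly (e.g.
`ticaLag = NA`), and the skip reason is recorded.

## 2. The synthetic generators

Every analysis is validated against data with planted, recoverable
truth. The generators are deliberately minimal: they produce exactly the
statistical structure each analysis claims to detect, and nothing else.

**What they emulate.** A C$\alpha$-only two-chain dimer (two ideal
helices per chain: rise 1.5 Å/residue, radius 2.3 Å, 100°/residue, a
semicircular loop between them) with a tagged inter-chain gauge pair at
an exact requested separation; isotropic harmonic fluctuation; Markovian
hopping between $K$ well-separated conformers; a two-state open/close
gate on the gauge distance; rigid-body diffusion (per-frame uniform
random rotations via quaternions plus uniform translations); and
slow/fast feature sets (one OU process with a chosen correlation time
among unit white-noise features).

**What they do not emulate.** No force field, no solvent, no side
chains, no anharmonicity, no correlated residue motions beyond the
planted modes, no kinetic detail beyond first-order Markov switching.
They are test instruments, not physics.

Design decisions worth knowing when reading results:

* **Metastable states** are smooth sinusoidal offset fields added to the
  template, rescaled so that every pair of state centres is at least
  `rmsdFloor` apart in *superposed* RMSD — the quantity the clustering
  actually sees. The hidden chain is cyclic
  (`cyclicTransitionMatrix(K, switchProb)`): state $k$ steps to $k+1$
  with probability `switchProb`, which guarantees every state is
  reachable and makes the last first-visit time a meaningful plateau
  truth. With `K = 1` no label randomness is drawn, so the generator
  reduces bit-exactly to `simulateHarmonic()` at the same seed.
* **The gate** plants its signal *axially*: the gauge distance is
  $d_{\text{state}} + \sqrt{2}\,\bar\sigma z_t$ with $z_t$ standard
  normal, constructed so that the conditional mean of the distance given
  the hidden state is exactly the planted $d_{\text{open}}$ or
  $d_{\text{closed}}$ — recoverable without selection bias when
  occupancies are estimated at a mid-point threshold.
* **Reproducibility.** All generators run under a helper that pins the
  RNG kind (Mersenne-Twister / Inversion / Rejection) and restores the
  caller's RNG state, so results are bit-reproducible across sessions
  and independent of surrounding code.

## 3. Conventions and limitations

* **Units**: Å for distances, Å$^2$ for variances, ns for times (from
  the trajectory's `dt`). Frame and atom indices are 1-based throughout.
* **Memory**: the RMSD matrix is the only quadratic object and is
  guarded (Section 1.3). Everything else streams frame-by-frame.
* **File formats**: PDB and DCD I/O delegate to `bio3d`; a plain XYZ
  dialect is implemented natively for text-only fixtures. XTC is
  explicitly unsupported with an informative error.
* **Solvent** is stripped by residue name (`stripSolvent()`, default
  `HOH`/`WAT`) before analysis; stripping is idempotent and refuses to
  remove every atom.
* **Statistical bands in the tests** are derived, not tuned: RMSF bands
  from the $\sigma\sqrt 3$ closed form, tICA white-noise bounds of the
  $3/\sqrt T$ form hold per-eigenvalue only at small feature count (the
  acceptance test uses $p = 2$), OU autocorrelation bands use the
  Bartlett large-lag standard error, and occupancy bands are binomial.
* **Not implemented**: periodic-boundary reimaging (only a heuristic
  warning via `checkImagingArtifacts()`), mass-weighted superposition
  (all atoms weigh equally; the model is C$\alpha$-only), error bars on
  eigenvalues, and Bayesian/MSM kinetic models beyond the lag-$\tau$
  autocorrelation interpretation of tICA eigenvalues.

## 4. Choosing parameters in practice

* `rmsdCutoff`: 2.0 Å resolves backbone sub-states; lower it for
  near-degenerate basins, raise it for coarse counting. Sanity-check
  with the degenerate limits (huge cutoff → 1 cluster; tiny cutoff → one
  cluster per frame).
* `ticaLag`: pick a lag shorter than the slowest timescale you want to
  resolve but long enough to suppress fast noise; inspect the eigenvalue
  spectrum for a gap. The package will not choose for you.
* `kmeansK`: start from the leader/GROMOS cluster count.
* `stride`: only affects the RMSD matrix stage; choose the largest value
  that keeps the matrix under the memory guard while retaining several
  frames per expected basin.
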