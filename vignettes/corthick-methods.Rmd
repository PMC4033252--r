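---
title: "Methods: Laplacian streamline thickness and patch-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Laplacian streamline thickness and patch-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corthick)
```

This vignette documents the models, numerical choices and statistical
caveats behind the package, stage by stage. Everything stated here is
computed by the package's own test suite or the worked examples; no
external data are involved.

## 1. The thickness model

Cortical thickness is defined through the harmonic potential
$\psi$ solving Laplace's equation $\Delta\psi = 0$ on the gray ribbon,
with $\psi = 0$ on the white-matter boundary and $\psi = 1$ on the pial
boundary. The field's streamlines connect unique point pairs on the two
boundaries, and thickness at a pial vertex is the Euclidean distance
between the endpoints of the streamline through it — not the arc
length, so curved trajectories are measured by their chord.

**Discretization.** The solver uses the 7-point stencil on the voxel
grid with red–black Gauss–Seidel iteration and successive
over-relaxation (default $\omega = 1.8$, tolerance $10^{-6}$ on the
maximum update, cap 10,000 iterations). Boundary values are imposed at
the *compartment interfaces*, i.e. on the faces between gray and
non-gray voxels, via a half-spacing ghost formulation: a non-gray
neighbour contributes $2\psi_{bc} - \psi_{\text{gray}}$ with weight 2.
The alternative — pinning boundary voxel *centres* — places the
effective boundary half a voxel too far out on each side and biases
every thickness estimate by a full voxel; the interface formulation
removes that bias, which is why a slab phantom of separation $s$ is
recovered exactly and the 5→7 mm spherical shell is recovered within
half a voxel at every vertex (asserted in the test suite). The choice
of boundary values $\{0, 1\}$ is a convention; any affine rescaling
leaves the streamlines unchanged.

For interpolation and tracing, $\psi$ is extended one voxel beyond each
boundary by the same linear extrapolation, so the trilinearly
interpolated field crosses its 0 and 1 levels exactly at the
interfaces.

**Streamline integration.** 4th-order Runge–Kutta on the *normalized*
gradient (so the step size is an arc-length step), default step
$0.2 \times$ voxel spacing, both directions from the start point;
endpoints are located by linear interpolation of $\psi$ along the final
segment. Traces exceeding ten volume diagonals abort (degenerate
field); vertices whose trace fails are flagged on the map rather than
silently dropped. Pial vertices sitting exactly on the $\psi = 1$ level
are nudged a quarter-voxel inward along $-\nabla\psi$ before tracing.

**Accuracy, measured.** On the shell phantom the discrete solution's
dominant error is the staircase representation of the boundary, an
$O(h)$ effect: the spherical mean of $\psi$ at mid-shell deviates from
the closed form
$\psi(r) = (1/r_{in} - 1/r)/(1/r_{in} - 1/r_{out})$
by 0.006 at $h = 0.5$ mm and 0.002 at $h = 0.25$ mm, while pointwise
deviations (worst along grid axes) are roughly tenfold larger. The
acceptance check therefore solves at $h = 0.25$ mm with tolerance
$10^{-3}$ — tighter convergence would chase a discretization error it
cannot reduce — and compares the spherical mean. Thickness errors
shrink monotonically under grid refinement (median error 0.044 → 0.039
→ 0.025 mm for $h$ = 0.5, 0.25, 0.125 on the shell), which the suite
asserts strictly.

## 2. Smoothing on the mesh

Per-vertex maps are smoothed by iterated nearest-neighbour diffusion,
$x \leftarrow x + \lambda A^{-1}(S - D)x$ with $S$ the adjacency, $D$
the degree diagonal and $A$ the barycentric vertex-area diagonal.
Because $S$ is symmetric, the area-weighted total $a^\top x$ is
conserved to machine precision — the property that makes the operator a
diffusion rather than a shrinkage. $\lambda$ is set to $0.45
\min_i(a_i/d_i)$ for explicit-Euler stability. The iteration count for
a target FWHM is derived from the kernel's per-step variance, which is
*calibrated empirically* on the mesh (a few probe impulses, regressing
spread on step count): the closed-form estimate
$(\lambda/a_i)\sum_j \|e_{ij}\|^2$ overshoots by ~20% on
irregular-degree meshes and would bias every kernel narrow. The
resulting empirical FWHM is within 10% of target whenever the kernel is
resolved, i.e. $\sigma$ exceeds about one edge length; below that the
graph cannot represent the kernel and the map is left nearly raw (the
simulated-cohort mesh has ~4.6 mm edges, comfortably resolving the
default 10-mm FWHM). Geodesic-exact Gaussian kernels are out of scope.
Disconnected vertices are left untouched and flagged.

## 3. Synthetic data: what it emulates, and what not

`make_atlas_mesh()` builds two disjoint geodesic spheres (radius 70 mm,
the scale of a human hemisphere) and partitions each into 34 spatially
contiguous labels by seeded k-means — the structure, not the geometry,
of a standard cortical parcellation. `simulate_cohort()` generates

$$ t_{sv} = \mu + b_s + \varepsilon_{sv} - \delta_{\ell(v), g(s)}
   + \gamma\,[\text{scanner}_s = 2], $$

with baseline $\mu = 2.5$ mm (typical adult mean cortical thickness),
subject offset $b_s \sim N(0, 0.15^2)$ (between-subject variation of
mean thickness), vertex noise $\varepsilon$ with SD 0.3 mm smoothed on
the mesh with the same 10-mm kernel the analysis uses (so simulated
maps carry the spatial autocorrelation the statistics will see),
implanted label-wise thinning $\delta$, and an optional scanner offset
$\gamma$ (default 0, mirroring a two-scanner design with near-even
assignment within each diagnostic class). The default group sizes are
42 normal controls, 38 single-domain and 32 multi-domain amnestic MCI.
The magnitudes of real group effects in mm are not published for such
cohorts; the defaults here are free parameters of the generator, fixed
once, not estimates of any real sample. Values are floored at 0.05 mm;
with the default scales the floor is provably inert.

What the phantoms and cohorts do **not** emulate: folded cortical
geometry (partial-volume and deep-sulcus effects), registration error,
bias fields, motion, longitudinal change. Passing tests therefore
validate the *algorithms* under the stated statistical structure, not
performance on real MRI.

## 4. Group statistics

Vertex-wise pooled-variance two-sample $T$ (positive = first group
thicker); the identical routine ranks classifier features, so the two
stages cannot diverge. Cluster-level control replaces random-field
theory with a permutation maximal-cluster-mass test: threshold $|T|$ at
a two-sided vertex $p < 0.001$ (configurable; the cluster-forming level
is a declared choice, not an inference), take edge-connected components,
score each by mass $\sum |T|$ (extent available), and compare against
the permutation distribution of the *maximal* mass under group-label
exchange, $p = (1 + \#\{\max \ge m_{obs}\})/(B + 1)$. This is
assumption-lighter than random-field theory, exact under
exchangeability, and independently testable — the suite checks both
detection of an implanted 0.8 mm effect and family-wise error control
on null cohorts. Significance is strict ($p < \alpha$); permutation
$p$-values can equal 1, so every suprathreshold cluster is still
*reported*, sorted by corrected $p$. Tests are two-sided; the group
comparison is deliberately unadjusted for covariates.

## 5. Features and classification protocol

Each label is split into $k = 10$ patches by k-means on vertex
coordinates (10 restarts under a fixed seed; cluster indices are
relabelled by centroid order so feature columns are reproducible).
Labels with fewer than $k$ vertices fall back to one patch per vertex;
the generator guarantees $\ge 10$ vertices per label so the canonical
atlas always yields $34 \times 10 \times 2 = 680$ features. Patch means
are unweighted vertex averages. An optional step regresses a binary
scanner indicator out of every feature column (ordinary least squares;
residuals equalize the scanner means exactly).

The classification protocol handles class imbalance by construction:
each of 250 repetitions draws $\lfloor 0.5 \times \text{smallest
class}\rfloor$ subjects *from each class* for training — training sets
are exactly balanced — and tests on all remaining subjects. Inside each
repetition, and only there, features are z-scored with training
statistics and the top $K = \lfloor N/10 \rfloor$ features by $|T|$ are
selected; test rows never touch scaling, ranking or fitting (a
deliberately leaky variant that ranks once on all data exists behind
`select_on_all = TRUE`, for comparison only). The SVM is an RBF-kernel
C-classifier over the full $7 \times 10$ grid; decision scores are
oriented by training-set class means, and ACC/SPEC/SENS use the
classifier's native threshold 0 (no threshold is published for the
reference protocol; 0 is the canonical choice). The best model is the
grid point with the highest mean *test* AUC — the optimistic selection
the reference protocol uses; nested selection is intentionally not the
default. Exact ties resolve to smaller C, then smaller $\gamma$.

## 6. Evaluation, and the caveats that matter

ROC curves use the standard threshold sweep with simultaneous steps at
tied scores; AUC is the trapezoidal area and provably equals the
Mann–Whitney pairwise count with ties at ½ (asserted against a
brute-force oracle and against pROC). Curves are averaged vertically on
a 101-point FPR grid (population SD per grid point). The AUC-vs-chance
test is the Wilcoxon signed-rank of AUC − 0.5, one-sided; the "rank-sum
against a constant" reading is available as a flag but is formally a
one-sample problem.

Two statistical caveats are measured, not assumed, by this package's
null experiments:

1. **Repetition AUCs are dependent.** All repetitions share one cohort.
   A chance global thickness offset between the two groups (from the
   subject-level offsets $b_s$; SD $0.15\sqrt{2/40} \approx 0.034$ mm
   for two groups of 40) shifts *every* feature coherently, so the
   cohort's conditional mean AUC sits a random distance from 0.5 —
   measured cohort-level SD ≈ 0.03 across null cohorts, with the
   across-cohort mean unbiased at 0.499. Consequently (i) the
   repetition-level standard error drastically understates the
   variability of the mean AUC, and a "within 3 SE of chance" check on
   a single null cohort fails for most seeds even though nothing leaks;
   and (ii) the signed-rank test, which assumes independent samples, is
   strongly anticonservative on repetition AUCs (measured type-I ≈ 0.25
   at nominal 0.05 over 200 null experiments). The same test is
   perfectly calibrated on independent null AUC samples (also asserted).
   Reported $p$-values against chance should therefore be read as
   descriptive for a fixed cohort, not as population-level inference.
2. **Best-model selection is optimistic.** Choosing the grid point by
   test AUC adds a small positive bias (~0.01–0.02 over 70 highly
   correlated combinations at these sizes) on top of the cohort effect.

## 7. Problem sizes and determinism

Test-suite and example sizes were chosen as desk-scale defaults:
2,562-vertex hemispheres for full-atlas work, 162-vertex hemispheres for
statistical calibration loops, shells up to $h = 0.125$ mm for the
refinement study, 250 repetitions for headline experiments and 25 for
calibration sweeps. Every stochastic stage takes an explicit seed and
restores the caller's RNG state; identical inputs give bit-identical
potentials, splits, scores and manifests (`run_all()` writes per-file
checksums to prove it). On-disk formats are plain text (ASCII PLY, TSV,
JSON) plus NIfTI volumes, all with 0-based vertex indices and mm units.
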