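---
title: "Separating ligand unbinding pathways from biased MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating ligand unbinding pathways from biased MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsep)
```

## The problem

Enforced ligand unbinding simulations — targeted MD (TMD), where a
distance constraint moves the ligand's center of mass strictly linearly,
`x(t) = x0 + v t`, and steered MD (SMD), where a harmonic spring of
stiffness `k` lets `x(t)` fluctuate around `x0 + v t` — produce ensembles
of trajectories that leave the binding site along different exit routes.
Grouping trajectories by route ("pathway") matters twice over: pathways
are mechanistic observables in their own right, and mixing routes with
different friction inflates the dissipative-work correction in
free-energy estimates from nonequilibrium work (see *Free energies* below).

`pathsep` represents each trajectory by its ligand–protein contact
distances: residues whose Cα comes within 0.45 nm of any ligand atom in
any frame are contacts, and the feature at `(t, m)` is the minimal
heavy-atom distance (nm) between the ligand and contact residue `m` at
time step `t`. A trajectory is thus a `K × M` matrix; an ensemble is `N`
such matrices sharing the contact set (with possibly different `K`).

## Preprocessing

Three optional transforms are applied in a fixed order — smoothing, then
normalization, then PCA — matching how their effects compose:

* **Gaussian smoothing** (`gaussian_smooth`): per-column convolution with
  a normalized Gaussian kernel of standard deviation `sigma` frames,
  truncated at ±`sigma`. At the series edges the truncated kernel is
  renormalized over the available frames rather than padding: padding
  would fabricate data at exactly the trajectory ends, where the bound
  and unbound states sit. A `truncate` argument widens the window (e.g.
  the common 4-sigma truncation) for comparison; the narrow window is the
  default because the kernel width, not the tail, carries the filtering
  effect at these sigma values (2–10 frames).
* **Time-resolved normalization** (`time_normalize`): each element is
  divided by its mean over the ensemble at fixed `(t, m)`, so the
  ensemble mean of every element becomes exactly 1. This counteracts the
  unbounded growth of all distances during free diffusion after exit,
  which otherwise dominates every measure. It requires equal `K` and
  strictly positive element means (guarded at `1e-12`); it is *not*
  idempotent — renormalizing a normalized ensemble rescales again by the
  new (unit) means' sampling fluctuations — so the contract tested is the
  mean-one property, not idempotence.
* **Contact PCA** (`fit_pca` / `project_pca`): eigendecomposition of the
  contact covariance pooled over all trajectories and time steps
  (population divisor `N·K`). The projection is unitary, so the full-rank
  projection preserves all pairwise frame distances; components 1–4 are
  the conventional reduced subspace. PCA consumes whatever the preceding
  steps produced — the chain is explicit in `preprocess_config`, never
  guessed. Projections are computed on centered data (the means are part
  of the fitted model); since every downstream measure is either
  translation-invariant in feature space or centers its input, this
  convention changes no similarity value.

## Similarity measures

Four pairwise distances, spanning a range of sophistication:

* **Mean Euclidean** (`mean_euclidean`):
  `d_E = ⟨ ||p_t − q_t|| ⟩_t`, the per-frame feature-space distance
  averaged over time. Requires equal, aligned `K`. The per-frame distance
  is not divided by `M` (the literal definition); this affects only the
  overall scale, which the similarity transform removes.
* **Dependent DTW** (`dtw_dependent`): dynamic program over the `K × K'`
  grid accumulating *squared* per-frame Euclidean costs with
  steps (−1,−1), (−1,0), (0,−1), boundary (1,1)→(K,K′). The returned
  value is the square root of the minimal cumulative cost, keeping nm
  units and matching common DTW tooling; the raw cost is available via
  `squared = TRUE`. No band constraint is applied (none is standard for
  this application); DTW is not a metric (triangle inequality fails) but
  tolerates nonlinear time misalignment.
* **Procrustes disparity** (`procrustes_distance`): both matrices are
  column-centered and scaled to unit Frobenius norm, then superimposed by
  the optimal orthogonal map (reflections allowed) and scaling from the
  SVD; the disparity is the residual sum of squares, in [0, 1]. This is
  the standardized-matrix convention of the widely used implementations
  rather than the raw Frobenius minimum, so values are comparable across
  pairs. Because the cost of the underlying SVD grows steeply with `K`,
  trajectories are downsampled to every 5th frame by default
  (`stride = 5`), which leaves the similarities essentially unchanged.
* **Summed 1-D Wasserstein** (`wasserstein_distance`): each contact
  column is treated as an empirical distribution over sampled distances
  (uniform weights `1/K`, time order discarded); the order-1 Wasserstein
  distance is computed per contact by integrating `|F_p − F_q|` over the
  pooled support and summed over contacts. A true metric, invariant to
  time permutation, valid for unequal `K`.

`distance_matrix` evaluates all `N(N−1)/2` pairs (pure functions, so
evaluation order is irrelevant) and `to_similarity` maps distances
affinely onto similarities, `s_ij = 1 − d_ij / d_max`, giving unit
diagonal and zero at the most dissimilar pair.

## Clustering and scoring

The similarity matrix is clustered as a *fully connected* weighted graph
— no similarity cutoff; the Constant Potts Model presupposes that every
pair contributes — with the Leiden algorithm maximizing

    Phi_CPM = sum_c [ e_c − gamma · C(n_c, 2) ]

where `e_c` sums intra-cluster similarities and `gamma` is the
resolution. `leiden_cpm` runs 10 restarts from seed-derived random
states and keeps the partition with the best objective as recomputed by
the package's own `cpm_objective` evaluator, which is authoritative over
whatever backend performed the search; results are deterministic for a
fixed seed. Candidate resolutions come from the similarity distribution
itself (`select_gamma`): the median `Q2`, third quartile `Q3`, or their
mean. Quantiles use linear interpolation between order statistics
(R type 7) over the off-diagonal upper triangle — self-similarities are
not pairwise similarities and are excluded. Clusters of five or fewer
trajectories are reported together under a reserved `"?"` label
(`group_small_clusters`); cluster ids are contiguous `"1", "2", ...` in
decreasing size order.

Clusterings are scored against ground truth with normalized mutual
information (`nmi`): `MI / ((H(K) + H(C))/2)` in natural log, with the
conventions that two zero-entropy partitions score 1 and exactly one
scores 0. The `"?"` group is kept as a single cluster when scoring (it
is reported as one group); `drop_question = TRUE` excludes its members
instead, since either choice is defensible and they can differ.

## Free energies (dcTMD)

For constraint (TMD) pulling, the work `W(x) = ∫ f_c dx'` over `N`
realizations yields the free energy through the second-order cumulant
expansion of the Jarzynski equality,

    dG(x) ≈ ⟨W(x)⟩ − ⟨δW(x)²⟩ / (2 k_B T),

exact for Gaussian work distributions. The correction term is the
dissipative work `W_diss`. `free_energy` uses the unbiased (`N−1`)
variance estimator by default — standard for small-`N` cumulant
estimates, with the biased divisor as a flag. Temperature is a required
input, never assumed. `pathwise_free_energy` applies the estimator per
cluster, skipping `"?"` and any cluster below `min_cluster_size`
(default 100, the practical minimum for a converged variance);
`work_normality_diagnostics` provides Q–Q data and Shapiro–Wilk
statistics to judge the Gaussian-work assumption, without automatic
rejection. Work curves must share a grid; resampling is never done
silently. The estimator is documented for the constraint protocol, where
`x` and `t` are rigidly linked; in restraint pulling the mapping of work
onto `x` is protocol-dependent and out of scope.

Mixing routes inflates `W_diss`: the merged variance adds the
between-route spread of mean work to the within-route variance, which is
why pathway separation precedes free-energy estimation.

## The synthetic generator

`generate_ensemble` emulates the pulling kinematics on a point ligand:

* displacement along the pathway direction `u` is exactly `v·t`
  (constraint) or an exact discrete-time Ornstein–Uhlenbeck process
  around `v·t` with stationary variance `k_B T / k` (restraint) — the
  exact OU update, not an Euler scheme, so the statistics are
  independent of the frame spacing;
* perpendicular to `u`, a Gaussian random walk whose increments are
  scaled so the accumulated excursion reaches standard deviation
  `lateral_sigma` (per axis) at the final frame — `lateral_sigma` is the
  scale of the total lateral drift, not a per-step rate, which keeps
  "moderate" lateral noise moderate regardless of `K`;
* contact features are distances to 20 fixed pseudo-residue anchors
  drawn uniformly from a spherical shell of radius 1–3 nm around the
  binding site (a fixed sub-seed keeps the layout shared across
  scenarios of the same seed), plus `N(0, noise_sigma)` measurement
  noise floored at zero.

Defaults chosen once for the whole package: `v = 0.01` nm/ps with
`dt = 1` ps and `K = 200` frames — a 2 nm pull, emulating ~1 m/s
constant-velocity pulling over a typical unbinding distance at a reduced
frame count; `x0 = 0.5` nm; `T = 300` K; `spring_k = 1000` kJ/mol/nm²
(the customary SMD constant, giving ~0.05 nm positional fluctuations);
OU relaxation `tau = 5` ps; start-offset spread 0.02 nm;
`noise_sigma = 0.05` nm and `lateral_sigma = 0.1` nm as the moderate
noise condition. The presets `A_like` (directions (1,1,0) and (1,−1,0),
90° apart), `B_like` ((1,0,1) and (1,−1,0), 60°) and `C_like` (all
three) realize increasing overlap; labels are the direction tuples.

`generate_work_ensemble` realizes the Gaussian-work generative model
`W_i(x) = dG(x) + W_diss(x) + η_i(x)` with independent Gaussian
increments whose cumulative variance is exactly `2 k_B T W_diss(x)`
(hence `W_diss` must be nondecreasing), so `free_energy` recovers the
generating profile up to quantifiable sampling error.

**What the generator does and does not emulate.** It reproduces the
kinematic difference between constraint and restraint pulling,
direction-dependent contact geometry, and calibrated Gaussian work
statistics. It does not produce protein flexibility, contact formation
and breaking (saturating minimal distances), solvent or membrane
effects, or realistic contact counts (20 anchors versus >100 residues in
real systems). Passing tests therefore demonstrate correctness of the
machinery and recoverability under the generative model — not clustering
performance on real MD data.

### A known limitation worth stating plainly

On this generator's isotropic anchor shell the two pathways of the
`A_like` preset are approximately *mirror-exchangeable*: reflecting the
anchor set across the bisector plane of the two directions maps one
bundle's contact curves onto (a relabeling of) the other's. Procrustes
analysis optimizes over all orthogonal maps of contact space — and
column permutations and reflections are orthogonal — so it aligns the
two bundles almost perfectly: the noise-free between-pathway disparity
is ~0.003, below the within-pathway jitter floor, and Procrustes-based
clustering fails to recover the planted pathways (NMI ≈ 0.03–0.8
depending on seed) while Euclidean, DTW and Wasserstein measures recover
them exactly (NMI = 1) on every seed tested. Concentrating the anchors
near one pathway breaks the symmetry and restores Procrustes NMI = 1.
Real contact sets have no such symmetry — residue identities anchor the
feature space — so this is a fidelity limit of the synthetic benchmark
for rotation-invariant shape measures, and independently a reminder that
Procrustes' invariance to feature-space rotations discards physically
meaningful information (which residue is which) that the other measures
retain.

## Numerical choices

* Contact cutoff comparison is inclusive (`≤ 0.45` nm) — conventional,
  and the boundary has measure zero.
* Units fixed throughout: nm, ps, kJ/mol; K (temperature);
  `kB = 0.008314462618` kJ/(mol·K).
* Residues are identified as `"chain:resnum"` with 1-based numbering.
* Zero-variance columns, degenerate (constant) trajectories, all-zero
  distance matrices, non-increasing grids and unequal-length inputs to
  aligned-only operations all raise immediate, named errors rather than
  propagating NaN.
* Ensembles are stored as plain text: one CSV per trajectory plus a
  manifest TSV (`%.17g`, lossless for doubles); matrices as square CSV
  with `#` provenance comments; partitions as TSV with metadata header
  lines.
* Test problem sizes: oracle comparisons use hundreds of random
  instances with `K, K' ≤ 8` (exhaustive DTW path enumeration),
  `N ≤ 8` (exhaustive partition enumeration over all Bell(N) set
  partitions), and `n = 1000` work curves; the end-to-end benchmark uses
  2 × 40 trajectories with `K = 200` and 20 contacts.

## Limitations

Beyond the generator-fidelity point above: minimum-image/periodic
boundary handling is not performed (coordinates must be whole and
unwrapped); hydrogens are ignored by construction; independent
(per-feature) DTW, Hausdorff and Fréchet metrics, and alternative
clustering objectives are out of scope; reading MD trajectory formats
directly (XTC/TRR) is left to established readers — the package consumes
coordinate arrays or precomputed contact tables.
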