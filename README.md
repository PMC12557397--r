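# pathsep

Unsupervised separation of ligand **unbinding pathways** from ensembles of
biased molecular dynamics trajectories, with per-pathway free-energy
profiles.

## Who this is for

Computational biophysicists running enforced-unbinding simulations —
constant-velocity constraint targeted MD (TMD) or harmonic-restraint
steered MD (SMD) — who need to sort tens to hundreds of trajectories into
the exit routes ("pathways") the ligand actually took, without knowing the
number of routes in advance. Pathway-pure trajectory clusters are also the
prerequisite for dissipation-corrected free-energy estimates, because
mixing routes with different friction inflates the dissipative work.

## What it computes

Each trajectory is encoded as a `K × M` matrix of ligand–protein contact
distances (residues whose Cα comes within 0.45 nm of any ligand atom in
any frame; features are minimal heavy-atom distances, in nm). The package
then:

1. optionally preprocesses (Gaussian temporal smoothing σ, time-resolved
   normalization n_t, global standardization, contact PCA);
2. computes pairwise trajectory distances under one of four measures —
   mean Euclidean `d_E = ⟨||p_t − q_t||⟩_t`, dependent dynamic time
   warping (squared per-frame costs on the `K × K'` grid, square root of
   the minimal cumulative cost), Procrustes disparity (residual after
   optimal translation/scaling/orthogonal map of the standardized
   matrices, every 5th frame), or the summed per-contact 1-D Wasserstein
   distance — and converts them to similarities `s_ij = 1 − d_ij/d_max`;
3. clusters the fully connected similarity graph with the Leiden
   algorithm under the Constant Potts Model,
   `Φ_CPM = Σ_c [e_c − γ·C(n_c,2)]`, with the resolution γ taken from the
   similarity quantiles (Q2, Q3 or their mean) and clusters of ≤ 5
   members grouped under `"?"`;
4. scores clusterings against ground truth with normalized mutual
   information, `NMI = MI/[(H(K)+H(C))/2]`;
5. estimates per-pathway free energies from constraint-pulling work
   curves via the second-order cumulant expansion of the Jarzynski
   equality, `ΔG(x) ≈ ⟨W⟩ − ⟨δW²⟩/(2 k_B T)`, with Gaussian-work
   diagnostics.

A synthetic generator (`generate_ensemble`, `generate_overlapping_sets`,
`generate_work_ensemble`) emulates constraint/restraint pulling along
chosen Cartesian directions with ground-truth labels and calibrated
Gaussian work ensembles; it is the package's test bed.

## Worked example

```r
library(pathsep)

# two pulling directions 90 degrees apart, 20 restraint trajectories each
ens <- generate_overlapping_sets("A_like", seed = 42, n_per_direction = 20)
ens
#> trajectory_ensemble: N = 40 trajectories, M = 20 contacts, K in [200, 200]
#>   labels: (1,-1,0) x 20, (1,1,0) x 20

s <- to_similarity(distance_matrix(ens, "wasserstein"))
gamma <- select_gamma(s, "Q2")          # median pairwise similarity: 0.1304
p <- group_small_clusters(leiden_cpm(s, gamma, seed = 42))
p
#> pathway_partition: 40 trajectories, 2 clusters (gamma = 0.1304, objective = 306.7)
#>   sizes: 1:20  2:20
#>   small clusters (size <= 5) grouped under '?'

score_clustering(p, ens$labels)
#>   nmi        mi h_predicted   h_truth  n
#> 1   1 0.6931472   0.6931472 0.6931472 40
```

The two clusters of 20 are exactly the two pulling directions: NMI = 1
means perfect agreement with the ground truth (both partitions have
entropy log 2 ≈ 0.693 nats, all of it shared). With overlapping presets
(`"B_like"`, `"C_like"`) or higher noise the NMI drops below 1 and the
`"?"` group collects fragmented trajectories.

Free energies from work curves, per cluster:

```r
x  <- seq(0, 2, length.out = 51)                       # pulling coordinate, nm
we <- generate_work_ensemble(function(x) 40*x - 12*x^2,  # true dG (kJ/mol)
                             function(x) 6*x,            # dissipative work
                             temperature = 300, n = 300, x_grid = x, seed = 42)
free_energy(we)
#> free_energy_profile: 51 grid points, N = 300 trajectories
#>   dG range [0, 33.5] kJ/mol, max W_diss = 11.6 kJ/mol
# per-pathway: pathwise_free_energy(we, p, min_cluster_size = 100)
```

The recovered profile tracks the generating `ΔG(x) = 40x − 12x²`
(maximum 33.3 kJ/mol) within sampling error; `W_diss` at the endpoint is
~12 kJ/mol as generated.

A thin command-line front end is included at `inst/cli/pathsep.R`
(subcommands `run`, `synth`, `distances`, `cluster`, `score`, `dctmd`),
driven by a YAML `run_config`; `run_pipeline()` is the same workflow as a
function.

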