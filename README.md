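# connectoscope

Whole-brain **structural connectome** analysis in R: from per-subject
streamline-count matrices over a labeled region atlas to thresholded
weighted networks, graph-theoretical measures, community and hub taxonomy,
and group-level statistical inference.

The package targets the standard diffusion-tractography study design in
clinical neuroimaging — for example, comparing patients with task-specific
focal dystonias (writer's cramp, laryngeal dystonia) against healthy
controls — where each subject contributes a symmetric count matrix of
reconstructed white-matter streamlines between all pairs of 116 atlas
regions, and the scientific questions are: is the community architecture of
the network reorganized, are hubs gained, lost or downgraded, and which
nodes differ between groups?

Because individual-level neuroimaging data from such studies are rarely
shareable, the package includes a first-class **synthetic cohort
generator** with planted ground truth (community structure, hub
architecture, group effects, clinical correlations), so every stage of the
pipeline is testable against known truth.

## The pipeline

1. **Network construction** (`normalize_streamlines()`,
   `proportional_threshold()`, `prune_weak()`, `group_average()`):
   streamline counts `c_ij` are normalized by target-mask voxel counts,
   `w_ij = (c_ij/v_i + c_ij/v_j)/2`; every network is rescaled by the
   maximum edge weight pooled across the cohort; each network is
   proportionally thresholded to 50% density beginning with the weakest
   links; the bottom 10% of weakest edges is then removed per network.

2. **Graph measures** (`global_metrics()`, `nodal_metrics()`):
   - integration: characteristic path length
     `L = mean_{i<j} d(i,j)` and global efficiency
     `E = mean_{i<j} 1/d(i,j)`, with shortest paths on the
     connection-length matrix `1/w`, normalized by total weights;
   - segregation: Onnela weighted clustering coefficient
     `C_i = Σ_{jh} (ŵ_ij ŵ_ih ŵ_jh)^{1/3} / (k_i(k_i−1))`;
   - nodal influence: degree `k_i`, strength `s_i`, betweenness
     centrality `b_i` normalized by `(n−1)(n−2)`.

3. **Communities and hubs** (`louvain_partition()`, `identify_hubs()`,
   `module_migration()`, `compare_hubs()`): multi-iteration (n = 100)
   Louvain modularity maximization with consensus clustering; modularity
   `Q = Σ_c [W_c/W − (S_c/2W)²]` (Q ≤ 0.3 indicates a random-like
   network); hubs are nodes with degree or strength ≥ network mean + 1 SD,
   classified by participation coefficient
   `PI_i = 1 − Σ_m (κ_im/k_i)²` into provincial (PI ≤ 0.3) and connector
   (0.3 < PI ≤ 0.75) hubs; module migration and hub gain/loss/status
   change are quantified between group-level networks.

4. **Group inference** (`anova_global()`, `permutation_test()`,
   `spearman_correlation()`, `demographics_compare()`): split-plot ANOVA
   over the three global metrics; nodewise label-permutation tests
   (10,000 iterations, p ≤ .016 = .05/3) reporting the standard
   difference score (SDS, difference of group means); Spearman clinical
   correlations; t/Fisher demographic tables.

## Worked example

```r
library(connectoscope)

cfg <- pipeline_config(
  cohort = cohort_config(groups = c(controls = 16L, LD = 17L, WC = 15L),
                         seed = 7L),
  louvain_iterations = 100, n_perm = 2000, seed = 7L)
report <- run_pipeline(cfg)
report
#> <connectome_report>
#>   groups: controls=16, LD=17, WC=15
#>   group densities: controls=0.340, LD=0.340, WC=0.340
#>   modules: controls=5, LD=5, WC=5
#>   significant nodal differences: 34
```

All three group-averaged networks sit near the ~30% density typical of
mammalian connectomes, and consensus Louvain recovers the five planted
neural communities in every group. The global metrics do not differ
between groups (as designed — the planted effects are nodal):

```r
report$anova
#> <anova_global> split-plot ANOVA (group x metric)
#>         effect df_num df_den   f_value          p
#> 1        group      2     45 1.218e+00  3.055e-01
#> 3 group:metric      4     90 1.218e+00  3.089e-01
```

The nodewise permutation tests recover the planted effect at the right
supplementary motor area in the LD group (degree and strength increased
relative to controls):

```r
subset(report$significant_nodes, node == "Supp_Motor_Area_R",
       c(group, metric, mean_a, mean_b, sds, p))
#>     group   metric mean_a  mean_b    sds      p
#> 20     LD   degree 35.000 32.7500 2.2500 0.0030
#> 136    LD strength  1.641  1.3457 0.2948 0.0005
```

`mean_a`/`mean_b` are the patient/control group means, `sds` their
difference (the standard difference score), and `p` the two-sided
permutation p-value at the .016 significance level.

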