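# seroreact

Analysis pipeline for multiplexed suspension bead-array (xMAP) serum
autoantibody profiles measured against a curated antigen panel in an
exfoliative-glaucoma cohort, for researchers relating antibody reactivity
to clinical eye parameters (IOP, CCT, SE, visual-field indices, ...).

The package covers the full chain:

* **Pre-processing** — empty-well background estimation
  (mean + 1 SD), subtraction with floor-at-zero and +1 offset, clinical
  metadata join with exclusion reporting, robust spline normalization
  (rank-invariant, offset-concordant, hierarchically shrunk monotone
  maps), and per-antigen Box-Cox variance stabilization with
  profile-likelihood λ.
* **Association screening** — Spearman ρ of every antigen against every
  numeric clinical parameter with t-approximation p-values and
  Benjamini–Hochberg q-values; distance-based PERMANOVA
  (pseudo-F = ((SS<sub>T</sub> − SS<sub>W</sub>)/(a−1)) / (SS<sub>W</sub>/(N−a)) on Euclidean
  distances, permutation p with the +1/(n+1) convention) for categorical
  parameters; per-antigen permutation t-tests (Welch statistic) for
  significant categories.
* **Stratification & co-reactivity** — complete-linkage Euclidean
  clustering of patients into high/intermediate/low reactivity tiers,
  within-tier re-screening with zero-variance filtering, patient-scaled
  antigen–antigen Spearman correlation, and size-constrained antigen
  cluster extraction (eligible sizes 3–20).
* **Network analysis** — STRING-style edge lists filtered at
  strength > 0.15 (strict), and exact shortest-path recurrence counts
  R(v), R(e): for each unordered seed pair, the number of distinct
  hop-count shortest paths through every node and edge, computed by
  products of BFS path counts (σ<sub>sv</sub>·σ<sub>vt</sub> when
  d<sub>sv</sub> + d<sub>vt</sub> = d<sub>st</sub>) with per-pair conservation identities
  asserted.  Highly recurrent non-seed nodes are the "bridge"
  intermediaries connecting a seed set.
* **Synthetic cohorts** — `simulate_bead_array()` generates MFI plates,
  clinical tables and interaction graphs with planted, recorded ground
  truth (reactivity tiers, antigen–clinical correlations via a Gaussian
  copula on emitted ranks, co-reactive blocks, zero-variance antigens,
  bridge nodes), so every stage is testable without the original serum
  data.

## Worked example

```r
library(seroreact)

cfg <- sba_config(rng_seed = 7)      # the study-scale defaults
ds  <- simulate_bead_array(cfg)
ds
#> Synthetic bead-array dataset
#>   plate: 129 wells x 96 analytes (4 empty wells, 4 controls)
#>   clinical: 116 patients, 20 parameters
#>   graph: 60 nodes, 228 edges, bridges: BRG01

nm <- preprocess_plate(ds$plate, ds$clinical)
nm
#> Normalized reactivity matrix
#>   116 patients x 92 antigens (9 samples excluded at join, 0 antigens removed)
#>   - background: empty-well mean + 1 SD = 130.231
#>   - corrected: max(MFI - background, 0) + 1
#>   - join: 9 samples excluded (PAT008, PAT015, PAT031, PAT042, PAT066)
#>   - variance filter: removed 0 antigens
#>   - normalization: rsn
#>   - box-cox: offset 0, lambda in [-0.749, 0.657]
```

The 125-sample plate loses the 9 patients without clinical rows; the
background estimate sits one SD above the simulated 120-MFI plate
background.  Screening the normalized matrix against the derived clinical
variables:

```r
assoc <- spearman_screen(nm$values, transform_clinical(nm$clinical))
se <- assoc[assoc$parameter == "SE", ]
head(se[order(se$q + se$p * 1e-9), ], 4)
#>      antigen parameter        rho            p          q n_used
#> 279   PRT002        SE  0.3730212 3.724839e-05 0.02227453    116
#> 277   PRT001        SE  0.3400607 1.878308e-04 0.07488189    116
#> 286 PRT005_2        SE -0.2230808 1.608202e-02 0.87335145    116
#> 362   PRT061        SE  0.2097567 2.382839e-02 0.89172535    116
```

The two strongest spherical-equivalent associations are planted antigens
(`ds$truth$planted_assoc` records targets 0.3 and realized values 0.37 and
0.35 for this draw); q-values are BH-adjusted over the full
92 × 13 antigen–parameter family.  Stratifying patients on the corrected
log2 matrix:

```r
bg <- estimate_background(ds$plate)
jn <- join_clinical(subtract_and_floor(ds$plate, bg), ds$clinical)
cluster_patients(log2(jn$values), k = 3)
#> Patient stratification: 3 clusters (complete linkage, euclidean distance)
#>   high         n = 35   mean reactivity 9.492
#>   intermediate n = 45   mean reactivity 8.983
#>   low          n = 36   mean reactivity 8.443
```

— the planted 35/45/36 tier structure, recovered exactly in this draw.
Finally, bridge-node analysis over the antigens most positively
correlated with SE:

```r
seeds <- seed_from_associations(assoc, "SE", k = 10)
rep_  <- shortest_path_recurrence(filter_graph(ds$graph, 0.15), seeds)
rep_
#> Shortest-path recurrence over 9 seeds (36 pairs, 0 unreachable)
#>   top intermediaries: BRG01 (90), PRT047 (53), PRT015 (43), PRT058 (27), PRT024 (18)
#>   seeds missing from graph: PRT061
```

The planted bridge node dominates the recurrence ranking (it lies on all
90 cross-community shortest paths), and a seed protein absent from the
graph is reported rather than silently dropped.

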