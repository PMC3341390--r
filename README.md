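# smallworldfc

Small-world efficiency analysis of resting-state functional brain
networks, built for studying how hepatic encephalopathy (HE) — the
neuropsychiatric syndrome of liver cirrhosis, graded none → minimal →
overt — degrades the brain's economical network organization.

Functional connectivity (FC) is the Pearson correlation between regional
BOLD time series over the 90 regions of the AAL template. Thresholding
the correlation matrix gives a binary graph G whose organization is
quantified in efficiency terms (Latora–Marchiori):

- **global efficiency**
  `E_glob(G) = (1 / (N(N−1))) · Σ_{i≠j} 1 / L_ij`
  (mean inverse shortest path length; integration),
- **local efficiency** `E_loc(G) = mean_i E_glob(G_i)` with `G_i` the
  subgraph induced on node i's neighbours (segregation / fault
  tolerance),
- **nodal efficiency** `E_nod(i) = (1 / (N−1)) · Σ_{j≠i} 1 / L_ij` and
  **nodal strength** `S_i = (1 / (N−1)) · Σ_{j≠i} r_ij` (hub metrics).

G is **small-world** when it is more integrated than a degree-matched
regular lattice and more locally clustered than degree-matched rewired
random graphs:
`E_glob(regular) < E_glob(G) < E_glob(random)` and
`E_loc(random) < E_loc(G) < E_loc(regular)`.

Two binarization schemes are supported: a common correlation threshold
(*absolute* efficiency) and a common cost/density (*relative* efficiency,
equal edge counts across groups). Efficiencies are swept over thresholds
and summarized as *integrated* (threshold-averaged) values. Group-level
inference uses severity-trend regression (grade 0–3 with age/sex
covariates), covariate-adjusted ANOVA with Bonferroni post hoc, and the
ammonia–efficiency association. Because the underlying patient data were
never deposited, the package includes a first-class synthetic cohort
generator (70 subjects, groups 35/17/9/9, 290 timepoints at TR = 2 s)
whose disruption parameter degrades network efficiency monotonically —
every stage of the pipeline is testable end to end without any download.

## Worked example

```r
library(smallworldfc)

spec <- cohort_spec(seed = 7)       # study-sized synthetic cohort
cohort <- generate_cohort(spec)
print(spec)
#> cohort spec: 90 regions, 290 timepoints (TR 2s), seed 7
#>     label n_subjects disruption
#> 1 control         35       0.00
#> 2    noHE         17       0.15
#> 3     MHE          9       0.30
#> 4     OHE          9       0.45

# control-group network at 10% density and its small-world decision
ids <- cohort$subjects$subject_id[cohort$subjects$group == "control"]
ctrl_net <- threshold_cost(
  group_matrix(lapply(cohort$timeseries[ids], correlation_matrix)), 0.10)
small_world_check(ctrl_net, n_random = 20, seed = 7)
#> small-world check: 90 nodes, 400 edges
#>   E_glob: regular 0.2919 < real 0.3120 < random 0.4880 ?
#>   E_loc:  random 0.1164 < real 0.7770 < regular 0.8225 ?
#>   small-world criteria PASSED (20 surrogates)

# integrated efficiencies per subject, then the severity trend
ce <- cohort_efficiency(cohort, corr_thresholds = seq(0.10, 0.50, 0.05),
                        cost_thresholds = seq(0.10, 0.50, 0.05))
su <- ce$summary
aggregate(cbind(e_loc_abs, e_glob_abs) ~ group, su,
          function(x) round(mean(x), 3))
#>     group e_loc_abs e_glob_abs
#> 1 control     0.534      0.340
#> 2    noHE     0.471      0.301
#> 3     MHE     0.407      0.270
#> 4     OHE     0.341      0.230
severity_trend(su$e_loc_abs, su$grade, su$age, su$sex)
#> severity trend: b = -0.06527, t(66) = -25.513, p = 6.69e-36
#>   covariates: age, sex
```

The group network is small-world (intermediate between the lattice and
random baselines on both axes), integrated absolute local and global
efficiency fall monotonically across the severity gradient, and the
trend test reports a strongly negative grade coefficient — the synthetic
gradient is deliberately strong, so the statistics are larger than a
real cohort of this size would give.

## Analysis workflow

The `analysis/` directory holds the numbered end-to-end workflow, each
script a thin driver over the package that prints what it finds and
writes tables under `results/`:

| script | output |
| --- | --- |
| `01_simulate_cohort.R` | subject table, cohort layout, raw series (scratch/) |
| `02_preprocess.R` | detrend/nuisance/band-pass recovery summary |
| `03_connectivity.R` | group correlation matrices, 10%-density edge lists |
| `04_smallworld.R` | efficiency-vs-cost curves, small-world decisions |
| `05_regional.R` | per-subject integrated efficiencies, hub distributions, region ranking |
| `06_group_stats.R` | severity trends, ANOVA + post hoc, ammonia association, per-region trend table |

Run them in order from the repository root:
`Rscript analysis/01_simulate_cohort.R` … `Rscript analysis/06_group_stats.R`.

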