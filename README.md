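# socsurv

Social network position and mortality risk in wild animal populations.

Long-term photo-identification studies of social mammals (the motivating
system is a closed population of resident killer whales followed by annual
photographic census) record *grouped sightings*: which individuals were
together, in which group, in which encounter, year after year. `socsurv`
turns such records into survival inference about social position:

1. **Association networks** per sampling period from the simple ratio
   index under the gambit of the group,
   `SRI = x / (x + y_ab + y_a + y_b)`, with support for pooling sparse
   years into multi-year periods, and beta-binomial estimation of social
   differentiation `S` (the CV of true association indices) and the
   observed-vs-true correlation `r = sqrt(S²H̄ / (1 + S²H̄))`.
2. **Communities** by weighted random walks (walktrap, dendrogram cut at
   maximum modularity), with weighted Newman modularity
   `Q = Σ_c [W_c/W − (k_c/2W)²]`, bootstrap consistency `r_com`, and
   data-stream null tests.
3. **Within-community centrality**: normalized degree and rank-normalized
   closeness on edge lengths `1/SRI`; communities of fewer than five
   members are excluded.
4. **Extended Cox proportional-hazards models** on counting-process
   person-period data — the hazard ratio `exp(β)` is the multiplicative
   change in mortality risk per unit of (time-varying) centrality — fitted
   separately by sex and by resource (salmon) stratum, where low-salmon
   years are the lowest quartile of an annual abundance index; plus a
   binomial GLMM for degree vs resource class.
5. **Permutation inference**: within-community node permutations,
   checkerboard data-stream permutations preserving sighting counts and
   group sizes exactly, sex-imputation averaging for unknown-sex
   individuals, and the inclusive permutation p-value
   `p = (b + 1)/(m + 1)`.
6. A **synthetic-data generator** with known ground truth (communities,
   dyadic affinities, hazard coefficients, death times) so every stage has
   a parameter-recovery test surface.

## Worked example

Simulate a small population, build one year's network, detect communities,
compute centrality, and fit sex-stratified Cox models with a permutation
test:

```r
library(socsurv)

cfg <- synthetic_config(n_individuals = 40, n_communities = 4,
                        years = 1995:2002, pooling = NULL,
                        mean_obs_per_whale_year = 15,
                        hazard = list(beta0 = log(0.08)), seed = 11)
bundle <- run_pipeline(pipeline_config(synthetic = cfg, n_perm = 60,
                                       n_imp = 5, n_boot = 10, seed = 11))
bundle
```

```
socsurv pipeline results
  8 periods, 40 individuals, 14 events
  modularity range: 0.32-0.43
  social differentiation S = 1.57 (r = 0.99)
  degree_norm_M_all                Haz. =    6.657  z =   0.48  e =   4  p_perm = 0.623
  degree_norm_M_low                Haz. =    463.2  z =   0.57  e =   2  p_perm = 0.7705
  degree_norm_F_all                Haz. =    1.265  z =   0.14  e =   9  p_perm = 0.1639
  degree_norm_F_low                Haz. =  0.04371  z =  -1.43  e =   5  p_perm = 0.09836
  closeness_rank_norm_M_all        Haz. =     1.12  z =   0.07  e =   4  p_perm = 0.6557
  ...
```

Reading the output: each line is one extended Cox model (covariate, sex,
salmon stratum). `Haz.` is the hazard ratio per unit of normalized
within-community centrality and `e` the number of deaths the model saw;
`p_perm` is the one-sided node-permutation p-value. With only 2–9 events
per stratum the point estimates are wild (a hazard ratio of 463 on two
deaths) but none of the permutation tests comes close to significance —
exactly what a calibrated pipeline should report for a population this
small with no planted centrality effect. `modularity` of 0.32–0.43 says
the simulated society is compartmentalised; `S = 1.57` describes few
strong and many weak bonds, and `r = 0.99` says the sampled networks are
a precise image of the true association pattern.

Individual stages are plain functions returning classed objects:

```r
d   <- simulate_dataset(cfg)
m   <- compute_sri(d$encounters, "1996")       # sri_matrix
p   <- detect_communities(m)                   # community_partition
ct  <- centrality_table(m, p)                  # centrality_table
hazard_ratio_interpretation(0.25)
#> 75% decrease in risk per unit of variable
```

Networks export to GraphML (`write_network()`) for Gephi-style plotting.

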