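# ftdclust

Data-driven stratification of psychosis cohorts by formal thought disorder
(FTD), with a fully reproducible multi-step cluster-selection protocol and
the downstream subgroup-validation statistics.

## The problem

FTD — disturbances of thought, language and communication such as
conceptual disorganization or poverty of speech — marks illness severity in
early psychosis, but patients vary widely. A clinically useful
stratification must be more than a single clustering run: a candidate
subgrouping has to survive internal validity checks, stability under
perturbation, and out-of-sample generalizability before anyone compares
functioning or cognition across subgroups.

`ftdclust` implements that selection protocol as four checkpoints over a
matrix of ordinal symptom items (by default the five FTD-related items:
PANSS P2 and N5, scored 1–7; SANS 9, 10 and 12, scored 0–5, range-unit
scaled):

1. **Validity and stability screen** — k-means, hierarchical clustering
   (average and Ward.D2 linkage) and PAM are scored for every k in 2–10 on
   internal validity (connectivity, Dunn index, mean silhouette width
   s(i) = (b(i) − a(i)) / max(a(i), b(i))) and leave-one-column-out
   stability (APN, AD, ADM, FOM). Each measure votes for its optimal
   (algorithm, k); the modal vote wins.
2. **Multi-index re-vote for k** — a battery of eight internal indices
   (Calinski–Harabasz (B/(k−1))/(W/(n−k)), Davies–Bouldin, silhouette,
   Dunn, C-index, McClain–Rao, Hartigan, Krzanowski–Lai) votes on the
   number of clusters for the winning algorithm.
3. **Robustness** — cophenetic correlation and silhouette profiles for
   hierarchical candidates; bootstrap global and individual ST indices in
   [0, 1] (resample, recluster, optimally re-match labels) for the
   partitioning candidate.
4. **Generalizability** — cross-validated prediction strength: over
   repeated random half-splits, both halves are clustered independently,
   test points are classified to the nearest training centroid, and the
   worst-case proportion of test-cluster pairs co-assigned by the training
   classifier is averaged per k. The retained k is the one with the highest
   mean prediction strength among those ≥ 0.80.

The validation layer then compares the subgroups on functioning and
neurocognition: Shapiro–Wilk-gated Mann–Whitney U (with rank effect size
r = Z/√N, signed negative for deficits) or Welch's t tests, chi-square
associations with φ / Cramér's V, Benjamini–Hochberg FDR within declared
variable families, and FDR-corrected Spearman correlograms per subgroup.

Because clinical cohort data of this kind cannot be redistributed, the
package ships a calibrated synthetic-cohort generator
(`generate_cohort()`): a two-subgroup latent-severity model (n = 279,
75 high-severity) whose ordinal items hit specified per-subgroup medians
and whose functioning/neurocognition deficits are calibrated by pilot
simulation to specified rank effect sizes.

## Worked example

```r
library(ftdclust)

gen <- generate_cohort(generator_spec(seed = 1))
X   <- build_feature_matrix(gen$cohort)          # range-unit scaled 279 x 5

km <- kmeans_fit(X, 2, seed = 1)
km
#> partition: kmeans | k = 2 | sizes: 204/75

st_indices(X, "kmeans", 2, B = 100, seed = 1)
#> bootstrap stability: kmeans k = 2 | global ST = 0.998 over 100 replicates

ps_curve(X, "kmeans", k_grid = 2:5, iterations = 100, seed = 1)
#> prediction strength (kmeans, 100 half-split iterations)
#>  k mean_ps sd_ps
#>  2   0.974 0.044
#>  3   0.768 0.108
#>  4   0.739 0.087
#>  5   0.449 0.050
#> retained k (threshold 0.8, rule max_ps): 2

recovery_score(km, gen$truth)[c("ari", "accuracy")]
#> $ari [1] 0.773    $accuracy [1] 0.943
```

The two-cluster k-means solution splits the cohort 204/75, is almost
perfectly stable under bootstrap resampling (global ST 0.998), clearly
generalizes best at k = 2 (mean prediction strength 0.974 versus 0.768 at
k = 3), and recovers the generating subgroup labels with 94% accuracy.
`run_pipeline(pipeline_config(...))` chains all four checkpoints plus the
validation layer and writes CSV/JSON artifacts; `sanity_rerun()` contrasts
the main feature set against an alternative (e.g. noise) on stability and
generalizability.

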