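# fracloc

Subcellular localization of proteins from differential-centrifugation
label-free quantification (LFQ) profiles, plus read-coverage based
gene-model quality control.

## What it does and for whom

Spatial proteomics by sequential differential centrifugation (the LOPIT-DC
family of protocols) enriches different subcellular compartments in
successive fractions; proteins resident in the same organelle share a
characteristic abundance profile across the fraction series. `fracloc` is
for proteomics groups running such designs with MaxQuant label-free
quantification: it takes a `proteinGroups.txt`-dialect table (F fractions ×
R replicates) and produces compartment-labeled profile clusters and a
per-protein localization confidence score.

The processing chain is:

1. **Filtering** — drop contaminant / reverse / only-identified-by-site
   entries and groups with fewer than two peptides or no unique peptide
   (`filter_protein_groups()`); represent multi-member groups by their
   longest member (`select_representative()`).
2. **Imputation** — log2-transform; replace each missing cell with a draw
   from a Beta(2,2) rescaled to the interval between the 0.1 and 0.2
   percentiles of the observed log2 values of the same sample
   (left-censored non-detection model, `log2_and_impute()`).
3. **Fraction statistics** — Welch two-sample tests for every protein and
   every fraction pair, with Benjamini–Hochberg FDR per pair
   (`pairwise_fraction_tests()`); proteins enter clustering when all R
   replicates were observed in at least one fraction *and* at least one
   pair is significant (`select_clusterable()`).
4. **Clustering** — z-score each protein's fraction-mean profile
   (`standardize_profiles()`), train a 4×3 batch self-organizing map
   (`train_som()`), dissolve units whose mean member distance exceeds the
   75th percentile of all protein-to-codebook distances into an
   *uncategorized* pool (`merge_low_quality()`), and order the surviving
   clusters along the exact shortest path through their 2-D PCA
   coordinates (`order_clusters_tsp()`).
5. **Compartment assignment** — one-sided Fisher exact (hypergeometric
   upper tail) enrichment of localization categories per cluster,
   fold-enrichment (k/n)/(K/N), BH-adjusted (`fisher_enrichment()`);
   each cluster is labeled with its most-enriched specific compartment
   (`label_compartments()`); every protein's confidence score is the
   correlation between its standardized profile and each labeled cluster's
   median profile (`localization_confidence()`).

A second module implements annotation-evidence procedures for
transcriptome-assembly based gene models: N50/ExN50 statistics, hit-coverage
binning, RNA-seq coverage classification of split genes
(`classify_split_pair()`: a split is supported when the mean gap depth is
below 10% of the weaker flank) and of shorter-than-reference ORFs
(`classify_short_orf()`: supported when transcript-edge depth is below 10%
of ORF depth), a missense peptide-impact proportion, an ORF categorization
ladder, and precision / variant-rate arithmetic.

Because raw fractionation data is rarely shareable at development time, the
package ships a planted-truth synthetic generator (`synthetic_spec()`,
`generate_lfq_dataset()`, `generate_annotations()`,
`generate_coverage_scenarios()`, `generate_peptide_scenarios()`) emulating
the full study design: 10 fractions × 4 replicates, eight compartment
archetype profiles, log-scale Gaussian noise, left-censored missingness,
decoy rows and noisy category labels.

## Worked example

```r
library(fracloc)

spec        <- synthetic_spec(n_per_compartment = 60L, seed = 42)
dataset     <- generate_lfq_dataset(spec)
annotations <- generate_annotations(dataset$truth, spec)
res         <- fracloc_pipeline(dataset$table, annotations, seed = 42)

res$protein_groups
#> protein_groups: 480 groups, 40 samples (10 fractions x 4 replicates)
res$clusters
#> cluster_set: 9 clusters (sizes 60, 63, 58, 54, 5, 54, 59, 62, 59), 6 uncategorized
res$labels
#>        cluster1        cluster2        cluster3        cluster4        cluster5
#>              NA "mitochondrion"    "peroxisome"       "nucleus"              NA
#>        cluster6        cluster7        cluster8        cluster9
#>            "er"      "ribosome"              NA        "golgi"
```

480 planted proteins (8 compartments × 60) survive filtering; the SOM +
merge step leaves 9 tight clusters and sends 6 profiles to the
uncategorized pool. All six labelable compartments (mitochondrion,
ribosome, nucleus, peroxisome, ER, Golgi) are recovered by enrichment; the
two unlabeled clusters carry the planted chromatin-mix and terminal-spike
shapes, which by design match no specific compartment category.

```r
subset(res$enrichment, q_value < 0.05 & category == "mitochondrion")
#>     cluster      category  k  n  K   N fold_enrichment      p_value      q_value
#> 12 cluster2 mitochondrion 40 63 41 480        7.433217 8.934477e-41 6.432824e-39

head(res$confidence$assignment, 3)
#>   protein_id assigned_compartment assigned_cluster confidence
#> 1    PG00001        mitochondrion         cluster2  0.9476249
#> 2    PG00002        mitochondrion         cluster2  0.9612471
#> 3    PG00003        mitochondrion         cluster2  0.9985494
```

The enrichment row reads: 40 of the 63 proteins in cluster2 carry the
mitochondrion annotation, against 41 annotated among the 480 background
proteins — a 7.4-fold enrichment. The confidence column is the Pearson
correlation between each protein's standardized profile and the median
profile of its assigned compartment's cluster; among proteins planted in
the six labelable compartments, 98.1% receive the correct
confidence-argmax assignment in this run.

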