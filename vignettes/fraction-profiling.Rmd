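---
title: "Compartment assignment from fractionation LFQ profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment assignment from fractionation LFQ profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracloc)
```

# The measurement model

Sequential differential centrifugation separates a cell lysate into F
ordered fractions (F = 10 by default here, the last fraction being an
acetone precipitate of everything still in suspension). Organelles pellet
at characteristic speeds, so proteins resident in the same compartment
share a *fraction profile*: mitochondria come down early, microsomal
membranes (ER, peroxisome, lysosome) in the middle of the series,
ribosomes and soluble nuclear material late. Each fraction is measured by
label-free quantification (LFQ) in R independent replicates (R = 4 by
default), giving a protein × (fraction, replicate) intensity grid.

`fracloc` makes three modeling assumptions:

* **Multiplicative error.** LFQ intensities are treated on the log2 scale
  throughout; replicate noise is approximately additive there.
* **Missingness is left-censored.** A zero or empty LFQ cell means the
  peptide signal fell below the detection limit, not that abundance is
  zero. Missing cells are therefore imputed *low*: each is drawn from a
  Beta(2, 2) rescaled to the interval between two small quantiles
  (defaults: the 0.1 and 0.2 percentiles, `q_low = 0.001`,
  `q_high = 0.002`) of the observed log2 values of the same sample
  column. The Beta(2, 2) shape concentrates mass mid-interval and keeps
  draws strictly inside the bounds; the bounds, not the shape, carry the
  scientific content (any draw in that interval is "below detection").
  Both quantiles are exposed because the percentile convention differs
  between groups — some read "0.1–0.2 percentile" as 10–20%.
* **Shape, not height, encodes localization.** Before clustering, each
  protein's vector of fraction means is z-scored (mean subtracted, sample
  n−1 standard deviation). Two proteins with the same relative profile at
  different absolute abundance become identical. Constant profiles have no
  shape and are excluded with a reason code rather than silently divided
  by zero.

Imputation happens at replicate level (per-sample quantiles), *before*
replicate averaging: per-sample quantiles are the natural scale of the
detection limit, and averaging first would smear censored cells with
observed ones.

# Fraction statistics and the clusterable subset

For every protein and every unordered fraction pair the package runs a
Welch two-sample t-test on the R replicate log2 values per fraction, with
Benjamini–Hochberg adjustment within each pair across proteins
(`alpha = 0.05`, configurable). Welch's form was chosen over the pooled
t-test because four-replicate LFQ groups routinely violate equal-variance
assumptions; no moderated-variance (empirical Bayes) machinery is used, to
keep the test self-contained and exactly checkable against numeric
t-tail integration.

Imputation can produce (near-)constant groups, so the degenerate cases are
defined rather than left to error: both groups constant and equal gives
p = 1, both constant and unequal gives p = 0; such rows carry a
`degenerate` flag.

A protein is *clusterable* when (a) all R replicates were **observed** —
not imputed — in at least one fraction, and (b) it is significant in at
least one pairwise comparison. Rule (a) reads "measured" literally:
imputed values are not measurements.

# SOM clustering, merging, ordering

Standardized profiles are clustered on a rectangular self-organizing map
of 12 units (4 × 3 grid). The trainer is the deterministic batch rule:
per epoch, every profile is assigned to its nearest codebook (Euclidean
distance, ties to the first unit), then every codebook is recomputed as
the Gaussian-neighborhood-weighted mean of all profiles. The neighborhood
standard deviation decays linearly from half the larger grid dimension to
0.3 grid units over 500 epochs. Codebooks are initialized from a seeded
sample of the data, so a seed fully determines the model; batch training
removes any dependence on presentation order. These schedule constants are
conventional SOM practice and are exposed as arguments; the unit count is
the parameter with scientific meaning (an upper bound on the number of
distinguishable profile shapes).

**Quality merging.** Units capture noise as well as structure. The merge
threshold is the 75th percentile of *all* protein-to-assigned-codebook
distances; every unit whose members' *mean* distance exceeds it is
dissolved and its members moved to an `uncategorized` pool. This is a
deliberately literal reading of the percentile-over-all / mean-per-unit
construction: the threshold is global, the criterion is unit-level, so a
single diffuse unit cannot inflate its own threshold.

**Display ordering.** Surviving clusters are ordered along the exact
shortest open Hamiltonian path through their two-component PCA
coordinates, computed by Held–Karp dynamic programming (exact for the
12-unit ceiling; the test suite verifies it against brute-force
permutation enumeration up to 8 clusters). The path is open, not a closed
tour, because the purpose is a linear display order. Orientation is fixed
by starting at the endpoint with the smaller first-component coordinate;
PCA component signs are themselves fixed by making each component's
largest-magnitude loading positive.

# Compartment labeling and confidence

Per cluster × category, enrichment is the hypergeometric upper tail
P(X ≥ k) — the one-sided Fisher exact test with the alternative that
cluster members carry the category more often than the background — and
fold enrichment is the ratio of proportions (k/n)/(K/N) rather than the
conditional-MLE odds ratio, matching how fold-enrichments are conventionally
quoted for cluster annotation. Q-values are BH across all cells and are
invariant to cluster relabeling.

Each cluster is labeled with its most-enriched *specific* compartment
(default vocabulary: mitochondrion, ribosome, nucleus, peroxisome, ER,
Golgi) provided q < 0.05; ties on q go to the larger fold, then
alphabetical. Clusters with no category under the threshold stay
unlabeled — profile shapes such as a terminal acetone-precipitate spike
are real but not compartment-specific.

The per-protein confidence score is the Pearson correlation between the
protein's standardized profile and each labeled cluster's per-fraction
median profile; the argmax compartment is the assignment. Pearson is the
default because the profiles are continuous and already standardized;
Spearman is available (`method = "spearman"`), and is also what
`compare_to_reference()` uses for cross-study profile comparison, where
only the ranking of fractions is comparable across quantification
technologies. When fraction counts differ between study and reference,
the reference profile is linearly interpolated onto the study grid — a
declared convention, since no alignment of heterogeneous fractionation
schemes is canonical.

# Annotation QC conventions

All genomic intervals are 0-based half-open (bedGraph/BED convention);
coverage is strand-aggregated. Decisions the source procedures report
qualitatively are quantified with explicit defaults:

* a split gene is *evidently split* when the mean gap depth is below
  `gap_ratio_threshold = 0.1` times the mean depth of the **weaker**
  flank; a zero-length gap or an uncovered flank is uninformative and
  classified `probable_false_split` with a flag;
* a shorter-than-reference ORF is *supported* when the **larger** of the
  two transcript-edge mean depths (windows of `edge_window = 50` bases
  just outside each ORF end, truncated at the transcript bounds) is below
  `edge_ratio_threshold = 0.1` times the ORF mean depth; an ORF spanning
  its whole transcript has no edges and is supported by convention,
  flagged;
* the ORF categorization ladder is first-match-wins: no reference hit →
  `newly_annotated`; split pair → the split classification; hit coverage
  < 85% → the short-ORF classification; length ratio above 1.1 →
  `longer_than_reference`; else `high_correspondence`. Split evidence
  outranks short evidence when both exist (flagged).
* "average coverage" is the mean by default with a median flag, since
  either reading is defensible;
* the variant rate "1 in N bases" uses floor division, which reproduces
  the published worked examples exactly;
* ExN50 breaks expression ties by longer transcript first, for
  determinism.

# The synthetic generator

`generate_lfq_dataset()` emulates the study design the pipeline targets:
per protein a base log2 abundance (Normal, mean 26, sd 2 — typical
MaxQuant LFQ scale), plus its compartment archetype scaled by
`archetype_scale = 2` log2 units, plus i.i.d. Gaussian replicate noise
(`noise_sd = 0.15` log2 units), exponentiated to intensities.
Left-censoring removes cells with probability
`missing_rate · logistic(−(v − c)/1.5)` where c is the 15th percentile of
the pre-censoring log2 values — so censoring concentrates on low-abundance
cells, matching the imputation model. Contaminant, reverse, only-by-site
and low-evidence rows are appended to exercise the filters. The eight
default archetypes (`default_archetypes()`) are hand-set qualitative
shapes: early-pelleting mitochondria, mid-series drop-offs for
peroxisome/ER, Golgi persistence to step 8, a ribosomal peak in fractions
7–9, rising nuclear and chromatin profiles, and a terminal spike. With the
default noise the archetype separation is far above 4× the noise sd, which
is the regime the recovery tests assert (cluster/truth adjusted Rand index
≥ 0.8, ≥ 5 of 6 compartments labeled, ≥ 80% correct confidence argmax).

What the generator does **not** emulate — and therefore what passing
recovery tests do not demonstrate about real data: correlated replicate
effects (batch structure), intensity-dependent variance, proteins with
genuinely mixed or dynamic localization, annotation bias toward
well-studied compartments, and compartments whose real profiles are far
less separated than the planted archetypes (real peroxisome/ER/lysosome
profiles overlap substantially). The generator validates the machinery,
not the biology.

Every generator is a pure function of its spec and seed: reruns are
byte-identical, which the suite checks at file level.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run the full pipeline on the
default synthetic design (8 archetypes × 80 proteins, 10 × 4 grid) —
chosen as the smallest cohort where each archetype populates a SOM unit
comfortably — plus 100 coverage scenarios and a 2653-peptide missense
cohort mirroring the scale of the published analysis. Oracle-equivalence
tests enumerate all hypergeometric tables to N = 30 and all path
permutations to 8 clusters. A full pipeline run at this size takes on the
order of a second.

# Known limitations

* Compartment labels are only as good as the annotation table; the Fisher
  test treats labels as exchangeable draws, ignoring annotation
  correlation between paralogs.
* A protein in an unlabeled cluster still receives a confidence argmax
  over *labeled* clusters; consumers should condition on the assigned
  cluster's label when filtering.
* The SOM unit count bounds the number of recoverable profile classes;
  compartments sharing a profile (e.g. chromatin vs. nucleoplasm) will
  merge and must be separated by other evidence.
* No between-sample normalization is applied beyond what LFQ itself does;
  systematic loading differences between fractions propagate into the
  profiles.
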