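#' Run the full localization pipeline
#'
#' Convenience wrapper chaining the stages: read (if given a path), filter,
#' log2 + impute, replicate averaging, pairwise fraction tests, clusterable
#' selection, standardization, SOM training, low-quality merging, median
#' profiles, PCA + path ordering, enrichment, compartment labeling and
#' per-protein confidence scoring.
#'
#' @param table a protein-groups data.frame (e.g. from
#'   [generate_lfq_dataset()]), a `protein_groups` object, or a file path.
#' @param annotations long-format annotation data.frame (`protein_id`,
#'   `category`).
#' @param specific_categories compartments eligible as cluster labels;
#'   default the six labelable compartments.
#' @param design an [lfq_design()].
#' @param alpha significance / labeling threshold.
#' @param grid SOM grid, default `c(4, 3)`.
#' @param epochs SOM batch epochs.
#' @param merge_percentile merge threshold percentile.
#' @param q_low,q_high imputation quantile bounds.
#' @param seed RNG seed driving imputation and SOM initialization.
#' @return list with every intermediate stage (`protein_groups`, `lfq`,
#'   `means`, `tests`, `clusterable`, `z`, `som`, `clusters`, `medians`,
#'   `pca`, `cluster_order`, `enrichment`, `labels`, `confidence`).
#' @export
fracloc_pipeline <- function(table, annotations,
                             specific_categories = c("mitochondrion",
                                                     "ribosome", "nucleus",
                                                     "peroxisome", "er",
                                                     "golgi"),
                             design = lfq_design(), alpha = 0.05,
                             grid = c(4L, 3L), epochs = 500L,
                             merge_percentile = 75,
                             q_low = 0.001, q_high = 0.002, seed = 1L) {
  pg <- if (inherits(table, "protein_groups")) {
    table
  } else if (is.character(table)) {
    read_protein_groups(table, design)
  } else {
    path <- tempfile(fileext = ".txt")
    on.exit(unlink(path), add = TRUE)
    write_protein_groups(table, path)
    read_protein_groups(path, design)
  }
  pg <- filter_protein_groups(pg)
  lfq <- log2_and_impute(pg, q_low = q_low, q_high = q_high, seed = seed)
  means <- average_replicates(lfq)
  tests <- pairwise_fraction_tests(lfq, alpha = alpha)
  clusterable <- select_clusterable(lfq, tests, alpha = alpha)
  z <- standardize_profiles(means[clusterable, , drop = FALSE])
  som <- train_som(z, grid = grid, seed = seed, epochs = epochs)
  clusters <- merge_low_quality(som, percentile = merge_percentile)
  medians <- median_profiles(clusters, z)
  pca <- pca_2d(medians)
  cluster_order <- order_clusters_tsp(pca$scores)
  enrichment <- fisher_enrichment(clusters, annotations)
  labels <- label_compartments(enrichment, specific_categories, alpha = alpha)
  confidence <- if (any(!is.na(labels))) {
    localization_confidence(z, medians, labels)
  } else NULL
  list(protein_groups = pg, lfq = lfq, means = means, tests = tests,
       clusterable = clusterable, z = z, som = som, clusters = clusters,
       medians = medians, pca = pca, cluster_order = cluster_order,
       enrichment = enrichment, labels = labels, confidence = confidence)
}
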