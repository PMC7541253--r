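#' Category enrichment of profile clusters (one-sided Fisher test)
#'
#' For every cluster x category cell, tests whether cluster members carry the
#' category more often than the background, with the hypergeometric upper
#' tail `P(X >= k)` (the one-sided Fisher exact test).  Fold enrichment is
#' the ratio of proportions `(k/n) / (K/N)`.  Q-values are
#' Benjamini-Hochberg adjusted across all cells.
#'
#' @param clusterset a `cluster_set`.
#' @param annotations data.frame with columns `protein_id`, `category`
#'   (long format, one row per label).
#' @param background character vector of protein ids forming the test
#'   universe; must contain every cluster member.  Defaults to all clustered
#'   plus uncategorized proteins.
#' @param categories category vocabulary to test; defaults to all categories
#'   present in `annotations`.
#' @return data.frame: `cluster`, `category`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(clusterset, annotations, background = NULL,
                              categories = NULL) {
  stopifnot(inherits(clusterset, "cluster_set"),
            all(c("protein_id", "category") %in% names(annotations)))
  members_all <- unlist(clusterset$clusters, use.names = FALSE)
  if (is.null(background))
    background <- c(members_all, clusterset$uncategorized)
  if (!all(members_all %in% background))
    stop("background must contain every cluster member", call. = FALSE)
  if (is.null(categories))
    categories <- sort(unique(annotations$category))
  ann <- annotations[annotations$protein_id %in% background &
                       annotations$category %in% categories, , drop = FALSE]
  cat_sets <- split(ann$protein_id, factor(ann$category, levels = categories))
  N <- length(background)
  rows <- list()
  for (cl in names(clusterset$clusters)) {
    mem <- clusterset$clusters[[cl]]
    n <- length(mem)
    for (cat in categories) {
      hits <- unique(cat_sets[[cat]])
      K <- length(hits)
      k <- sum(mem %in% hits)
      if (K == 0L) {
        p <- 1
        fold <- NA_real_
      } else {
        p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        fold <- (k / n) / (K / N)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, category = cat, k = k, n = n, K = K, N = N,
        fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out
}

#' Label clusters with their most-enriched specific compartment
#'
#' Each cluster receives the compartment (from the specific category set)
#' with the smallest q-value below `alpha`; q ties are broken by larger fold
#' enrichment, then alphabetically.  Clusters with no category below the
#' threshold stay unlabeled (`NA`).
#'
#' @param enrichment output of [fisher_enrichment()].
#' @param specific_categories character vector of compartment categories
#'   eligible as labels.
#' @param alpha q-value threshold (default 0.05).
#' @return named character vector, cluster id -> compartment label or `NA`.
#' @export
label_compartments <- function(enrichment, specific_categories, alpha = 0.05) {
  e <- enrichment[enrichment$category %in% specific_categories &
                    !is.na(enrichment$q_value) &
                    enrichment$q_value < alpha, , drop = FALSE]
  clusters <- unique(enrichment$cluster)
  out <- setNames(rep(NA_character_, length(clusters)), clusters)
  if (nrow(e) > 0L) {
    e <- e[order(e$cluster, e$q_value, -e$fold_enrichment, e$category), ]
    best <- e[!duplicated(e$cluster), ]
    out[best$cluster] <- best$category
  }
  out
}

#' Per-protein localization confidence scores
#'
#' Correlates each protein's standardized fraction profile with the median
#' profile of every labeled cluster.  The correlation to each compartment is
#' the confidence score; the compartment maximizing it is the assignment.
#'
#' @param z matrix of standardized profiles (proteins x fractions, >= 3
#'   fractions).
#' @param medians cluster x fraction matrix of median profiles
#'   (see [median_profiles()]).
#' @param labels named character vector mapping cluster id -> compartment
#'   (see [label_compartments()]); unlabeled (`NA`) clusters are ignored.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `scores` (protein x compartment matrix) and
#'   `assignment` (data.frame: `protein_id`, `assigned_compartment`,
#'   `assigned_cluster`, `confidence`).
#' @export
localization_confidence <- function(z, medians, labels, method = "pearson") {
  stopifnot(is.matrix(z), ncol(z) >= 3L, is.matrix(medians))
  labeled <- labels[!is.na(labels)]
  if (length(labeled) == 0L)
    stop("no labeled clusters to score against", call. = FALSE)
  med <- medians[names(labeled), , drop = FALSE]
  rownames(med) <- unname(labeled)
  const <- apply(med, 1L, sd) == 0
  scores <- suppressWarnings(cor(t(z), t(med), method = method))
  scores[, const] <- NA_real_
  comp_order <- order(colnames(scores))
  best <- apply(scores[, comp_order, drop = FALSE], 1L, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  assigned <- colnames(scores)[comp_order][best]
  cluster_of <- setNames(names(labeled), unname(labeled))
  assignment <- data.frame(
    protein_id = rownames(z),
    assigned_compartment = assigned,
    assigned_cluster = unname(cluster_of[assigned]),
    confidence = scores[cbind(seq_len(nrow(scores)),
                              match(assigned, colnames(scores)))],
    stringsAsFactors = FALSE
  )
  list(scores = scores, assignment = assignment)
}

#' Compare median cluster profiles with external reference profiles
#'
#' Spearman rank correlation between each compartment's median profile and a
#' reference profile of the same compartment (e.g. from an independent
#' fractionation experiment).  When fraction counts differ, the reference is
#' linearly interpolated onto the profile grid.
#'
#' @param medians compartment x fraction matrix (rownames = compartment
#'   names).
#' @param reference compartment x fraction matrix of reference profiles.
#' @return list with `per_compartment` (named correlations), `average`, and
#'   `unmatched` (reference compartments with no counterpart).
#' @export
compare_to_reference <- function(medians, reference) {
  stopifnot(is.matrix(medians), is.matrix(reference))
  shared <- intersect(rownames(medians), rownames(reference))
  unmatched <- setdiff(rownames(reference), rownames(medians))
  if (length(shared) == 0L)
    stop("no compartment names shared with the reference", call. = FALSE)
  f <- ncol(medians)
  rho <- vapply(shared, function(cp) {
    ref <- reference[cp, ]
    if (length(ref) != f) {
      ref <- approx(seq(0, 1, length.out = length(ref)), ref,
                    xout = seq(0, 1, length.out = f))$y
    }
    cor(medians[cp, ], ref, method = "spearman")
  }, 0)
  list(per_compartment = rho, average = mean(rho), unmatched = unmatched)
}
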