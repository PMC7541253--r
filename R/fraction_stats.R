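#' Welch two-sample tests between all fraction pairs
#'
#' For every protein and every unordered fraction pair, a Welch two-sample
#' t-test compares the replicate log2 intensities of the two fractions.
#' P-values are adjusted by Benjamini-Hochberg within each fraction pair
#' across proteins.  Zero-variance degeneracies (which imputation can
#' create) are resolved by convention: both groups constant and equal gives
#' p = 1, both constant and unequal gives p = 0; such rows are flagged.
#'
#' @param lfq an `lfq_matrix` (imputation done).
#' @param alpha significance threshold carried into the result attributes.
#' @return data.frame with columns `protein_id`, `fraction_i`, `fraction_j`
#'   (`i < j`), `mean_diff` (mean i minus mean j, log2 units), `t_stat`,
#'   `df`, `p_value`, `q_value`, `degenerate`.
#' @export
pairwise_fraction_tests <- function(lfq, alpha = 0.05) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  fractions <- sort(unique(lfq$design$fraction))
  reps <- table(lfq$design$fraction)
  if (any(reps < 2L))
    stop("need >= 2 replicates per fraction", call. = FALSE)
  cols <- lapply(fractions, function(f) which(lfq$design$fraction == f))
  prot <- rownames(lfq$values)
  pieces <- list()
  for (a in seq_along(fractions)[-length(fractions)]) {
    for (b in (a + 1L):length(fractions)) {
      x <- lfq$values[, cols[[a]], drop = FALSE]
      y <- lfq$values[, cols[[b]], drop = FALSE]
      n1 <- ncol(x); n2 <- ncol(y)
      m1 <- rowMeans(x); m2 <- rowMeans(y)
      v1 <- apply(x, 1L, var); v2 <- apply(y, 1L, var)
      se2 <- v1 / n1 + v2 / n2
      t_stat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * pt(-abs(t_stat), df)
      degen <- v1 == 0 & v2 == 0
      p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
      t_stat[degen] <- NA_real_
      df[degen] <- NA_real_
      pieces[[length(pieces) + 1L]] <- data.frame(
        protein_id = prot,
        fraction_i = fractions[a], fraction_j = fractions[b],
        mean_diff = m1 - m2, t_stat = t_stat, df = df,
        p_value = p, q_value = benjamini_hochberg(p),
        degenerate = degen, stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, pieces)
  attr(out, "alpha") <- alpha
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] after validating the input).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("contract violation: p-values outside [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Count significant proteins per fraction pair
#'
#' @param results output of [pairwise_fraction_tests()].
#' @param alpha q-value threshold.
#' @return symmetric F x F integer matrix (zero diagonal) of the number of
#'   proteins with `q_value < alpha` in each pair.
#' @export
significance_counts <- function(results, alpha = 0.05) {
  fractions <- sort(unique(c(results$fraction_i, results$fraction_j)))
  f <- length(fractions)
  out <- matrix(0L, f, f,
                dimnames = list(paste0("F", fractions), paste0("F", fractions)))
  sig <- results[results$q_value < alpha, , drop = FALSE]
  if (nrow(sig) > 0L) {
    tab <- table(factor(sig$fraction_i, levels = fractions),
                 factor(sig$fraction_j, levels = fractions))
    out <- out + tab + t(tab)
    dimnames(out) <- list(paste0("F", fractions), paste0("F", fractions))
  }
  out
}

#' Select the clusterable protein subset
#'
#' A protein enters clustering when (a) all replicates were *observed*
#' (before imputation) in at least one fraction, and (b) it is significant
#' (`q < alpha`) in at least one pairwise fraction comparison.
#'
#' @param lfq an `lfq_matrix` (its `mask` records pre-imputation
#'   missingness).
#' @param results output of [pairwise_fraction_tests()].
#' @param alpha q-value threshold.
#' @return character vector of protein ids, in matrix order.
#' @export
select_clusterable <- function(lfq, results, alpha = 0.05) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  fractions <- sort(unique(lfq$design$fraction))
  complete_any <- rep(FALSE, nrow(lfq$values))
  for (f in fractions) {
    cols <- which(lfq$design$fraction == f)
    complete_any <- complete_any |
      rowSums(lfq$mask[, cols, drop = FALSE]) == 0L
  }
  sig_ids <- unique(results$protein_id[results$q_value < alpha])
  ids <- rownames(lfq$values)
  ids[complete_any & ids %in% sig_ids]
}
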