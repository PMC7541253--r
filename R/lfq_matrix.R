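#' Log2-transform intensities and impute left-censored missing values
#'
#' Observed intensities are log2-transformed.  Each missing cell is replaced
#' by a draw from a Beta(2, 2) distribution rescaled to the interval between
#' two low empirical quantiles of the *observed* log2 values of the same
#' sample column — a left-censored imputation reflecting that missing LFQ
#' values arise predominantly from low-abundance non-detection.
#'
#' @param pg a `protein_groups` object (raw intensities, `NA` = missing).
#' @param q_low,q_high quantile bounds of the imputation interval within each
#'   sample; defaults 0.001 and 0.002 (the 0.1 and 0.2 percentiles).
#' @param seed integer RNG seed; the same seed reproduces the matrix exactly.
#' @return an `lfq_matrix` object: list with `values` (protein x sample log2
#'   matrix, complete), `mask` (TRUE where the raw value was missing),
#'   `imputed` (TRUE where a value was drawn), `design`, `proteins`.
#' @export
log2_and_impute <- function(pg, q_low = 0.001, q_high = 0.002, seed = NULL) {
  stopifnot(inherits(pg, "protein_groups"))
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
    stop("require 0 <= q_low < q_high <= 1", call. = FALSE)
  x <- log2(pg$intensity)
  mask <- is.na(x)
  empty <- colSums(!mask) == 0L
  if (any(empty))
    stop("imputation error: no observed values in sample(s) ",
         paste(sQuote(colnames(x)[empty]), collapse = ", "), call. = FALSE)
  vals <- x
  with_seed_if(seed, {
    for (j in seq_len(ncol(x))) {
      miss <- which(mask[, j])
      if (length(miss) == 0L) next
      obs <- x[!mask[, j], j]
      bounds <- quantile(obs, c(q_low, q_high), names = FALSE, type = 7)
      vals[miss, j] <- bounds[1L] +
        (bounds[2L] - bounds[1L]) * rbeta(length(miss), 2, 2)
    }
  })
  structure(list(values = vals, mask = mask, imputed = mask,
                 design = pg$design, proteins = rownames(vals)),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("lfq_matrix: %d proteins x %d samples; %d cells imputed\n",
              nrow(x$values), ncol(x$values), sum(x$imputed)))
  invisible(x)
}

#' Average log2 intensities over replicates
#'
#' @param lfq an `lfq_matrix`.
#' @param observed_only if TRUE, average only originally observed cells
#'   (proteins with no observation in a fraction get `NA` there); default
#'   FALSE averages the complete (imputed) matrix.
#' @return protein x fraction matrix of mean log2 intensities, fraction
#'   columns in increasing fraction order.
#' @export
average_replicates <- function(lfq, observed_only = FALSE) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  fractions <- sort(unique(lfq$design$fraction))
  out <- matrix(NA_real_, nrow = nrow(lfq$values), ncol = length(fractions),
                dimnames = list(rownames(lfq$values), paste0("F", fractions)))
  for (i in seq_along(fractions)) {
    cols <- which(lfq$design$fraction == fractions[i])
    v <- lfq$values[, cols, drop = FALSE]
    if (observed_only) {
      v[lfq$mask[, cols, drop = FALSE]] <- NA_real_
      out[, i] <- rowMeans(v, na.rm = TRUE)
      out[!is.finite(out[, i]), i] <- NA_real_
    } else {
      out[, i] <- rowMeans(v)
    }
  }
  out
}

#' Pairwise Pearson correlations between samples
#'
#' Computed over originally observed values only; a sample pair sharing fewer
#' than three finite values gets `NA`.  The result is symmetric with unit
#' diagonal.
#'
#' @param lfq an `lfq_matrix`.
#' @param min_shared minimum shared observations per pair (default 3).
#' @return sample x sample correlation matrix.
#' @export
replicate_correlation <- function(lfq, min_shared = 3L) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  v <- lfq$values
  v[lfq$mask] <- NA_real_
  s <- ncol(v)
  out <- matrix(NA_real_, s, s, dimnames = list(colnames(v), colnames(v)))
  diag(out) <- 1
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    ok <- is.finite(v[, i]) & is.finite(v[, j])
    if (sum(ok) >= min_shared) {
      r <- cor(v[ok, i], v[ok, j])
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Most dynamic proteins across the fractionation series
#'
#' Ranks proteins by the sample variance of their fraction means and returns
#' the top `n`; ties are broken by identifier so the selection is
#' deterministic.
#'
#' @param means protein x fraction matrix (see [average_replicates()]).
#' @param n number of proteins to return; `n >=` number of proteins returns
#'   all.
#' @return character vector of protein ids.
#' @export
most_dynamic <- function(means, n) {
  stopifnot(is.matrix(means), n >= 1)
  v <- apply(means, 1L, var)
  ord <- order(-v, rownames(means))
  rownames(means)[ord][seq_len(min(n, nrow(means)))]
}
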