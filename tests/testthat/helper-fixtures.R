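# fixture builders and independent oracles used across the suite

# build an lfq_matrix directly (values already log2; mask = missing-at-read)
make_lfq <- function(values, fractions, replicates, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  structure(list(
    values = values, mask = mask, imputed = mask,
    design = data.frame(sample = colnames(values), fraction = fractions,
                        replicate = replicates, stringsAsFactors = FALSE),
    proteins = rownames(values)
  ), class = "lfq_matrix")
}

# build a minimal MaxQuant-dialect table (one LFQ column per sample name)
make_pg_table <- function(ids, intensities, peptides = 5L, unique = 2L,
                          reverse = "", contaminant = "", site = "",
                          lengths = NULL) {
  n <- length(ids)
  if (is.null(lengths)) lengths <- rep("500", n)
  df <- data.frame(
    `Protein IDs` = ids, `Sequence lengths` = lengths,
    Peptides = rep_len(peptides, n), `Unique peptides` = rep_len(unique, n),
    Reverse = rep_len(reverse, n),
    `Potential contaminant` = rep_len(contaminant, n),
    `Only identified by site` = rep_len(site, n),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(intensities, check.names = FALSE))
}

write_pg_fixture <- function(tab) {
  path <- tempfile(fileext = ".txt")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# exhaustive hypergeometric upper tail P(X >= k) from binomial coefficients
hyper_upper_tail <- function(k, K, n, N) {
  js <- max(k, 0L):min(n, K)
  js <- js[js >= n - (N - K)]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hand step-up Benjamini-Hochberg
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# all permutations of v (recursive, for the TSP brute-force oracle)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

open_path_length <- function(points, ord) {
  sum(sqrt(rowSums((points[ord[-length(ord)], , drop = FALSE] -
                      points[ord[-1L], , drop = FALSE])^2)))
}

brute_force_shortest_path <- function(points) {
  min(vapply(perms(seq_len(nrow(points))),
             function(p) open_path_length(points, p), 0))
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
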