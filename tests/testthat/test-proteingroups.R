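test_that("reading parses flags, zero-as-missing and the sample design", {
  ints <- data.frame(
    `LFQ intensity F1_R1` = c("1000", "0", "2000"),
    `LFQ intensity F1_R2` = c("1500", "1200", ""),
    `LFQ intensity F2_R1` = c("900", "800", "700"),
    `LFQ intensity F2_R2` = c("950", "850", "750"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  tab <- make_pg_table(c("A", "B", "C"), ints,
                       reverse = c("", "+", ""))
  pg <- read_protein_groups(write_pg_fixture(tab))

  expect_equal(nrow(pg$table), 3L)
  expect_equal(sum(pg$table$is_reverse), 1L)
  expect_true(pg$table$is_reverse[2])
  # zero and empty cells are missing
  expect_true(is.na(pg$intensity["B", "F1_R1"]))
  expect_true(is.na(pg$intensity["C", "F1_R2"]))
  expect_equal(pg$intensity["A", "F1_R1"], 1000)
  expect_equal(sort(unique(pg$design$fraction)), c(1L, 2L))
  expect_equal(sort(unique(pg$design$replicate)), c(1L, 2L))
})

test_that("a header-only file yields an empty record list", {
  ints <- data.frame(`LFQ intensity F1_R1` = character(0),
                     check.names = FALSE)
  tab <- make_pg_table(character(0), ints)
  pg <- read_protein_groups(write_pg_fixture(tab))
  expect_equal(nrow(pg$table), 0L)
  expect_equal(nrow(pg$intensity), 0L)
})

test_that("missing mandatory columns and unresolvable LFQ names are errors", {
  ints <- data.frame(`LFQ intensity F1_R1` = "10", check.names = FALSE)
  tab <- make_pg_table("A", ints)
  bad <- tab[, setdiff(names(tab), "Peptides")]
  expect_error(read_protein_groups(write_pg_fixture(bad)), "Peptides")

  tab2 <- make_pg_table("A", data.frame(`LFQ intensity weird` = "10",
                                        check.names = FALSE))
  expect_error(read_protein_groups(write_pg_fixture(tab2)), "design error")
})

test_that("filtering applies the peptide-evidence and flag rules and is idempotent", {
  ints <- data.frame(`LFQ intensity F1_R1` = as.character(1:6),
                     check.names = FALSE)
  tab <- make_pg_table(paste0("P", 1:6), ints,
                       peptides = c(2L, 3L, 1L, 5L, 5L, 5L),
                       unique = c(1L, 0L, 1L, 2L, 2L, 2L),
                       reverse = c("", "", "", "+", "", ""),
                       contaminant = c("", "", "", "", "+", ""))
  pg <- read_protein_groups(write_pg_fixture(tab))
  f <- filter_protein_groups(pg)
  # kept: P1 (2 peptides, 1 unique) and P6; removed: no unique, single
  # peptide, reverse, contaminant
  expect_equal(f$table$group_id, c("P1", "P6"))
  f2 <- filter_protein_groups(f)
  expect_equal(f2$table, f$table)
  expect_equal(f2$intensity, f$intensity)
})

test_that("representative selection takes the longest member, ties lexicographic", {
  expect_equal(select_representative("A", 100)$representative_id, "A")
  expect_equal(select_representative(c("A", "B"), c(100, 250))$representative_id,
               "B")
  tie <- select_representative(c("B", "A"), c(100, 100))
  expect_equal(tie$representative_id, "A")
  expect_equal(tie$rule, "longest_tie_lexicographic")
  # invariant to member listing order
  expect_equal(select_representative(c("X", "Y", "Z"), c(5, 9, 2)),
               select_representative(c("Z", "Y", "X"), c(2, 9, 5)))
  expect_error(select_representative(character(0), integer(0)), "empty")
})

test_that("imputed values stay inside the per-sample quantile interval", {
  set.seed(11)
  n <- 200L
  vals <- matrix(2^rnorm(n * 4, 25, 2), n, 4,
                 dimnames = list(sprintf("P%03d", 1:n),
                                 c("F1_R1", "F1_R2", "F2_R1", "F2_R2")))
  vals[sample(length(vals), 150)] <- 0
  ints <- as.data.frame(formatC(vals, format = "f", digits = 2))
  names(ints) <- paste0("LFQ intensity ", colnames(vals))
  tab <- make_pg_table(rownames(vals), ints)
  pg <- read_protein_groups(write_pg_fixture(tab))

  lfq <- log2_and_impute(pg, q_low = 0.01, q_high = 0.05, seed = 3)
  expect_false(any(is.na(lfq$values)))
  expect_identical(lfq$imputed, lfq$mask)
  for (j in seq_len(ncol(lfq$values))) {
    obs <- lfq$values[!lfq$mask[, j], j]
    b <- quantile(obs, c(0.01, 0.05), names = FALSE)
    imp <- lfq$values[lfq$mask[, j], j]
    expect_true(all(imp >= b[1] & imp <= b[2]))
  }
  # seeded determinism
  lfq2 <- log2_and_impute(pg, q_low = 0.01, q_high = 0.05, seed = 3)
  expect_identical(lfq$values, lfq2$values)
  # no missing cells: plain log2 transform, nothing imputed
  vals2 <- vals; vals2[vals2 == 0] <- 1000
  ints2 <- as.data.frame(formatC(vals2, format = "f", digits = 2))
  names(ints2) <- paste0("LFQ intensity ", colnames(vals2))
  pg2 <- read_protein_groups(write_pg_fixture(make_pg_table(rownames(vals2), ints2)))
  lfq3 <- log2_and_impute(pg2, seed = 1)
  expect_false(any(lfq3$imputed))
  expect_equal(lfq3$values, log2(pg2$intensity))
})

test_that("imputation fails loudly on an all-missing sample column", {
  ints <- data.frame(`LFQ intensity F1_R1` = c("0", "0"),
                     `LFQ intensity F1_R2` = c("10", "20"),
                     check.names = FALSE)
  pg <- read_protein_groups(write_pg_fixture(make_pg_table(c("A", "B"), ints)))
  expect_error(log2_and_impute(pg, seed = 1), "F1_R1")
})

test_that("replicate averaging takes arithmetic means, observed-only mode skips missing", {
  v <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("P1", c("F1_R1", "F1_R2", "F1_R3", "F1_R4")))
  lfq <- make_lfq(v, fractions = rep(1L, 4), replicates = 1:4)
  expect_equal(unname(average_replicates(lfq)[1, 1]), 2.5)

  mask <- matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4)
  lfq2 <- make_lfq(v, rep(1L, 4), 1:4, mask = mask)
  expect_equal(unname(average_replicates(lfq2, observed_only = TRUE)[1, 1]),
               1.5)
})

test_that("replicate correlations are symmetric, unit-diagonal, permutation-stable", {
  set.seed(4)
  v <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20), c("F1_R1", "F1_R2", "F2_R1")))
  v[, 3] <- -v[, 1]  # exact negation
  lfq <- make_lfq(v, c(1L, 1L, 2L), c(1L, 2L, 1L))
  r <- replicate_correlation(lfq)
  expect_equal(diag(r), setNames(rep(1, 3), colnames(v)))
  expect_equal(r, t(r))
  expect_equal(r["F1_R1", "F2_R1"], -1)
  expect_equal(r["F1_R1", "F1_R2"], cor(v[, 1], v[, 2]))
  # permuting protein order leaves the matrix unchanged
  perm <- sample(20)
  lfq_p <- make_lfq(v[perm, ], c(1L, 1L, 2L), c(1L, 2L, 1L))
  expect_equal(replicate_correlation(lfq_p), r)
  # fewer than three shared observations: undefined
  mask <- matrix(FALSE, 20, 3); mask[3:20, 2] <- TRUE
  lfq_m <- make_lfq(v, c(1L, 1L, 2L), c(1L, 2L, 1L), mask = mask)
  expect_true(is.na(replicate_correlation(lfq_m)["F1_R1", "F1_R2"]))
})

test_that("most_dynamic ranks by fraction-mean variance with brute-force agreement", {
  m <- matrix(c(5, 5, 5,
                1, 5, 9,
                2, 2, 3,
                0, 4, 8,
                7, 7, 7.5), 5, 3, byrow = TRUE,
              dimnames = list(paste0("P", 1:5), paste0("F", 1:3)))
  expect_equal(most_dynamic(m, 1), "P2")
  expect_setequal(most_dynamic(m, 10), rownames(m))
  v <- apply(m, 1, var)
  expect_equal(most_dynamic(m, 3), rownames(m)[order(-v, rownames(m))][1:3])
})

test_that("generated tables round-trip through the reader", {
  spec <- synthetic_spec(n_per_compartment = 5L, seed = 9)
  d <- generate_lfq_dataset(spec)
  pg <- read_protein_groups(write_pg_fixture(d$table))
  expect_equal(nrow(pg$table), nrow(d$table))
  expect_equal(sum(pg$table$is_contaminant), spec$n_contaminants)
  expect_equal(sum(pg$table$is_reverse), spec$n_reverse)
  expect_equal(sum(pg$table$is_only_by_site), spec$n_only_by_site)
  # zero cells in the written table come back as missing
  lfq_cols <- grep("^LFQ intensity ", names(d$table))
  zeros <- sum(d$table[, lfq_cols] == "0")
  expect_equal(sum(is.na(pg$intensity)), zeros)
})
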