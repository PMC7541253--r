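test_that("N50 follows the descending cumulative-sum definition", {
  expect_equal(n50(1000), 1000)
  expect_equal(n50(c(500, 400, 300, 200, 100)), 400)
  expect_equal(n50(c(2, 2, 2)), 2)
  expect_equal(n50(c(100, 200, 500, 400, 300)), 400)  # order-invariant
  expect_error(n50(numeric(0)), "empty")
})

test_that("ExN50 takes the minimal expression prefix and reduces to N50 at 100", {
  tr <- data.frame(length = c(100, 1000), expression = c(90, 10))
  expect_equal(exn50(tr, 90), 100)
  expect_equal(exn50(tr, 100), 1000)
  one <- data.frame(length = 777, expression = 5)
  expect_equal(exn50(one, 37), 777)
  set.seed(23)
  many <- data.frame(length = sample(100:5000, 50),
                     expression = rexp(50, 1 / 100))
  expect_equal(exn50(many, 100), n50(many$length))
  # the prefix is a non-increasing-expression head of the sorted list
  ord <- order(-many$expression, -many$length)
  expr <- many$expression[ord]
  cutoff <- which(cumsum(expr) >= 0.9 * sum(expr))[1]
  expect_equal(exn50(many, 90), n50(many$length[ord][1:cutoff]))
})

test_that("hit-coverage binning closes the top bin and uses a strict threshold", {
  h <- hit_coverage_bins(c(95))
  expect_equal(h$counts[10], 1L)
  expect_equal(h$fraction_above, 1)
  expect_equal(hit_coverage_bins(c(80))$fraction_above, 0)  # strict
  h2 <- hit_coverage_bins(c(5, 15, 95, 85))
  expect_equal(h2$counts, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(h2$fraction_above, 0.5)
  expect_equal(hit_coverage_bins(c(100))$counts[10], 1L)  # 100 in top bin
  expect_error(hit_coverage_bins(c(50, 101)), "contract")
})

test_that("split-pair classification compares gap depth against the weaker flank", {
  # gap depth 0, flanks 50: supported split
  tr <- coverage_track("chr", 0, 300, c(rep(50, 100), rep(0, 100), rep(50, 100)))
  r <- classify_split_pair(tr, c(0, 100), c(200, 300), c(100, 200))
  expect_equal(r$class, "evidently_split")
  # uniform coverage: false split
  tr2 <- coverage_track("chr", 0, 300, rep(50, 300))
  expect_equal(classify_split_pair(tr2, c(0, 100), c(200, 300),
                                   c(100, 200))$class,
               "probable_false_split")
  # threshold arithmetic: gap 4 vs flanks 50/60 -> 4 < 0.1 * 50
  tr3 <- coverage_track("chr", 0, 300, c(rep(50, 100), rep(4, 100), rep(60, 100)))
  expect_equal(classify_split_pair(tr3, c(0, 100), c(200, 300),
                                   c(100, 200))$class,
               "evidently_split")
  # threshold 0 never supports a split unless the gap is exactly empty
  expect_equal(classify_split_pair(tr3, c(0, 100), c(200, 300), c(100, 200),
                                   gap_ratio_threshold = 0)$class,
               "probable_false_split")
  expect_equal(classify_split_pair(tr, c(0, 100), c(200, 300), c(100, 200),
                                   gap_ratio_threshold = 1e-9)$class,
               "evidently_split")
  # conventions: zero-length gap and zero flank coverage
  r0 <- classify_split_pair(tr2, c(0, 100), c(100, 300), c(100, 100))
  expect_equal(r0$class, "probable_false_split")
  expect_equal(r0$flag, "zero_length_gap")
  tr4 <- coverage_track("chr", 0, 300, c(rep(0, 100), rep(10, 100), rep(50, 100)))
  r4 <- classify_split_pair(tr4, c(0, 100), c(200, 300), c(100, 200))
  expect_equal(r4$class, "probable_false_split")
  expect_equal(r4$flag, "zero_flank_coverage")
})

test_that("short-ORF classification tests edge coverage against the ORF", {
  # ORF covered at 100, empty edges: supported
  d <- c(rep(0, 100), rep(100, 300), rep(0, 100))
  tr <- coverage_track("tx", 0, 500, d)
  expect_equal(classify_short_orf(tr, c(100, 400), c(0, 500))$class,
               "supported_shorter")
  # edges as covered as the ORF: falsely shortened
  tr2 <- coverage_track("tx", 0, 500, rep(100, 500))
  expect_equal(classify_short_orf(tr2, c(100, 400), c(0, 500))$class,
               "probably_falsely_shorter")
  # worse edge mean 15 vs threshold 0.1 * 100 = 10: not supported
  d3 <- c(rep(0, 100), rep(100, 300), rep(15, 100))
  tr3 <- coverage_track("tx", 0, 500, d3)
  r3 <- classify_short_orf(tr3, c(100, 400), c(0, 500))
  expect_equal(r3$class, "probably_falsely_shorter")
  expect_equal(r3$mean_edge_right, 15)
  # ORF spanning the whole transcript: no edges, supported by convention
  r4 <- classify_short_orf(tr2, c(0, 500), c(0, 500))
  expect_equal(r4$class, "supported_shorter")
  expect_equal(r4$flag, "no_edge_region")
})

test_that("missense impact counts lost peptides among missense overlaps", {
  # the printed counts: 2325 affected of 2653
  pep <- data.frame(overlaps_missense = TRUE, trinity = TRUE,
                    silkbase = rep(c(FALSE, TRUE), c(2325, 328)))
  r <- missense_peptide_impact(pep)
  expect_equal(r$affected, 2325)
  expect_equal(r$total, 2653)
  expect_equal(r$proportion, 2325 / 2653)
  expect_equal(round(100 * r$proportion), 88)

  pep2 <- data.frame(overlaps_missense = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     trinity = TRUE,
                     silkbase = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(missense_peptide_impact(pep2)$proportion, 0.75)
  pep3 <- data.frame(overlaps_missense = TRUE, trinity = TRUE,
                     silkbase = rep(TRUE, 4))
  expect_equal(missense_peptide_impact(pep3)$proportion, 0)
  pep4 <- data.frame(overlaps_missense = FALSE, trinity = TRUE,
                     silkbase = TRUE)
  expect_true(is.na(missense_peptide_impact(pep4)$proportion))
  # brute-force recount on a random fixture
  set.seed(3)
  pep5 <- data.frame(overlaps_missense = runif(200) < 0.6, trinity = TRUE,
                     silkbase = runif(200) < 0.4)
  r5 <- missense_peptide_impact(pep5)
  expect_equal(r5$proportion,
               sum(pep5$overlaps_missense & !pep5$silkbase) /
                 sum(pep5$overlaps_missense))
  expect_true(r5$proportion >= 0 && r5$proportion <= 1)
})

test_that("ORF categorization applies the decision ladder exactly once per record", {
  rec <- data.frame(
    orf_id = paste0("orf", 1:7),
    has_reference_hit = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    hit_coverage = c(NA, 95, 95, 95, 80, 80, 95),
    split_class = c(NA, NA, "evidently_split", "probable_false_split",
                    NA, NA, NA),
    short_class = c(NA, NA, NA, NA, "supported_shorter",
                    "probably_falsely_shorter", NA),
    length_ratio = c(NA, 1.0, 1.0, 1.0, 0.7, 0.7, 1.5),
    stringsAsFactors = FALSE
  )
  out <- categorize_orfs(rec)
  expect_equal(out$category,
               c("newly_annotated", "high_correspondence", "evidently_split",
                 "probable_false_split", "evidently_shorter",
                 "probably_falsely_shorter", "longer_than_reference"))
  expect_equal(nrow(out), nrow(rec))          # exactly one label each
  # ladder is stable under record shuffling
  set.seed(6)
  perm <- sample(nrow(rec))
  out_p <- categorize_orfs(rec[perm, ])
  expect_equal(out_p$category[order(out_p$orf_id)],
               out$category[order(out$orf_id)])
  # split takes precedence over short, flagged
  rec2 <- rec[3, ]; rec2$short_class <- "supported_shorter"
  out2 <- categorize_orfs(rec2)
  expect_equal(out2$category, "evidently_split")
  expect_equal(out2$flag, "split_takes_precedence")
})

test_that("precision and variant-rate arithmetic reproduce the printed values", {
  expect_equal(precision_rate(6273, 348, 64), 93.4)
  expect_equal(precision_rate(100, 0, 0), 100.0)
  expect_equal(precision_rate(10, 1, 1), 80.0)
  expect_error(precision_rate(0, 0, 0))
  expect_equal(variant_rate(126300, 16393027), 129)
  expect_equal(variant_rate(187534, 19826985), 105)
  expect_equal(variant_rate(1, 100), 100)
  expect_equal(variant_rate(0, 100), Inf)
})

test_that("coverage tracks round-trip through bedGraph and BED files", {
  scen <- generate_coverage_scenarios(1, 1, 0, 0, depth = 30, seed = 2)
  bg_path <- tempfile(fileext = ".bedgraph")
  bed_path <- tempfile(fileext = ".bed")
  write_bedgraph(scen$tracks, bg_path)
  write_bed6(scen$intervals, bed_path)
  tracks <- read_bedgraph(bg_path)
  expect_setequal(names(tracks), names(scen$tracks))
  for (ref in names(tracks)) {
    expect_equal(tracks[[ref]]$depth, scen$tracks[[ref]]$depth)
    expect_equal(tracks[[ref]]$start, scen$tracks[[ref]]$start)
  }
  bed <- read_bed6(bed_path)
  expect_equal(nrow(bed), nrow(scen$intervals))
  expect_equal(sort(bed$name), sort(scen$intervals$name))
  expect_equal(bed$start[bed$name == scen$intervals$name[1]],
               scen$intervals$start[1])
})
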