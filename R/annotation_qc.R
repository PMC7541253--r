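#' N50 assembly statistic
#'
#' The largest length L such that contigs of length >= L together contain at
#' least half of the assembly's total bases, computed by a descending
#' cumulative sum.
#'
#' @param lengths positive contig lengths (non-empty).
#' @return a single length.
#' @export
#' @examples
#' n50(c(500, 400, 300, 200, 100))  # 400
n50 <- function(lengths) {
  if (length(lengths) == 0L)
    stop("contract violation: empty length list", call. = FALSE)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Expression-weighted N50 (ExN50)
#'
#' Transcripts are sorted by expression (descending); the minimal prefix
#' accumulating at least `x` percent of the total expression is taken and its
#' N50 returned.  Expression ties are broken by longer transcript first so
#' the prefix is deterministic.
#'
#' @param transcripts data.frame with columns `length` and `expression`
#'   (non-negative; total > 0).
#' @param x expression percentile, `0 < x <= 100` (e.g. 90 for E90N50).
#' @return a single length.
#' @export
exn50 <- function(transcripts, x) {
  stopifnot(all(c("length", "expression") %in% names(transcripts)),
            x > 0, x <= 100, all(transcripts$expression >= 0),
            sum(transcripts$expression) > 0)
  ord <- order(-transcripts$expression, -transcripts$length)
  expr <- transcripts$expression[ord]
  cutoff <- which(cumsum(expr) >= x / 100 * sum(expr))[1L]
  n50(transcripts$length[ord][seq_len(cutoff)])
}

#' Bin hit-coverage percentages and report the fraction above a threshold
#'
#' @param coverages percent values in `[0, 100]`.
#' @param bin_width bin width in percent (default 10).
#' @param threshold reporting threshold; the returned fraction counts values
#'   *strictly* greater than it.
#' @return list with `breaks`, `counts` (top bin closed, i.e. 100 falls in
#'   the last bin) and `fraction_above`.
#' @export
hit_coverage_bins <- function(coverages, bin_width = 10, threshold = 80) {
  if (any(coverages < 0 | coverages > 100))
    stop("contract violation: coverage values outside [0, 100]", call. = FALSE)
  breaks <- seq(0, 100, by = bin_width)
  nbin <- length(breaks) - 1L
  idx <- pmin(floor(coverages / bin_width) + 1L, nbin)
  list(breaks = breaks,
       counts = tabulate(idx, nbins = nbin),
       fraction_above = mean(coverages > threshold))
}

#' Classify a candidate split-gene pair by gap coverage
#'
#' A split into two genes is supported (`evidently_split`) when the mean
#' read depth over the gap between them falls below `gap_ratio_threshold`
#' times the mean depth of the *weaker* flanking transcript; continuous
#' coverage across the gap instead indicates a false split.
#'
#' @param track a [coverage_track()] spanning all three intervals.
#' @param left,right,gap 0-based half-open intervals `c(start, end)`, ordered
#'   `left <= gap <= right` on the reference.
#' @param gap_ratio_threshold gap-to-flank depth ratio below which the split
#'   is supported (default 0.1).
#' @param stat per-region summary, `"mean"` or `"median"`.
#' @return list with `class` (`"evidently_split"` or
#'   `"probable_false_split"`), the three region depths, and `flag`
#'   (`NA`, `"zero_length_gap"`, or `"zero_flank_coverage"`).
#' @export
classify_split_pair <- function(track, left, right, gap,
                                gap_ratio_threshold = 0.1,
                                stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!(left[2L] <= gap[1L] && gap[2L] <= right[1L]))
    stop("intervals must be ordered left <= gap <= right", call. = FALSE)
  res <- list(class = "probable_false_split",
              mean_gap = NA_real_, mean_left = NA_real_,
              mean_right = NA_real_, flag = NA_character_)
  res$mean_left <- mean_depth(track, left[1L], left[2L], stat)
  res$mean_right <- mean_depth(track, right[1L], right[2L], stat)
  if (gap[1L] == gap[2L]) {
    res$flag <- "zero_length_gap"
    return(res)
  }
  res$mean_gap <- mean_depth(track, gap[1L], gap[2L], stat)
  weaker <- min(res$mean_left, res$mean_right)
  if (weaker == 0) {
    res$flag <- "zero_flank_coverage"
    return(res)
  }
  if (res$mean_gap < gap_ratio_threshold * weaker)
    res$class <- "evidently_split"
  res
}

#' Classify a shorter-than-reference ORF by transcript-edge coverage
#'
#' An ORF shorter than its reference counterpart is supported
#' (`supported_shorter`) when the transcript regions just outside the ORF
#' show an evident absence of reads: the larger of the two edge-region mean
#' depths must fall below `edge_ratio_threshold` times the ORF's mean depth.
#'
#' @param track a [coverage_track()].
#' @param orf,transcript 0-based half-open intervals `c(start, end)` with
#'   `orf` inside `transcript`.
#' @param edge_window edge region size in bases on each side (truncated at
#'   the transcript bounds; default 50).
#' @param edge_ratio_threshold edge-to-ORF depth ratio (default 0.1).
#' @param stat per-region summary, `"mean"` or `"median"`.
#' @return list with `class` (`"supported_shorter"` or
#'   `"probably_falsely_shorter"`), `mean_orf`, `mean_edge_left`,
#'   `mean_edge_right`, `flag`.
#' @export
classify_short_orf <- function(track, orf, transcript, edge_window = 50,
                               edge_ratio_threshold = 0.1,
                               stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!(transcript[1L] <= orf[1L] && orf[2L] <= transcript[2L]))
    stop("ORF must lie inside the transcript", call. = FALSE)
  left <- c(max(transcript[1L], orf[1L] - edge_window), orf[1L])
  right <- c(orf[2L], min(transcript[2L], orf[2L] + edge_window))
  m_orf <- mean_depth(track, orf[1L], orf[2L], stat)
  m_l <- if (left[2L] > left[1L]) mean_depth(track, left[1L], left[2L], stat)
         else NA_real_
  m_r <- if (right[2L] > right[1L]) mean_depth(track, right[1L], right[2L], stat)
         else NA_real_
  res <- list(class = "probably_falsely_shorter", mean_orf = m_orf,
              mean_edge_left = m_l, mean_edge_right = m_r,
              flag = NA_character_)
  if (is.na(m_l) && is.na(m_r)) {  # ORF fills the transcript: no edges
    res$class <- "supported_shorter"
    res$flag <- "no_edge_region"
    return(res)
  }
  worst <- max(m_l, m_r, na.rm = TRUE)
  if (worst < edge_ratio_threshold * m_orf)
    res$class <- "supported_shorter"
  res
}

#' Proportion of missense-overlapping peptides lost in an alternate search
#'
#' Among peptides overlapping a predicted missense position (all identified
#' in the base search space), the proportion that the alternate search space
#' failed to identify — the measurable impact of sequence variation on
#' peptide identification.
#'
#' @param peptides data.frame with logical columns `overlaps_missense` plus
#'   one identification column per search space.
#' @param base_space,alt_space names of the identification columns.
#' @return list with `affected`, `total`, `proportion` (`NA` when no peptide
#'   overlaps a missense position).
#' @export
missense_peptide_impact <- function(peptides, base_space = "trinity",
                                    alt_space = "silkbase") {
  stopifnot(all(c("overlaps_missense", base_space, alt_space) %in%
                  names(peptides)))
  if (!all(peptides[[base_space]]))
    stop("every peptide must be identified in the base search space",
         call. = FALSE)
  ov <- peptides$overlaps_missense
  total <- sum(ov)
  affected <- sum(ov & !peptides[[alt_space]])
  list(affected = affected, total = total,
       proportion = if (total == 0L) NA_real_ else affected / total)
}

#' Categorize ORFs against a reference annotation
#'
#' Applies a fixed decision ladder per ORF (first match wins):
#' no reference hit -> `newly_annotated`; member of a split pair -> its
#' split classification; hit coverage below `coverage_cutoff` -> its
#' short-ORF classification (`supported_shorter` reported as
#' `evidently_shorter`); longer than the reference beyond
#' `length_tolerance` -> `longer_than_reference`; otherwise
#' `high_correspondence`.
#'
#' @param records data.frame with columns `orf_id`, `has_reference_hit`
#'   (logical), `hit_coverage` (percent, `NA` allowed when no hit),
#'   `split_class` (`NA`, `"evidently_split"` or `"probable_false_split"`),
#'   `short_class` (`NA`, `"supported_shorter"` or
#'   `"probably_falsely_shorter"`), `length_ratio` (ORF / reference length).
#' @param coverage_cutoff hit-coverage percent below which the short branch
#'   applies (default 85).
#' @param length_tolerance length ratio above which an ORF counts as longer
#'   than its reference (default 1.1).
#' @return data.frame with `orf_id`, `category`, `flag`.
#' @export
categorize_orfs <- function(records, coverage_cutoff = 85,
                            length_tolerance = 1.1) {
  needed <- c("orf_id", "has_reference_hit", "hit_coverage",
              "split_class", "short_class", "length_ratio")
  stopifnot(all(needed %in% names(records)))
  n <- nrow(records)
  category <- character(n)
  flag <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (!r$has_reference_hit) {
      category[i] <- "newly_annotated"
    } else if (!is.na(r$split_class)) {
      category[i] <- r$split_class
      if (!is.na(r$short_class)) flag[i] <- "split_takes_precedence"
    } else if (!is.na(r$hit_coverage) && r$hit_coverage < coverage_cutoff) {
      if (is.na(r$short_class)) {
        category[i] <- "probably_falsely_shorter"
        flag[i] <- "no_coverage_evidence"
      } else if (r$short_class == "supported_shorter") {
        category[i] <- "evidently_shorter"
      } else {
        category[i] <- "probably_falsely_shorter"
      }
    } else if (!is.na(r$length_ratio) && r$length_ratio > length_tolerance) {
      category[i] <- "longer_than_reference"
    } else {
      category[i] <- "high_correspondence"
    }
  }
  data.frame(orf_id = records$orf_id, category = category, flag = flag,
             stringsAsFactors = FALSE)
}

#' Gene-assignment precision rate
#'
#' Percentage of detected protein groups not implicated as false splits or
#' falsely shortened gene models, reported to one decimal.
#'
#' @param total_detected total detected protein groups.
#' @param n_false_split_proteins proteins in probable false splits.
#' @param n_false_short probably-falsely-shorter ORFs.
#' @return percent, one decimal.
#' @export
#' @examples
#' precision_rate(6273, 348, 64)  # 93.4
precision_rate <- function(total_detected, n_false_split_proteins,
                           n_false_short) {
  stopifnot(total_detected > 0, n_false_split_proteins >= 0,
            n_false_short >= 0,
            n_false_split_proteins + n_false_short <= total_detected)
  round(100 * (total_detected - n_false_split_proteins - n_false_short) /
          total_detected, 1)
}

#' Sequence-variation rate as "1 in N bases"
#'
#' @param n_changes number of base changes observed (>= 0).
#' @param n_bases number of bases compared.
#' @return integer N (`floor(n_bases / n_changes)`); `Inf` when no changes.
#' @export
#' @examples
#' variant_rate(126300, 16393027)  # 129
variant_rate <- function(n_changes, n_bases) {
  stopifnot(n_changes >= 0, n_bases > 0)
  if (n_changes == 0) return(Inf)  # no-variation sentinel
  floor(n_bases / n_changes)
}
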