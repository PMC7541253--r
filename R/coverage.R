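#' Per-base coverage over a reference interval
#'
#' Coordinates are 0-based, half-open (the bedGraph/BED convention):
#' `depth[1]` covers base `[start, start+1)`.
#'
#' @param reference reference sequence name.
#' @param start,end interval bounds, `0 <= start < end`.
#' @param depth non-negative per-base depths, length `end - start`.
#' @return a `coverage_track` object.
#' @export
coverage_track <- function(reference, start, end, depth) {
  stopifnot(start >= 0, end > start, length(depth) == end - start,
            all(depth >= 0))
  structure(list(reference = reference, start = as.integer(start),
                 end = as.integer(end), depth = as.numeric(depth)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s:%d-%d (mean depth %.2f)\n",
              x$reference, x$start, x$end, mean(x$depth)))
  invisible(x)
}

#' Mean depth over a subinterval of a coverage track
#'
#' @param track a `coverage_track`.
#' @param start,end 0-based half-open subinterval, inside the track span.
#'   A zero-length interval returns `NA`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return a single number.
#' @export
mean_depth <- function(track, start, end, stat = c("mean", "median")) {
  stopifnot(inherits(track, "coverage_track"))
  stat <- match.arg(stat)
  if (end == start) return(NA_real_)
  if (start < track$start || end > track$end || end < start)
    stop("interval outside coverage span", call. = FALSE)
  idx <- (start - track$start + 1L):(end - track$start)
  if (stat == "mean") mean(track$depth[idx]) else median(track$depth[idx])
}

#' Read a bedGraph file into coverage tracks
#'
#' Uses `rtracklayer` to parse the file, then expands the interval scores to
#' per-base depth, one track per reference sequence (uncovered positions
#' inside a track's span get depth 0).
#'
#' @param path bedGraph file path.
#' @return named list of [coverage_track()] objects, one per reference.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  refs <- unique(as.character(GenomicRanges::seqnames(gr)))
  out <- lapply(refs, function(ref) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ref]
    s0 <- GenomicRanges::start(g) - 1L  # to 0-based
    e0 <- GenomicRanges::end(g)
    lo <- min(s0); hi <- max(e0)
    depth <- numeric(hi - lo)
    for (i in seq_along(g)) {
      depth[(s0[i] - lo + 1L):(e0[i] - lo)] <- g$score[i]
    }
    coverage_track(ref, lo, hi, depth)
  })
  names(out) <- refs
  out
}

#' Read a BED6 interval file
#'
#' @param path BED file path.
#' @return data.frame with `reference`, `start` (0-based), `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    reference = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) NA_character_ else gr$name,
    score = if (is.null(gr$score)) 0 else gr$score,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write coverage tracks to a bedGraph file
#'
#' Consecutive equal depths are collapsed into single bedGraph lines.
#'
#' @param tracks named list of [coverage_track()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  lines <- character(0)
  for (tr in tracks) {
    r <- rle(tr$depth)
    ends <- tr$start + cumsum(r$lengths)
    starts <- c(tr$start, head(ends, -1L))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%g",
                              tr$reference, starts, ends, r$values))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals to a BED6 file
#'
#' @param intervals data.frame with `reference`, `start` (0-based), `end`,
#'   `name`, and optional `score`, `strand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "+"
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     intervals$reference, intervals$start, intervals$end,
                     intervals$name, score, strand), path)
  invisible(path)
}
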