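#' Describe how LFQ sample columns map to (fraction, replicate)
#'
#' MaxQuant writes one `LFQ intensity <sample>` column per sample; the sample
#' naming differs between facilities.  The design holds a regular expression
#' with two capture groups — fraction index first, replicate index second —
#' applied to the part of the column name after `"LFQ intensity "`.
#'
#' @param pattern regular expression with exactly two integer capture groups.
#' @param prefix column prefix identifying LFQ columns.
#' @return an object of class `lfq_design`.
#' @export
#' @examples
#' lfq_design()  # matches columns like "LFQ intensity F3_R2"
lfq_design <- function(pattern = "^F(\\d+)_R(\\d+)$",
                       prefix = "LFQ intensity ") {
  structure(list(pattern = pattern, prefix = prefix), class = "lfq_design")
}

.required_pg_columns <- c(
  "Protein IDs", "Peptides", "Unique peptides",
  "Reverse", "Potential contaminant", "Only identified by site"
)

#' Read a MaxQuant-dialect protein-groups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect into a
#' `protein_groups` object: per-group metadata (members, peptide counts,
#' contaminant / reverse / only-by-site flags) plus a protein x sample raw
#' intensity matrix.  Zero and empty LFQ cells are recorded as missing
#' (`NA`): MaxQuant writes 0 for non-detection, not for zero abundance.
#'
#' @param path path to the tab-separated table (header row required).
#' @param design an [lfq_design()] mapping LFQ column names to
#'   (fraction, replicate).
#' @return a `protein_groups` object: list with `table` (metadata
#'   data.frame with list-columns `member_ids`, `member_lengths`),
#'   `intensity` (numeric matrix, `NA` = missing) and `design`
#'   (data.frame sample/fraction/replicate).
#' @export
read_protein_groups <- function(path, design = lfq_design()) {
  stopifnot(inherits(design, "lfq_design"))
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(.required_pg_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("protein-groups format error: missing column(s) ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)

  lfq_cols <- grep(paste0("^", design$prefix), names(raw), value = TRUE)
  if (length(lfq_cols) == 0L)
    stop("protein-groups format error: no LFQ intensity columns found",
         call. = FALSE)
  sample_names <- sub(paste0("^", design$prefix), "", lfq_cols)
  m <- regmatches(sample_names, regexec(design$pattern, sample_names))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("design error: LFQ column(s) not resolvable to (fraction, replicate): ",
         paste(sQuote(lfq_cols[bad]), collapse = ", "), call. = FALSE)
  design_df <- data.frame(
    sample = sample_names,
    fraction = as.integer(vapply(m, `[`, "", 2L)),
    replicate = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )

  n <- nrow(raw)
  member_ids <- strsplit(raw[["Protein IDs"]], ";", fixed = TRUE)
  if (any(lengths(member_ids) == 0L) && n > 0L)
    stop("protein-groups format error: empty 'Protein IDs' entry", call. = FALSE)
  member_lengths <- if ("Sequence lengths" %in% names(raw)) {
    lapply(strsplit(raw[["Sequence lengths"]], ";", fixed = TRUE), as.integer)
  } else {
    rep(list(NA_integer_), n)
  }

  flag <- function(col) !is.na(raw[[col]]) & raw[[col]] == "+"
  tab <- data.frame(
    group_id = if (n > 0L) vapply(member_ids, `[`, "", 1L) else character(0),
    n_peptides = as.integer(raw[["Peptides"]]),
    n_unique_peptides = as.integer(raw[["Unique peptides"]]),
    is_contaminant = flag("Potential contaminant"),
    is_reverse = flag("Reverse"),
    is_only_by_site = flag("Only identified by site"),
    stringsAsFactors = FALSE
  )
  tab$member_ids <- member_ids
  tab$member_lengths <- member_lengths

  intensity <- matrix(NA_real_, nrow = n, ncol = length(lfq_cols),
                      dimnames = list(tab$group_id, design_df$sample))
  for (j in seq_along(lfq_cols)) {
    v <- suppressWarnings(as.numeric(raw[[lfq_cols[j]]]))
    v[!is.na(v) & v == 0] <- NA_real_
    intensity[, j] <- v
  }

  structure(list(table = tab, intensity = intensity, design = design_df),
            class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d groups, %d samples (%d fractions x %d replicates)\n",
              nrow(x$table), nrow(x$design),
              length(unique(x$design$fraction)),
              length(unique(x$design$replicate))))
  invisible(x)
}

#' Filter protein groups by evidence and decoy flags
#'
#' Retains groups with at least two peptides, at least one of them unique,
#' and none of the contaminant / reverse / only-identified-by-site flags set.
#' Row order is preserved; the operation is idempotent.
#'
#' @param pg a `protein_groups` object.
#' @return the filtered `protein_groups` object, with a `"removed"` attribute
#'   giving removal counts per rule.
#' @export
filter_protein_groups <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  t <- pg$table
  flagged <- t$is_contaminant | t$is_reverse | t$is_only_by_site
  low_pept <- t$n_peptides < 2L
  no_unique <- t$n_unique_peptides < 1L
  keep <- !flagged & !low_pept & !no_unique
  out <- pg
  out$table <- t[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out$intensity <- pg$intensity[keep, , drop = FALSE]
  attr(out, "removed") <- c(
    flagged = sum(flagged),
    fewer_than_two_peptides = sum(!flagged & low_pept),
    no_unique_peptide = sum(!flagged & !low_pept & no_unique)
  )
  out
}

#' Choose the representative member of a protein group
#'
#' The longest member represents the group; length ties are broken by the
#' lexicographically smallest identifier so the choice does not depend on the
#' order members are listed in.
#'
#' @param member_ids character vector of member identifiers (non-empty).
#' @param member_lengths integer amino-acid lengths, parallel to `member_ids`.
#' @return list with `representative_id` and `rule` (`"longest"` or
#'   `"longest_tie_lexicographic"`).
#' @export
select_representative <- function(member_ids, member_lengths) {
  if (length(member_ids) == 0L)
    stop("contract violation: empty protein group", call. = FALSE)
  stopifnot(length(member_ids) == length(member_lengths))
  best <- which(member_lengths == max(member_lengths))
  tie <- length(best) > 1L
  rep_id <- sort(member_ids[best])[1L]
  list(representative_id = rep_id,
       rule = if (tie) "longest_tie_lexicographic" else "longest")
}

#' Representatives for every group in a table
#'
#' @param pg a `protein_groups` object with known member lengths.
#' @return data.frame with `group_id`, `representative_id`, `rule`.
#' @export
representatives <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  res <- Map(select_representative, pg$table$member_ids, pg$table$member_lengths)
  data.frame(
    group_id = pg$table$group_id,
    representative_id = vapply(res, `[[`, "", "representative_id"),
    rule = vapply(res, `[[`, "", "rule"),
    stringsAsFactors = FALSE
  )
}
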