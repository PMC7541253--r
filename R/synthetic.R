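#' Default compartment archetype profiles
#'
#' Eight qualitative fraction-profile shapes on a standardized (z) scale for
#' a 10-step differential-centrifugation series: mitochondria pellet early
#' (high in the first three fractions), peroxisome/ER-type profiles fall off
#' after the fourth or fifth step, Golgi persists until step 8, ribosomes
#' peak in fractions 7-9, nuclear and chromatin-associated profiles rise
#' through the series, and a terminal-spike shape jumps in the final
#' acetone-precipitate fractions.
#'
#' @return 8 x 10 matrix, rownames are compartment names.
#' @export
default_archetypes <- function() {
  rbind(
    mitochondrion  = c( 1.5,  1.4,  1.2, -0.3, -0.6, -0.7, -0.7, -0.6, -0.6, -0.6),
    peroxisome     = c( 1.1,  1.1,  1.0,  0.9, -0.5, -0.7, -0.8, -0.8, -0.7, -0.6),
    er             = c( 0.6,  0.7,  0.9,  1.0,  0.9, -0.6, -0.9, -0.9, -0.9, -0.8),
    golgi          = c( 0.5,  0.6,  0.6,  0.7,  0.7,  0.7,  0.6,  0.5, -1.5, -1.6),
    ribosome       = c(-0.8, -0.8, -0.7, -0.5, -0.2,  0.4,  1.2,  1.4,  1.3, -0.4),
    nucleus        = c(-1.0, -0.9, -0.8, -0.4,  0.0,  0.4,  0.7,  0.9,  1.0,  0.8),
    chromatin_mix  = c(-0.9, -0.8, -0.6, -0.2,  0.2,  0.6,  0.9,  1.1,  1.2, -1.4),
    terminal_spike = c(-0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.4, -0.3,  1.8,  2.0)
  )
}

#' Parameterize the synthetic LFQ data generator
#'
#' Bundles every knob of the planted-truth generator.  Defaults emulate the
#' study design the pipeline targets: 10 fractions in quadruplicate, eight
#' compartment archetypes, Gaussian log-scale replicate noise, left-censored
#' missingness, decoy/contaminant rows and noisy category annotations.
#'
#' @param n_fractions,n_replicates design dimensions (defaults 10 and 4).
#' @param archetypes compartment x fraction matrix of z-scale profile
#'   shapes; see [default_archetypes()].
#' @param n_per_compartment proteins per compartment (recycled across
#'   compartments).
#' @param archetype_scale log2 units per archetype z unit (profile
#'   amplitude; default 2).
#' @param noise_sd replicate noise standard deviation, log2 units
#'   (default 0.15).
#' @param missing_rate maximum left-censoring probability in `[0, 1]`
#'   (default 0.25); realised probability decays logistically with log2
#'   intensity.
#' @param n_contaminants,n_reverse,n_only_by_site,n_low_evidence counts of
#'   flagged / low-evidence filler rows exercising the filters.
#' @param category_tpr probability that a compartment member carries its
#'   true category label (default 0.6).
#' @param category_fpr probability of each spurious label (default 0.01).
#' @param base_log_abundance `c(mean, sd)` of the per-protein base log2
#'   abundance (default 26, 2 — typical LFQ scale).
#' @param seed integer RNG seed.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_fractions = 10L, n_replicates = 4L,
                           archetypes = default_archetypes(),
                           n_per_compartment = 80L,
                           archetype_scale = 2,
                           noise_sd = 0.15,
                           missing_rate = 0.25,
                           n_contaminants = 10L, n_reverse = 10L,
                           n_only_by_site = 5L, n_low_evidence = 10L,
                           category_tpr = 0.6, category_fpr = 0.01,
                           base_log_abundance = c(mean = 26, sd = 2),
                           seed = 1L) {
  if (ncol(archetypes) != n_fractions)
    stop("spec error: archetype length must equal n_fractions", call. = FALSE)
  stopifnot(n_replicates >= 2L,
            missing_rate >= 0, missing_rate <= 1,
            category_tpr >= 0, category_tpr <= 1,
            category_fpr >= 0, category_fpr <= 1,
            noise_sd >= 0, archetype_scale > 0,
            all(n_per_compartment >= 0))
  n_per <- rep_len(as.integer(n_per_compartment), nrow(archetypes))
  names(n_per) <- rownames(archetypes)
  structure(list(
    n_fractions = as.integer(n_fractions),
    n_replicates = as.integer(n_replicates),
    archetypes = archetypes, n_per_compartment = n_per,
    archetype_scale = archetype_scale, noise_sd = noise_sd,
    missing_rate = missing_rate,
    n_contaminants = as.integer(n_contaminants),
    n_reverse = as.integer(n_reverse),
    n_only_by_site = as.integer(n_only_by_site),
    n_low_evidence = as.integer(n_low_evidence),
    category_tpr = category_tpr, category_fpr = category_fpr,
    base_log_abundance = base_log_abundance,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a MaxQuant-dialect protein-groups table with planted truth
#'
#' For each protein a base log2 abundance is drawn, the compartment
#' archetype (scaled to log2 units) is added per fraction, i.i.d. Gaussian
#' replicate noise is added and the result exponentiated to intensities.
#' Left-censored missingness removes low-intensity cells with logistically
#' increasing probability.  Contaminant, reverse, only-by-site and
#' low-evidence rows are appended to exercise the filters.  The generator is
#' a pure function of the spec (same seed, byte-identical output).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (data.frame in the MaxQuant protein-groups
#'   dialect; missing LFQ cells are written as 0) and `truth` (list:
#'   `compartment` named vector, `archetypes`, `spec`).
#' @export
generate_lfq_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  FF <- spec$n_fractions; RR <- spec$n_replicates
  comps <- rownames(spec$archetypes)
  n_real <- sum(spec$n_per_compartment)
  compartment <- rep(comps, spec$n_per_compartment)
  ids <- sprintf("PG%05d", seq_len(n_real))
  names(compartment) <- ids

  sample_names <- as.vector(outer(seq_len(FF), seq_len(RR),
                                  function(f, r) sprintf("F%d_R%d", f, r)))
  frac_of <- as.integer(sub("^F(\\d+)_R\\d+$", "\\1", sample_names))

  out <- with_seed_if(spec$seed, {
    base <- rnorm(n_real, spec$base_log_abundance[["mean"]],
                  spec$base_log_abundance[["sd"]])
    profile <- spec$archetype_scale * spec$archetypes[compartment, , drop = FALSE]
    v <- matrix(NA_real_, n_real, FF * RR,
                dimnames = list(ids, sample_names))
    for (j in seq_along(sample_names)) {
      v[, j] <- base + profile[, frac_of[j]] +
        rnorm(n_real, 0, spec$noise_sd)
    }
    # left-censoring: logistic in log2 intensity, centred low in the
    # intensity distribution so censoring hits low-abundance cells hardest
    miss <- matrix(FALSE, n_real, FF * RR)
    if (spec$missing_rate > 0) {
      centre <- quantile(v, 0.15, names = FALSE)
      p_miss <- spec$missing_rate * plogis(-(v - centre) / 1.5)
      miss <- matrix(runif(length(v)) < p_miss, n_real, FF * RR)
    }
    intensity <- 2^v
    intensity[miss] <- 0

    # group membership: a third of the groups carry 2-3 members
    n_members <- sample(c(1L, 1L, 2L, 3L), n_real, replace = TRUE)
    member_ids <- lapply(seq_len(n_real), function(i) {
      sprintf("TRINITY_DN%05d_c0_g%d", i, seq_len(n_members[i]))
    })
    member_lengths <- lapply(n_members, function(k) sample(100:1500, k))
    n_pept <- 2L + rpois(n_real, 8)
    n_uniq <- pmin(n_pept, 1L + rpois(n_real, 3))

    filler <- function(n, prefix) {
      if (n == 0L) return(NULL)
      fid <- sprintf("%s%03d", prefix, seq_len(n))
      fint <- matrix(2^rnorm(n * FF * RR, spec$base_log_abundance[["mean"]],
                             spec$base_log_abundance[["sd"]]),
                     n, FF * RR, dimnames = list(fid, sample_names))
      list(ids = fid, intensity = fint,
           lengths = sample(100:1500, n, replace = TRUE))
    }
    cont <- filler(spec$n_contaminants, "CON__P")
    rev_ <- filler(spec$n_reverse, "REV__P")
    obs <- filler(spec$n_only_by_site, "OBS__P")
    low <- filler(spec$n_low_evidence, "LOW__P")

    list(intensity = intensity, member_ids = member_ids,
         member_lengths = member_lengths, n_pept = n_pept, n_uniq = n_uniq,
         cont = cont, rev_ = rev_, obs = obs, low = low)
  })

  fmt_num <- function(x) sub("\\.?0+$", "", formatC(x, format = "f", digits = 4))
  build_rows <- function(ids_, members, lengths, pept, uniq, intensity,
                         contaminant = "", reverse = "", site = "") {
    if (length(ids_) == 0L) return(NULL)
    df <- data.frame(
      `Protein IDs` = vapply(members, paste, "", collapse = ";"),
      `Sequence lengths` = vapply(lengths, paste, "", collapse = ";"),
      Peptides = pept, `Unique peptides` = uniq,
      Reverse = reverse, `Potential contaminant` = contaminant,
      `Only identified by site` = site,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    lfq <- as.data.frame(apply(intensity, 2L, fmt_num),
                         stringsAsFactors = FALSE)
    if (length(ids_) == 1L) lfq <- as.data.frame(t(lfq))  # apply drops dim
    names(lfq) <- paste0("LFQ intensity ", colnames(intensity))
    cbind(df, lfq)
  }

  real <- build_rows(ids,
                     lapply(seq_along(ids), function(i) {
                       m <- out$member_ids[[i]]
                       m[1L] <- ids[i]  # group id leads the member list
                       m
                     }),
                     out$member_lengths, out$n_pept, out$n_uniq,
                     out$intensity)
  fill_rows <- function(f, ...) {
    if (is.null(f)) return(NULL)
    build_rows(f$ids, as.list(f$ids), as.list(f$lengths),
               rep(5L, length(f$ids)), rep(2L, length(f$ids)),
               f$intensity, ...)
  }
  low_rows <- if (is.null(out$low)) NULL else {
    r <- build_rows(out$low$ids, as.list(out$low$ids),
                    as.list(out$low$lengths),
                    rep(1L, length(out$low$ids)),   # fails the 2-peptide rule
                    rep(1L, length(out$low$ids)),
                    out$low$intensity)
    r
  }
  tab <- rbind(real,
               fill_rows(out$cont, contaminant = "+"),
               fill_rows(out$rev_, reverse = "+"),
               fill_rows(out$obs, site = "+"),
               low_rows)
  rownames(tab) <- NULL

  truth <- list(compartment = compartment,
                archetypes = spec$archetypes, spec = spec)
  list(table = tab, truth = truth)
}

#' Write a protein-groups table to a tab-separated file
#'
#' @param table data.frame from [generate_lfq_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate noisy category annotations from planted truth
#'
#' Each real protein receives its true compartment label with probability
#' `category_tpr` and each wrong label with probability `category_fpr`.
#'
#' @param truth the `truth` element of [generate_lfq_dataset()].
#' @param spec the [synthetic_spec()] used (supplies the probabilities).
#' @param seed RNG seed (defaults to the spec's seed plus one so the draw is
#'   independent of the intensity draw but still a pure function of the
#'   spec).
#' @return data.frame with `protein_id`, `category` (long format).
#' @export
generate_annotations <- function(truth, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- rownames(spec$archetypes)
  ids <- names(truth$compartment)
  with_seed_if(seed, {
    rows <- lapply(seq_along(ids), function(i) {
      true_cat <- truth$compartment[[i]]
      labs <- character(0)
      if (runif(1) < spec$category_tpr) labs <- true_cat
      wrong <- setdiff(vocab, true_cat)
      labs <- c(labs, wrong[runif(length(wrong)) < spec$category_fpr])
      if (length(labs) == 0L) return(NULL)
      data.frame(protein_id = ids[i], category = labs,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(protein_id = character(0), category = character(0),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate coverage scenarios for the split / short-ORF classifiers
#'
#' Each scenario lives on its own reference sequence.  True splits carry
#' near-zero Poisson gap depth between two covered flanks; false splits are
#' covered throughout.  True short-ORF scenarios have empty transcript
#' edges around a covered ORF; false ones are covered edge to edge.
#'
#' @param n_split_true,n_split_false,n_short_true,n_short_false scenario
#'   counts.
#' @param depth mean Poisson read depth of covered regions (default 50).
#' @param seed RNG seed.
#' @return list with `tracks` (named list of [coverage_track()]),
#'   `intervals` (BED-style data.frame with a `role` column:
#'   left/right/gap/transcript/orf) and `truth` (data.frame: `scenario`,
#'   `kind`, `label`).
#' @export
generate_coverage_scenarios <- function(n_split_true, n_split_false,
                                        n_short_true, n_short_false,
                                        depth = 50, seed = 1L) {
  stopifnot(n_split_true >= 0, n_split_false >= 0,
            n_short_true >= 0, n_short_false >= 0, depth > 0)
  flank <- 400L; gap <- 200L; tx_len <- 1000L
  orf <- c(300L, 700L)
  with_seed_if(seed, {
    tracks <- list(); intervals <- list(); truth <- list()
    add_split <- function(i, true_gap) {
      ref <- sprintf("split_%s_%03d", if (true_gap) "true" else "false", i)
      lam_gap <- if (true_gap) 0.02 * depth else depth
      d <- c(rpois(flank, depth), rpois(gap, lam_gap), rpois(flank, depth))
      tracks[[ref]] <<- coverage_track(ref, 0L, 2L * flank + gap, d)
      intervals[[length(intervals) + 1L]] <<- data.frame(
        reference = ref, start = c(0L, flank, flank + gap),
        end = c(flank, flank + gap, 2L * flank + gap),
        name = paste0(ref, c("_left", "_gap", "_right")),
        role = c("left", "gap", "right"), stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <<- data.frame(
        scenario = ref, kind = "split",
        label = if (true_gap) "evidently_split" else "probable_false_split",
        stringsAsFactors = FALSE
      )
    }
    add_short <- function(i, true_short) {
      ref <- sprintf("short_%s_%03d", if (true_short) "true" else "false", i)
      lam_edge <- if (true_short) 0.01 * depth else depth
      d <- c(rpois(orf[1L], lam_edge),
             rpois(orf[2L] - orf[1L], depth),
             rpois(tx_len - orf[2L], lam_edge))
      tracks[[ref]] <<- coverage_track(ref, 0L, tx_len, d)
      intervals[[length(intervals) + 1L]] <<- data.frame(
        reference = ref, start = c(0L, orf[1L]), end = c(tx_len, orf[2L]),
        name = paste0(ref, c("_transcript", "_orf")),
        role = c("transcript", "orf"), stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <<- data.frame(
        scenario = ref, kind = "short",
        label = if (true_short) "supported_shorter"
                else "probably_falsely_shorter",
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(n_split_true)) add_split(i, TRUE)
    for (i in seq_len(n_split_false)) add_split(i, FALSE)
    for (i in seq_len(n_short_true)) add_short(i, TRUE)
    for (i in seq_len(n_short_false)) add_short(i, FALSE)
    list(
      tracks = tracks,
      intervals = if (length(intervals)) do.call(rbind, intervals)
                  else data.frame(),
      truth = if (length(truth)) do.call(rbind, truth) else data.frame()
    )
  })
}

#' Generate peptide identification scenarios for the missense analysis
#'
#' Peptides identified in the base search space, each overlapping a planted
#' missense position; a planted fraction of them is flagged unidentified in
#' the alternate search space.
#'
#' @param n_proteins number of proteins peptides are drawn from.
#' @param n_peptides number of missense-overlapping peptides.
#' @param affected_fraction planted probability a peptide is lost in the
#'   alternate space, in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `peptides` (data.frame usable by
#'   [missense_peptide_impact()]) and `truth` (`affected` logical vector).
#' @export
generate_peptide_scenarios <- function(n_proteins, n_peptides,
                                       affected_fraction, seed = 1L) {
  stopifnot(affected_fraction >= 0, affected_fraction <= 1,
            n_peptides >= 0, n_proteins >= 1)
  with_seed_if(seed, {
    affected <- runif(n_peptides) < affected_fraction
    start <- sample.int(500, n_peptides, replace = TRUE)
    peptides <- data.frame(
      peptide_id = sprintf("pep%05d", seq_len(n_peptides)),
      protein_id = sprintf("PG%05d",
                           sample.int(n_proteins, n_peptides, replace = TRUE)),
      start = start, end = start + sample.int(25, n_peptides, replace = TRUE),
      overlaps_missense = TRUE,
      trinity = TRUE,
      silkbase = !affected,
      stringsAsFactors = FALSE
    )
    list(peptides = peptides, truth = list(affected = affected))
  })
}
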