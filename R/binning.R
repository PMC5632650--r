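# Contig-origin deconvolution for mixed host-endosymbiont assemblies.
#
# Four lines of evidence per contig, formalized as votes:
#   (1) homology-coverage ratio vs symbiont-side / host-side reference sets,
#   (2) GC content,
#   (3) read depth relative to host-candidate depth,
#   (4) absence from an aposymbiotic (symbiont-cured) host assembly.

#' Binning configuration
#'
#' Thresholds for the four-evidence contig classifier. Defaults reflect a
#' high-GC host (~65% GC, ~25x depth) mixed with a low-GC, high-copy-number
#' endosymbiont (43-49% GC, ~874x depth): the GC cutoff sits midway between
#' the symbiont upper bound and the host value, and depth evidence is relative
#' (fold over the median depth of host candidates) so it transfers across
#' datasets.
#'
#' @param gc_symbiont_max GC fraction at or below which the GC vote is "for"
#'   symbiont (default 0.56).
#' @param depth_fold_min symbiont depth vote requires
#'   `mean_depth >= depth_fold_min * median(host-candidate depth)` (default 5).
#' @param apo_cov_max a contig counts as absent from the aposymbiotic assembly
#'   when its best-match query coverage is below this (default 0.5).
#' @param min_votes minimum number of "for" votes for a symbiont call
#'   (default 2).
#' @param ratio_required if `TRUE` (default) the homology-ratio vote must be
#'   "for" (not merely unavailable) to call symbiont.
#' @param dup_window multiplicative window around 2x the median symbiont depth
#'   flagging putative duplicated fragments (default `c(1.6, 2.4)`).
#' @return a list of class `binning_config`.
#' @export
binning_config <- function(gc_symbiont_max = 0.56, depth_fold_min = 5,
                           apo_cov_max = 0.5, min_votes = 2L,
                           ratio_required = TRUE, dup_window = c(1.6, 2.4)) {
  stopifnot(gc_symbiont_max > 0, gc_symbiont_max < 1,
            depth_fold_min > 0, apo_cov_max >= 0, apo_cov_max <= 1,
            min_votes >= 1, length(dup_window) == 2, dup_window[1] < dup_window[2])
  structure(list(gc_symbiont_max = gc_symbiont_max,
                 depth_fold_min = depth_fold_min,
                 apo_cov_max = apo_cov_max,
                 min_votes = as.integer(min_votes),
                 ratio_required = ratio_required,
                 dup_window = dup_window),
            class = "binning_config")
}

#' GC fraction of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator and
#' denominator. Vectorized over sequences.
#'
#' @param sequence character vector of nucleotide sequences.
#' @return numeric vector in [0, 1]; errors if a sequence contains no
#'   unambiguous base.
#' @examples
#' gc_fraction(c("GCGC", "ATAT", "ATGCN"))
#' @export
gc_fraction <- function(sequence) {
  stopifnot(is.character(sequence), all(nchar(sequence) > 0))
  set <- Biostrings::DNAStringSet(toupper(sequence))
  freq <- Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  if (any(denom == 0)) abort("GC fraction undefined: sequence contains no A/C/G/T")
  unname((freq[, "G"] + freq[, "C"]) / denom)
}

#' Fraction of a contig covered by homology hits
#'
#' Computes the length of the union of query-side hit intervals divided by
#' the contig length; overlapping hits are counted once.
#'
#' @param hits hit tibble ([read_tabular_hits()] layout) whose rows all have
#'   the contig as query.
#' @param contig_length contig length in bp.
#' @return fraction in [0, 1].
#' @examples
#' hits <- tibble::tibble(query_id = "c", subject_id = "s",
#'                        qstart = c(1L, 51L), qend = c(100L, 150L),
#'                        evalue = 0)
#' query_coverage(hits, 200)  # 0.75
#' @export
query_coverage <- function(hits, contig_length) {
  stopifnot(contig_length > 0)
  if (nrow(hits) == 0L) return(0)
  assert_cols(hits, c("qstart", "qend"), "hit tibble")
  if (length(unique(hits$query_id)) > 1L) {
    abort("query_coverage expects hits of a single contig")
  }
  iv <- hit_query_intervals(hits)
  if (any(iv$end > contig_length) || any(iv$start < 0)) {
    abort("hit extends beyond contig length")
  }
  union_width(iv$start, iv$end) / contig_length
}

#' Homology-coverage ratio
#'
#' Ratio of symbiont-side to host-side query coverage. Values above 1 are
#' evidence of symbiont origin. By convention `cov_host == 0` with positive
#' symbiont coverage gives `Inf` (counts as > 1), and both coverages zero
#' gives `NA` (evidence unavailable).
#'
#' @param cov_symbiont,cov_host coverages in [0, 1]. Vectorized.
#' @return numeric vector (possibly `Inf` or `NA`).
#' @export
homology_ratio <- function(cov_symbiont, cov_host) {
  stopifnot(all(cov_symbiont >= 0 & cov_symbiont <= 1, na.rm = TRUE),
            all(cov_host >= 0 & cov_host <= 1, na.rm = TRUE))
  out <- cov_symbiont / cov_host           # x/0 -> Inf, 0/0 -> NaN
  out[is.nan(out)] <- NA_real_
  out
}

#' Assemble the per-contig evidence table
#'
#' Computes every evidence feature the classifier consumes: length, GC,
#' mean depth, query coverage against the symbiont-side and host-side
#' reference sets, the homology ratio, and (when an aposymbiotic hit table is
#' given) whether the contig is effectively absent from the aposymbiotic
#' assembly.
#'
#' @param contigs tibble from [read_fasta()] (columns `id`, `sequence`).
#' @param hits_symbiont,hits_host hit tibbles with assembly contigs as
#'   queries against the symbiont-side and host-side reference sets.
#' @param depth tibble `(contig_id, mean_depth)`, or per-base
#'   `(contig_id, pos, depth)` which is averaged per contig.
#' @param hits_apo optional hit tibble against the aposymbiotic assembly;
#'   `NULL` leaves the absence evidence unavailable.
#' @param config a [binning_config()].
#' @return tibble with one row per contig: `contig_id`, `length`,
#'   `gc_fraction`, `mean_depth`, `cov_symbiont`, `cov_host`,
#'   `homology_ratio`, `apo_absent`.
#' @export
contig_features <- function(contigs, hits_symbiont, hits_host, depth,
                            hits_apo = NULL, config = binning_config()) {
  assert_cols(contigs, c("id", "sequence"), "contig tibble")
  lens <- nchar(contigs$sequence)
  cov_for <- function(hits) {
    vapply(seq_along(contigs$id), function(i) {
      h <- hits[hits$query_id == contigs$id[i], , drop = FALSE]
      query_coverage(h, lens[i])
    }, numeric(1))
  }
  cov_sym <- cov_for(hits_symbiont)
  cov_host <- cov_for(hits_host)
  if (!is.null(depth)) {
    assert_cols(depth, "contig_id", "depth tibble")
    if ("mean_depth" %in% names(depth)) {
      d <- depth
    } else {
      assert_cols(depth, c("pos", "depth"), "per-base depth tibble")
      d <- depth |>
        group_by(.data$contig_id) |>
        summarise(mean_depth = mean(.data$depth), .groups = "drop")
    }
    md <- d$mean_depth[match(contigs$id, d$contig_id)]
  } else {
    md <- rep(NA_real_, nrow(contigs))
  }
  apo_absent <- rep(NA, nrow(contigs))
  if (!is.null(hits_apo)) {
    apo_cov <- vapply(seq_along(contigs$id), function(i) {
      h <- hits_apo[hits_apo$query_id == contigs$id[i], , drop = FALSE]
      if (nrow(h) == 0L) return(0)
      max((h$qend - h$qstart + 1) / lens[i])
    }, numeric(1))
    apo_absent <- apo_cov < config$apo_cov_max
  }
  tibble(
    contig_id = contigs$id,
    length = lens,
    gc_fraction = gc_fraction(contigs$sequence),
    mean_depth = md,
    cov_symbiont = cov_sym,
    cov_host = cov_host,
    homology_ratio = homology_ratio(cov_sym, cov_host),
    apo_absent = apo_absent
  )
}

vote_levels <- c("for", "against", "unavailable")

vote3 <- function(condition) {
  out <- ifelse(is.na(condition), "unavailable", ifelse(condition, "for", "against"))
  factor(out, levels = vote_levels)
}

#' Classify contigs as symbiont, host, or ambiguous
#'
#' Each contig receives four votes: homology ratio > 1; GC at or below
#' `gc_symbiont_max`; mean depth at least `depth_fold_min` times the median
#' depth of the host candidates (contigs whose ratio vote is "against"); and
#' absence from the aposymbiotic assembly. A contig is labelled `symbiont`
#' when the ratio vote is "for" (or unavailable, if `ratio_required = FALSE`)
#' and at least `min_votes` votes are "for"; `host` when the ratio vote is
#' "against" and the "for" count falls short; `ambiguous` otherwise.
#' Unavailable evidence never counts for either side.
#'
#' @param features tibble from [contig_features()] (columns `contig_id`,
#'   `gc_fraction`, `mean_depth`, `homology_ratio`, `apo_absent`; `NA` marks
#'   unavailable evidence).
#' @param config a [binning_config()].
#' @return `features` with added columns `vote_ratio`, `vote_gc`,
#'   `vote_depth`, `vote_apo` (factors for/against/unavailable), `n_for`,
#'   and `label`; class `endosieve_bins`.
#' @export
classify_contigs <- function(features, config = binning_config()) {
  assert_cols(features, c("contig_id", "gc_fraction", "mean_depth",
                          "homology_ratio", "apo_absent"), "feature tibble")
  stopifnot(inherits(config, "binning_config"))

  vote_ratio <- vote3(features$homology_ratio > 1)
  vote_gc <- vote3(features$gc_fraction <= config$gc_symbiont_max)

  host_candidate_depths <- features$mean_depth[vote_ratio == "against"]
  host_candidate_depths <- host_candidate_depths[!is.na(host_candidate_depths)]
  if (length(host_candidate_depths) > 0L) {
    host_median <- median(host_candidate_depths)
    vote_depth <- vote3(features$mean_depth >= config$depth_fold_min * host_median)
  } else {
    vote_depth <- vote3(rep(NA, nrow(features)))
  }
  vote_apo <- vote3(features$apo_absent)

  votes <- cbind(as.character(vote_ratio), as.character(vote_gc),
                 as.character(vote_depth), as.character(vote_apo))
  if (any(rowSums(votes == "unavailable") == 4L)) {
    abort(sprintf("all four evidences unavailable for contig(s): %s",
                  paste(features$contig_id[rowSums(votes == "unavailable") == 4L],
                        collapse = ", ")))
  }
  n_for <- rowSums(votes == "for")
  ratio_ok <- vote_ratio == "for" |
    (vote_ratio == "unavailable" & !config$ratio_required)
  label <- dplyr::case_when(
    ratio_ok & n_for >= config$min_votes ~ "symbiont",
    vote_ratio == "against" & n_for < config$min_votes ~ "host",
    .default = "ambiguous"
  )
  out <- features |>
    mutate(vote_ratio = vote_ratio, vote_gc = vote_gc,
           vote_depth = vote_depth, vote_apo = vote_apo,
           n_for = as.integer(n_for),
           label = factor(label, levels = c("symbiont", "host", "ambiguous")))
  class(out) <- c("endosieve_bins", class(out))
  out
}

#' Flag putative duplicated symbiont fragments by doubled depth
#'
#' Among symbiont-labelled contigs, a contig is flagged when its mean depth
#' divided by the median symbiont depth falls inside `dup_window`
#' (default 1.6-2.4x, bracketing genuinely duplicated ~2x fragments). The
#' median is computed after excluding the duplicate candidates themselves
#' (depth above `dup_window[1]` times the plain median) whenever at least one
#' non-candidate remains.
#'
#' @param bins tibble from [classify_contigs()] (or any tibble with
#'   `contig_id`, `mean_depth`, `label`).
#' @param config a [binning_config()].
#' @return character vector of flagged contig ids (possibly empty).
#' @export
flag_duplicates <- function(bins, config = binning_config()) {
  assert_cols(bins, c("contig_id", "mean_depth", "label"), "bin tibble")
  sym <- bins[bins$label == "symbiont" & !is.na(bins$mean_depth), , drop = FALSE]
  if (nrow(sym) == 0L) return(character(0))
  med0 <- median(sym$mean_depth)
  keep <- sym$mean_depth <= config$dup_window[1] * med0
  med <- if (any(keep)) median(sym$mean_depth[keep]) else med0
  fold <- sym$mean_depth / med
  sym$contig_id[fold >= config$dup_window[1] & fold <= config$dup_window[2]]
}

#' One-call contig binning
#'
#' Convenience wrapper chaining [contig_features()], [classify_contigs()] and
#' [flag_duplicates()].
#'
#' @inheritParams contig_features
#' @return the [classify_contigs()] tibble with an extra logical
#'   `duplicate_flag` column.
#' @export
bin_contigs <- function(contigs, hits_symbiont, hits_host, depth,
                        hits_apo = NULL, config = binning_config()) {
  feats <- contig_features(contigs, hits_symbiont, hits_host, depth,
                           hits_apo = hits_apo, config = config)
  bins <- classify_contigs(feats, config)
  dup <- flag_duplicates(bins, config)
  bins$duplicate_flag <- bins$contig_id %in% dup
  bins
}
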