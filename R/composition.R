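# Genome-composition and codon-usage statistics: GC content (whole genome,
# genes, intergenic), nucleotide composition by codon position, amino-acid
# frequencies, relative synonymous codon usage (RSCU) and its standard
# deviation as a scalar codon-usage-bias measure, gene/intergenic length
# distributions, and one-way ANOVA + Tukey HSD group comparisons.

genetic_code_table <- function(code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  tibble(codon = names(gc), amino_acid = unname(gc))
}

coerce_cds <- function(cds) {
  if (is.character(cds)) cds <- tibble(id = sprintf("cds_%d", seq_along(cds)),
                                       sequence = toupper(cds))
  assert_cols(cds, "sequence", "coding-set tibble")
  if (is.null(cds[["id"]])) cds$id <- sprintf("cds_%d", seq_len(nrow(cds)))
  cds$sequence <- toupper(cds$sequence)
  bad <- nchar(cds$sequence) %% 3L != 0L
  if (any(bad)) {
    abort(sprintf("CDS length not divisible by 3: %s",
                  paste(cds$id[bad], collapse = ", ")))
  }
  with_n <- stringr::str_detect(cds$sequence, "[^ACGT]")
  if (any(with_n)) {
    warn(sprintf("%d CDS containing ambiguous bases excluded", sum(with_n)))
    cds <- cds[!with_n, , drop = FALSE]
  }
  cds
}

split_codons <- function(sequences) {
  unlist(lapply(sequences, function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return(character(0))
    substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  }), use.names = FALSE)
}

#' Codon counts over a set of coding sequences
#'
#' Counts codons over the concatenation of all in-frame CDS. When
#' `stop_included = TRUE`, a terminal stop codon on each CDS is tallied
#' separately (attribute `terminal_stops`) and excluded from the sense
#' counts; internal stop codons remain counted in the table (they are flagged
#' by `is_stop` and excluded from RSCU downstream) and their number is
#' reported in the `internal_stops` attribute.
#'
#' @param cds tibble with a `sequence` column (and optional `id`), or a
#'   character vector of in-frame CDS. Sequences containing ambiguous bases
#'   are excluded with a warning; lengths must be divisible by 3.
#' @param code NCBI genetic code id (default `"11"`, bacterial).
#' @param stop_included do the CDS carry their terminal stop codon?
#' @return tibble of all 64 codons: `codon`, `amino_acid`, `is_stop`,
#'   `count`.
#' @examples
#' codon_counts("ATGGCC")
#' @export
codon_counts <- function(cds, code = "11", stop_included = FALSE) {
  cds <- coerce_cds(cds)
  tab <- genetic_code_table(code)
  codons <- split_codons(cds$sequence)
  terminal <- character(0)
  if (stop_included && nrow(cds) > 0L) {
    last <- stringr::str_sub(cds$sequence, -3L)
    last <- last[nchar(cds$sequence) >= 3L]
    is_term_stop <- tab$amino_acid[match(last, tab$codon)] == "*"
    terminal <- last[is_term_stop]
    # remove one terminal stop occurrence per CDS that ends in a stop
    per_seq <- lapply(cds$sequence, function(s) {
      cs <- split_codons(s)
      if (length(cs) > 0L && tab$amino_acid[match(cs[length(cs)], tab$codon)] == "*") {
        cs <- cs[-length(cs)]
      }
      cs
    })
    codons <- unlist(per_seq, use.names = FALSE)
  }
  counts <- table(factor(codons, levels = tab$codon))
  out <- tab |>
    mutate(is_stop = .data$amino_acid == "*",
           count = as.integer(counts[.data$codon]))
  n_internal <- sum(out$count[out$is_stop])
  if (n_internal > 0L) {
    warn(sprintf("%d internal stop codon(s) found; excluded from RSCU", n_internal))
  }
  attr(out, "terminal_stops") <- length(terminal)
  attr(out, "internal_stops") <- n_internal
  out
}

#' Relative synonymous codon usage
#'
#' For each amino-acid family i of size n_i with family total T_i > 0,
#' `RSCU_c = n_i * x_c / T_i`: the observed count of codon c relative to the
#' count expected under uniform synonymous usage. Values sum to the family
#' size within each family; 1.0 means no bias. Stop codons are excluded;
#' families with zero total are marked `NA` (undefined).
#'
#' @param counts codon-count tibble from [codon_counts()].
#' @return tibble of class `rscu_table`: `codon`, `amino_acid`,
#'   `family_size`, `count`, `rscu`.
#' @examples
#' cc <- codon_counts(c("GAAGAAGAAGAG"))
#' dplyr::filter(rscu(cc), amino_acid == "E")
#' @export
rscu <- function(counts) {
  assert_cols(counts, c("codon", "amino_acid", "count"), "codon-count tibble")
  stopifnot(all(counts$count >= 0))
  out <- counts |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$amino_acid) |>
    mutate(family_size = n(),
           family_total = sum(.data$count),
           rscu = ifelse(.data$family_total > 0,
                         .data$family_size * .data$count / .data$family_total,
                         NA_real_)) |>
    ungroup() |>
    select("codon", "amino_acid", "family_size", "count", "rscu")
  class(out) <- c("rscu_table", class(out))
  out
}

#' Standard deviation of RSCU values: a scalar codon-usage-bias measure
#'
#' The sample standard deviation (divisor N - 1) over the RSCU values of all
#' sense codons, excluding stop codons, the amino acids encoded by a single
#' codon (methionine and tryptophan under the bacterial code), and families
#' with zero observed counts. Zero means perfectly uniform synonymous usage;
#' larger values mean stronger bias.
#'
#' @param table an `rscu_table` from [rscu()].
#' @param divisor `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return non-negative scalar.
#' @export
rscu_sd <- function(table, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  assert_cols(table, c("rscu", "family_size"), "RSCU table")
  vals <- table$rscu[table$family_size > 1L & !is.na(table$rscu)]
  if (length(vals) < 2L) abort("need at least 2 defined RSCU values")
  s <- sd(vals)
  if (divisor == "n") s <- s * sqrt((length(vals) - 1) / length(vals))
  s
}

#' GC fraction at each codon position
#'
#' @inheritParams codon_counts
#' @return named numeric vector `c(pos1, pos2, pos3)`: fraction of G or C at
#'   codon positions 1-3 over all codons of all CDS.
#' @examples
#' gc_by_codon_position("ATGGCC")
#' @export
gc_by_codon_position <- function(cds, code = "11") {
  cds <- coerce_cds(cds)
  codons <- split_codons(cds$sequence)
  if (length(codons) == 0L) abort("empty coding set")
  vapply(1:3, function(k) {
    base <- substr(codons, k, k)
    mean(base %in% c("G", "C"))
  }, numeric(1)) |> setNames(c("pos1", "pos2", "pos3"))
}

#' Amino-acid frequencies of a coding set
#'
#' Translates every codon under the genetic code and returns the frequency of
#' each of the 20 amino acids over all non-stop residues.
#'
#' @inheritParams codon_counts
#' @return tibble `amino_acid`, `count`, `frequency`; frequencies sum to 1.
#' @export
aa_frequencies <- function(cds, code = "11") {
  cds <- coerce_cds(cds)
  tab <- genetic_code_table(code)
  codons <- split_codons(cds$sequence)
  aa <- tab$amino_acid[match(codons, tab$codon)]
  aa <- aa[aa != "*"]
  if (length(aa) == 0L) abort("no amino-acid residues in coding set")
  lv <- sort(setdiff(unique(tab$amino_acid), "*"))
  counts <- table(factor(aa, levels = lv))
  tibble(amino_acid = lv,
         count = as.integer(counts),
         frequency = as.integer(counts) / length(aa))
}

#' Gene and intergenic length distributions from annotation coordinates
#'
#' Gene lengths are `end - start` per feature (pseudogene features excluded).
#' Intergenic lengths are the gaps between consecutive spans of the merged
#' gene-span union on each contig; contig-terminal flanks are excluded in
#' linear mode and joined across the origin in circular mode.
#'
#' @param annotations feature tibble ([read_gff3()] layout).
#' @param contig_lengths named integer vector of contig lengths (required for
#'   `circular = TRUE`).
#' @param circular treat each contig as circular?
#' @return tibble `contig_id`, `region` (`"gene"` or `"intergenic"`),
#'   `length`.
#' @export
gene_intergenic_lengths <- function(annotations, contig_lengths = NULL,
                                    circular = FALSE) {
  assert_cols(annotations, c("contig_id", "start", "end"), "annotation tibble")
  ann <- annotations
  if (!is.null(ann[["feature_type"]])) {
    ann <- filter(ann, .data$feature_type != "pseudogene")
  }
  genes <- tibble(contig_id = ann$contig_id, region = "gene",
                  length = as.integer(ann$end - ann$start))
  inter <- ann |>
    group_by(.data$contig_id) |>
    dplyr::reframe({
      m <- merge_intervals(.data$start, .data$end)
      gaps <- integer(0)
      if (nrow(m) > 1L) gaps <- m$start[-1] - m$end[-nrow(m)]
      if (circular) {
        if (is.null(contig_lengths)) abort("circular mode requires contig_lengths")
        clen <- contig_lengths[[.data$contig_id[1]]]
        wrap <- (clen - m$end[nrow(m)]) + m$start[1]
        if (wrap > 0L) gaps <- c(gaps, wrap)
      }
      tibble(region = rep("intergenic", length(gaps)),
             length = as.integer(gaps))
    })
  bind_rows(genes, inter[names(genes)])
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The standard group-comparison procedure for composition statistics across
#' genomes: one-way analysis of variance followed by Tukey's honest
#' significant difference test at level `alpha`. Degenerate inputs with zero
#' between-group variance return `F = 0`, `p = 1` and no significant pair.
#'
#' @param data data frame with the response and grouping columns.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @param alpha significance level (default 0.05).
#' @return object of class `group_comparison`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()].
#' @export
group_compare <- function(data, value, group, alpha = 0.05) {
  assert_cols(data, c(value, group), "comparison data")
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  if (nlevels(df$g) < 2L) abort("need at least 2 groups")
  if (any(table(df$g) < 2L)) abort("every group needs at least 2 values")
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  ssb <- an[["Sum Sq"]][1]
  if (!is.finite(f) || ssb < .Machine$double.eps^0.75) {
    f <- 0; p <- 1
  }
  tk <- TukeyHSD(fit)$g
  tukey <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = ifelse(is.finite(tk[, "p adj"]), tk[, "p adj"], 1)
  )
  tukey$significant <- tukey$p_adj < alpha
  structure(list(f_statistic = f, p_value = p,
                 df_between = an[["Df"]][1], df_within = an[["Df"]][2],
                 alpha = alpha, tukey = tukey),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat(sprintf("Tukey HSD at alpha = %g: %d of %d pairs significant\n",
              x$alpha, sum(x$tukey$significant), nrow(x$tukey)))
  invisible(x)
}

#' Extract CDS nucleotide sequences from a genome and its annotation
#'
#' Pulls the spans of the requested feature type and reverse-complements
#' minus-strand features, yielding in-frame coding sequences.
#'
#' @param genome tibble from [read_fasta()].
#' @param annotations feature tibble ([read_gff3()] layout).
#' @param feature_type which features to extract (default `"CDS"`).
#' @return tibble `id`, `sequence`.
#' @export
extract_cds <- function(genome, annotations, feature_type = "CDS") {
  assert_cols(genome, c("id", "sequence"), "genome tibble")
  feats <- filter(annotations, .data$feature_type == !!feature_type)
  seqs <- vapply(seq_len(nrow(feats)), function(i) {
    g <- genome$sequence[match(feats$contig_id[i], genome$id)]
    s <- substr(g, feats$start[i] + 1L, feats$end[i])
    if (identical(feats$strand[i], "-")) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  tibble(id = feats$id, sequence = seqs)
}

#' Genome composition summary
#'
#' One-stop computation of the composition statistics for a genome: total,
#' genic and intergenic GC; GC by codon position; amino-acid frequencies;
#' RSCU table and RSCU-SD; gene and intergenic length distributions.
#'
#' @param genome tibble from [read_fasta()].
#' @param annotations feature tibble ([read_gff3()] layout); CDS features
#'   provide the coding set.
#' @param code NCBI genetic code id (default `"11"`).
#' @param stop_included do annotated CDS include the terminal stop codon?
#' @param circular treat contigs as circular for intergenic gaps?
#' @return object of class `composition_summary` with elements `summary`
#'   (one-row tibble), `rscu`, `aa_frequencies`, `lengths`.
#' @export
composition_summary <- function(genome, annotations, code = "11",
                                stop_included = TRUE, circular = FALSE) {
  cds <- extract_cds(genome, annotations, "CDS")
  counts <- codon_counts(cds, code = code, stop_included = stop_included)
  rtab <- rscu(counts)
  clens <- setNames(nchar(genome$sequence), genome$id)
  lens <- gene_intergenic_lengths(annotations, clens, circular = circular)
  # gene spans masked to N leave intergenic DNA; N never enters GC denominators
  masked <- mask_genes(genome, annotations)
  inter_concat <- paste(
    stringr::str_remove_all(masked$sequences$sequence, "N"), collapse = "")
  gene_concat <- paste(cds$sequence, collapse = "")
  gpos <- gc_by_codon_position(cds, code = code)
  s <- tibble(
    gc_total = gc_fraction(paste(genome$sequence, collapse = "")),
    gc_genes = if (nchar(gene_concat) > 0) gc_fraction(gene_concat) else NA_real_,
    gc_intergenic = if (nchar(inter_concat) > 0) gc_fraction(inter_concat) else NA_real_,
    gc_pos1 = gpos[["pos1"]], gc_pos2 = gpos[["pos2"]], gc_pos3 = gpos[["pos3"]],
    rscu_sd = rscu_sd(rtab),
    n_genes = nrow(cds),
    median_gene_length = median(lens$length[lens$region == "gene"]),
    median_intergenic_length = median(lens$length[lens$region == "intergenic"])
  )
  structure(list(summary = s, rscu = rtab,
                 aa_frequencies = aa_frequencies(cds, code = code),
                 lengths = lens),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary>\n")
  print(x$summary)
  invisible(x)
}
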