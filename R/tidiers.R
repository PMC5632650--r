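# broom-style accessors for the package's fitted/derived objects.

#' Tidy a group comparison: the Tukey HSD pairwise table
#'
#' @param x a [group_compare()] result.
#' @param ... unused.
#' @return tibble `comparison`, `diff`, `conf_low`, `conf_high`, `p_adj`,
#'   `significant`.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$tukey
}

#' Glance at a group comparison: the ANOVA summary
#'
#' @param x a [group_compare()] result.
#' @param ... unused.
#' @return one-row tibble `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `alpha`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within, alpha = x$alpha)
}

#' Tidy a Dollo map: per-edge gain and loss totals
#'
#' @param x a [dollo_map()] result.
#' @param ... unused.
#' @return tibble `child`, `child_label`, `is_root_edge`, `gains`, `losses`.
#' @export
tidy.dollo_map <- function(x, ...) {
  x$edges
}

#' Glance at a Dollo map: total gains and losses
#'
#' @param x a [dollo_map()] result.
#' @param ... unused.
#' @return one-row tibble `n_ogs`, `n_skipped`, `total_gains`,
#'   `total_losses`, `gains_at_root`.
#' @export
glance.dollo_map <- function(x, ...) {
  tibble(n_ogs = nrow(x$events), n_skipped = length(x$skipped),
         total_gains = sum(x$edges$gains), total_losses = sum(x$edges$losses),
         gains_at_root = sum(x$events$gain_at_root))
}

#' Tidy a supermatrix: the partition table
#'
#' @param x a [concatenate_alignments()] result.
#' @param ... unused.
#' @return tibble `gene`, `start`, `end` (1-based inclusive columns).
#' @export
tidy.supermatrix <- function(x, ...) {
  x$partitions
}

#' Glance at a supermatrix
#'
#' @param x a [concatenate_alignments()] result.
#' @param ... unused.
#' @return one-row tibble `n_taxa`, `n_characters`, `n_genes`.
#' @export
glance.supermatrix <- function(x, ...) {
  tibble(n_taxa = nrow(x$alignment), n_characters = x$n_characters,
         n_genes = nrow(x$partitions))
}

#' Glance at a composition summary
#'
#' @param x a [composition_summary()] result.
#' @param ... unused.
#' @return the one-row summary tibble.
#' @export
glance.composition_summary <- function(x, ...) {
  x$summary
}

#' Tidy a composition summary: the RSCU table
#'
#' @param x a [composition_summary()] result.
#' @param ... unused.
#' @return the `rscu_table` tibble.
#' @export
tidy.composition_summary <- function(x, ...) {
  x$rscu
}
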