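#' Count DMRs by context and direction
#'
#' @param dmrs A DMR tibble from [call_dmrs()]/[find_dmrs()].
#' @return A tibble `context, direction, n` over the full CG/CHG/CHH x
#'   hyper/hypo grid (zero-filled), with `n` summing to `nrow(dmrs)`.
#' @export
summarize_dmrs <- function(dmrs) {
  grid <- tidyr::expand_grid(context = CONTEXTS,
                             direction = c("hyper", "hypo"))
  counts <- if (nrow(dmrs) == 0) {
    tibble(context = character(), direction = character(), n = integer())
  } else {
    dmrs %>% count(.data$context, .data$direction)
  }
  grid %>%
    left_join(counts, by = c("context", "direction")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Fraction of early DMRs also identified at a later timepoint
#'
#' An early DMR is shared when it overlaps a late DMR of the same sequence and
#' context by at least `overlap_rule` bp. The percentage is
#' `100 * shared / n_early`, reported to one decimal — the convention under
#' which 163 of 1010 shared regions reads 16.1% and 108 of 1002 reads 10.8%.
#'
#' @param dmrs_early,dmrs_late DMR tibbles from the same comparison label at
#'   two timepoints.
#' @param config An [integration_config()] (supplies `overlap_rule`).
#' @return A one-row tibble `shared, n_early, percentage`.
#' @export
overlap_fraction <- function(dmrs_early, dmrs_late, config = integration_config()) {
  if (nrow(dmrs_early) == 0) {
    abort("overlap percentage undefined for an empty early DMR set",
          class = "methdmr_validation_error")
  }
  min_bp <- config$overlap_rule
  shared <- 0L
  if (nrow(dmrs_late) > 0) {
    hits <- inner_join(
      dmrs_early %>% mutate(.id = row_number()) %>%
        select(".id", "seq_id", "context", "start", "end"),
      dmrs_late %>% select("seq_id", "context",
                           start_l = "start", end_l = "end"),
      by = c("seq_id", "context"),
      relationship = "many-to-many"
    ) %>%
      mutate(shared_bp = pmin(.data$end, .data$end_l) -
               pmax(.data$start, .data$start_l) + 1L) %>%
      filter(.data$shared_bp >= min_bp)
    shared <- dplyr::n_distinct(hits$.id)
  }
  tibble(
    shared = shared,
    n_early = nrow(dmrs_early),
    percentage = round(100 * shared / nrow(dmrs_early), 1)
  )
}

#' Join DMRs to gene-expression records
#'
#' Unigenes serve as both the methylation coordinate system and the gene
#' identifier, so a DMR maps to the gene whose sequence carries it. When
#' several DMRs map to one gene, the one with the largest absolute level
#' difference `|level_b - level_a|` represents the gene. Genes with a DMR but
#' no expression record are dropped and their number reported via a message
#' and the `n_unmatched` attribute.
#'
#' @param dmrs A DMR tibble.
#' @param expression An expression tibble from [read_expression_table()] /
#'   [expression_table()].
#' @param config An [integration_config()].
#' @return A tibble of gene-level pairs: `gene_id, meth_log2fc, expr_log2fc,
#'   direction, level_diff, is_deg`, one row per gene.
#' @export
associate_dmr_genes <- function(dmrs, expression, config = integration_config()) {
  per_gene <- dmrs %>%
    mutate(level_diff = .data$level_b - .data$level_a) %>%
    group_by(gene_id = .data$seq_id) %>%
    slice(which.max(abs(.data$level_diff))) %>%
    ungroup() %>%
    select("gene_id", "meth_log2fc", "direction", "level_diff")
  matched <- inner_join(per_gene, expression, by = "gene_id")
  n_unmatched <- nrow(per_gene) - nrow(matched)
  if (n_unmatched > 0) {
    inform(sprintf("%d DMR gene(s) absent from the expression table were dropped",
                   n_unmatched))
  }
  out <- matched %>%
    select("gene_id", "meth_log2fc", expr_log2fc = "log2fc",
           "direction", "level_diff", dplyr::any_of("is_deg"))
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Correlate methylation and expression changes in sign regimes
#'
#' Pairs are partitioned by the sign of `meth_log2fc * expr_log2fc` into a
#' positive and a negative regime (zero products are excluded and counted),
#' and Pearson's r with its t-transform p-value (n - 2 df) is computed per
#' regime. A regime with fewer than 3 pairs is reported as not computable.
#'
#' @param pairs Tibble with `meth_log2fc` and `expr_log2fc` columns (e.g. from
#'   [associate_dmr_genes()]).
#' @return An object of class `meth_expr_cor`; see [tidy.meth_expr_cor()].
#' @export
split_and_correlate <- function(pairs) {
  prod <- pairs$meth_log2fc * pairs$expr_log2fc
  one_set <- function(sub) {
    if (nrow(sub) < 3) {
      return(list(r = NA_real_, p = NA_real_, n = nrow(sub), computable = FALSE))
    }
    ct <- stats::cor.test(sub$meth_log2fc, sub$expr_log2fc, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(sub),
         computable = TRUE)
  }
  out <- list(
    positive = one_set(pairs[!is.na(prod) & prod > 0, , drop = FALSE]),
    negative = one_set(pairs[!is.na(prod) & prod < 0, , drop = FALSE]),
    n_excluded = sum(prod == 0, na.rm = TRUE)
  )
  class(out) <- "meth_expr_cor"
  out
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  cat("Methylation-expression correlation by sign regime\n")
  for (set in c("positive", "negative")) {
    s <- x[[set]]
    if (isTRUE(s$computable)) {
      cat(sprintf("  %s: r = %.3f, p = %.3g, n = %d\n", set, s$r, s$p, s$n))
    } else {
      cat(sprintf("  %s: not computable (n = %d < 3)\n", set, s$n))
    }
  }
  cat(sprintf("  excluded zero-product pairs: %d\n", x$n_excluded))
  invisible(x)
}

#' Tidy a methylation-expression correlation
#'
#' @param x A `meth_expr_cor` object.
#' @param ... Unused.
#' @return A tibble with one row per sign regime: `set, r, p, n, computable`.
#' @export
tidy.meth_expr_cor <- function(x, ...) {
  tibble(
    set = c("positive", "negative"),
    r = c(x$positive$r, x$negative$r),
    p = c(x$positive$p, x$negative$p),
    n = c(x$positive$n, x$negative$n),
    computable = c(x$positive$computable, x$negative$computable)
  )
}

#' Glance at a methylation-expression correlation
#'
#' @inheritParams tidy.meth_expr_cor
#' @return A one-row tibble with both regimes' r/p/n and the excluded-pair
#'   count.
#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble(
    r_positive = x$positive$r, p_positive = x$positive$p,
    n_positive = x$positive$n,
    r_negative = x$negative$r, p_negative = x$negative$p,
    n_negative = x$negative$n,
    n_excluded = x$n_excluded
  )
}

#' Compare expression shifts of DMR genes against all genes
#'
#' Two-sided Wilcoxon rank-sum test on the absolute expression log2 fold
#' changes of DMR-associated genes versus the full gene background (a
#' superset that includes the DMR genes). The exact distribution is
#' enumerated when both groups have at most 10 observations and no ties;
#' otherwise the tie-corrected normal approximation is used.
#'
#' @param dmr_genes,all_genes Numeric vectors of expression log2 fold changes,
#'   or tibbles carrying an `expr_log2fc` / `log2fc` column.
#' @return The two-sided p-value.
#' @export
compare_expression_shift <- function(dmr_genes, all_genes) {
  x <- abs(extract_log2fc(dmr_genes))
  y <- abs(extract_log2fc(all_genes))
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty", class = "methdmr_validation_error")
  }
  no_ties <- !anyDuplicated(c(x, y))
  exact <- length(x) <= 10 && length(y) <= 10 && no_ties
  if (!exact && stats::var(c(x, y)) == 0) {
    return(1)  # all values identical: no rank information, z = 0
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE)$p.value
  )
}

extract_log2fc <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x)) {
    for (col in c("expr_log2fc", "log2fc")) {
      if (col %in% names(x)) return(x[[col]])
    }
  }
  abort("expected a numeric vector or a table with an expr_log2fc/log2fc column",
        class = "methdmr_validation_error")
}
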