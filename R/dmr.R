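#' Call differentially methylated cytosines within candidate bins
#'
#' Every cytosine of the bins' context lying inside a retained bin and covered
#' by at least `min_cov` reads in both conditions is tested with a per-site
#' two-sided Fisher's exact test. A site is a DMC iff `p < dmc_p`, the level
#' fold change is `>= dmc_fc`, and the absolute level difference reaches the
#' context-specific threshold (`dmc_absdiff`: 0.4 CG, 0.2 CHG, 0.1 CHH by
#' default).
#'
#' @param bins Retained bins from [call_candidate_bins()].
#' @param pooled_a,pooled_b Pooled `methylome` tibbles (conditions A/B).
#' @param config A [dmr_config()].
#' @return A tibble of distinct DMC sites: `seq_id, pos, strand, context,
#'   n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b, level_a, level_b, diff,
#'   fold_change, p`.
#' @export
call_dmcs <- function(bins, pooled_a, pooled_b, config = dmr_config()) {
  if (nrow(bins) == 0) return(empty_dmc_table())
  ctx <- unique(bins$context)
  if (length(ctx) != 1) {
    abort("bins from different contexts mixed in one DMC call",
          class = "methdmr_validation_error")
  }
  spans <- bins %>%
    group_by(.data$seq_id) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  # candidate sites: union of bin spans is a superset of the bins; the precise
  # per-bin membership test happens in the join below
  a <- filter_by_coverage(pooled_a, config$min_cov) %>%
    filter(.data$context == !!ctx) %>% as_tibble()
  b <- filter_by_coverage(pooled_b, config$min_cov) %>%
    filter(.data$context == !!ctx) %>% as_tibble()
  sites <- inner_join(a, b, by = c("seq_id", "pos", "strand", "context"),
                      suffix = c("_a", "_b"))
  in_bin <- inner_join(
    sites,
    bins %>% select("seq_id", "start", "end"),
    by = join_by(seq_id, pos >= start, pos <= end)
  ) %>%
    distinct(.data$seq_id, .data$pos, .data$strand, .keep_all = TRUE) %>%
    select(-"start", -"end")
  if (nrow(in_bin) == 0) return(empty_dmc_table())
  out <- in_bin %>%
    mutate(
      level_a = methylation_level(.data$n_meth_a, .data$n_unmeth_a),
      level_b = methylation_level(.data$n_meth_b, .data$n_unmeth_b),
      diff = .data$level_b - .data$level_a,
      fold_change = level_fold_change(.data$level_a, .data$level_b, config$epsilon),
      p = fisher_p_vec(.data$n_meth_a, .data$n_unmeth_a,
                       .data$n_meth_b, .data$n_unmeth_b)
    ) %>%
    filter(
      .data$p < config$dmc_p,
      .data$fold_change >= config$dmc_fc,
      abs(.data$diff) >= config$dmc_absdiff[[ctx]]
    ) %>%
    select("seq_id", "pos", "strand", "context",
           "n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b",
           "level_a", "level_b", "diff", "fold_change", "p") %>%
    arrange(.data$seq_id, .data$pos, .data$strand)
  out
}

empty_dmc_table <- function() {
  tibble(
    seq_id = character(), pos = integer(), strand = character(),
    context = character(),
    n_meth_a = integer(), n_unmeth_a = integer(),
    n_meth_b = integer(), n_unmeth_b = integer(),
    level_a = numeric(), level_b = numeric(), diff = numeric(),
    fold_change = numeric(), p = numeric()
  )
}

#' Merge DMC-rich bins into differentially methylated regions
#'
#' Bins containing fewer than `min_dmcs` distinct DMCs are dropped. Surviving
#' bins on the same sequence and context are merged when they overlap or abut,
#' and neighbouring regions separated by no more than `merge_gap` bp
#' (`start2 - end1 - 1`) are joined into a larger DMR. Levels, the signed log2
#' methylation change, the direction (hyper = higher in condition B), and the
#' distinct-DMC count are recomputed from pooled counts over each final span.
#'
#' @param bins Retained bins from [call_candidate_bins()].
#' @param dmcs DMC table from [call_dmcs()].
#' @param pooled_a,pooled_b Pooled `methylome` tibbles (conditions A/B).
#' @param config A [dmr_config()].
#' @return A tibble of DMRs sorted by `(seq_id, start)`: `seq_id, start, end,
#'   context, dmc_count, n_bins, level_a, level_b, meth_log2fc, direction,
#'   min_q`.
#' @export
call_dmrs <- function(bins, dmcs, pooled_a, pooled_b, config = dmr_config()) {
  if (nrow(bins) == 0) return(empty_dmr_table())
  ctx <- unique(bins$context)
  if (length(ctx) != 1) {
    abort("bins from different comparisons/contexts mixed in one DMR call",
          class = "methdmr_validation_error")
  }
  # distinct DMCs per bin (a DMC shared by overlapping bins counts in each)
  bins <- bins %>% mutate(.bin_id = row_number())
  if (nrow(dmcs) > 0) {
    per_bin <- inner_join(
      bins %>% select(".bin_id", "seq_id", "start", "end"),
      dmcs %>% select("seq_id", "pos", "strand"),
      by = join_by(seq_id, start <= pos, end >= pos)
    ) %>%
      distinct(.data$.bin_id, .data$seq_id, .data$pos, .data$strand) %>%
      count(.data$.bin_id, name = "dmc_count")
  } else {
    per_bin <- tibble(.bin_id = integer(), dmc_count = integer())
  }
  bins <- bins %>%
    left_join(per_bin, by = ".bin_id") %>%
    mutate(dmc_count = dplyr::coalesce(.data$dmc_count, 0L)) %>%
    filter(.data$dmc_count >= config$min_dmcs)
  if (nrow(bins) == 0) return(empty_dmr_table())

  # single sorted pass: gap <= 0 merges overlapping/abutting bins, and since
  # merge_gap >= 0 the <= merge_gap join subsumes that intermediate step
  merged <- bins %>%
    arrange(.data$seq_id, .data$start, .data$end) %>%
    group_by(.data$seq_id) %>%
    mutate(
      prev_end = dplyr::lag(cummax(.data$end)),
      new_region = is.na(.data$prev_end) |
        (.data$start - .data$prev_end - 1L > config$merge_gap),
      region = cumsum(.data$new_region)
    ) %>%
    group_by(.data$seq_id, .data$region) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_bins = dplyr::n(), min_q = min(.data$q), .groups = "drop") %>%
    select(-"region")

  a <- filter_by_coverage(pooled_a, config$min_cov) %>%
    filter(.data$context == !!ctx) %>% as_tibble()
  b <- filter_by_coverage(pooled_b, config$min_cov) %>%
    filter(.data$context == !!ctx) %>% as_tibble()
  span_counts <- function(sample_ctx) {
    inner_join(merged %>% select("seq_id", "start", "end"), sample_ctx,
               by = join_by(seq_id, start <= pos, end >= pos)) %>%
      group_by(.data$seq_id, .data$start, .data$end) %>%
      summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
                .groups = "drop")
  }
  counts <- inner_join(span_counts(a), span_counts(b),
                       by = c("seq_id", "start", "end"), suffix = c("_a", "_b"))
  if (nrow(dmcs) > 0) {
    span_dmcs <- inner_join(
      merged %>% select("seq_id", "start", "end"),
      dmcs %>% select("seq_id", "pos", "strand"),
      by = join_by(seq_id, start <= pos, end >= pos)
    ) %>%
      count(.data$seq_id, .data$start, .data$end, name = "dmc_count")
  } else {
    span_dmcs <- tibble(seq_id = character(), start = integer(),
                        end = integer(), dmc_count = integer())
  }
  merged %>%
    inner_join(counts, by = c("seq_id", "start", "end")) %>%
    left_join(span_dmcs, by = c("seq_id", "start", "end")) %>%
    mutate(
      context = !!ctx,
      dmc_count = dplyr::coalesce(.data$dmc_count, 0L),
      level_a = methylation_level(.data$n_meth_a, .data$n_unmeth_a),
      level_b = methylation_level(.data$n_meth_b, .data$n_unmeth_b),
      meth_log2fc = methylation_log2fc(.data$level_a, .data$level_b, config$epsilon),
      direction = if_else(.data$level_b > .data$level_a, "hyper", "hypo")
    ) %>%
    select("seq_id", "start", "end", "context", "dmc_count", "n_bins",
           "level_a", "level_b", "meth_log2fc", "direction", "min_q") %>%
    arrange(.data$seq_id, .data$start)
}

empty_dmr_table <- function() {
  tibble(
    seq_id = character(), start = integer(), end = integer(),
    context = character(), dmc_count = integer(), n_bins = integer(),
    level_a = numeric(), level_b = numeric(), meth_log2fc = numeric(),
    direction = character(), min_q = numeric()
  )
}

#' Run the full hierarchical DMR caller on one comparison
#'
#' Convenience wrapper chaining [call_candidate_bins()], [call_dmcs()] and
#' [call_dmrs()] for every context in `config$contexts_analyzed`.
#'
#' @param pooled_a,pooled_b Pooled `methylome` tibbles (control / treatment).
#' @param catalog A [sequence_catalog()].
#' @param config A [dmr_config()].
#' @return A tibble of DMRs across the analysed contexts, with per-stage
#'   record counts in attribute `stage_counts` and the DMC table in attribute
#'   `dmcs`.
#' @export
find_dmrs <- function(pooled_a, pooled_b, catalog, config = dmr_config()) {
  res <- purrr::map(config$contexts_analyzed, function(ctx) {
    bins <- call_candidate_bins(pooled_a, pooled_b, catalog, ctx, config)
    dmcs <- call_dmcs(bins, pooled_a, pooled_b, config)
    dmrs <- call_dmrs(bins, dmcs, pooled_a, pooled_b, config)
    list(n_tested = attr(bins, "n_tested"), n_retained = nrow(bins),
         dmcs = dmcs, dmrs = dmrs)
  })
  dmrs <- bind_rows(purrr::map(res, "dmrs")) %>%
    arrange(.data$seq_id, .data$start)
  attr(dmrs, "dmcs") <- bind_rows(purrr::map(res, "dmcs"))
  attr(dmrs, "stage_counts") <- tibble(
    context = config$contexts_analyzed,
    bins_tested = purrr::map_int(res, ~ as.integer(.x$n_tested)),
    bins_retained = purrr::map_int(res, ~ as.integer(.x$n_retained)),
    dmcs = purrr::map_int(res, ~ nrow(.x$dmcs)),
    dmrs = purrr::map_int(res, ~ nrow(.x$dmrs))
  )
  dmrs
}
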