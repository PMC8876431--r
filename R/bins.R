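#' Enumerate sliding bins over a sequence
#'
#' Bins of `bin_size` bp advance by `step` bp: starts 1, 1 + step, 1 + 2*step,
#' ... for every full window. A sequence shorter than one bin yields the single
#' window `[1, seq_len]`; when the last full window ends before the sequence
#' end, one trailing window anchored at `[seq_len - bin_size + 1, seq_len]` is
#' appended so every cytosine is covered by at least one bin.
#'
#' @param seq_len Sequence length in bp, >= 1.
#' @param config A [dmr_config()].
#' @return A tibble `start, end` (1-based inclusive), in scan order.
#' @export
enumerate_bins <- function(seq_len, config = dmr_config()) {
  seq_len <- as.integer(seq_len)
  stopifnot(seq_len >= 1L)
  bin <- config$bin_size
  step <- config$step
  if (seq_len < bin) {
    return(tibble(start = 1L, end = seq_len))
  }
  starts <- seq.int(1L, seq_len - bin + 1L, by = step)
  ends <- starts + bin - 1L
  if (ends[length(ends)] < seq_len) {
    starts <- c(starts, seq_len - bin + 1L)
    ends <- c(ends, seq_len)
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

# Pooled per-bin counts for one coverage-filtered sample restricted to one
# context: inner non-equi join of sites into bins.
bin_counts_one <- function(bins, sample_ctx) {
  joined <- inner_join(
    bins, sample_ctx,
    by = join_by(seq_id, start <= pos, end >= pos)
  )
  joined %>%
    group_by(.data$seq_id, .data$start, .data$end) %>%
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              n_sites = dplyr::n(), .groups = "drop")
}

#' Scan bins and retain significant candidate windows
#'
#' For each enumerated bin, read counts of the analysed context are pooled
#' across the cytosines covered in each condition and compared by a two-sided
#' Fisher's exact test on the 2x2 table (methylated/unmethylated by
#' condition). Bins with no covered cytosine in either condition are untested
#' and excluded from the multiple-testing family. P-values are
#' Benjamini-Hochberg adjusted across all tested bins of this context and
#' comparison; a bin is retained when `q < bin_fdr` and the methylation-level
#' fold change exceeds `bin_fc`.
#'
#' @param pooled_a,pooled_b Pooled `methylome` tibbles for conditions A
#'   (control) and B (treatment); coverage filtering at `config$min_cov` is
#'   (re)applied internally.
#' @param catalog A [sequence_catalog()].
#' @param context One methylation context, e.g. `"CHH"`.
#' @param config A [dmr_config()].
#' @return A tibble of retained bins with columns `seq_id, start, end, context,
#'   n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b, level_a, level_b, fold_change,
#'   p, q`. The number of tested bins is stored in attribute `n_tested`, the
#'   full tested table in attribute `tested_bins`.
#' @export
call_candidate_bins <- function(pooled_a, pooled_b, catalog, context, config = dmr_config()) {
  if (!context %in% config$contexts_analyzed) {
    abort(sprintf("context %s is not in config$contexts_analyzed", context),
          class = "methdmr_config_error")
  }
  for (s in list(pooled_a, pooled_b)) {
    unknown <- setdiff(unique(s$seq_id), catalog$seq_id)
    if (length(unknown) > 0) {
      abort(paste0("sample contains seq_ids absent from the catalog: ",
                   paste(head(unknown, 3), collapse = ", ")),
            class = "methdmr_validation_error")
    }
  }
  a <- filter_by_coverage(pooled_a, config$min_cov) %>%
    filter(.data$context == !!context)
  b <- filter_by_coverage(pooled_b, config$min_cov) %>%
    filter(.data$context == !!context)

  bins <- catalog %>%
    group_by(.data$seq_id) %>%
    dplyr::reframe(enumerate_bins(.data$length[1], config))

  ca <- bin_counts_one(bins, as_tibble(a))
  cb <- bin_counts_one(bins, as_tibble(b))
  tested <- inner_join(ca, cb, by = c("seq_id", "start", "end"),
                       suffix = c("_a", "_b"))
  if (nrow(tested) == 0) {
    out <- empty_bin_table(context)
    attr(out, "n_tested") <- 0L
    attr(out, "tested_bins") <- out
    return(out)
  }
  tested <- tested %>%
    mutate(
      context = !!context,
      level_a = methylation_level(.data$n_meth_a, .data$n_unmeth_a),
      level_b = methylation_level(.data$n_meth_b, .data$n_unmeth_b),
      fold_change = level_fold_change(.data$level_a, .data$level_b, config$epsilon),
      p = fisher_p_vec(.data$n_meth_a, .data$n_unmeth_a,
                       .data$n_meth_b, .data$n_unmeth_b),
      q = bh_adjust(.data$p)
    ) %>%
    select("seq_id", "start", "end", "context",
           "n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b",
           "level_a", "level_b", "fold_change", "p", "q") %>%
    arrange(.data$seq_id, .data$start)

  retained <- tested %>%
    filter(.data$q < config$bin_fdr, .data$fold_change > config$bin_fc)
  attr(retained, "n_tested") <- nrow(tested)
  attr(retained, "tested_bins") <- tested
  retained
}

empty_bin_table <- function(context = character(0)) {
  tibble(
    seq_id = character(), start = integer(), end = integer(),
    context = character(),
    n_meth_a = integer(), n_unmeth_a = integer(),
    n_meth_b = integer(), n_unmeth_b = integer(),
    level_a = numeric(), level_b = numeric(),
    fold_change = numeric(), p = numeric(), q = numeric()
  )
}
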