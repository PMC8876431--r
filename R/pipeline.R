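fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Write a DMR table as TSV
#'
#' Columns: `seq_id, start, end` (1-based inclusive), `context, dmc_count,
#' level_a, level_b, meth_log2fc, direction, min_q`. Output is byte-stable.
#'
#' @param dmrs A DMR tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  header <- paste("seq_id", "start", "end", "context", "dmc_count",
                  "level_a", "level_b", "meth_log2fc", "direction", "min_q",
                  sep = "\t")
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                   dmrs$seq_id, dmrs$start, dmrs$end, dmrs$context,
                   dmrs$dmc_count, fmt_num(dmrs$level_a), fmt_num(dmrs$level_b),
                   fmt_num(dmrs$meth_log2fc), dmrs$direction,
                   fmt_num(dmrs$min_q))
  writeLines(c("# coordinates: 1-based inclusive", header, lines), path)
  invisible(path)
}

#' Write DMRs as BED6
#'
#' BED coordinates are 0-based half-open; the name is `context:direction` and
#' the score is `min(1000, round(-10 * log10(q)))` from the region's smallest
#' bin q-value.
#'
#' @inheritParams write_dmr_table
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$min_q, 1e-300))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   dmrs$seq_id, dmrs$start - 1L, dmrs$end,
                   paste0(dmrs$context, ":", dmrs$direction), score)
  writeLines(c("# coordinates: 0-based half-open (BED)", lines), path)
  invisible(path)
}

#' Write gene-level methylation-expression pairs as TSV
#'
#' @param pairs Pairs tibble from [associate_dmr_genes()], annotated with the
#'   sign regime of each pair.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pairs_table <- function(pairs, path) {
  prod <- pairs$meth_log2fc * pairs$expr_log2fc
  set <- dplyr::case_when(prod > 0 ~ "positive",
                          prod < 0 ~ "negative",
                          TRUE ~ "excluded")
  header <- paste("gene_id", "meth_log2fc", "expr_log2fc", "direction", "set",
                  sep = "\t")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s",
                   pairs$gene_id, fmt_num(pairs$meth_log2fc),
                   fmt_num(pairs$expr_log2fc), pairs$direction, set)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run the full pipeline: simulate or load, filter, call, integrate, report
#'
#' Orchestrates the whole workflow. Inputs are either a [sim_config()] (the
#' experiment is simulated) or per-condition cytosine-report paths plus an
#' expression-table path. Writes `dmrs.tsv`, `dmrs.bed`, `pairs.tsv`,
#' `summary.json` and `manifest.json` into `out_dir`; outputs are identical
#' for identical configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()], or NULL when file inputs are given.
#' @param control_paths,treatment_paths Character vectors of cytosine-report
#'   paths (replicates are pooled by count summation).
#' @param expression_path Path to the expression TSV, or NULL.
#' @param catalog Optional [sequence_catalog()] for file inputs; when absent,
#'   each sequence's length is taken as its last covered position.
#' @param config A [dmr_config()].
#' @param integration A [integration_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `dmrs`, `pairs`, `summary`, `manifest` and
#'   the output paths.
#' @export
run_pipeline <- function(out_dir,
                         sim = NULL,
                         control_paths = NULL,
                         treatment_paths = NULL,
                         expression_path = NULL,
                         catalog = NULL,
                         config = dmr_config(),
                         integration = integration_config(),
                         quiet = FALSE) {
  validate_dmr_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))
  if (is.null(sim) && (is.null(control_paths) || is.null(treatment_paths))) {
    abort("provide either a sim_config or control/treatment report paths",
          class = "methdmr_usage_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(sim)) {
    validate_sim_config(sim)
    say("simulating experiment (seed %d, %d genes, %d planted regions)",
        sim$seed, sim$n_genes, sim$n_planted)
    exp_data <- simulate_experiment(sim)
    control <- exp_data$control
    treatment <- exp_data$treatment
    catalog <- exp_data$catalog_obj$catalog
    expression <- expression_table(exp_data$expression, integration)
    truth <- exp_data$truth
  } else {
    say("reading %d control and %d treatment report(s)",
        length(control_paths), length(treatment_paths))
    read_all <- function(paths, cond) {
      lapply(paths, read_cytosine_report, condition = cond)
    }
    control <- pool_replicates(read_all(control_paths, "control"))
    treatment <- pool_replicates(read_all(treatment_paths, "treatment"))
    if (is.null(catalog)) {
      all_sites <- bind_rows(as_tibble(control), as_tibble(treatment))
      catalog <- all_sites %>%
        group_by(.data$seq_id) %>%
        summarise(length = max(.data$pos), .groups = "drop")
    }
    expression <- if (!is.null(expression_path)) {
      read_expression_table(expression_path, integration)
    } else NULL
    truth <- NULL
  }

  sites_read <- c(control = nrow(control), treatment = nrow(treatment))
  control_f <- filter_by_coverage(control, config$min_cov)
  treatment_f <- filter_by_coverage(treatment, config$min_cov)
  say("coverage filter (>= %d reads): control %d -> %d, treatment %d -> %d sites",
      config$min_cov, nrow(control), nrow(control_f),
      nrow(treatment), nrow(treatment_f))

  dmrs <- find_dmrs(control_f, treatment_f, catalog, config)
  sc <- attr(dmrs, "stage_counts")
  say("bins tested %d, retained %d; DMCs %d; DMRs %d",
      sum(sc$bins_tested), sum(sc$bins_retained), sum(sc$dmcs), nrow(dmrs))

  pairs <- NULL
  correlations <- NULL
  wilcoxon <- NULL
  if (!is.null(expression) && nrow(dmrs) > 0) {
    pairs <- suppressMessages(associate_dmr_genes(dmrs, expression, integration))
    correlations <- split_and_correlate(pairs)
    wilcoxon <- compare_expression_shift(pairs$expr_log2fc, expression$log2fc)
    say("integration: %d gene pairs, Wilcoxon p = %.3g", nrow(pairs), wilcoxon)
  }

  summary <- list(
    dmr_counts = summarize_dmrs(dmrs),
    n_dmrs = nrow(dmrs),
    correlations = if (!is.null(correlations)) glance(correlations) else NULL,
    wilcoxon_p = wilcoxon
  )
  manifest <- list(
    tool = "methdmr",
    version = as.character(packageVersion("methdmr")),
    seed = if (!is.null(sim)) sim$seed else NULL,
    dmr_config = unclass(config),
    integration_config = unclass(integration),
    sim_config = if (!is.null(sim)) unclass(sim) else NULL,
    input_digests = if (is.null(sim)) {
      lapply(c(control_paths, treatment_paths, expression_path),
             function(p) unname(tools::md5sum(p)))
    } else NULL,
    counts = list(
      sites_read = as.list(sites_read),
      sites_after_filter = list(control = nrow(control_f),
                                treatment = nrow(treatment_f)),
      bins_tested = sum(sc$bins_tested),
      bins_retained = sum(sc$bins_retained),
      dmcs = sum(sc$dmcs),
      dmrs = nrow(dmrs),
      pairs = if (!is.null(pairs)) nrow(pairs) else 0L
    )
  )

  paths <- list(
    dmrs_tsv = file.path(out_dir, "dmrs.tsv"),
    dmrs_bed = file.path(out_dir, "dmrs.bed"),
    pairs_tsv = file.path(out_dir, "pairs.tsv"),
    summary_json = file.path(out_dir, "summary.json"),
    manifest_json = file.path(out_dir, "manifest.json")
  )
  write_dmr_table(dmrs, paths$dmrs_tsv)
  write_dmr_bed(dmrs, paths$dmrs_bed)
  if (!is.null(pairs)) write_pairs_table(pairs, paths$pairs_tsv)
  jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                       digits = 8, pretty = TRUE, dataframe = "columns",
                       null = "null")
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = 8, pretty = TRUE, null = "null")

  invisible(list(dmrs = dmrs, pairs = pairs, truth = truth, summary = summary,
                 manifest = manifest, paths = paths))
}

#' Human-readable summary of a pipeline run
#'
#' Renders the run's summary (context/direction table, correlation and
#' Wilcoxon results) as text; the numbers are exactly those of
#' `summary.json`.
#'
#' @param run Return value of [run_pipeline()].
#' @return A character vector of lines, invisibly; also printed.
#' @export
report_summary <- function(run) {
  s <- run$summary
  lines <- c("DMR calling summary", sprintf("  total DMRs: %d", s$n_dmrs))
  counts <- s$dmr_counts %>% filter(.data$n > 0)
  if (nrow(counts) > 0) {
    lines <- c(lines, sprintf("  %s %s: %d", counts$context,
                              counts$direction, counts$n))
  }
  if (!is.null(s$correlations)) {
    g <- s$correlations
    lines <- c(lines,
               "Methylation-expression correlation",
               sprintf("  positive regime: r = %s, p = %s, n = %d",
                       fmt_num(g$r_positive), fmt_num(g$p_positive), g$n_positive),
               sprintf("  negative regime: r = %s, p = %s, n = %d",
                       fmt_num(g$r_negative), fmt_num(g$p_negative), g$n_negative),
               sprintf("  Wilcoxon p (|expr log2FC|, DMR genes vs all): %s",
                       fmt_num(s$wilcoxon_p)))
  } else if (s$n_dmrs == 0) {
    lines <- c(lines, "  no DMRs: integration not performed")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
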