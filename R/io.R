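CONTEXTS <- c("CG", "CHG", "CHH")

site_key_cols <- c("seq_id", "pos", "strand")

#' Construct a methylome sample
#'
#' A methylome sample is a tibble with one row per cytosine and columns
#' `seq_id`, `pos` (1-based), `strand` (`+`/`-`), `context` (CG/CHG/CHH),
#' `n_meth`, `n_unmeth`. The `(seq_id, pos, strand)` key must be unique.
#'
#' @param sites Data frame of per-cytosine records.
#' @param sample_id,condition Optional labels stored as attributes.
#' @param catalog Optional sequence catalog (`tibble(seq_id, length)`); when
#'   supplied, every site position must fall within its sequence.
#' @return A validated tibble of class `methylome`.
#' @export
methylome <- function(sites, sample_id = NULL, condition = NULL, catalog = NULL) {
  required <- c(site_key_cols, "context", "n_meth", "n_unmeth")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("methylome sample is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "methdmr_validation_error")
  }
  out <- as_tibble(sites) %>%
    mutate(
      seq_id = as.character(.data$seq_id),
      pos = as.integer(.data$pos),
      strand = as.character(.data$strand),
      context = as.character(.data$context),
      n_meth = as.integer(.data$n_meth),
      n_unmeth = as.integer(.data$n_unmeth)
    ) %>%
    select(dplyr::all_of(required))

  if (any(out$pos < 1L)) {
    abort("site positions must be >= 1", class = "methdmr_validation_error")
  }
  if (any(out$n_meth < 0L) || any(out$n_unmeth < 0L)) {
    abort("read counts must be non-negative", class = "methdmr_validation_error")
  }
  bad_strand <- !out$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("invalid strand token(s): ",
                 paste(unique(out$strand[bad_strand]), collapse = ", ")),
          class = "methdmr_validation_error")
  }
  bad_ctx <- !out$context %in% CONTEXTS
  if (any(bad_ctx)) {
    abort(paste0("invalid context token(s): ",
                 paste(unique(out$context[bad_ctx]), collapse = ", ")),
          class = "methdmr_validation_error")
  }
  dup <- duplicated(out[site_key_cols])
  if (any(dup)) {
    ex <- out[dup, ][1, ]
    abort(sprintf("duplicate (seq_id, pos, strand) key: %s:%d:%s",
                  ex$seq_id, ex$pos, ex$strand),
          class = "methdmr_validation_error")
  }
  if (!is.null(catalog)) {
    joined <- left_join(out, catalog, by = "seq_id")
    if (any(is.na(joined$length))) {
      abort("sample contains seq_ids absent from the catalog",
            class = "methdmr_validation_error")
    }
    if (any(joined$pos > joined$length)) {
      abort("site position exceeds catalog sequence length",
            class = "methdmr_validation_error")
    }
  }
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  class(out) <- c("methylome", class(out))
  out
}

#' Read a per-cytosine methylation report
#'
#' Reads a headerless 6-column TSV in CX-report column order: `seq_id`, `pos`
#' (1-based), `strand`, `n_meth`, `n_unmeth`, `context`. An optional seventh
#' trinucleotide column is tolerated and ignored. Malformed context tokens and
#' negative counts raise parse errors naming the offending line; duplicate
#' `(seq_id, pos, strand)` keys raise a validation error.
#'
#' @param path File path.
#' @param sample_id,condition Optional labels attached to the sample.
#' @return A `methylome` tibble.
#' @export
read_cytosine_report <- function(path, sample_id = NULL, condition = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "methdmr_io_error")
  }
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(methylome(
      tibble(seq_id = character(), pos = integer(), strand = character(),
             context = character(), n_meth = integer(), n_unmeth = integer()),
      sample_id = sample_id, condition = condition
    ))
  }
  if (!ncol(raw) %in% c(6L, 7L)) {
    abort(sprintf("expected 6 (or 7) tab-separated columns, found %d", ncol(raw)),
          class = "methdmr_parse_error")
  }
  names(raw)[1:6] <- c("seq_id", "pos", "strand", "n_meth", "n_unmeth", "context")

  fail_line <- function(what, idx) {
    abort(sprintf("%s at line %d of %s", what, idx[1], path),
          class = "methdmr_parse_error")
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos)) fail_line("non-integer position", which(is.na(pos)))
  n_meth <- suppressWarnings(as.integer(raw$n_meth))
  if (anyNA(n_meth)) fail_line("non-integer methylated count", which(is.na(n_meth)))
  n_unmeth <- suppressWarnings(as.integer(raw$n_unmeth))
  if (anyNA(n_unmeth)) fail_line("non-integer unmethylated count", which(is.na(n_unmeth)))
  if (any(n_meth < 0L)) fail_line("negative methylated count", which(n_meth < 0L))
  if (any(n_unmeth < 0L)) fail_line("negative unmethylated count", which(n_unmeth < 0L))
  bad_ctx <- !raw$context %in% CONTEXTS
  if (any(bad_ctx)) {
    abort(sprintf("malformed context token '%s' at line %d of %s",
                  raw$context[which(bad_ctx)[1]], which(bad_ctx)[1], path),
          class = "methdmr_parse_error")
  }
  bad_strand <- !raw$strand %in% c("+", "-")
  if (any(bad_strand)) fail_line("malformed strand token", which(bad_strand))

  methylome(
    tibble(seq_id = raw$seq_id, pos = pos, strand = raw$strand,
           context = raw$context, n_meth = n_meth, n_unmeth = n_unmeth),
    sample_id = sample_id, condition = condition
  )
}

#' Write a per-cytosine methylation report
#'
#' Writes the 6-column headerless TSV dialect read by
#' [read_cytosine_report()], sorted by `(seq_id, pos, strand)`. Output is
#' byte-stable for a given sample.
#'
#' @param sample A `methylome` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cytosine_report <- function(sample, path) {
  sample <- methylome(sample,
                      sample_id = attr(sample, "sample_id"),
                      condition = attr(sample, "condition"))
  out <- sample %>%
    arrange(.data$seq_id, .data$pos, .data$strand) %>%
    select("seq_id", "pos", "strand", "n_meth", "n_unmeth", "context")
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s",
                   out$seq_id, out$pos, out$strand,
                   out$n_meth, out$n_unmeth, out$context)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Keep cytosines covered by at least `min_cov` reads
#'
#' Per the workflow's coverage rule, only cytosines covered by at least four
#' reads in a library enter the analysis (default `min_cov = 4`).
#'
#' @param sample A `methylome` tibble.
#' @param min_cov Minimum `n_meth + n_unmeth`; must be >= 1.
#' @return The filtered `methylome` tibble; the input is unmodified.
#' @export
filter_by_coverage <- function(sample, min_cov = 4L) {
  if (length(min_cov) != 1 || is.na(min_cov) || min_cov < 1) {
    abort("min_cov must be a single value >= 1", class = "methdmr_config_error")
  }
  out <- sample[sample$n_meth + sample$n_unmeth >= min_cov, , drop = FALSE]
  attr(out, "sample_id") <- attr(sample, "sample_id")
  attr(out, "condition") <- attr(sample, "condition")
  out
}

#' Pool replicate methylome samples by count summation
#'
#' Sums methylated and unmethylated counts element-wise across replicates of
#' one condition, so that Fisher's exact test downstream operates on a single
#' 2x2 table per unit. A site present in any replicate is present in the pool.
#'
#' @param samples A list of `methylome` tibbles sharing one condition label
#'   (when labels are attached).
#' @return A pooled `methylome` tibble.
#' @export
pool_replicates <- function(samples) {
  if (!is.list(samples) || length(samples) == 0 || is.data.frame(samples)) {
    abort("samples must be a non-empty list of methylome tibbles",
          class = "methdmr_validation_error")
  }
  conds <- unique(unlist(lapply(samples, function(s) attr(s, "condition"))))
  if (length(conds) > 1) {
    abort(paste0("cannot pool samples with mixed condition labels: ",
                 paste(conds, collapse = ", ")),
          class = "methdmr_validation_error")
  }
  pooled <- bind_rows(lapply(samples, as_tibble)) %>%
    group_by(.data$seq_id, .data$pos, .data$strand, .data$context) %>%
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              .groups = "drop")
  # a site must not change context across replicates
  dup <- duplicated(pooled[site_key_cols])
  if (any(dup)) {
    abort("replicates disagree on the context of a shared site",
          class = "methdmr_validation_error")
  }
  methylome(pooled, condition = if (length(conds) == 1) conds else NULL)
}

#' Read a gene-expression table
#'
#' Reads a headered TSV with columns `gene_id`, `log2fc`, `fdr` and flags
#' differentially expressed genes under the active [integration_config()]:
#' `is_deg` is true iff `fdr < deg_fdr` and `|log2fc| >= log2(deg_fc)`
#' (defaults FDR < 0.05 and fold change >= 2).
#'
#' @param path File path.
#' @param config An [integration_config()].
#' @return A tibble `gene_id, log2fc, fdr, is_deg`.
#' @export
read_expression_table <- function(path, config = integration_config()) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "methdmr_io_error")
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("gene_id", "log2fc", "fdr")
  if (!all(required %in% names(raw))) {
    abort(paste0("expression table must have columns: ",
                 paste(required, collapse = ", ")),
          class = "methdmr_parse_error")
  }
  log2fc <- suppressWarnings(as.numeric(raw$log2fc))
  fdr <- suppressWarnings(as.numeric(raw$fdr))
  if (anyNA(log2fc)) {
    abort(sprintf("non-numeric log2fc at data line %d of %s",
                  which(is.na(log2fc))[1], path),
          class = "methdmr_parse_error")
  }
  if (anyNA(fdr)) {
    abort(sprintf("non-numeric fdr at data line %d of %s",
                  which(is.na(fdr))[1], path),
          class = "methdmr_parse_error")
  }
  expression_table(tibble(gene_id = raw$gene_id, log2fc = log2fc, fdr = fdr),
                   config = config)
}

#' Flag DEGs in an in-memory expression table
#'
#' @param genes Tibble with `gene_id`, `log2fc`, `fdr`.
#' @param config An [integration_config()].
#' @return The tibble with an `is_deg` column added/recomputed.
#' @export
expression_table <- function(genes, config = integration_config()) {
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id in expression table: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]),
          class = "methdmr_validation_error")
  }
  genes %>%
    mutate(is_deg = .data$fdr < config$deg_fdr &
             abs(.data$log2fc) >= log2(config$deg_fc))
}

#' Build a sequence catalog
#'
#' @param seq_id Character vector of sequence (unigene) identifiers.
#' @param length Integer vector of sequence lengths in bp (all >= 1).
#' @return A tibble `seq_id, length`.
#' @export
sequence_catalog <- function(seq_id, length) {
  if (any(length < 1)) {
    abort("all catalog lengths must be >= 1", class = "methdmr_validation_error")
  }
  if (anyDuplicated(seq_id)) {
    abort("duplicate seq_id in catalog", class = "methdmr_validation_error")
  }
  tibble(seq_id = as.character(seq_id), length = as.integer(length))
}
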