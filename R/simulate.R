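clip_level <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Generate a unigene catalog with context-specific cytosine positions
#'
#' Gene lengths are drawn uniformly from `gene_length_range`; cytosine
#' positions are placed independently per context by per-bp Bernoulli draws at
#' the configured densities (defaults CG 0.04, CHG 0.03, CHH 0.10 sites/bp),
#' with a random strand per site. The output is fully determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `catalog` (a [sequence_catalog()]) and `sites`
#'   (tibble `seq_id, pos, strand, context`).
#' @export
generate_catalog <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    n <- config$n_genes
    lengths <- sample(seq.int(config$gene_length_range[1],
                              config$gene_length_range[2]),
                      n, replace = TRUE)
    seq_ids <- sprintf("gene%04d", seq_len(n))
    catalog <- sequence_catalog(seq_ids, lengths)
    sites <- purrr::map2(seq_ids, lengths, function(id, len) {
      per_ctx <- purrr::map(CONTEXTS, function(ctx) {
        dens <- config$cytosine_density[[ctx]]
        if (dens <= 0) return(NULL)
        pos <- which(runif(len) < dens)
        if (length(pos) == 0) return(NULL)
        tibble(seq_id = id, pos = as.integer(pos),
               strand = sample(c("+", "-"), length(pos), replace = TRUE),
               context = ctx)
      })
      bind_rows(per_ctx)
    }) %>%
      bind_rows() %>%
      # a cytosine has exactly one context; CG wins rare positional collisions
      mutate(.ctx_rank = match(.data$context, CONTEXTS)) %>%
      arrange(.data$seq_id, .data$pos, .data$strand, .data$.ctx_rank) %>%
      distinct(.data$seq_id, .data$pos, .data$strand, .keep_all = TRUE) %>%
      select(-".ctx_rank")
    list(catalog = catalog, sites = sites)
  })
}

#' Plant ground-truth differentially methylated regions
#'
#' Chooses `n_planted` non-overlapping windows of `planted_width` bp, one per
#' gene, uniformly over genes long enough to hold one. Directions are assigned
#' by `fraction_hyper`. A planted delta is the between-condition level
#' difference of the region: hyper regions raise the treatment to
#' `baseline + delta`; hypo regions anchor the control at `baseline + delta`
#' and leave the treatment at baseline, so the contrast magnitude is `delta`
#' in both regimes (target levels are clipped to `[0.01, 0.99]`).
#'
#' @param catalog_obj Output of [generate_catalog()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param grid_step Grid the region starts snap to when
#'   `config$align_to_grid` is TRUE.
#' @return Ground-truth tibble: `seq_id, start, end, context, delta,
#'   direction, level_a_target, level_b_target, expected_meth_log2fc`.
#' @export
plant_dmrs <- function(catalog_obj, config = sim_config(), seed = config$seed,
                       grid_step = 50L) {
  catalog <- catalog_obj$catalog
  if (config$n_planted == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  context = character(), delta = numeric(),
                  direction = character(), level_a_target = numeric(),
                  level_b_target = numeric(), expected_meth_log2fc = numeric()))
  }
  eligible <- catalog %>% filter(.data$length >= config$planted_width)
  if (nrow(eligible) < config$n_planted) {
    abort(sprintf("cannot place %d non-overlapping regions: only %d genes are >= %d bp",
                  config$n_planted, nrow(eligible), config$planted_width),
          class = "methdmr_validation_error")
  }
  withr::with_seed(seed, {
    chosen <- eligible %>% slice(sample(dplyr::n(), config$n_planted))
    start_max <- chosen$length - config$planted_width + 1L
    start <- as.integer(floor(runif(config$n_planted) * start_max)) + 1L
    if (config$align_to_grid) {
      start <- pmin(((start - 1L) %/% grid_step) * grid_step + 1L, start_max)
    }
    n_hyper <- round(config$fraction_hyper * config$n_planted)
    dirs <- sample(c(rep("hyper", n_hyper),
                     rep("hypo", config$n_planted - n_hyper)))
    base <- config$baseline_level[[config$planted_context]]
    delta <- if_else(dirs == "hyper", config$planted_delta, -config$planted_delta)
    la <- clip_level(base + pmax(0, -delta))
    lb <- clip_level(base + pmax(0, delta))
    tibble(
      seq_id = chosen$seq_id,
      start = start,
      end = start + config$planted_width - 1L,
      context = config$planted_context,
      delta = delta,
      direction = dirs,
      level_a_target = la,
      level_b_target = lb,
      expected_meth_log2fc = methylation_log2fc(la, lb)
    ) %>%
      arrange(.data$seq_id, .data$start)
  })
}

#' Simulate one condition's per-cytosine counts
#'
#' Each site's methylation level is drawn from a beta distribution centred on
#' the context baseline (shifted inside planted regions according to the
#' condition; see [plant_dmrs()]) with concentration `level_dispersion`;
#' coverage follows the configured Poisson or negative-binomial model; the
#' methylated count is binomial in coverage and level. Zero-coverage sites are
#' emitted with zero counts and fall to the downstream coverage filter.
#'
#' @param catalog_obj Output of [generate_catalog()].
#' @param config A [sim_config()].
#' @param truth Ground truth from [plant_dmrs()], or NULL for a null
#'   (no-effect) sample.
#' @param seed Integer seed.
#' @param condition `"control"` or `"treatment"`.
#' @return A `methylome` tibble.
#' @export
generate_condition <- function(catalog_obj, config = sim_config(), truth = NULL,
                               seed = config$seed,
                               condition = c("control", "treatment")) {
  condition <- match.arg(condition)
  sites <- catalog_obj$sites
  mean_level <- unname(config$baseline_level[sites$context])
  if (!is.null(truth) && nrow(truth) > 0) {
    hit <- inner_join(
      sites %>% mutate(.row = row_number()),
      truth %>% select("seq_id", "context", "start", "end", "delta"),
      by = join_by(seq_id, context, pos >= start, pos <= end)
    )
    if (nrow(hit) > 0) {
      shift <- if (condition == "control") pmax(0, -hit$delta) else pmax(0, hit$delta)
      mean_level[hit$.row] <- mean_level[hit$.row] + shift
    }
  }
  mean_level <- clip_level(mean_level)
  withr::with_seed(seed, {
    n <- nrow(sites)
    conc <- config$level_dispersion
    level <- rbeta(n, mean_level * conc, (1 - mean_level) * conc)
    coverage <- switch(config$coverage_model,
      poisson = rpois(n, config$coverage_mean),
      nbinom = rnbinom(n, size = config$coverage_size, mu = config$coverage_mean)
    )
    n_meth <- rbinom(n, coverage, level)
    methylome(
      sites %>% mutate(n_meth = n_meth, n_unmeth = coverage - n_meth),
      sample_id = paste0(condition, "_seed", seed),
      condition = condition
    )
  })
}

#' Simulate an expression table coupled to planted methylation changes
#'
#' Genes carrying a planted DMR are "coupled": their expression log2 fold
#' change is `sign * coupling * expected_meth_log2fc` plus Gaussian noise,
#' with the sign positive for a `coupling_sign_mix` fraction of coupled genes.
#' Uncoupled genes receive pure noise. FDR values are simulated so coupled
#' genes are predominantly DEGs.
#'
#' @param truth Ground truth from [plant_dmrs()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param gene_ids All gene identifiers to emit (defaults to the truth's
#'   genes only).
#' @return A tibble `gene_id, log2fc, fdr` with a `coupling` attribute
#'   (tibble `gene_id, sign, expected_expr_log2fc`).
#' @export
generate_expression <- function(truth, config = sim_config(), seed = config$seed,
                                gene_ids = unique(truth$seq_id)) {
  coupled <- truth %>%
    group_by(gene_id = .data$seq_id) %>%
    slice(which.max(abs(.data$expected_meth_log2fc))) %>%
    ungroup() %>%
    select("gene_id", meth = "expected_meth_log2fc")
  withr::with_seed(seed, {
    sgn <- if_else(runif(nrow(coupled)) < config$coupling_sign_mix, 1, -1)
    coupled <- coupled %>%
      mutate(sign = sgn,
             expected_expr_log2fc = .data$sign * config$coupling * .data$meth)
    tab <- tibble(gene_id = gene_ids) %>%
      left_join(coupled, by = "gene_id") %>%
      mutate(
        log2fc = if_else(
          is.na(.data$expected_expr_log2fc),
          rnorm(dplyr::n(), 0, config$expr_noise_sd),
          .data$expected_expr_log2fc + rnorm(dplyr::n(), 0, config$expr_noise_sd)
        ),
        fdr = if_else(is.na(.data$expected_expr_log2fc),
                      runif(dplyr::n(), 0, 1),
                      runif(dplyr::n(), 0, 0.04))
      )
    out <- tab %>% select("gene_id", "log2fc", "fdr")
    attr(out, "coupling") <- coupled %>%
      select("gene_id", "sign", "expected_expr_log2fc")
    out
  })
}

#' Score called DMRs against the planted ground truth
#'
#' A planted region is recovered when some called DMR of the same context and
#' direction overlaps it by at least `overlap_rule` bp. Sensitivity is the
#' recovered fraction of planted regions; precision the fraction of calls
#' overlapping any truth region of the same context; direction agreement the
#' fraction of context-overlapped truth regions whose best-overlapping call
#' has the planted direction. The boundary error of a recovered region is the
#' mean absolute start/end offset of its best-overlapping call.
#'
#' @param called DMR tibble from [call_dmrs()]/[find_dmrs()].
#' @param truth Ground truth from [plant_dmrs()].
#' @param overlap_rule Minimum shared bp.
#' @return A one-row tibble: `sensitivity, precision, direction_agreement,
#'   mean_boundary_error, n_planted, n_called, n_recovered`.
#' @export
evaluate_recovery <- function(called, truth, overlap_rule = 1L) {
  n_planted <- nrow(truth)
  n_called <- nrow(called)
  empty <- tibble(sensitivity = NA_real_, precision = NA_real_,
                  direction_agreement = NA_real_,
                  mean_boundary_error = NA_real_,
                  n_planted = n_planted, n_called = n_called,
                  n_recovered = 0L)
  if (n_planted == 0 || n_called == 0) {
    if (n_planted > 0) empty$sensitivity <- 0
    if (n_called > 0) empty$precision <- 0
    return(empty)
  }
  hits <- inner_join(
    truth %>% mutate(.truth_id = row_number()) %>%
      select(".truth_id", "seq_id", "context", "start", "end", "direction"),
    called %>% mutate(.call_id = row_number()) %>%
      select(".call_id", "seq_id", "context",
             start_c = "start", end_c = "end", dir_c = "direction"),
    by = c("seq_id", "context"),
    relationship = "many-to-many"
  ) %>%
    mutate(shared_bp = pmin(.data$end, .data$end_c) -
             pmax(.data$start, .data$start_c) + 1L) %>%
    filter(.data$shared_bp >= overlap_rule)

  recovered <- hits %>% filter(.data$direction == .data$dir_c)
  best <- recovered %>%
    group_by(.data$.truth_id) %>%
    slice(which.max(.data$shared_bp)) %>%
    ungroup() %>%
    mutate(boundary_error = (abs(.data$start_c - .data$start) +
                               abs(.data$end_c - .data$end)) / 2)
  overlapped <- hits %>%
    group_by(.data$.truth_id) %>%
    slice(which.max(.data$shared_bp)) %>%
    ungroup()
  tibble(
    sensitivity = dplyr::n_distinct(recovered$.truth_id) / n_planted,
    precision = dplyr::n_distinct(hits$.call_id) / n_called,
    direction_agreement = if (nrow(overlapped) > 0) {
      mean(overlapped$direction == overlapped$dir_c)
    } else NA_real_,
    mean_boundary_error = if (nrow(best) > 0) mean(best$boundary_error) else NA_real_,
    n_planted = n_planted,
    n_called = n_called,
    n_recovered = dplyr::n_distinct(recovered$.truth_id)
  )
}

#' Simulate a complete two-condition methylome experiment
#'
#' Chains [generate_catalog()], [plant_dmrs()], [generate_condition()] (control
#' and treatment) and [generate_expression()] with seeds derived from
#' `config$seed`, so the whole experiment is reproducible from one integer.
#'
#' @param config A [sim_config()].
#' @param null_experiment When TRUE, no regions are planted and both
#'   conditions are drawn from identical parameters (with different seeds).
#' @return A list: `catalog_obj`, `truth`, `control`, `treatment`,
#'   `expression`, `config`.
#' @export
simulate_experiment <- function(config = sim_config(), null_experiment = FALSE) {
  catalog_obj <- generate_catalog(config)
  truth <- if (null_experiment) NULL else plant_dmrs(catalog_obj, config,
                                                     seed = config$seed + 1L)
  control <- generate_condition(catalog_obj, config, truth,
                                seed = config$seed + 2L, condition = "control")
  treatment <- generate_condition(catalog_obj, config, truth,
                                  seed = config$seed + 3L, condition = "treatment")
  expr <- if (is.null(truth) || nrow(truth) == 0) {
    generate_expression(
      tibble(seq_id = character(), expected_meth_log2fc = numeric()),
      config, seed = config$seed + 4L, gene_ids = catalog_obj$catalog$seq_id
    )
  } else {
    generate_expression(truth, config, seed = config$seed + 4L,
                        gene_ids = catalog_obj$catalog$seq_id)
  }
  list(catalog_obj = catalog_obj, truth = truth, control = control,
       treatment = treatment, expression = expr, config = config)
}
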