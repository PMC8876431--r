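#' Configuration for the sliding-bin DMR caller
#'
#' Collects every tunable of the hierarchical DMR procedure. Defaults are the
#' thresholds of the published workflow: 200-bp bins advanced in 50-bp steps,
#' a minimum of 4 reads per cytosine per library, bin retention at
#' Benjamini-Hochberg FDR < 0.05 with a methylation-level fold change > 1.5,
#' DMC calling at per-site Fisher P < 0.01, fold change >= 2 and absolute
#' methylation differences of 0.4 / 0.2 / 0.1 for CG / CHG / CHH, retention of
#' bins holding at least 7 DMCs, and joining of neighbouring regions separated
#' by at most 100 bp. Analysis is restricted to the CHH context by default,
#' where plant DMRs are by far the most numerous.
#'
#' @param bin_size Bin width in bp.
#' @param step Step size in bp; must satisfy `1 <= step <= bin_size`.
#' @param min_cov Minimum read coverage per cytosine per condition.
#' @param bin_fdr BH-adjusted significance threshold for candidate bins.
#' @param bin_fc Minimum methylation-level fold change for candidate bins
#'   (strict inequality, `fold_change > bin_fc`).
#' @param dmc_p Per-cytosine Fisher P threshold (strict, `p < dmc_p`).
#' @param dmc_fc Per-cytosine level fold-change threshold (`fc >= dmc_fc`).
#' @param dmc_absdiff Named numeric vector of minimum absolute methylation
#'   differences per context, `c(CG = 0.4, CHG = 0.2, CHH = 0.1)`.
#' @param min_dmcs Minimum number of DMCs a bin must contain to be retained.
#' @param merge_gap Maximum gap in bp across which neighbouring regions are
#'   joined.
#' @param epsilon Pseudocount added to both levels in ratio computations, so
#'   fold changes stay finite when a level is 0.
#' @param contexts_analyzed Character subset of `c("CG", "CHG", "CHH")`.
#'
#' @return A list of class `dmr_config`.
#' @examples
#' cfg <- dmr_config()
#' cfg$bin_size
#' @export
dmr_config <- function(bin_size = 200L,
                       step = 50L,
                       min_cov = 4L,
                       bin_fdr = 0.05,
                       bin_fc = 1.5,
                       dmc_p = 0.01,
                       dmc_fc = 2.0,
                       dmc_absdiff = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                       min_dmcs = 7L,
                       merge_gap = 100L,
                       epsilon = 0.01,
                       contexts_analyzed = "CHH") {
  cfg <- list(
    bin_size = as.integer(bin_size), step = as.integer(step),
    min_cov = as.integer(min_cov), bin_fdr = bin_fdr, bin_fc = bin_fc,
    dmc_p = dmc_p, dmc_fc = dmc_fc, dmc_absdiff = dmc_absdiff,
    min_dmcs = as.integer(min_dmcs), merge_gap = as.integer(merge_gap),
    epsilon = epsilon, contexts_analyzed = contexts_analyzed
  )
  class(cfg) <- "dmr_config"
  validate_dmr_config(cfg)
  cfg
}

validate_dmr_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$bin_size >= 1L, "bin_size must be >= 1")
  chk(cfg$step >= 1L && cfg$step <= cfg$bin_size,
      "step must satisfy 1 <= step <= bin_size")
  chk(cfg$min_cov >= 1L, "min_cov must be >= 1")
  chk(cfg$bin_fdr > 0 && cfg$bin_fdr <= 1, "bin_fdr must be in (0, 1]")
  chk(cfg$bin_fc > 1, "bin_fc must be > 1")
  chk(cfg$dmc_p > 0 && cfg$dmc_p <= 1, "dmc_p must be in (0, 1]")
  chk(cfg$dmc_fc >= 1, "dmc_fc must be >= 1")
  chk(all(c("CG", "CHG", "CHH") %in% names(cfg$dmc_absdiff)),
      "dmc_absdiff must name all of CG, CHG, CHH")
  chk(all(cfg$dmc_absdiff > 0 & cfg$dmc_absdiff <= 1),
      "each dmc_absdiff must be in (0, 1]")
  chk(cfg$min_dmcs >= 1L, "min_dmcs must be >= 1")
  chk(cfg$merge_gap >= 0L, "merge_gap must be >= 0")
  chk(cfg$epsilon > 0, "epsilon must be > 0")
  chk(length(cfg$contexts_analyzed) >= 1 &&
        all(cfg$contexts_analyzed %in% c("CG", "CHG", "CHH")),
      "contexts_analyzed must be a non-empty subset of {CG, CHG, CHH}")
  if (length(problems) > 0) {
    abort(c("Invalid dmr_config:", setNames(problems, rep("x", length(problems)))),
          class = "methdmr_config_error")
  }
  invisible(cfg)
}

#' Configuration for methylome-transcriptome integration
#'
#' @param deg_fdr FDR threshold below which a gene counts as differentially
#'   expressed.
#' @param deg_fc Expression fold-change threshold; a DEG requires
#'   `|log2fc| >= log2(deg_fc)`.
#' @param overlap_rule Minimum shared bp for two regions to count as the same
#'   DMR across comparisons.
#' @param multi_dmr_rule How to pick one DMR when several map to a gene:
#'   `"largest_absdiff"` keeps the DMR with the largest `|level_b - level_a|`.
#'
#' @return A list of class `integration_config`.
#' @export
integration_config <- function(deg_fdr = 0.05,
                               deg_fc = 2,
                               overlap_rule = 1L,
                               multi_dmr_rule = c("largest_absdiff")) {
  multi_dmr_rule <- match.arg(multi_dmr_rule)
  if (!(deg_fdr > 0 && deg_fdr <= 1)) {
    abort("deg_fdr must be in (0, 1]", class = "methdmr_config_error")
  }
  if (deg_fc < 1) {
    abort("deg_fc must be >= 1", class = "methdmr_config_error")
  }
  if (overlap_rule < 1) {
    abort("overlap_rule must be >= 1 bp", class = "methdmr_config_error")
  }
  structure(
    list(deg_fdr = deg_fdr, deg_fc = deg_fc,
         overlap_rule = as.integer(overlap_rule),
         multi_dmr_rule = multi_dmr_rule),
    class = "integration_config"
  )
}

#' Configuration for the synthetic methylome generator
#'
#' Describes the simulated study: unigene-like reference sequences carrying
#' context-specific cytosines, beta-binomial methylation counts, planted
#' differentially methylated regions, and an expression table coupled to the
#' planted methylation changes in positive and negative regimes.
#'
#' Per-context cytosine densities and baseline levels follow typical plant
#' methylome ordering (CG high, CHG intermediate, CHH low and dense). A planted
#' delta is the between-condition level difference of the region: for hyper
#' regions the treatment rises above baseline; for hypo regions the control is
#' anchored at `baseline + |delta|` and the treatment sits at baseline, so the
#' planted contrast has magnitude `|delta|` in both regimes.
#'
#' @param n_genes Number of reference sequences (unigenes).
#' @param gene_length_range Two-element bp range for uniform gene lengths.
#' @param cytosine_density Named per-context site densities (sites/bp).
#' @param baseline_level Named per-context mean methylation levels.
#' @param level_dispersion Beta concentration; larger = less site-to-site
#'   biological variability.
#' @param coverage_mean Mean read depth per site.
#' @param coverage_model `"poisson"` or `"nbinom"`.
#' @param coverage_size Negative-binomial size when `coverage_model = "nbinom"`.
#' @param n_planted Number of planted DMRs.
#' @param planted_width Width of each planted region in bp.
#' @param planted_delta Magnitude of the planted level difference.
#' @param planted_context Context in which regions are planted.
#' @param fraction_hyper Fraction of planted regions that are hypermethylated
#'   in the treatment.
#' @param align_to_grid Align planted region starts to the 50-bp bin grid.
#' @param coupling Magnitude of the expression-methylation coupling.
#' @param coupling_sign_mix Fraction of coupled genes with a positive sign.
#' @param expr_noise_sd SD of the Gaussian noise on expression log2 fold
#'   changes.
#' @param seed Integer seed; fully determines the generator output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       gene_length_range = c(1500L, 2500L),
                       cytosine_density = c(CG = 0.04, CHG = 0.03, CHH = 0.10),
                       baseline_level = c(CG = 0.80, CHG = 0.50, CHH = 0.10),
                       level_dispersion = 20,
                       coverage_mean = 25,
                       coverage_model = c("poisson", "nbinom"),
                       coverage_size = 10,
                       n_planted = 20L,
                       planted_width = 200L,
                       planted_delta = 0.4,
                       planted_context = "CHH",
                       fraction_hyper = 0.5,
                       align_to_grid = TRUE,
                       coupling = 0.8,
                       coupling_sign_mix = 0.5,
                       expr_noise_sd = 0.5,
                       seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    cytosine_density = cytosine_density,
    baseline_level = baseline_level,
    level_dispersion = level_dispersion,
    coverage_mean = coverage_mean,
    coverage_model = coverage_model,
    coverage_size = coverage_size,
    n_planted = as.integer(n_planted),
    planted_width = as.integer(planted_width),
    planted_delta = planted_delta,
    planted_context = planted_context,
    fraction_hyper = fraction_hyper,
    align_to_grid = isTRUE(align_to_grid),
    coupling = coupling,
    coupling_sign_mix = coupling_sign_mix,
    expr_noise_sd = expr_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ctx <- c("CG", "CHG", "CHH")
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(length(cfg$gene_length_range) == 2 &&
        cfg$gene_length_range[1] >= 1 &&
        cfg$gene_length_range[1] <= cfg$gene_length_range[2],
      "gene_length_range must be an increasing pair of lengths >= 1")
  chk(all(ctx %in% names(cfg$cytosine_density)) &&
        all(cfg$cytosine_density >= 0),
      "cytosine_density must name CG/CHG/CHH with non-negative values")
  chk(all(ctx %in% names(cfg$baseline_level)) &&
        all(cfg$baseline_level > 0 & cfg$baseline_level < 1),
      "baseline_level must name CG/CHG/CHH with values in (0, 1)")
  chk(cfg$level_dispersion > 0, "level_dispersion must be > 0")
  chk(cfg$coverage_mean >= 1, "coverage_mean must be >= 1")
  chk(cfg$n_planted >= 0L, "n_planted must be >= 0")
  chk(cfg$planted_width >= 1L, "planted_width must be >= 1")
  chk(cfg$planted_delta > 0 && cfg$planted_delta < 1,
      "planted_delta must be in (0, 1)")
  chk(cfg$planted_context %in% ctx, "planted_context must be CG, CHG or CHH")
  chk(cfg$fraction_hyper >= 0 && cfg$fraction_hyper <= 1,
      "fraction_hyper must be in [0, 1]")
  chk(cfg$coupling_sign_mix >= 0 && cfg$coupling_sign_mix <= 1,
      "coupling_sign_mix must be in [0, 1]")
  chk(cfg$expr_noise_sd >= 0, "expr_noise_sd must be >= 0")
  if (length(problems) > 0) {
    abort(c("Invalid sim_config:", setNames(problems, rep("x", length(problems)))),
          class = "methdmr_config_error")
  }
  invisible(cfg)
}
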