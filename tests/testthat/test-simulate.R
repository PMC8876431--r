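test_that("catalog generation is seeded and respects context densities", {
  cfg <- sim_config(n_genes = 20L, seed = 5L)
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1, c2)
  expect_true(all(c1$catalog$length >= cfg$gene_length_range[1] &
                    c1$catalog$length <= cfg$gene_length_range[2]))

  # CHH site count per genome ~ Binomial(total bp, 0.10); check within 4 sd
  total_bp <- sum(c1$catalog$length)
  n_chh <- sum(c1$sites$context == "CHH")
  expect_lt(abs(n_chh - 0.10 * total_bp), 4 * sqrt(total_bp * 0.10 * 0.90))

  # zero density for a context yields no sites of that context
  cfg0 <- sim_config(n_genes = 10L,
                     cytosine_density = c(CG = 0.04, CHG = 0, CHH = 0.10),
                     seed = 6L)
  expect_equal(sum(generate_catalog(cfg0)$sites$context == "CHG"), 0)

  # sites are unique keys within their sequences
  expect_equal(anyDuplicated(c1$sites[c("seq_id", "pos", "strand")]), 0)
})

test_that("planted regions are in-bounds, disjoint, and direction-consistent", {
  cfg <- sim_config(n_genes = 30L, n_planted = 25L, seed = 8L)
  cat_obj <- generate_catalog(cfg)
  truth <- plant_dmrs(cat_obj, cfg)
  expect_equal(nrow(truth), 25)
  joined <- dplyr::left_join(truth, cat_obj$catalog, by = "seq_id")
  expect_true(all(joined$start >= 1 & joined$end <= joined$length))
  expect_equal(anyDuplicated(truth$seq_id), 0)  # one region per gene: disjoint
  expect_equal(truth$direction, ifelse(truth$delta > 0, "hyper", "hypo"))
  expect_true(all(abs(truth$level_b_target - truth$level_a_target) ==
                    cfg$planted_delta))

  expect_equal(nrow(plant_dmrs(cat_obj, sim_config(n_planted = 0L))), 0)
  all_hyper <- plant_dmrs(cat_obj, sim_config(n_genes = 30L, n_planted = 10L,
                                              fraction_hyper = 1), seed = 9L)
  expect_true(all(all_hyper$direction == "hyper"))
  expect_error(
    plant_dmrs(cat_obj, sim_config(n_genes = 30L, n_planted = 31L), seed = 1L),
    class = "methdmr_validation_error"
  )
})

test_that("condition simulation is seeded, calibrated, and emits zero-coverage sites", {
  cfg <- sim_config(n_genes = 15L, seed = 21L, coverage_mean = 3)
  cat_obj <- generate_catalog(cfg)
  s1 <- generate_condition(cat_obj, cfg, NULL, seed = 22L)
  s2 <- generate_condition(cat_obj, cfg, NULL, seed = 22L)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))

  # every catalog site is emitted; zero-coverage ones drop at the filter
  expect_equal(nrow(s1), nrow(cat_obj$sites))
  expect_gt(sum(s1$n_meth + s1$n_unmeth == 0), 0)
  expect_equal(sum(filter_by_coverage(s1, 1)$n_meth +
                     filter_by_coverage(s1, 1)$n_unmeth == 0), 0)

  # unplanted CHH sites average near the 0.10 baseline
  cfg2 <- sim_config(n_genes = 100L, seed = 31L)
  cat2 <- generate_catalog(cfg2)
  s3 <- filter_by_coverage(generate_condition(cat2, cfg2, NULL, seed = 32L), 4)
  chh <- s3[s3$context == "CHH", ]
  expect_gt(nrow(chh), 1e4)
  lev <- mean(methylation_level(chh$n_meth, chh$n_unmeth))
  expect_lt(abs(lev - 0.10), 0.02)

  # planted regions shift the right condition in the right direction
  cfg3 <- sim_config(n_genes = 20L, n_planted = 10L, seed = 41L)
  cat3 <- generate_catalog(cfg3)
  truth <- plant_dmrs(cat3, cfg3)
  ctl <- generate_condition(cat3, cfg3, truth, seed = 42L, condition = "control")
  trt <- generate_condition(cat3, cfg3, truth, seed = 43L, condition = "treatment")
  in_region <- function(s, tr) {
    dplyr::inner_join(tibble::as_tibble(s), tr,
                      by = dplyr::join_by(seq_id, context, pos >= start, pos <= end))
  }
  hyper <- truth[truth$direction == "hyper", ]
  hc <- in_region(ctl, hyper); ht <- in_region(trt, hyper)
  expect_lt(abs(sum(hc$n_meth) / sum(hc$n_meth + hc$n_unmeth) - 0.10), 0.05)
  expect_lt(abs(sum(ht$n_meth) / sum(ht$n_meth + ht$n_unmeth) - 0.50), 0.07)
  hypo <- truth[truth$direction == "hypo", ]
  lc <- in_region(ctl, hypo); lt <- in_region(trt, hypo)
  expect_lt(abs(sum(lc$n_meth) / sum(lc$n_meth + lc$n_unmeth) - 0.50), 0.07)
  expect_lt(abs(sum(lt$n_meth) / sum(lt$n_meth + lt$n_unmeth) - 0.10), 0.05)
})

test_that("expression simulation couples planted genes with the planted sign", {
  cfg <- sim_config(n_genes = 40L, n_planted = 20L, seed = 51L)
  cat_obj <- generate_catalog(cfg)
  truth <- plant_dmrs(cat_obj, cfg)
  tab <- generate_expression(truth, cfg, seed = 52L,
                             gene_ids = cat_obj$catalog$seq_id)
  expect_equal(nrow(tab), 40)
  expect_identical(tab, generate_expression(truth, cfg, seed = 52L,
                                            gene_ids = cat_obj$catalog$seq_id))
  coup <- attr(tab, "coupling")
  expect_setequal(coup$gene_id, unique(truth$seq_id))

  # coupling 0 with no noise pins every log2fc at 0
  cfg0 <- sim_config(n_genes = 40L, n_planted = 20L, coupling = 0,
                     expr_noise_sd = 0, seed = 53L)
  tab0 <- generate_expression(truth, cfg0, seed = 54L,
                              gene_ids = cat_obj$catalog$seq_id)
  expect_true(all(tab0$log2fc == 0))

  # coupled genes are predominantly DEGs under the default thresholds
  flagged <- expression_table(tab)
  deg_rate <- mean(flagged$is_deg[flagged$gene_id %in% coup$gene_id])
  expect_gt(deg_rate, 0.8)
})

test_that("recovery scoring handles exact, empty, and simulated calls", {
  cfg <- sim_config(n_genes = 20L, n_planted = 8L, seed = 61L)
  cat_obj <- generate_catalog(cfg)
  truth <- plant_dmrs(cat_obj, cfg)
  as_calls <- tibble::tibble(
    seq_id = truth$seq_id, start = truth$start, end = truth$end,
    context = truth$context, direction = truth$direction
  )
  perfect <- evaluate_recovery(as_calls, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$mean_boundary_error, 0)

  none <- evaluate_recovery(as_calls[0, ], truth)
  expect_equal(none$sensitivity, 0)

  # wrong-direction calls overlap but do not count as recovered
  flipped <- dplyr::mutate(as_calls,
                           direction = ifelse(direction == "hyper", "hypo", "hyper"))
  fr <- evaluate_recovery(flipped, truth)
  expect_equal(fr$sensitivity, 0)
  expect_equal(fr$direction_agreement, 0)
  expect_equal(fr$precision, 1)
})
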