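test_that("DMC calling applies p, fold-change, and context absdiff criteria", {
  cfg <- dmr_config(contexts_analyzed = c("CG", "CHG", "CHH"))
  bins_chh <- fake_bins(1, 200)

  # CHH site A = (0, 20), B = (10, 10): diff 0.5, fc 51, enumerated p < 0.01
  a <- make_sites("g1", 50L, 0L, 20L)
  b <- make_sites("g1", 50L, 10L, 10L)
  expect_lt(oracle_fisher_p(0, 20, 10, 10), 0.01)
  dmcs <- call_dmcs(bins_chh, a, b, cfg)
  expect_equal(nrow(dmcs), 1)
  expect_equal(dmcs$diff, 0.5)
  expect_equal(dmcs$p, oracle_fisher_p(0, 20, 10, 10), tolerance = 1e-12)

  # identical counts in both conditions: diff 0, fc 1 -> not a DMC
  expect_equal(nrow(call_dmcs(bins_chh, a, a, cfg)), 0)

  # CG site with |diff| = 0.3 and tiny p fails the 0.4 CG threshold
  acg <- make_sites("g1", 50L, 0L, 40L, context = "CG")
  bcg <- make_sites("g1", 50L, 12L, 28L, context = "CG")
  expect_lt(oracle_fisher_p(0, 40, 12, 28), 0.001)
  expect_equal(nrow(call_dmcs(fake_bins(1, 200, context = "CG"), acg, bcg, cfg)), 0)
  # the same contrast in CHH context (threshold 0.1) is a DMC
  achh <- make_sites("g1", 50L, 0L, 40L)
  bchh <- make_sites("g1", 50L, 12L, 28L)
  expect_equal(nrow(call_dmcs(bins_chh, achh, bchh, cfg)), 1)

  # sites below min_cov in either condition are ineligible
  alow <- make_sites("g1", 50L, 0L, 3L)
  expect_equal(nrow(call_dmcs(bins_chh, alow, b, cfg)), 0)
})

test_that("bins merge across gaps <= 100 bp but not 101, and spans recompute", {
  cfg <- dmr_config(min_dmcs = 1L)
  pos <- c(10L, 310L)
  a <- make_sites("g1", pos, c(0L, 0L), c(20L, 20L))
  b <- make_sites("g1", pos, c(10L, 10L), c(10L, 10L))
  dmcs <- tibble::tibble(seq_id = "g1", pos = pos, strand = "+")

  # overlap merge: retained bins [1,200] and [51,250] -> one DMR [1,250]
  a_ov <- make_sites("g1", c(10L, 210L), c(0L, 0L), c(20L, 20L))
  b_ov <- make_sites("g1", c(10L, 210L), c(10L, 10L), c(10L, 10L))
  dmcs_ov <- tibble::tibble(seq_id = "g1", pos = c(10L, 210L), strand = "+")
  over <- call_dmrs(fake_bins(c(1, 51), c(200, 250)), dmcs_ov, a_ov, b_ov, cfg)
  expect_equal(nrow(over), 1)
  expect_equal(c(over$start, over$end), c(1L, 250L))

  # gap 100 joins, gap 101 does not
  g100 <- call_dmrs(fake_bins(c(1, 301), c(200, 400)), dmcs, a, b, cfg)
  expect_equal(nrow(g100), 1)
  expect_equal(c(g100$start, g100$end), c(1L, 400L))
  expect_equal(g100$dmc_count, 2L)
  expect_equal(g100$level_a, 0)        # pooled over the merged span
  expect_equal(g100$level_b, 0.5)
  expect_equal(g100$direction, "hyper")

  a2 <- make_sites("g1", c(10L, 310L, 320L), c(0L, 0L, 0L), c(20L, 20L, 20L))
  b2 <- make_sites("g1", c(10L, 310L, 320L), c(10L, 10L, 10L), rep(10L, 3))
  g101 <- call_dmrs(fake_bins(c(1, 302), c(200, 401)),
                    tibble::tibble(seq_id = "g1", pos = c(10L, 310L), strand = "+"),
                    a2, b2, cfg)
  expect_equal(nrow(g101), 2)
  expect_equal(g101$start, c(1L, 302L))

  # bins below the DMC-count floor are dropped before merging
  cfg7 <- dmr_config(min_dmcs = 7L)
  expect_equal(nrow(call_dmrs(fake_bins(1, 200), dmcs, a, b, cfg7)), 0)
})

test_that("condition swap flips directions but preserves spans and q", {
  sim <- sim_config(n_genes = 12L, n_planted = 6L, seed = 207L)
  e <- simulate_experiment(sim)
  cfg <- dmr_config()
  ab <- find_dmrs(filter_by_coverage(e$control), filter_by_coverage(e$treatment),
                  e$catalog_obj$catalog, cfg)
  ba <- find_dmrs(filter_by_coverage(e$treatment), filter_by_coverage(e$control),
                  e$catalog_obj$catalog, cfg)
  expect_gt(nrow(ab), 0)
  expect_equal(ab[c("seq_id", "start", "end", "context")],
               ba[c("seq_id", "start", "end", "context")],
               ignore_attr = TRUE)
  expect_equal(ab$min_q, ba$min_q, tolerance = 1e-12)
  expect_equal(ab$direction,
               ifelse(ba$direction == "hyper", "hypo", "hyper"))
  expect_equal(ab$meth_log2fc, -ba$meth_log2fc, tolerance = 1e-12)
})

test_that("merging is idempotent on its own output spans", {
  sim <- sim_config(n_genes = 12L, n_planted = 6L, seed = 303L)
  e <- simulate_experiment(sim)
  cfg <- dmr_config()
  a <- filter_by_coverage(e$control)
  b <- filter_by_coverage(e$treatment)
  bins <- call_candidate_bins(a, b, e$catalog_obj$catalog, "CHH", cfg)
  dmcs <- call_dmcs(bins, a, b, cfg)
  dmrs <- call_dmrs(bins, dmcs, a, b, cfg)
  expect_gt(nrow(dmrs), 0)
  respun <- call_dmrs(
    dmrs %>% dplyr::mutate(q = min_q) %>%
      dplyr::select(seq_id, start, end, context, q),
    dmcs, a, b, cfg
  )
  expect_equal(respun[c("seq_id", "start", "end", "direction", "level_a",
                        "level_b", "dmc_count")],
               dmrs[c("seq_id", "start", "end", "direction", "level_a",
                      "level_b", "dmc_count")])
})
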