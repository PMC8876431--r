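fake_dmrs <- function(seq_id, start, end, context = "CHH",
                      direction = "hyper", level_a = 0.1, level_b = 0.5) {
  tibble::tibble(
    seq_id = seq_id, start = as.integer(start), end = as.integer(end),
    context = context, dmc_count = 8L, n_bins = 1L,
    level_a = level_a, level_b = level_b,
    meth_log2fc = methylation_log2fc(level_a, level_b),
    direction = direction, min_q = 1e-4
  )
}

test_that("DMR summaries count by context and direction, permutation-invariant", {
  empty <- summarize_dmrs(fake_dmrs(character(), integer(), integer(),
                                    context = character(),
                                    direction = character(),
                                    level_a = numeric(), level_b = numeric()))
  expect_equal(sum(empty$n), 0)
  expect_equal(nrow(empty), 6)  # full CG/CHG/CHH x hyper/hypo grid

  d <- fake_dmrs(paste0("g", 1:5), 1, 200,
                 direction = c("hyper", "hyper", "hyper", "hypo", "hypo"))
  s <- summarize_dmrs(d)
  expect_equal(s$n[s$context == "CHH" & s$direction == "hyper"], 3L)
  expect_equal(s$n[s$context == "CHH" & s$direction == "hypo"], 2L)
  expect_equal(sum(s$n), nrow(d))
  expect_equal(summarize_dmrs(d[sample(5), ]), s)
})

test_that("cross-timepoint overlap fraction matches the printed convention", {
  # self-overlap is total
  x <- fake_dmrs(paste0("g", 1:4), 1, 200)
  expect_equal(overlap_fraction(x, x),
               tibble::tibble(shared = 4L, n_early = 4L, percentage = 100))
  # disjoint coordinates share nothing
  y <- fake_dmrs(paste0("g", 1:4), 500, 700)
  expect_equal(overlap_fraction(x, y)$percentage, 0)
  expect_error(overlap_fraction(x[0, ], x), class = "methdmr_validation_error")

  # same-seq but different-context regions do not overlap
  z <- fake_dmrs(paste0("g", 1:4), 1, 200, context = "CG")
  expect_equal(overlap_fraction(x, z)$shared, 0L)

  # the one-decimal percentage convention: 163/1010 -> 16.1, 108/1002 -> 10.8
  early <- fake_dmrs(paste0("e", 1:1010), 1, 200)
  late <- fake_dmrs(paste0("e", 1:163), 101, 300)
  expect_equal(overlap_fraction(early, late),
               tibble::tibble(shared = 163L, n_early = 1010L, percentage = 16.1))
  early2 <- fake_dmrs(paste0("f", 1:1002), 1, 200)
  late2 <- fake_dmrs(paste0("f", 1:108), 200, 400)  # single shared bp suffices
  expect_equal(overlap_fraction(early2, late2)$percentage, 10.8)
})

test_that("DMR-gene association aggregates by largest level difference", {
  expr <- expression_table(tibble::tibble(
    gene_id = c("g1", "g2"), log2fc = c(1.5, -0.2), fdr = c(0.01, 0.9)
  ))
  d1 <- fake_dmrs("g1", 1, 200)
  pairs <- suppressMessages(associate_dmr_genes(d1, expr))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$meth_log2fc, d1$meth_log2fc)
  expect_equal(pairs$expr_log2fc, 1.5)

  # two DMRs on one gene: |level diff| 0.3 vs 0.5 -> the 0.5 DMR wins
  d2 <- dplyr::bind_rows(
    fake_dmrs("g1", 1, 200, level_a = 0.2, level_b = 0.5),
    fake_dmrs("g1", 400, 600, level_a = 0.1, level_b = 0.6)
  )
  pairs2 <- suppressMessages(associate_dmr_genes(d2, expr))
  expect_equal(pairs2$level_diff, 0.5)

  # DMR gene missing from the expression table is dropped and counted
  d3 <- dplyr::bind_rows(d1, fake_dmrs("g9", 1, 200))
  expect_message(p3 <- associate_dmr_genes(d3, expr), "1 DMR gene")
  expect_equal(p3$gene_id, "g1")
  expect_equal(attr(p3, "n_unmatched"), 1L)
})

test_that("sign-regime correlation recovers exact and planted relationships", {
  meth <- c(-2, -1, 0.5, 1, 2, -0.5)
  exact_pos <- tibble::tibble(meth_log2fc = meth, expr_log2fc = 2 * meth)
  res <- split_and_correlate(exact_pos)
  expect_equal(res$positive$r, 1)
  expect_equal(res$negative$n, 0)
  expect_false(res$negative$computable)

  exact_neg <- tibble::tibble(meth_log2fc = meth, expr_log2fc = -meth)
  expect_equal(split_and_correlate(exact_neg)$negative$r, -1)

  # zero products are excluded and counted
  withzero <- tibble::tibble(meth_log2fc = c(meth, 1), expr_log2fc = c(2 * meth, 0))
  expect_equal(split_and_correlate(withzero)$n_excluded, 1L)

  # tidy/glance accessors agree with the object
  td <- generics::tidy(res)
  expect_equal(td$r[td$set == "positive"], 1)
  expect_equal(generics::glance(res)$n_negative, 0)

  # planted coupling 0.8, n = 200, noise 0.5: the recovered r lies in the
  # strong range implied by the generative correlation
  withr::with_seed(404, {
    m <- sample(c(-2.2, 2.2), 200, replace = TRUE)
    pairs <- tibble::tibble(meth_log2fc = m,
                            expr_log2fc = 0.8 * m + rnorm(200, 0, 0.5))
    fit <- split_and_correlate(pairs)
    expect_gt(fit$positive$r, 0.9)
    expect_lt(fit$positive$p, 0.001)
  })
})

test_that("expression-shift comparison matches the exact enumeration oracle", {
  # worked enumeration: one tail 1/20, doubled
  expect_equal(compare_expression_shift(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # symmetry and self-comparison
  expect_equal(compare_expression_shift(c(1, 2, 3), c(4, 5, 6)),
               compare_expression_shift(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(compare_expression_shift(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(compare_expression_shift(numeric(0), 1:3),
               class = "methdmr_validation_error")

  # exact branch equals the enumeration oracle for all group sizes <= 7
  withr::with_seed(77, {
    for (i in 1:40) {
      nx <- sample(1:7, 1); ny <- sample(1:7, 1)
      vals <- sample(seq(0.1, 60, by = 0.1), nx + ny)  # distinct, positive
      x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
      expect_equal(compare_expression_shift(x, y), oracle_wilcoxon_p(x, y),
                   tolerance = 1e-12)
    }
  })

  # tied/large inputs take the tie-corrected normal approximation
  big <- c(rep(1, 30), rep(2, 25))
  expect_equal(
    compare_expression_shift(big, c(rep(1, 10), rep(2, 40))),
    suppressWarnings(wilcox.test(big, c(rep(1, 10), rep(2, 40)),
                                 exact = FALSE, correct = FALSE)$p.value)
  )
})
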