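#' Methylation level of a cytosine or pooled region
#'
#' The methylation level is the fraction of reads supporting methylation,
#' `n_meth / (n_meth + n_unmeth)`.
#'
#' @param n_meth,n_unmeth Non-negative read counts (vectorised).
#' @return Numeric level(s) in `[0, 1]`.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  total <- n_meth + n_unmeth
  if (any(total < 1)) {
    abort("methylation level undefined at zero coverage",
          class = "methdmr_validation_error")
  }
  n_meth / total
}

#' Direction-agnostic fold change between two methylation levels
#'
#' Computes `(max(a, b) + eps) / (min(a, b) + eps)`, a symmetric ratio >= 1.
#' The pseudocount keeps the ratio finite when the smaller level is 0.
#'
#' @param level_a,level_b Levels in `[0, 1]` (vectorised).
#' @param epsilon Pseudocount, > 0.
#' @return Fold change(s) >= 1.
#' @export
level_fold_change <- function(level_a, level_b, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  (pmax(level_a, level_b) + epsilon) / (pmin(level_a, level_b) + epsilon)
}

#' Signed log2 methylation change (treatment vs control)
#'
#' `log2((level_b + eps) / (level_a + eps))`; positive values mean higher
#' methylation in condition B (treatment).
#'
#' @inheritParams level_fold_change
#' @return Signed log2 ratio(s).
#' @export
methylation_log2fc <- function(level_a, level_b, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  log2((level_b + epsilon) / (level_a + epsilon))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' P-value by the point-probability rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more likely than
#' the observed one.
#'
#' @param a,b,c,d Cell counts: `a`/`b` methylated/unmethylated in condition A,
#'   `c`/`d` in condition B.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("Fisher table cells must be non-negative integers",
          class = "methdmr_validation_error")
  }
  if (sum(cells) == 0) {
    abort("Fisher test undefined for the all-zero table",
          class = "methdmr_validation_error")
  }
  stats::fisher.test(matrix(as.integer(cells), nrow = 2, byrow = TRUE))$p.value
}

# Vectorised two-sided Fisher p for many tables; same point-probability rule,
# computed directly from the hypergeometric pmf (avoids per-call fisher.test
# overhead in the bin scan).
fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]          # condition-A margin
    m2 <- c[i] + d[i]          # condition-B margin
    k <- a[i] + c[i]           # methylated margin
    if (m1 + m2 == 0) {
      abort("Fisher test undefined for the all-zero table",
            class = "methdmr_validation_error")
    }
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    dens <- stats::dhyper(lo:hi, m1, m2, k)
    d_obs <- stats::dhyper(a[i], m1, m2, k)
    # relative tolerance absorbs floating-point ties between mirror tables
    p[i] <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, order-aligned with the input and clipped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]", class = "methdmr_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}
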