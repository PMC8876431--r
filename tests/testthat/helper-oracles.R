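# Independent oracles, implemented from first principles so they share no code
# with the package internals they check.

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, using binomial coefficients directly.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  N <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  pmf <- choose(m1, xs) * choose(m2, k - xs) / choose(N, k)
  p_obs <- pmf[xs == a]
  # small relative tolerance absorbs floating-point ties of mirror tables
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from the textbook formula:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled observations to the first group.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Compact constructor for methylome fixtures.
make_sites <- function(seq_id, pos, n_meth, n_unmeth,
                       context = "CHH", strand = "+", ...) {
  methylome(tibble::tibble(seq_id = seq_id, pos = pos, strand = strand,
                           context = context, n_meth = n_meth,
                           n_unmeth = n_unmeth), ...)
}

# A random valid methylome sample for property-style round trips.
random_sample <- function(n = 50, seed = 1) {
  withr::with_seed(seed, {
    key <- unique(tibble::tibble(
      seq_id = sample(sprintf("g%02d", 1:5), n, replace = TRUE),
      pos = sample.int(2000, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE)
    ))
    methylome(dplyr::mutate(
      key,
      context = sample(c("CG", "CHG", "CHH"), nrow(key), replace = TRUE),
      n_meth = rpois(nrow(key), 5),
      n_unmeth = rpois(nrow(key), 5)
    ))
  })
}
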