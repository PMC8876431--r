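# Minimal retained-bin fixture for exercising DMC counting and merging.
fake_bins <- function(start, end, seq_id = "g1", context = "CHH", q = 1e-4) {
  tibble::tibble(
    seq_id = seq_id, start = as.integer(start), end = as.integer(end),
    context = context,
    n_meth_a = 0L, n_unmeth_a = 0L, n_meth_b = 0L, n_unmeth_b = 0L,
    level_a = NA_real_, level_b = NA_real_, fold_change = NA_real_,
    p = q, q = q
  )
}
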