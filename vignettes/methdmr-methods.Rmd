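---
title: "Hierarchical sliding-window DMR calling and methylome-transcriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical sliding-window DMR calling and methylome-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdmr)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads methylation as per-cytosine
counts of converted (unmethylated) and unconverted (methylated) bases. In
plants, cytosine methylation occurs in three sequence contexts — CG, CHG and
CHH (H = A, C or T) — maintained by distinct enzymatic pathways, and
treatment-induced methylation changes are typically interrogated by comparing
two conditions region by region. `methdmr` implements a hierarchical,
context-aware differentially-methylated-region (DMR) caller for data mapped to
de-novo-assembled unigenes (so the sequence identifier doubles as the gene
identifier), together with downstream integration of DMRs with a
gene-expression table.

## The procedure

For one comparison (control condition A vs treatment condition B) and one
context, the caller proceeds in four stages:

1. **Coverage filter.** Only cytosines covered by at least `min_cov = 4` reads
   in a library are used. Replicates, when present, are pooled by count
   summation beforehand so each unit of testing is a single 2x2 table.
2. **Candidate-bin scan.** Bins of 200 bp advance in 50-bp steps. Per bin,
   counts of the analysed context are pooled over covered cytosines in each
   condition, and the 2x2 table (methylated/unmethylated by condition) is
   tested with a two-sided Fisher's exact test (point-probability rule).
   P-values are Benjamini-Hochberg adjusted across all *tested* bins of the
   context; bins lacking coverage in either condition are untested and
   excluded from the family rather than assigned p = 1, which would inflate
   the family with empty windows. Bins with FDR < 0.05 and a methylation-level
   fold change > 1.5 are retained. The methylation level is the methylated
   read fraction; the fold change is the symmetric ratio
   $(\max(\ell_A,\ell_B)+\varepsilon)/(\min(\ell_A,\ell_B)+\varepsilon)$ with
   pseudocount $\varepsilon = 0.01$, which keeps the ratio finite when a level
   is exactly 0 (behaviour at zero levels is otherwise undefined).
3. **DMC calling.** Within retained bins, each cytosine covered at
   `min_cov` in both conditions is tested with a per-site Fisher's exact
   test. A differentially methylated cytosine (DMC) requires P < 0.01, a
   level fold change >= 2 (same symmetric ratio), and an absolute level
   difference of at least 0.4, 0.2 or 0.1 for CG, CHG and CHH respectively —
   the thresholds scale with each context's dynamic range.
4. **Retention and merging.** Bins with at least 7 DMCs are retained.
   Retained bins that overlap or abut are merged, and neighbouring regions
   separated by no more than 100 bp are joined into a larger DMR. Because the
   joining gap is non-negative, both steps are a single sorted sweep that
   links a bin to the growing region whenever
   $\mathrm{start}_2 - \mathrm{end}_1 - 1 \le 100$; the result is identical
   to performing the overlap merge first. Final region statistics (levels,
   signed log2 methylation change
   $\log_2((\ell_B+\varepsilon)/(\ell_A+\varepsilon))$, direction,
   distinct-DMC count) are recomputed from pooled counts over the final span
   rather than averaged over member bins, keeping level estimates
   coverage-weighted. A DMR is *hyper*methylated when the treatment level
   exceeds the control level.

By default only the CHH context is analysed (`contexts_analyzed = "CHH"`):
in plant treatment-response datasets CHH DMRs outnumber CG and CHG DMRs by
roughly an order of magnitude, and the machinery runs identically for the
other contexts when requested.

Two deliberate interface conventions guard against coordinate confusion: all
internal coordinates and TSV outputs are 1-based inclusive (matching
cytosine-report conventions), while BED exports are 0-based half-open, and
both carry a header comment saying so.

### Sequence ends

The step grid leaves up to `bin_size - 1` trailing bases uncovered, so after
the full windows one extra window anchored at the sequence end is appended
(and a sequence shorter than one bin becomes a single whole-sequence window).
Every covered cytosine therefore lies in at least one bin. Overlapping
significant bins are inevitable with a step smaller than the bin size, which
is why merging precedes the gap-bounded joining.

## Integration with expression

Because unigenes are the coordinate space, a DMR maps to a gene directly by
its sequence identifier. When several DMRs land on one gene, the DMR with the
largest absolute level difference represents the gene — the configurable
`multi_dmr_rule` — so each gene contributes one point downstream. Three
summaries follow:

- **Context/direction counts** (`summarize_dmrs()`), the standard reporting
  shape for DMR studies.
- **Cross-timepoint overlap** (`overlap_fraction()`): an early DMR is "also
  identified" later when it shares at least `overlap_rule = 1` bp with a
  late DMR of the same sequence and context; the percentage is reported to
  one decimal. Requiring identical bins instead of coordinate overlap would
  understate persistence whenever boundaries shift by a step.
- **Fold-change correlation** (`split_and_correlate()`): gene pairs are split
  by the sign of the product of methylation and expression log2 fold changes
  into positive and negative regimes (zero products are excluded and
  counted, since they carry no sign information); Pearson's r and its
  t-transform p-value (n - 2 df) are computed per regime, and a regime with
  fewer than 3 pairs is reported as not computable rather than an error.
- **Expression-shift comparison** (`compare_expression_shift()`): a two-sided
  Wilcoxon rank-sum test on the *absolute* expression log2 fold changes of
  DMR genes versus all genes (a superset background). Absolute values are
  used because the question is whether DMR genes show *more differential*
  expression, in either direction. The exact null distribution is used when
  both groups have at most 10 observations and no ties; otherwise the
  tie-corrected normal approximation (without continuity correction, so two
  identical groups give z = 0 and p = 1).

A gene is a DEG when FDR < 0.05 and |fold change| >= 2
(`integration_config()`), mirroring common RNA-seq reporting thresholds.

## The synthetic methylome generator

WGBS datasets of the scale this workflow targets (tens of millions of
methylated cytosines per sample) cannot be shipped or regenerated at desk
scale, so the package includes a seeded generator that gives every pipeline
stage a test surface with known truth.

What it emulates:

- **Unigene-like references**: gene lengths uniform in 1.5-2.5 kb by default,
  with per-context cytosine densities (CG 0.04, CHG 0.03, CHH 0.10 sites/bp)
  reflecting the relative abundance of the three contexts.
- **Biological overdispersion**: each site's methylation level is drawn from
  a beta distribution centred on its context baseline (CG 0.80, CHG 0.50,
  CHH 0.10 — the typical plant methylome ordering) with concentration 20, and
  counts are binomial in a Poisson(25) coverage. Beta-binomial rather than
  plain binomial variation is what makes the null calibration test meaningful:
  with purely binomial noise every Fisher test would be exactly calibrated by
  construction.
- **Planted DMRs**: non-overlapping 200-bp windows (one per gene, aligned to
  the 50-bp bin grid by default; a toggle plants them off-grid to stress the
  tiling), each with a level difference of magnitude `planted_delta = 0.4`.
  A *hyper* region raises the treatment to baseline + delta; a *hypo* region
  anchors the **control** at baseline + delta and leaves the treatment at
  baseline. This "loss of locally elevated methylation" construction is the
  natural model for CHH hypomethylation — RdDM-targeted loci sit above the
  genome-wide background — and it keeps the planted contrast magnitude equal
  in both regimes. (Shifting the treatment *down* from a 0.10 CHH baseline
  would clip at the 0.01 floor and produce a ~0.09 contrast that the 0.1
  absolute-difference DMC threshold excludes by construction.)
- **Coupled expression**: genes carrying a planted region receive
  `sign * coupling * meth_log2fc` plus Gaussian noise (coupling 0.8, noise SD
  0.5), with the sign positive for half the coupled genes — reproducing the
  positive and negative methylation-expression regimes seen in real
  integration scatter plots. Simulated FDRs make coupled genes predominantly
  DEGs.

What it does **not** emulate: read-level artefacts (incomplete bisulfite
conversion, mapping bias, strand asymmetries), linkage between neighbouring
sites beyond the shared regional mean, and genome-scale context composition.
Passing tests on synthetic data therefore demonstrate the *procedure's*
correctness and calibration, not the biological validity of any particular
real-data finding.

## Numerical choices

- Fisher tests use the two-sided point-probability rule; probabilities tied
  with the observed table up to a 1e-7 relative tolerance are included, the
  standard guard against floating-point asymmetry between mirror tables.
- The BH family is all tested bins of one context within one comparison;
  contexts are analysed and reported separately.
- Strands are never collapsed (no CpG strand symmetrisation): no combining
  rule is assumed, and CHH methylation is strand-specific anyway.
- Bin-level fold change compares *pooled* levels, not mean per-cytosine
  levels: pooling weights cytosines by coverage and matches the 2x2 table
  actually tested.
- Direction ties (`level_b == level_a` over a merged span) are labelled
  hypo; they cannot occur in practice because retention requires a fold
  change > 1.5 at the bin level.

## Validation problem sizes

The test suite and acceptance script validate on 50-gene x ~2-kb simulated
genomes (roughly 1,900 tested bins per run): 20 null seeds for calibration
(expected retained-DMR count at most `bin_fdr` x tested bins; in practice 0),
20 planted seeds for recovery (mean sensitivity >= 0.9 at delta 0.4, coverage
25, CHH density 0.10, with 100% direction agreement), and 100 seeds for the
coupling recovery (both regimes |r| > 0.5 in >= 95% of seeds). These sizes
give stable Monte-Carlo estimates while keeping a full run in tens of
seconds; sensitivity at these parameters was confirmed by per-site Fisher
power checks before the defaults were frozen.

## Known limitations

- The caller tests pooled counts, so replicate-to-replicate biological
  variability does not enter the test statistic (unlike beta-binomial
  regression callers such as dmrseq or methylKit's overdispersed models);
  with few or no replicates — the setting this workflow addresses — there is
  no information to estimate it from.
- BH is applied per context and comparison; running many comparisons still
  multiplies families.
- `overlap_fraction()` counts early regions with any qualifying late overlap;
  it is not symmetric in its arguments, matching how persistence percentages
  are reported.
- The generator plants at most one region per gene; multi-DMR genes arise in
  calls (via split regions) but are rarer than in real data.

## A worked example

```{r example, eval = FALSE}
library(methdmr)

run <- run_pipeline(
  out_dir = tempfile("methdmr_run_"),
  sim = sim_config(seed = 11),
  config = dmr_config(),           # 200/50 bins, CHH, all default thresholds
  integration = integration_config()
)
report_summary(run)
evaluate_recovery(run$dmrs, run$truth)
```
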