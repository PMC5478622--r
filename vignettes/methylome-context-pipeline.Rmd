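---
title: "Methylome context of CpG-island regions and tandem gene pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome context of CpG-island regions and tandem gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemCGI)
```

## The analysis model

tandemCGI studies where DNA methylation sits relative to two genomic
context systems, and how tumor-specific hypermethylation distributes
over them:

1. **CpG-island regions (CGIR).** Each CpG island (CGI) is extended by a
   2 kb *shore* and a further 2 kb *shelf* on each side.  Flanks are
   named N (lower-coordinate, p-arm side) and S (higher-coordinate,
   q-arm side) purely by chromosome coordinate order.  Relative to a
   gene, a shore is *5′* or *3′*: for a Watson-strand (`+`) gene the
   N-shore is the 5′-shore, for a Crick-strand (`-`) gene the S-shore
   is.  This re-labelling is where strand enters; the N/S naming itself
   never depends on it.
2. **Gene context.** Probes are classified per overlapping gene as
   TSS1500 (1500–200 bp upstream of the TSS), TSS200 (final 200 bp),
   5′-UTR, first exon, gene body or 3′-UTR, with per-gene precedence in
   that order (TSS200 highest).  TSS1500–first-exon count as *promoter*,
   body and 3′-UTR as *coding*.  TSS proximity is a boundary-inclusive
   ±300 bp window.
3. **Tandem pairs.** Two same-strand genes where the transcription end
   site (TES) of the upstream gene lies a short intergenic distance
   upstream of the downstream gene's TSS.  The downstream promoter CGI
   of such a pair is the island overlapping the downstream TSS ± 300 bp.
   Pairs are binned by TES–TSS distance in half-open 1 kb bins, the
   "k kb" bin meaning [k−1, k) kb, with an overflow group beyond the
   last edge.
4. **Hypermethylation score.** Per region, per-sample mean beta values
   (percent) are averaged within the tumor and the normal group; the
   score is tumor mean − normal mean, computed on unrounded values and
   rounded half-up only at report time.  Ranking is by difference, then
   tumor mean, then region id.

Aggregation is an unweighted arithmetic mean over a region's member
probes, then a missing-aware group statistic (median by default for
distributional summaries, mean for the score); missing values are
excluded pairwise and never imputed.  Beta values (fraction methylated,
in [0, 1]) are used throughout rather than M-values.

## Numerical and boundary conventions

These choices are deliberate and tested; several fill gaps where no
published convention exists.

* **Coordinates** are 0-based half-open internally.  BED is read
  verbatim, GTF converted from 1-based inclusive; printed 1-based
  inclusive table coordinates can be converted with `from_one_based()`.
* **TSS/TES.**  The TSS *base* of a `-` gene is the last base of its
  interval.  Distances between genes, however, use half-open *boundary*
  coordinates (`+`: downstream start − upstream end; `-`: upstream
  start − downstream end).  With boundary coordinates the two strands
  are exact mirror images: reflecting a chromosome and flipping strands
  leaves every TES–TSS distance unchanged, which the test suite asserts.
  Base-position arithmetic on the `-` strand would shift distances by
  one and break that symmetry.
* **Flank truncation.**  Where two islands face each other across a gap
  smaller than twice the flank width, facing flanks are truncated at the
  midpoint of the gap; an odd gap gives the extra base to the
  lower-coordinate island.  The rule is deterministic and symmetric; the
  exact rule used by the array annotation is not published, so this is
  the package's own choice, validated against a per-bp nearest-island
  oracle.
* **Tandem adjacency.**  A pair requires adjacency: any intervening gene
  (either strand) overlapping the TES–TSS gap disqualifies it, because
  an intervening promoter would confound the occlusion interpretation.
  Overlapping (read-through) pairs are dropped rather than assigned
  distance 0, keeping the distance interpretable as an intergenic gap.
* **Downstream-CGI ties** go to the island whose nearest edge is closest
  to the TSS, exact ties to the lower-coordinate island.
* **Rounding** is half-up (84.5 → 85), matching how published
  two-normal-sample means and differences behave; banker's rounding
  would contradict them.
* **Degenerate statistics.**  The rank-sum test is computed by full
  enumeration of group assignments with midranks whenever the pooled
  sample has ≤ 10 observations, so all-tie input yields p = 1 rather
  than a failure; larger samples use the normal approximation with
  continuity correction.  A zero-variance t-test input returns p = 1
  (equal means) or 0 (unequal) instead of erroring.  The chi-square test
  applies no continuity correction.  No multiple-testing adjustment is
  applied by default (raw p with significance stars); `p.adjust` can be
  applied downstream if desired.
* **Open choices resolved.**  One TSS per gene is used (alternative
  TSSs are out of scope).  The distance-bin analysis summarizes each
  downstream CGI by its per-sample mean (per-probe pooling is possible
  via `stratified_distribution` but is not the default).  The shore
  asymmetry comparison defaults to an unpaired pooled rank-sum; a
  per-gene paired signed-rank variant is available via `paired = TRUE`.

## The synthetic-data generator

`simulate_genome()` and `simulate_beta()` produce a toy genome and a
450K-style beta matrix embodying the generative structure the analysis
assumes, so every stage runs and is validated with no downloads.

Defaults encode the study conditions the analysis targets:

| parameter | default | meaning |
|---|---|---|
| `mu_tss_cgi` | 0.08 | TSS-associated CGI probes (~8% methylation) |
| `mu_body_cgi_normal` / `_tumor` | 0.17 / 0.72 | gene-body CGI probes, normal vs tumor |
| `mu_no_cgir` | 0.82 | open-sea probes outside any CGIR |
| `mu_shore_base` / `mu_shelf` | 0.35 / 0.75 | shore and shelf probes |
| `delta_shore` | 0.15 | offset added to 5′-shore probe means, both groups |
| `delta0`, `lambda` | 0.6, 1500 bp | tumor effect Δ(d) = Δ₀·e^(−d/λ) on downstream tandem promoter CGIs |
| `tandem_distance_grid` | 170, 500, 1500, 2500, 4500, 7000 bp | planted TES–TSS distances (170 bp mirrors the tightest known tandem locus) |
| `kappa` | 0.45 | logit-scale noise s.d. |
| `n_tumor` / `n_normal` | 3 / 2 | sample counts, echoing a three-cell-line vs two-normal design |
| `n_genes`, genome | 150 genes on 2 × 1.7 Mb | problem size used throughout the tests |

The class means were chosen to echo the medians such analyses report on
real arrays (unmethylated TSS islands near 8%, body CGIs rising from
~17% to ~72% in tumor, open sea near 82%, shores between); the
exponential form of Δ(d) is a modeling convenience — real data show only
a binned, decreasing pattern — so recovery tests assert monotonicity,
never the functional form.

**Noise model.**  Probe values are logit-normal:
β = logistic(m + κZ).  The location m is *mean-calibrated* by quadrature
so that E[β] equals the configured class mean exactly (a plain
logit-normal centred at logit(μ) would be biased toward 0.5).  κ = 0
returns expectations exactly.  Expectations pushed outside [0, 1] by
effects are clipped to [0.001, 0.999] with a warning count.

**Truth tables** (probe class, orientation, planted flag, pair
distances, expected betas) are emitted alongside the data, so recovery
tests compare pipeline output against recorded ground truth rather than
re-deriving it from generator internals.

**Determinism.**  `simulate_genome()` seeds the RNG with `seed`,
`simulate_beta()` with `seed + 1`; identical configuration gives
bit-identical output.

What the generator does **not** emulate: type I/II probe chemistry,
background/dye bias, batch effects, SNP-overlapping or cross-reactive
probes, copy-number distortion of betas, biological heterogeneity
between tumor samples, or realistic gene/CGI length distributions.
Passing recovery tests therefore demonstrate the pipeline's correctness
under its own assumed generative structure — not robustness to array
artifacts, which must come from upstream preprocessing.

## Validation strategy and problem sizes

* Every geometric operation is checked against an independent
  brute-force oracle: per-bp nearest-island labelling for segmentation,
  a per-bp strand-local classifier for gene context, an exhaustive
  pairwise scan for tandem detection (over 1000 randomized cases).
* The exact rank-sum path is checked against full enumeration for all
  pooled sizes ≤ 8, including heavily tied input; the chi-square
  statistic against the hand-computed margins formula.
* Published worked examples: per-cell-line promoter methylation values
  for P2RY6, RASSF1A, AOX1 and CDKN1C (shipped under `inst/extdata/`)
  reproduce their printed mean and difference columns exactly under
  half-up rounding.
* End-to-end recovery on the default simulation (150 genes, ~3,500
  probes, 5 samples): planted downstream-tandem CGIs fill the top of the
  ranked table (precision 1.0 at the tested seeds), the shore offset is
  recovered within ±0.03, per-bin tandem effects are monotone
  non-increasing, and with Δ₀ = 0 the near-vs-far contrast rejects at a
  rate consistent with the nominal α = 0.05 over 200 replicates.

## Limitations

* CGI locations are inputs; the package never recomputes islands from
  sequence, and raw IDAT preprocessing/normalization is out of scope.
* Convergent and divergent gene-pair configurations are not analyzed.
* The ranked tables use a deterministic tie-break (difference, tumor
  mean, region id); published rankings are not always internally
  consistent at ties, so comparisons should be on scores, not rank
  positions.
* Region aggregation (unweighted probe mean) is one of several
  defensible summaries; the group statistic is configurable but the
  probe weighting is not.
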