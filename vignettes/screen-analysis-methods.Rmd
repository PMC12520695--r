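---
title: "Methods: bottlenecked CRISPR screen ranking and rank aggregation"
author: "screenrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottlenecked CRISPR screen ranking and rank aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenrank)
```

# Overview

`screenrank` analyzes two pooled CRISPR screen designs whose common feature
is a severe selective bottleneck between the input cell pool and the
sequenced output:

1. **An in vivo metastasis enrichment screen.** A genome-wide activation
   library (three sgRNAs per gene) is transduced into tumor cells; the pool
   is transplanted into mice; lungs of mice that develop metastasis are
   sequenced and compared with an input baseline taken at transplantation.
   Genes whose guides are reproducibly over-represented in lungs are
   candidate metastasis drivers.
2. **A two-gate reporter-stability sort.** Cells carry a
   DsRed-IRES-EGFP–substrate reporter whose EGFP/DsRed ratio tracks the
   stability of the fused substrate protein, plus a knockout library of
   candidate regulators. The top and bottom 5% of cells by fluorescence
   ratio are sorted and sequenced; guides enriched in the low gate mark
   genes whose loss destabilizes the substrate (candidate stabilizers).

Both readouts reduce to guide-by-sample count matrices keyed on a library
manifest, which is why the package shares its I/O, normalization and
quantification layers between the two designs.

# The in vivo enrichment ranking

The gene ranking follows the standard analysis for in vivo enrichment
screens, stage by stage:

1. **Low-coverage exclusion.** A guide with fewer than `min_lung_reads`
   raw reads (default 50) in a lung sample is excluded from that mouse's
   analysis. The floor is applied per lung sample, because the fold-change
   statistic in the next step is also per mouse. Filtering happens on raw
   counts *before* normalization, and excluded guides still contribute to
   their column's total during normalization: the filter expresses "too few
   reads to trust in this mouse", not "absent from the sequencing run".
2. **Total-count normalization.** Each sample is scaled to
   `normalization_scale` total reads (default $10^6$: reads-per-million),
   making samples of different depth comparable.
3. **Per-mouse fold change.** For each retained guide $g$ and mouse $m$,
   $$\mathrm{FC}_{g,m} = \frac{\mathrm{lung}_{g,m} + c}{\mathrm{input}_g + c},$$
   with a symmetric pseudocount $c$ (default 0.5 RPM) that keeps guides
   absent from the input finite while leaving well-covered guides
   essentially untouched.
4. **Cross-mouse averaging.** Each guide's per-mouse fold changes are
   combined into one value. By default the arithmetic mean runs over *all*
   metastatic mice: an excluded (guide, mouse) pair contributes zero to the
   numerator but still counts in the denominator. See below for why.
5. **Best-guide-per-gene ranking.** A gene is represented by its most
   enriched surviving guide; genes are ranked by that value, descending.
   Ties are broken lexicographically by symbol so the ranking is
   reproducible; genes with no surviving guide are omitted.

## Why the average runs over all metastatic mice

A lung library that passes through a clonal bottleneck is *jackpotted*: a
few founder clones make up most of the reads, so a neutral guide that
happens to seed one lung can show a per-mouse fold change of 20 or more in
that single mouse. If the cross-mouse average were taken only over mice in
which a guide is retained, such a guide would keep its single-mouse jackpot
value untouched (`n_mice_retained = 1`) and outrank genuinely enriched
genes that seed most mice at more moderate fold changes. Dividing by the
number of metastatic mice instead rewards reproducibility across animals:
a guide enriched 17-fold in 7 of 8 mice averages ~15, while a one-mouse
jackpot of 40 averages 5. In simulation under the default bottleneck
scenario this choice is what separates reliable driver recovery from
near-random rankings. The retained-only mean remains available
(`invivo_config(average_over = "retained")`) for shallow-bottleneck designs
where most guides are retained in most animals, and the geometric mean
(`averaging = "geometric"`, always over retained mice, since a zero would
annihilate the product) for users who prefer a scale-symmetric average of
ratios.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_lung_reads` | 50 | raw reads | below this, per-mouse abundance is dominated by PCR/sampling noise |
| `normalization_scale` | 1e6 | reads | RPM; any positive value gives the same ranking |
| `pseudocount` | 0.5 | RPM | finite fold changes for input dropouts; negligible for counts ≫ 1 RPM |
| `averaging` / `average_over` | arithmetic / all | — | see above |

No p-value is attached to the in vivo ranking: with one input column and a
handful of heavily bottlenecked lungs there is no credible null model at
the gene level, and the ranking is consumed by a triage step rather than a
significance cut. The triage stage (`select_enriched()` +
`intersect_sets()`) therefore exposes the enrichment cutoff — top-N or a
minimum average fold change — as an explicit, recorded parameter rather
than hard-coding a "significant" threshold, and reports the overlap with an
interactome list in screen-rank order together with exclusive Venn region
counts.

# The sorted-screen statistic: alpha-RRA with a permutation null

Each guide gets a score
$s_g = \log_2\!\big((\mathrm{low}_g + c)/(\mathrm{high}_g + c)\big)$ on
RPM-normalized gate counts, positive when the guide is enriched in the low
gate (the stabilizer direction for this reporter; `direction = "high"`
flips it). The scoring statistic is deliberately a transparent normalized
log-ratio rather than a count-model test: the gene-level aggregation below
is rank-based, so any monotone per-guide statistic yields the same result,
and a simple ratio is easy to validate.

Guides are ranked by descending score and ranks are normalized to
$r = \mathrm{rank}/n \in (0, 1]$, with average ranks on ties. For a gene
with $k$ guides at sorted normalized ranks $r_{(1)} \le \dots \le r_{(k)}$,
classical robust rank aggregation asks how surprising the $j$-th best rank
would be if the gene's ranks were uniform:
$$\rho = \min_{j} P\big(U_{(j)} \le r_{(j)}\big), \qquad
P\big(U_{(j)} \le x\big) = \mathrm{pbeta}(x;\, j,\, k - j + 1),$$
the Beta order-statistic tail for $k$ i.i.d. uniforms. The *alpha* variant
restricts the minimum to guides inside the top `alpha` fraction of the
global ranking (default 0.25), so a gene is judged only on its active
guides and inert guides cannot dilute it; a gene with no guide in the top
fraction scores $\rho = 1$.

Significance comes from a permutation null that preserves the library
structure: for each gene size, `n_permutations` draws of that many
normalized ranks are sampled without replacement from the observed rank
pool (equivalent to permuting gene labels over guides), and
$$p = \frac{1 + \#\{\rho_\mathrm{null} \le \rho_\mathrm{obs}\}}{n_\mathrm{permutations} + 1},$$
which is valid (never zero, floor $1/(n_\mathrm{perm}+1)$) and
deterministic given the seed. Gene-level FDR is Benjamini–Hochberg across
all genes.

Two calibration facts shape the defaults:

* At `alpha < 1` the null p-value distribution has an atom at 1 by
  construction — every gene with no guide in the top fraction gets
  $\rho = 1$ (with three guides per gene and `alpha = 0.25`, about
  $0.75^3 \approx 42\%$ of null genes). Uniformity of null p-values is
  therefore checked at `alpha = 1`, where the statistic is continuous; the
  test suite verifies a Kolmogorov–Smirnov distance below 0.05 over 1,000
  no-effect genes.
* `alpha = 0.25` and 10,000 permutations are implementation defaults (a
  top-quartile focus is the common choice for 3-guide libraries; 10,000
  permutations give a p-value floor of $10^{-4}$); both are surfaced in the
  configuration and recorded in pipeline provenance.

# What the synthetic-data generator emulates

The generator is the package's stand-in for deposited sequencing data; its
defaults are the study conditions the analysis stages are validated
against.

**Library.** `generate_library()` defaults to 23,430 genes × 3 guides
= 70,290 sgRNAs (the genome-wide activation library design) with random
distinct 20-mers as protospacers.

**Input baseline.** Per-guide abundance is log-normal with $\sigma = 0.5$
(typical plasmid-pool skew: a ~3-fold 10–90% spread); sequencing is a
multinomial draw. Representation defaults to 500 cells/sgRNA, and
sequencing depth defaults to one read per cell, since the screen protocol
fixes coverage rather than depth.

**Lung colonization.** Each of `n_mice` (default 18) mice develops
metastasis with probability 0.5 (matching the observed 9-of-18 penetrance
of the modeled screen). A metastatic lung is founded by
`clones_per_mouse = 200` clones drawn with probability proportional to
input abundance × per-gene seeding weight; founder clones expand
independently with log-normal noise ($\sigma = 0.5$); reads are multinomial
at $10^6$ per lung. The founding step is the bottleneck: with 200 founders
against 70,290 (or, desk-scaled, 1,500) guides, most guides are absent from
any given lung and the library is jackpotted, which is the qualitative
signature of in vivo screens that this model is built to reproduce. The
paper-scale screen gives no quantitative measure of its complexity
collapse, so 200 founders is a modeling choice, exposed in the
configuration. Driver genes are spiked by seeding weight (default scenario:
5 drivers at weight 20).

**Null lungs.** `simulate_null_lungs()` resamples lungs multinomially from
the input abundance with no bottleneck — the sequencing-only null used to
check that average fold changes center at 1.

**Sorted gates.** Each of `n_cells` cells carries one uniformly drawn
guide; its reporter log-ratio is normal around the per-gene effect
(baseline $\sigma = 1$); the top and bottom `floor(0.05 * n_cells)` cells
form the gates; gate reads are multinomial over the gate's cell
composition. A stabilizer gene's knockout shifts its cells' log-ratio by
−2 SD in the default scenario. The per-guide *cell* compositions are
returned alongside the read counts because read counts are overdispersed
relative to multinomial sampling of cells (each sorted cell contributes
many reads), and null-calibration checks must be made at the cell level.

**Desk-scale scenarios.** The exercised defaults are scaled so the whole
suite runs in seconds: `invivo_scenario()` uses 500 genes × 3 guides,
8 mice at full penetrance, 200 clones/mouse and $10^6$ reads/sample;
`sortscreen_scenario()` uses the same library size with $10^5$ sorted
cells. Full-scale configurations (23,430 genes, 18 mice, penetrance 0.5)
are constructed by `invivo_scenario("full")` but not exercised by the
tests. Under the scaled defaults, all 5 spiked drivers rank in the top 10
of the in vivo ranking, and all 5 spiked stabilizers in the top 10 by RRA,
in ≥ 90% of 20 seeds — the package's two headline recovery properties.

**What the simulator does not model.** PCR amplification bias and
sequencing error (quantification is exact-match by design), guide-level
efficacy differences within a gene, mouse-to-mouse biology beyond
penetrance and clone sampling, doublet infections, spectral/compensation
effects in sorting (fluorescence is a single log-ratio scalar), and
inter-gate contamination. Passing recovery tests therefore demonstrates
that the statistics behave correctly under the screens' sampling
structure, not that any particular biological hit list is reproduced —
reproducing the modeled study's hit lists would require its deposited
sequencing reads and its (unstated) enrichment cutoff.

# Numerical choices and degenerate inputs

* Guide quantification is exact string match on the forward strand after
  removal of the constant portion (fixed prefix length or anchor search);
  a read too short for extraction, or whose 20-mer matches no protospacer,
  is counted unmatched, and `matched + unmatched = total` always holds.
* Zero-total samples are a hard error at normalization (they cannot be
  normalized, and silently propagating NaN would poison fold changes).
* Guides retained in zero mice are dropped from the ranking and reported
  in a side list; a gene loses its entry only when all its guides are
  dropped.
* Tied guide scores get average ranks before normalization, so the RRA
  ranking is invariant to input order.
* All generators and the permutation null are pure functions of
  (configuration, seed); RNG state of the caller is saved and restored, so
  package calls never perturb user-level reproducibility.
* Gene symbols are uppercased at every I/O boundary; no alias or ortholog
  mapping is attempted when intersecting screen genes with interactome
  protein symbols — identity of uppercased symbols is the join rule.

# Known limitations

* The in vivo ranking is an ordering, not an inference; downstream triage
  must choose a cutoff and should report it (the pipeline records it in
  output metadata).
* Exact-match quantification undercounts libraries sequenced with high
  error rates; a mismatch-tolerant mode is a possible extension but is
  deliberately not the default.
* The RRA permutation null conditions on the observed rank pool and gene
  sizes; with very few genes the p-value floor $1/(n_\mathrm{perm}+1)$ is
  coarse.
* `sortscreen_rra()` expects one high and one low gate sample; replicate
  gates should be summed or averaged upstream.
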