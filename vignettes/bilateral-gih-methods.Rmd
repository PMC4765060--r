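---
title: "Methods: bilateral fold-change analysis and gene interaction hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral fold-change analysis and gene interaction hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bigih)
```

## The problem this package addresses

After a unilateral brain injury (for instance a controlled cortical impact
in rat), gene expression changes on *both* sides of the brain: strongly on
the injured (ipsilateral) side and, more subtly, on the mirror-image
(contralateral) side, where a suppression of cell-death genes may reflect
an endogenous protective response. Telling these patterns apart requires
comparing two fold-change datasets gene by gene — ipsilateral vs. naive
and contralateral vs. naive — and then deciding which of the changed genes
matter most. `bigih` implements that workflow end to end:

1. detection calls and fold-change selection per side,
2. the bilateral ratio and the four-way partition of changed genes,
3. assembly of genes of interest (GOI) from pathway and network sources,
4. the gene interaction hierarchy (GIH): degree-based tiering of the GOI
   in an interaction network,
5. enrichment rank comparison between unranked GOI and top-tier genes,
6. delta-delta-Ct qPCR confirmation,

plus a seeded generator that produces synthetic experiments with the same
statistical structure, so every stage is testable without microarrays or a
proprietary interaction knowledge base.

## Detection calls

Probe pairs on 3'-expression arrays carry a perfect-match (PM) and a
mismatch (MM) intensity. The discrimination score
$R = (PM - MM)/(PM + MM)$ lies in $[-1, 1]$ and measures target-specific
signal. A gene's detection p-value is the one-sided exact Wilcoxon
signed-rank test of $H_1: \mathrm{median}(R) > \tau$, and the call is
*present* if $p < \alpha_1$, *marginal* if $\alpha_1 \le p < \alpha_2$,
*absent* otherwise. The defaults $\tau = 0.015$, $\alpha_1 = 0.04$,
$\alpha_2 = 0.06$ follow standard MAS5 practice; all three are
configurable through `analysis_config()`.

Numerically, zeros ($R_i = \tau$) are discarded and tied absolute
deviations receive midranks. The p-value is exact: from the classical
signed-rank distribution when the deviations are tie-free, and by full
enumeration of the $2^n$ sign assignments when ties are present (probe
sets are small, typically 11 pairs, so enumeration is cheap up to
$n = 16$; beyond that a tie-corrected normal approximation with continuity
correction is used). If every score equals $\tau$ the test is degenerate:
$p = 1$, absent, with a warning.

Full MAS5 signal summarization (Tukey biweight, background zones, array
scaling) is out of scope; the pipeline consumes summarized expression
values and, optionally, probe-level PM/MM tables for the detection stage.

## Fold changes and the presence rule

Fold changes are ratios of arithmetic means of replicate intensities —
the simplest deterministic estimator, chosen because spreadsheet-based
analyses of this design do not prescribe another one. They are expressed
in the signed convention: $m_\text{exp}/m_\text{ctrl}$ when at least 1,
otherwise $-(m_\text{ctrl}/m_\text{exp})$, so magnitudes are never inside
$(-1, 1)$ and the sign is the direction. A non-positive group mean is an
error rather than an infinite fold change.

A gene is *changed* on a side when $|fc| \ge 2$ (the cutoff is inclusive:
exactly 2-fold counts) **and** the presence rule holds. The default rule
is a single shared gate: present — strictly the present call, marginal
does not count — in all ipsilateral samples *or* all contralateral
samples. Presence in naive samples is deliberately not required: genes
silenced in controls and induced by injury are exactly the interesting
ones. A stricter `per_side_all` variant is available.

## The bilateral ratio and partition

For genes changed on both sides, the ratio of relative expression is
computed by linearizing each signed fold change onto the positive ratio
scale ($fc \mapsto fc$ if positive, $1/|fc|$ if negative) and re-signing
the quotient:

$$
r = \frac{\mathrm{lin}(fc_I)}{\mathrm{lin}(fc_C)}, \qquad
\text{ratio} = \begin{cases} r & r \ge 1 \\ -1/r & r < 1. \end{cases}
$$

This single rule reproduces the five published piecewise case formulas
(both up with ipsilateral larger; both down, either side more extreme; and
the two opposite-direction cases) exactly on their domains — the test
suite checks this equivalence on random draws from each domain. It also
covers a sixth configuration the five-case list omits (both sides up with
the contralateral change larger), by the same symmetry that defines the
negative-ratio branch of the both-down case; such rows are flagged
`extrapolated` in the output since the published formulas never exercise
them.

Genes are partitioned into `unique_ipsi`, `unique_contra`,
`common_similar` and `common_different`. "Changed differently" is a
strict threshold on the ratio **magnitude**: $|\text{ratio}| > 2$. The
magnitude reading is the only consistent one, because reference tables
include genes with negative ratios (more extreme contralaterally) among
the changed-differently set; exactly $|\text{ratio}| = 2$ stays
`common_similar`. Reported tables round fold changes and ratios to three
decimals; in-memory values keep full precision.

## GOI assembly and overlap accounting

The candidate pool for a side is its unique changed genes plus all
changed-differently genes. Sources — a canonical (apoptosis-signaling)
pathway list first, then interaction-network gene lists in network-ID
order — each contribute their members intersected with that pool. The
accounting for each source records the members found, the overlap with
the *running union* of everything contributed so far (seed first), and
the net new genes. The final GOI set is order-independent; the accounting
columns are not, which is why the source order is part of the interface.
A source gene outside the pool is silently excluded — that is precisely
the "overlapping genes" operation, not an error.

The packaged reference lists (`tbi_goi_sources()`) are the printed
per-network GOI columns, i.e. already pool-intersected, so they are
assembled with `pool = NULL`. Re-running the accounting on them
reproduces the published per-network (total, overlap, net) triples and
the 170 / 115 GOI totals.

## The gene interaction hierarchy

GOI are ranked by their number of direct interaction partners *among the
GOI*: the interaction edge list (user-supplied; two-column TSV or SIF,
undirected, deduplicated, self-loops dropped) is restricted to GOI-GOI
edges, and each gene's distinct-neighbour count is its score. Interaction
type and direction are discarded; first-order neighbourhood is treated as
directionless, and the focal gene is always excluded from its own
neighbour list (the generalization of removing the focal gene from an
exported neighbour list, applied as full self-loop exclusion).

Tier cutoffs are fractions of the *other* genes in the main component
(largest connected component; ties broken toward the component holding
the lexicographically smallest symbol, for deterministic output). With
main-component size $m$:

* primary: connections $> \mathrm{round}_{1/2\uparrow}(0.10\,(m-1))$
* secondary: connections $\ge \lceil 0.05\,(m-1) \rceil$ (up to the
  primary cutoff)
* peripheral: at least one connection below the secondary minimum
* orphan: no connections at all.

The integerization pair — round-half-up for the primary cutoff, ceiling
for the secondary minimum — is the only simple rule consistent with both
published instantiations of the verbal "more than 10% / 5%–10%" rule:
$m = 145$ gives cutoffs (>14, ≥8) and $m = 78$ gives (>8, ≥4), although a
literal "more than 10% of 77 = 7.7" would have read ">7". For very small
main components the ceiling can exceed the rounded primary cutoff; the
secondary minimum is then clamped so the (possibly empty) secondary band
stays well defined. Connected genes outside the main component are tiered
by the same thresholds and flagged `off_main_component` rather than
hidden among the orphans.

Tier membership of the published hierarchies depends on a proprietary
interaction knowledge base, so those tables ship as data
(`tbi_gih()`) and the algorithm is validated instead by properties:
degree counts against brute-force enumeration, threshold reproduction at
both published sizes, and planted-hub recovery on synthetic networks.

## Enrichment and rank shifts

Association between a gene set and an annotation is the right-tailed
Fisher exact probability — the hypergeometric upper tail including the
observed overlap. The default universe is all genes measured on the
platform (user-overridable); a knowledge-base universe of the kind
commercial tools use cannot be reproduced, which is a documented
divergence, and published function rankings are therefore not treated as
recomputable targets. Ties in p are broken by descending overlap and then
alphabetically. No multiple-testing correction is applied by default
(raw Fisher p-values are the reporting convention this pipeline mirrors);
`adjust = "BH"` adds a Benjamini–Hochberg column without changing the
ranking. The seed category from which the genes were originally selected
(e.g. "cell death and survival") can be excluded by name via the
`exclude` argument — a named option rather than hard-coded behaviour.

`rank_shift()` compares two rankings (typically: unranked GOI versus the
top two GIH tiers) with `shift = rank_before - rank_after`, positive when
a function moved up. `cross_reference_tiers()` counts annotated genes per
tier with up/down fractions, mirroring the cell-cycle cross-referencing of
the reference dataset (35 of 42 top-two-tier genes ipsilaterally, 19 of
27 contralaterally).

## qPCR

`delta_delta_ct()` implements the standard Livak computation:
$\Delta Ct = Ct_\text{target} - Ct_\text{reference}$ per well, the naive
mean $\Delta Ct$ as calibrator, and $2^{-\Delta\Delta Ct}$ per
experimental replicate. Each replicate is compared against the naive
*mean* (replicate-vs-mean rather than pairing, the standard choice when no
pairing is stated; with $n = 2$ per group pairing would be arbitrary).
Amplification efficiency is fixed at 2 — no efficiency correction. The
computation is invariant under any constant shift of all Ct values, and
one fewer target cycle exactly doubles the reported expression; both are
enforced as tests. Group comparisons use the one-tailed pooled-variance t
test with $n_a + n_b - 2$ degrees of freedom; zero pooled variance with
equal means degenerates to $p = 0.5$ with a warning.

## The synthetic generator

`sim_params()` encodes the emulated study conditions: 3 replicates in
each of 3 groups; 45% of genes differentially expressed, split 40%
unique-ipsilateral / 15% unique-contralateral / 45% common, with 18% of
common genes changed differently; 88% of unique-ipsilateral changes up
and 75% of unique-contralateral changes down; about 1 in 24
changed-differently genes more extreme contralaterally. Fold-change
magnitudes are log-uniform on $[2, 40]$ — a bounded, heavy-tailed choice
spanning most of the observed range while keeping ratios finite and
testable. Baselines are log-normal around 500 intensity units
(`sdlog = 1`), and replicate noise is multiplicative log-normal with
`noise_sigma = 0.15`, i.e. roughly a 15% coefficient of variation, a
typical replicate CV for summarized 3'-array intensities. Detection
dropout defaults to 0 (every expressed gene called present); planted
changed-similar genes keep their ratio below $0.95 \times$ the cutoff and
changed-different genes above $1.1 \times$, so classes remain
recoverable under noise.

Networks are preferential-attachment graphs over the GOI plus background
genes, with planted hubs given additional within-GOI edges until their
induced degree reaches twice the primary cutoff for a main component
spanning all GOI. Annotations are one focal set whose hub content is
controlled by `hub_enrichment` plus random background sets.

Every generator is deterministic given its seed; a single root seed fans
out to the expression, network and annotation stages with fixed offsets,
so a pipeline run is reproducible from one integer.

What the generator does **not** emulate: probe-sequence effects, spatial
array artifacts, batch effects, correlated gene modules, or the scale-free
degree-and-clustering structure of curated interaction databases. Passing
tests therefore demonstrate algorithmic correctness on data with the
assumed statistical structure, not robustness to real-array pathologies.

One deliberate deviation in the validation design: under no enrichment,
Fisher p-values are discrete and therefore *super-uniform*, so the null
calibration check bounds the exceedance rate
$P(p \le 0.05) \lesssim 0.05$ over seeded runs instead of testing
uniformity with a Kolmogorov–Smirnov statistic, which would reject merely
because of discreteness.

## Problem sizes and runtime choices

The test and acceptance workloads are sized to be exact where exactness
is cheap and statistical where it is not: exhaustive sign-assignment
enumeration up to 12 probe pairs; exhaustive hypergeometric tails up to
universe size 25; brute-force neighbour checks on random graphs of up to
50 nodes; planted-hub recovery over 200 seeded networks of 100 GOI; and
end-to-end recovery on 2000-gene simulations. These sizes give the
property checks enough power (binomial half-width of a few percentage
points) while keeping the whole suite fast on a single CPU.

## Known limitations

* Gene identity is the uppercased symbol; no alias or orthology mapping,
  so composite symbols (e.g. `HSPA1A/HSPA1B`) are single identifiers and
  symbol variants from different annotation eras will not merge.
* The hierarchy is only as meaningful as the supplied edge list; the
  package deliberately ships no interaction database.
* Probe-set-to-gene reconciliation (several probe sets, one symbol) is by
  arithmetic mean, a choice the underlying study designs leave unstated.
* With two replicates per qPCR group, published standard errors and exact
  p-values cannot be recomputed without the underlying Ct values; the
  module is validated by its algebraic invariants instead.
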