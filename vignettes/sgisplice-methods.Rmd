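---
title: "Methods: interaction scoring and junction-level differential splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction scoring and junction-level differential splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgisplice)
```

# Scope

`sgisplice` implements two statistical pipelines used to characterise
genetic interactions among RNA-binding-protein genes in *C. elegans* and
their downstream effects on alternative splicing:

1. **Competitive-fitness interaction scoring.** Marked mutant and
   wild-type worms are co-seeded on a plate; after growth the mutant
   fraction summarises multi-generational competitive fitness. Double
   mutants are scored against a multiplicative null model, and synthetic
   genetic interactions are called by a conservative three-criterion
   procedure.
2. **Junction-level differential alternative splicing.** STAR
   splice-junction count files are mined for junctions that share a splice
   site; relative junction usage is compared between genotypes with exact
   tests, events are classified (cassette exon, alternative 5'/3' splice
   site), usage profiles are clustered, and 7-mer RNA-binding-protein
   cis-elements are tested for enrichment around regulated cassette exons.

Upstream steps — read alignment, gene counting, and differential-expression
calling — are consumed as their standard outputs, not reimplemented.

# The fitness model

A competition plate seeds equal numbers of mutant and wild-type founders,
so in the absence of a fitness defect half the final population is mutant.
**Relative fitness** is the observed mutant fraction over that null
fraction:

$$F = \frac{\text{mutants}/\text{total}}{0.5},$$

e.g. a plate on which 40% of worms are mutant gives $F = 0.8$. Under the
multiplicative null model of genetic interaction, a non-interacting double
mutant has expected fitness $F_{\mathrm{exp}} = F_1 F_2$, and the
**synthetic effect** is

$$\varepsilon = F_{\mathrm{obs}} - F_{\mathrm{exp}}.$$

Negative $\varepsilon$ is aggravating (the double is worse than expected,
down to synthetic lethality at $F_{\mathrm{obs}} = 0$), positive
$\varepsilon$ alleviating.

## The three-criterion call

`call_interaction()` declares a pair significant only if all of:

1. $|\varepsilon| \ge 0.20$ (effect-size threshold);
2. **replication** — at least two biological replicates whose individual
   $\varepsilon$ agrees in sign with the pooled estimate;
3. a two-sided Fisher exact test of the pooled observed
   (mutant, wild-type) counts against the null-expectation counts
   $\bigl(\mathrm{round}(N F_{\mathrm{exp}}/2),\; N -
   \mathrm{round}(N F_{\mathrm{exp}}/2)\bigr)$, Bonferroni-corrected over
   the number of double mutants tested, below $\alpha = 0.01$.

Replicates are pooled by summing counts before computing $F$ and before
the exact test: the procedure tests aggregate counts, and an exact test
needs one integer table. Rounding of the expected counts is nearest-integer
(the null expectation is a continuous quantity; the table must be
integral). A double mutant with zero surviving homozygotes is recorded as
`lethal` and bypasses the exact test — lethality is its own evidence class,
and it counts as an interaction in `interaction_summary()`.

## Why singles are measured deeper than doubles

In an all-against-all screen of $n$ genes, each single-mutant estimate
$\hat F_i$ enters $n - 1$ expected-fitness products, and its error is
shared by every criterion for those pairs (the $\varepsilon$ screen, the
expected-count table, and — because the bias is common to all plates of a
pair — the replication check). The screen design therefore measures the
few singles at twice the pooled depth of any one double:
`competition_scenario()` defaults to six 200-worm plates per single and
three per double. With singles at the doubles' depth, the shared
product-noise alone produces occasional screen-level false calls even
though the per-pair type-I error stays well under 1%.

# The splicing model

STAR's `SJ.out.tab` files give per-intron split-read counts with 1-based
inclusive intron coordinates. Two junctions on a chromosome form an
**alternative pair** when they share exactly one end: a shared start
(donor, on the plus strand) with different ends is an alternative 3'
splice site, a shared end the converse on the plus strand, and the
assignments swap on the minus strand. When $k > 2$ junctions share a site,
all $\binom{k}{2}$ pairs are considered.

**Relative junction usage** for a pair is $u = c_1/(c_1 + c_2)$, with
$j_1$ defined as the junction with the smaller non-shared coordinate so
the direction of $u$ is reproducible. Pairs with fewer than 30 reads
summed over all samples are discarded (boundary inclusive). Only
uniquely-mapping reads are counted; multimappers are ignored, the standard
choice for junction quantification.

Differential usage between genotypes pools replicate counts per genotype
and applies the two-sided Fisher exact test to
$[[c_1^A, c_2^A], [c_1^B, c_2^B]]$, Bonferroni-corrected over the pairs
tested in that comparison, at adjusted $\alpha = 0.05$. Pooling is the
minimal reading of an exact test on counts with three replicates per
genotype; it conditions on total depth and does not model
between-replicate overdispersion (a known limitation, see below).

## Event classification

A pair is a **cassette exon** when its longer (skipping) junction spans an
inclusion chain: some junction shares the skipping junction's start and
ends before another junction sharing its end begins; the enclosed segment
is the cassette exon. This rule needs only the junction table itself.
Pairs failing the chain rule are classified by their shared-site class and
strand as alternative 5'/3' splice sites. Junctions with STAR strand code
0 are retained, classified under plus-strand conventions, and flagged
low-confidence — dropping them silently would bias event counts.

## Clustering

Usage matrices (significant pairs × samples) and expression matrices
(log2 fold change over the gene's mean, pseudocount 1) are clustered with
K-means, $K = 10$ and 1000 restarts by default. `kmeans_cluster()` runs
Lloyd's algorithm from seeded random initialisations (initial centres
sampled from the distinct rows), keeps the restart with minimal
within-cluster sum of squares, and breaks inertia ties by keeping the
first restart — determinism given the seed. Distance is Euclidean on the
supplied matrix with no internal rescaling: inputs are already on
comparable scales ($u \in [0,1]$; log2 ratios). Sub-seeds are drawn once
from the master seed, so the best inertia is non-increasing in the number
of restarts. Cells where a pair has zero reads in one sample are imputed
with the pair's mean usage across the remaining samples so clustering sees
a complete matrix; after the 30-count filter such cells are rare.

# Motif enrichment

The motif analysis takes the most-changed significant cassette events —
top 25 by $|\Delta u|$ with increased inclusion and top 25 with increased
skipping, ties broken by genomic coordinate — and extracts five regions
per event: both flanking exons in full, the cassette exon, and the 250
bases of each flanking intron adjacent to the cassette (the full intron,
flagged, when shorter). Minus-strand events are reverse-complemented so
sequences read 5'→3' on the transcript. The 250-base default covers the
proximal regulatory windows where splicing regulators concentrate and is
configurable.

Enrichment against an equal number of control regions is tested per
region and per direction (increased skipping and increased inclusion
separately, since regulator position encodes outcome) on the
presence/absence 2×2 table with the two-sided Fisher exact test at
$p < 0.05$; the unit is presence per sequence, which is what a 2×2 exact
test implies. Motif hits are exact, overlapping matches of any 7-mer in
the set (published RNA motifs' U mapped to T); no IUPAC wildcards or PWM
scoring. Odds ratios use the Haldane $+0.5$ correction when a cell is
zero.

# Shared statistical primitives

The two-sided Fisher exact p-value is computed from the conditional
hypergeometric distribution: the sum of probabilities of all tables with
the observed margins whose probability does not exceed the observed
table's, with a relative tie tolerance of $10^{-7}$ guarding against
floating-point ties — the convention of standard implementations. The test
suite verifies equality with exhaustive enumeration over every 2×2 table
with $n \le 40$ and with `stats::fisher.test()` on random tables.
Bonferroni adjustment is $\min(1, p \cdot m)$; set overlaps use the
upper-tail hypergeometric probability.

# What the synthetic data emulate — and what they do not

The generators produce every input the pipelines consume, with planted
ground truth:

- `simulate_competition()` collapses the two-generation growth assay into
  a single binomial draw of the final plate fraction,
  $\mathrm{Binomial}(N, F_{\mathrm{true}}/2)$. The inferential target
  uses only the final fraction, so this shortcut preserves it; it does
  not model brood-size dynamics, generation overlap, or plate-to-plate
  environmental variation (real replicates are likely overdispersed
  relative to binomial).
- `simulate_junction_counts()` / `simulate_junction_files()` lay out a
  toy transcriptome — by default 100 cassette trios (alternating strand)
  plus 150 alternative-5' and 150 alternative-3' pairs, i.e. 500 testable
  pairs — and draw inclusion reads per event per sample as
  $\mathrm{Binomial}(\text{depth}, \psi)$ at depth 200 with three
  replicates per genotype. Planted events shift $\psi$ by exactly 0.4
  (25 up, 25 down by default); baselines are uniform on $[0.2, 0.8]$.
  Depth is per event, since the usage statistic conditions on totals; the
  generator does not emulate expression-dependent depth, overdispersion,
  novel junction discovery noise, or mapping artefacts.
- `simulate_toy_genome()` writes a random genome consistent with the
  planted junction coordinates, so region extraction is exact by
  construction.
- `simulate_motif_sequences()` plants a motif once per sequence with a
  group-specific probability on a uniform ACGT background (25 sequences
  of 250 bases per group, probabilities 0.75 vs 0.15 — a five-fold
  contrast — by default). Background hits occur naturally; GC content and
  length matching beyond equal counts are not modelled.

Consequently, passing calibration and power checks on these generators
demonstrates the statistical machinery is correct under idealised
(binomial, independent) noise; it does not demonstrate robustness to the
overdispersion, composition biases, and annotation errors of real
sequencing data.

# Problem sizes used by the test suite

The packaged checks run the screens at the design scale: 100 seeded
13-gene screens (78 doubles at 600 pooled worms each) for exact recovery
of three planted $\varepsilon = -0.4$ interactions plus 1000 null pairs
for the type-I rate; 200 null splicing datasets of 500 pairs for
family-wise calibration and 10 seeded datasets for power and
classification; 200 null and 50 contrast simulations for motif
calibration and power; exhaustive Fisher verification over all 135,750
tables with $n \le 40$.

# Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon_threshold` | 0.20 | minimum \|synthetic effect\| (dimensionless fitness units) |
| `alpha_fitness` | 0.01 | Bonferroni-adjusted threshold, interaction screen |
| `null_fraction` | 0.5 | expected mutant plate fraction under equal fitness |
| `min_total` | 30 | junction-pair count filter, summed over all samples |
| `alpha_splicing` | 0.05 | Bonferroni-adjusted threshold, differential usage |
| `kmeans_k`, `kmeans_runs` | 10, 1000 | heatmap clustering |
| `n_each` | 25 | top events per direction for motif analysis |
| `intron_flank` | 250 nt | proximal intron window adjacent to the cassette exon |
| `alpha_motif` | 0.05 | motif enrichment threshold |

# Known limitations

- Pooling replicates before the exact tests ignores biological
  overdispersion in both pipelines; with three replicates an exact test
  is the pragmatic choice, but p-values on real data are anti-conservative
  to the extent replicates disagree.
- Bonferroni control is deliberately conservative; no FDR alternative is
  offered because the procedures are defined around family-wise control.
- Event classification covers cassette exons and alternative splice
  sites; intron retention, mutually exclusive exons and complex events
  fall into the splice-site classes or `other`.
- Motif matching is literal 7-mers; degenerate motifs require expanding
  the input list.
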