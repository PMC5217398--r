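---
title: "Methods: SAGE-style DGE tag profiling with dgetag"
author: "dgetag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAGE-style DGE tag profiling with dgetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

# The measurement model

NlaIII/MmeI DGE tag profiling reduces each transcript to a 21 nt tag:
NlaIII cuts double-stranded cDNA at every CATG, the 3'-most restriction
fragment is retained on oligo(dT) beads, and MmeI releases the CATG
anchor plus the 17 nt immediately downstream. Sequencing the resulting
library yields reads whose multiplicity is proportional to transcript
abundance. Two consequences shape the whole analysis:

1. **The reference is a tag library, not a genome.** Identification works
   by exact string comparison of 21-mers against all possible CATG + 17 nt
   windows of an oriented transcript set (`buildTagIndex`). Every CATG
   occurrence with at least 17 downstream nucleotides is indexed —
   including overlapping sites — because a single mismatch search must see
   every window a read could have come from. Sites whose window contains
   an N are skipped (conservative: an uncertain reference base cannot
   anchor identification). Only the sense strand is scanned by default;
   unigene-style references are oriented transcripts and the chemistry
   reads the mRNA 3' end. `antisense = TRUE` adds the reverse complement
   for unoriented references.

2. **Counts are closed-sum.** A library's clean-tag total is the natural
   denominator, so expression is normalized to TPM = count / total × 10⁶
   (tags per million clean tags — a library-size normalization, not the
   modern length-aware metric), and two libraries are compared by an
   exact conditional test rather than a dispersion model.

# Tag cleaning

`cleanTags` applies five filters, in order, each read charged to exactly
one class so that raw total = clean + Σ removed holds exactly on every
input:

| class | rule |
| --- | --- |
| adaptor | the 3' adaptor's leading k-mer (k = 8 by default) occurs at position > 1: tag followed by adaptor |
| empty | the adaptor k-mer starts the read: adaptor only, no tag |
| low-quality | any ambiguous base call (N) |
| length | read length ≠ 21 nt |
| singleton | library copy number < 2, applied after exact-sequence aggregation |

The adaptor rule is configuration, not biology: DGE protocols differ in
adaptor sequence, and k-mer substring matching (rather than alignment) is
what fixed-length tag pipelines use. Position 1 versus position > 1
distinguishes "adaptor only" from "tag + adaptor" deterministically, which
keeps the two classes mutually exclusive. The copy ≥ 2 filter is applied
per library, before mapping: single-copy tags are dominated by
sequencing errors (a 0.5 % per-base error rate turns ~10 % of reads into
near-singleton error variants) and removing them is part of the assay's
standard definition of a "clean tag".

`copyNumberDistribution` reports each copy-number bin's share of the
total clean tags, and `saturationCurve` subsamples the clean multiset
without replacement on a shared permutation — nested prefixes — so each
curve is monotone by construction and the per-step new-gene rate is
well-defined.

# Tag-to-gene resolution

`resolveTags` implements a two-level policy:

- **Perfect first.** A verbatim index hit governs; 1-mismatch neighbours
  are then ignored entirely. This makes resolution a pure function of tag
  and index, and adding neighbours can never change a perfect call.
- **One mismatch, variable region only.** The CATG anchor must match
  exactly — the restriction site defines the read, and the biological
  rationale for tolerating one mismatch (SNPs between cultivars) applies
  to the transcribed 17-mer. A query therefore has exactly 51 candidate
  neighbours.
- **Ambiguity removes.** At the governing level, a tag resolves only if
  exactly one gene is hit; otherwise its whole count is discarded as
  ambiguous. No fractional allocation — with single-gene credit the
  accounting identity unmapped + ambiguous + unambiguous = clean total is
  exact, and it is asserted inside `mapLibrary` on every run.

Mapping percentages use total clean tags as denominator, and "genes
detected" means genes with ≥ 1 unambiguous tag, matching the conventional
library-statistics table that `mappingStatsTable` reproduces.

# The exact test

For a gene with counts $x, y$ in libraries of clean totals $N_1, N_2$,
the Audic–Claverie conditional law of the second count given the first is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial-shaped distribution with mean $(x+1)N_2/N_1$. All
terms are evaluated in log space with `lgamma`, so overflow cannot occur
at any realistic count or total; upper tails are summed outward in
chunks until the increment falls below machine precision, which past the
mode converges geometrically.

**Two-sided construction.** The p-value is min(1, 2 × smaller tail), the
observed count included in its tail. The deficit-side tail is computed
as the excess tail of the exchanged pair $(y, N_2; x, N_1)$: by the exact
negative-binomial/binomial tail duality, the two tails so defined are
precisely the two tails of $y \mid x+y \sim \mathrm{Binom}(x+y,
N_2/(N_1+N_2))$, which makes the p-value *exactly* invariant under
exchanging the two libraries — a property the test suite asserts to
machine precision, together with term-by-term oracle agreement below
$10^{-9}$ over the full $(x,y) \in [0,50]^2$ grid. A naive "sum
$p(k\mid x)$ for $k \le y$" deficit tail would correspond to a binomial
tail at $x+y+1$ trials and break that symmetry; we chose the symmetric
construction.

**Calibration.** Because the test is discrete and the observed point is
included, it is slightly conservative: under 20 seeded null simulations
(2,000 genes, two libraries of 2×10⁵ clean tags, gamma-distributed
abundances), the fraction of tested genes with two-sided p < 0.05 is
≈ 0.041–0.045 — within three per-simulation binomial standard errors of
the nominal 0.05, but systematically below it. This is a property of any
exact discrete two-sided test at these counts, not an implementation
artifact; the practical consequence is mildly conservative FDR control.

**Calling.** Genes with $x + y = 0$ are untestable and are excluded from
both the test and the Benjamini–Hochberg family (including them would
dilute the adjustment with p = 1 entries). BH is used for the FDR step —
the standard choice for this design — and the default thresholds are
FDR < 0.001 with |log₂ ratio| ≥ 1. The log₂ ratio is computed on TPM;
whether the original tag pipelines used TPM or raw counts is ambiguous
(the two coincide at equal totals), and TPM is the scale on which the
threshold is interpretable across libraries. When one count is zero, that
side only is floored at `zeroFloor = 0.5` tags for the ratio — the
p-value always uses the raw integers, so the floor affects reporting and
the threshold, never significance.

`vennDecompose` partitions the DE union of two contrasts (0.5 h and 24 h
stress against the same control, in the demo layout) into eight disjoint
classes: common direction, direction reversal, and each duration-only
class. `ddctFoldChange` provides the 2^-ΔΔCt helper used when validating
tag-based calls by qRT-PCR.

# GO enrichment

`goEnrich` computes the upper hypergeometric tail per term via `phyper`
and flags terms under the dual threshold p < 0.01 and FDR < 0.05 (BH,
within one namespace when one is supplied). The background universe
defaults to the full tag-mapped reference gene set — the closest
available analogue of a "genome background" for a tag assay — and is an
explicit argument, so the tested-gene universe can be substituted.
Annotations are taken as given; no GO-graph ancestor closure is applied
by default because annotation sets differ in whether they are already
closed, but `propagateAnnotations` closes over a supplied child→parent
table when needed.

# The simulator and what it does (not) emulate

The generator exists so that every downstream stage has known truth:

- `generateTranscriptome` draws uniform-random sequences (lengths
  200–1200 nt by default, the EST-like range) and guarantees every gene
  one valid CATG site, planting one only where none arose by chance.
- `makeDEScenario` draws baseline abundances from a gamma distribution
  with shape 2 — right-skewed, with a dynamic range of a few hundred
  between typical low- and high-expressed genes, a reasonable stand-in
  for bulk transcript abundance — and plants a fraction of genes
  (default 10 %) at a fixed |log₂FC| (default 2), split evenly up/down,
  renormalizing both condition vectors.
- `simulateTagLibrary` draws each informative read's gene multinomially,
  emits the gene's 3'-most tag (the fragment the bead chemistry keeps),
  and passes it through per-base substitution errors
  (Binomial(21, rate) errors per read). Junk reads are injected at the
  profile's fractions as mutually exclusive classes in a fixed priority
  order (adaptor > empty > length > ambiguous-base), which makes the
  filter accounting exactly predictable. Defaults — 0.5 % per-base
  error, 2 % adaptor, 1 % each empty/length/N — are typical magnitudes
  for Illumina-era tag libraries. An optional `leakySiteRate` emits
  non-3'-most tags of multi-site genes, creating realistic multi-site and
  ambiguous-tag cases; its default is 0 because the rate of such reads in
  real libraries is not established.

Not modelled: base-quality scores (beyond N presence), PCR duplication,
adaptor sequencing errors, positional error profiles, and any biological
correlation structure between genes (counts are multinomial given
abundance). Passing tests therefore demonstrate correctness of the
algorithms and calibration of the statistics under idealized sampling —
not robustness to artifacts a real sequencer would add.

All stochastic operations take explicit integer seeds; the pipeline
derives per-stage seeds from one master seed, and identical seeds
reproduce byte-identical artifacts (asserted in the suite by hashing two
complete demo runs).

# Numerical and problem-size choices

- The exact-test oracle comparisons run over the full $[0,50]^2$ count
  grid at totals $(10^5, 10^5)$ and $(10^5, 2\times10^5)$; tail sums are
  compared at $10^{-9}$, normalization of $p(\cdot\mid x)$ at $10^{-9}$.
- Calibration and recovery simulations use 2,000 genes and libraries of
  2×10⁵ clean tags, 20 seeds each — large enough for ±0.005 precision on
  the null rejection rate and stable sensitivity estimates, small enough
  to run in seconds. Sensitivity is reported over planted genes with
  baseline TPM ≥ 100: below that, a four-fold *decrease* carries too few
  counts for any exact test at this depth, so including unexpressed genes
  would measure depth, not method.
- Hypergeometric p-values are validated against exhaustive subset
  enumeration on universes of N ≤ 30 (at $10^{-12}$) and the tail
  complement identity is checked in exact integer arithmetic (all
  binomial coefficients involved are < 2⁵³, so double-precision integer
  arithmetic is exact).
- The demo pipeline uses 200 genes × 6 libraries × 20,000 reads: every
  artifact of the full design (two genotypes, three time points, four
  contrasts, two Venn decompositions) at interactive runtime.

# Known limitations

- One library per condition: the Audic–Claverie test models sampling
  noise only. Biological replication would require a dispersion-aware
  model, which is out of scope by design.
- Tag-level identification cannot distinguish transcripts sharing their
  3'-most CATG + 17 nt window; such genes are systematically ambiguous
  and invisible to the pipeline, exactly as in the original assay.
- The 1-mismatch policy resolves each tag independently; a tag whose
  true origin lost its sequenced copy to an error can be credited via a
  neighbour even when another gene's perfect tag exists elsewhere in the
  library. Per-tag independence is the documented contract.
- `saturationCurve` treats the clean library as the population; it
  measures within-library saturation, not how many genes a deeper
  sequencing run would find.
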