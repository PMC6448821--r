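---
title: "Mapping a dominant trait to a gene-conversion chimera: models and design choices"
author: "tractScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant trait to a gene-conversion chimera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractScan)
```

## The scientific problem

A lager-brewing-relevant yeast (*Saccharomyces eubayanus*) that cannot
import maltotriose can evolve that ability de novo. The genetic route is
striking: an ectopic gene conversion copies a short tract (~230 bp) from
one maltose-transporter paralog (*MALT3*-like, the donor) into another
(*MALT4*-like, the recipient), producing a chimeric allele that encodes a
functional maltotriose transporter. Establishing this involves four
analyses that this package implements as reusable, testable components:

1. **Tetrad segregation analysis.** Sporulating the backcrossed
   heterozygote and phenotyping tetrads tests whether the trait is a
   dominant single locus: every fully viable tetrad should segregate 2:2.
2. **Bulk-segregant analysis (BSA).** Segregant spores are pooled by
   phenotype and sequenced; genomic windows in which allele frequencies
   are at opposite fixation between pools contain candidate loci.
3. **Chimera detection.** Within the candidate gene, informative sites
   (positions where two paralogs differ) are assigned to one parent or the
   other; a run of donor-supporting sites delimits the conversion tract,
   whose substitutions are then classified codon by codon.
4. **Division budget.** The serial-passaging regime of the evolution
   experiment implies a number of cell divisions during which the
   conversion could arise; the budget is simple arithmetic over passages,
   interval length, division rate and lineage count.

A fifth component, the synthetic-data generator, produces every input the
other four consume, together with ground truth, so that each stage can be
validated by parameter recovery rather than by fixtures copied from any
particular dataset.

## Sequence primitives

**Global alignment.** Pairwise global (Needleman–Wunsch) alignment with
match +1, mismatch −1 and a linear gap score of −2 per column. The dynamic
programming is delegated to `Biostrings::pairwiseAlignment()` with a
custom substitution matrix in which `N` never scores as a match (not even
against another `N`); test suites verify the scores against an independent
dynamic-programming oracle. Output is deterministic for a given input and
scoring scheme.

**Percent identity.** Two conventions coexist in the field, so both are
implemented and the choice is explicit in the API. `percentIdentity()`
defaults to the common p-identity convention: columns gapped in either row
are excluded from the denominator. Inside sliding windows
(`slidingIdentity()`) the default flips: gap columns count as mismatches,
so that indel-rich windows score low rather than silently dropping out of
the track. Window width defaults to 10 bp with step 1; positions are
reported at the window's centre column, 1-based. Windows in which more
than half the columns involve `N` are masked to `NA`.

**Codon-level operations.** `translateCds()` applies the standard genetic
code (`N`-containing codons become `X`; terminal stops are removed and
flagged; internal stops warn). `codonAlign()` back-translates a protein
alignment through the source CDSs, expanding residues to codons and gaps
to `---`, and refuses inconsistent protein/CDS pairs naming the offending
residue. `classifyCodonChange()` labels a codon pair `none`,
`synonymous`, `nonsynonymous` (single-position changes, by amino-acid
comparison), `multi_hit` (two or more positions) or `stop` (either codon
is a stop); the classification is tested exhaustively against a
translate-and-compare oracle over all single-position sense-codon pairs.

## Chimera detection model

The detector is deliberately a **run-based parsimony segmentation**, not a
hidden Markov model. The evidence for a conversion event of this kind is a
single clean cluster of donor-matching sites (tens of SNPs in a couple of
hundred base pairs); the simplest model that distinguishes conversion from
recurrent point mutation is a minimum run length of donor-supporting
informative sites, `minRun = 3` by default. Isolated donor-matching sites
below the threshold are reported separately as point conversions or
homoplasy, never silently merged.

The three-way register between candidate and two parents is
candidate-anchored: each parent is globally aligned to the candidate and
projected onto the candidate's ungapped coordinates. Positions whose
projection is gapped in any row, or that involve `N`, are skipped and
tallied. Register projections use a stiffer gap score (−8) than the
default alignment: the paralogous CDSs compared here are expected to be
co-linear, and under a mild penalty the optimal alignment of sequences
diverged by ~20% occasionally introduces a micro-indel detour that
converts a few mismatches and corrupts the register; a detour must rescue
at least eight mismatches to pay off at −8.

Because the conversion boundary between two flanking informative sites is
unobservable, every tract is reported with **two spans**: the *minimal*
span from the first to the last donor-supporting site, and the *maximal*
span extending to just inside the nearest flanking recipient-supporting
sites (or the gene ends). The true breakpoints lie between them.

`scanGeneFamily()` evaluates every ordered (recipient, donor) pair in the
panel and ranks them by

1. fewest informative sites explained by neither parent (residual), then
2. fewest tracts, then
3. smallest total donor-attributed span, then
4. lexicographic identifiers.

Key 3 is a parsimony rule the scan needs for tracts touching a gene end:
there the recipient and donor roles are otherwise symmetric (both orders
give one tract and zero residual), and the pair attributing the *smaller*
segment to the donor is the biologically sensible reading. Any tie
surviving keys 1–3 sets a `tie` flag on the report.

Tract statistics count per-site SNPs between candidate and recipient
within the maximal span, then classify affected codons. Multi-hit codons
are classified once by their net amino-acid effect, so the per-site SNP
tally and the per-codon synonymous/nonsynonymous tallies remain separate
quantities, as they are in practice when a conversion tract introduces
several clustered substitutions per codon. Codon pairs involving a stop
count as nonsynonymous.

## Bulk-segregant scan

Input is per-site allele counts for two phenotype pools — the minimal
sufficient statistic for this scan; read alignment and assembly are out of
scope. A site is called a **fixed difference** when the alternative-allele
frequencies lie at opposite near-fixation extremes (`freqPos >= 0.95` and
`freqNeg <= 0.05`, or the reverse) with both pools at depth ≥ 10. Strict
1/0 fixation is deliberately not required: with pools of 30 segregants at
~100× depth, sequencing error (~0.5%) and a single mis-phenotyped
segregant (1/30 ≈ 3.3%) both stay inside the 5% tolerance, while any
unlinked marker sits near 50% in both pools and cannot approach the
thresholds. All three values are exposed as arguments and CLI flags, and
raising `fixHi` (or lowering `fixLo`) can only shrink the fixed set — a
monotonicity property under test.

Candidate reporting tiles each contig with non-overlapping 1-kb windows
(`GenomicRanges::tileGenome()`); windows with at least one fixed call are
reported, and adjacent candidates are merged into regions in a companion
report so a locus straddling a tile boundary is one region.

Regions where closely related paralogs collapse onto a single reference
locus produce spurious "fixed" differences. `flagArtifacts()` proxies this
with depth: a window whose mean site depth exceeds 1.8× the genome median
is flagged (approaching the 2× expected when two copies map to one
place). Flagging only annotates — no window is removed — since depth
inflation is evidence, not proof, of a mapping artifact.

## Tetrad analysis and the division budget

`segregationAnalysis()` tallies segregation patterns over fully viable
tetrads, tests pooled spore counts against 1:1 with the exact two-sided
binomial test (minimum-likelihood convention: summing all outcome
probabilities no larger than the observed one — the convention of
`stats::binom.test`, stated here because two-sided conventions differ),
and judges consistency with a dominant single locus. Occasional deviant
tetrads — gene conversion at the locus itself can produce 3:1 — are
tolerated up to a configurable 10% of tetrads before consistency is
rejected; uniform 2:2 is of course consistent, uniform 4:0 is not.

`estimateDivisions()` multiplies passages × mean passage interval ×
divisions/day × lineages. The passage interval is a 3–4 day range averaged
at its midpoint (3.5 days, configurable); the division rate defaults to
one per day, appropriate for strains that cannot consume the primary
carbon source and grow only on the glucose supplement. Both the exact
value and a nearest-10 rounding are reported, since published budgets of
this kind are conventionally rounded.

## What the simulator emulates — and what it does not

`makeScenario()` generates, per seed: a four-member paralog family
(1848-bp CDSs, ~616 codons — MFS sugar-transporter scale — at 80%
pairwise nucleotide identity), one conversion tract of 230 bp at a random
position between a random recipient/donor pair, 15 backcross tetrads with
2:2 causal segregation and independently assorting markers, and pooled
allele counts over 200 segregating sites on a 100-kb genome at 100× depth
with 0.5% error. These defaults are the conditions the analyses are
validated under; each is overridable through `config`.

The family generator diverges genes from a common random ancestor by
codon-aware point mutation: proposed changes that create a stop codon are
rejected (so amino-acid identity tracks nucleotide identity, as in real
transporter families), with a transition/transversion ratio of 2. A
greedy controller always mutates the pair currently farthest above its
target identity — choosing the member whose other pairs have the most
slack — until every realized pairwise identity is within ±2 percentage
points of target; at short CDS lengths, where a single mutation moves
identity by 100/L points, the controller restarts from a fresh ancestor
(still a pure function of the seed) rather than accept an out-of-band
family, and reports inconsistent target matrices as configuration errors.

Deliberate simplifications, which bound what passing tests can show about
real data:

* **No indels** within the family, so candidate and parents share a
  coordinate system exactly. Real paralogs can differ by indels; the scan
  tolerates them through alignment projection, but tract recovery rates
  are only certified for the co-linear case.
* **Counts, not reads.** Pooled sequencing is simulated at the
  allele-count level (depth Poisson around the mean; alternative reads
  binomial with error-convolved success probability). Mapping bias, index
  hopping and reference bias are not modelled; the collapsed-duplicate
  depth artifact is emulated only as a depth multiplier.
* **Full penetrance, no linkage.** Phenotype equals causal genotype, and
  non-causal markers assort independently (free recombination). Real
  linkage would spread fixation over neighbouring windows, which the
  region-merging report is designed to absorb, but power under partial
  penetrance is not certified.
* **One conversion event.** Multiple or nested tracts are representable
  in the output (a list of tracts) but the generator plants exactly one.

## Numerical and interface conventions

* Coordinates are 1-based inclusive throughout the package, the
  R/Bioconductor convention; the BED writer converts to the format's
  0-based half-open convention (window 1001–2000 → `1000 2000`), and
  every output file states its convention in a header comment.
* All simulators route randomness through an internal seed scope that
  restores the caller's RNG state: generated datasets are pure functions
  of `(config, seed)`, and scenario files are byte-reproducible, which
  the test suite asserts at the file level and through the command line.
* Ties anywhere (parental-pair ranking, identical panel members) resolve
  deterministically and are flagged rather than hidden.
* Degenerate inputs fail loudly: empty sequences, windows longer than the
  alignment, zero comparable columns, tetrads without four spores, pool
  tables with unsorted positions, out-of-bounds tracts.

## Validation sizes

The acceptance suite (`scripts/acceptance.R` and the corresponding
tests) recomputes: the analytic cross quantities (30 + 30 segregants and
60 spores from 15 tetrads; division budgets of 1050 and 2100 for three-
and six-lineage regimes); chimera parameter recovery and SNP-count oracle
agreement over 200 seeded scenarios at the default study conditions; and
BSA detection power plus null false-positive rate over 100 causal and 100
null pooled-sequencing replicates. These problem sizes give binomial
standard errors of ~1.5% on the recovery rates while keeping the whole
validation run to a few minutes on one CPU.

## Known limitations

* The scan assumes the candidate is explained by **one** recipient
  backbone; mosaic genes with two donors would surface as residual
  unexplained sites rather than a second donor assignment.
* Maximal spans are honest but wide at low informative-site density; with
  parents more than ~95% identical, a 230-bp tract may contain too few
  informative sites to pass `minRun`, and sensitivity decays — by design,
  since the same data could not support a conversion call.
* The fixed-difference criterion targets fully penetrant, near-clonal
  pools. Quantitative traits need allele-frequency-difference or
  G-statistic scans, which are out of scope here.
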