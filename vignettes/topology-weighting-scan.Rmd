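---
title: "Topology-weighting scans for shared ancestry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-weighting scans for shared ancestry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryscan)
```

## The problem and the model

Mimetic wing patterns recur across *Heliconius* species and races.
When two non-sister taxa share a pattern because they share the causal
allele — by introgression or by sorting of an ancestral polymorphism —
the genealogy at the causal locus groups them together even though the
genome-wide signal follows the species tree. This package turns that
observation into a scan: find the narrow intervals where local
genealogies place a chosen comimetic pair together while the rest of
the taxa keep their species relationships.

A scan compares **six taxon groups**: the two focal comimics plus four
reference groups. Each window of 100 SNPs (sliding by 25) gets an
unrooted tree with one tip per individual. The tree is summarized by
its **topology weighting**: every combination of one tip per group
induces one of the $(2k-5)!! = 105$ unrooted six-leaf topologies, and
the weight of a topology is the fraction of combinations inducing it.
Weights are non-negative and sum to one, so they behave like a
distribution over genealogy shapes within the window.

Of the 105 topologies, exactly **five** are diagnostic of shared
ancestry for a given comparison: those in which the focal pair is a
cherry and the induced topology on the four reference groups equals
the species tree. The five arise constructively — the pair-cherry can
attach to each of the five edges of the four-taxon species tree — and
`shared_ancestry_set()` builds them that way; the test suite verifies
the construction against a brute-force predicate filter over the full
enumeration. The per-window scan statistic is the sum of those five
weights: 0 when no subtree supports shared ancestry, 1 when every
subtree does.

### Assumptions

* The signal of interest is *local genealogy shape*; branch lengths are
  used only to build topologies, never interpreted.
* Groups are the unit of analysis. Within-group structure (e.g. a
  single migrant individual) dilutes a window's weighting rather than
  flipping it, which is exactly the behavior wanted for detecting
  partial sweeps of introgressed haplotypes.
* Sites are informative jointly, not singly: 100-SNP windows trade
  genomic resolution (~ the window span) for stable trees.

## Pipeline and parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| min depth | 5 reads | `mask_low_quality()` | calls below are unreliable; strict `<` so DP = 5 survives |
| min GQ | 20 (phred) | `mask_low_quality()` | same rule, strict `<` |
| minor-allele count | ≥ 2 copies | `filter_mac()` | removes singletons/monomorphic sites that carry no grouping signal |
| site missingness | ≤ 10% | `filter_missingness()` | keeps window trees comparable across samples |
| window size / step | 100 / 25 SNPs | `make_windows()` | only full windows get trees; trailing partial windows are dropped |
| per-sample window minimum | 30 non-missing SNPs | `window_passes()` | a tip with fewer calls contributes noise tips |
| sampling CI | Wilson, 95%, full width < 0.05 | `weight_sampled()` | stopping rule for iterative subtree sampling |
| exact-mode ceiling | 10⁵ combinations | `topology_weights()` | full enumeration whenever feasible |
| peak threshold | 1.0 (API), 0.95 (recommended with sampled weights) | `call_peaks()` | see "Numerical choices" |
| diagnostic-SNP missingness | ≤ 20% of contrast samples | `diagnostic_fixed_snps()` | fixed differences tolerate more missingness than tree building |
| cluster gap | 5 kb | `cluster_snps()` | the scale of observed diagnostic-SNP clusters near regulatory elements |

The minor-allele rule is implemented as a **count** (< 2 observed
copies) rather than a frequency recomputed over non-missing samples:
the intended cutoff is two copies in the fixed study panel, and a
count stays well-defined at sites with missing calls.

Two readings of the per-window sufficiency rule are possible — 30
non-missing genotypes per sample, or 30 segregating sites per sample.
The package uses non-missing calls per tip, the most literal reading;
users with data close to the threshold should be aware of the choice.

For the diagnostic scan, the missingness denominator is the samples of
the two contrast groups (after exclusions), not the full panel:
taxa excluded for known independent origins of a phenotype should not
count toward a site's missingness. Required-presence taxa are a data
statement, not logic — e.g. taxa that alone separate two confounded
phenotypes must be observed at every qualifying site.

## From diploid calls to tips

The analysis needs one sequence per individual, and nothing downstream
uses phase. Rather than IUPAC codes (which no distance function
handles well) or statistical phasing (unavailable for many panels),
heterozygous calls are resolved by a fair coin — **pseudo-
haploidization**. The coin for cell $(i, j)$ is derived from
`(seed, site index, sample index)` through a multiplicative hash
modulo $2^{31}-1$, so the resolution of any one cell is independent of
processing order: permuting samples or re-running the same matrix
reproduces the identical tip sequences. A two-tips-per-sample mode is
a possible extension; it would double tip counts and weight
within-individual allele combinations, which the current groups-of-
samples design does not need.

## Numerical choices

* **Tree builder.** Windows get neighbor-joining trees on Hamming-
  proportion distances with pairwise-complete site handling and no
  substitution-model correction — distances only feed a topology, and
  at within-clade divergences (< a few %) model corrections are
  monotone and cannot change the NJ ordering materially. Negative NJ
  branch estimates are clamped to 0. Externally built maximum-
  likelihood trees can be supplied per window (`read_newick_stream()`),
  which rejects polytomies and tip-set mismatches. A window in which
  some tip pair shares no observed site is degenerate; it is skipped
  and logged rather than guessed at.
* **Canonical topology identity.** A topology is stored as its set of
  nontrivial bipartitions, each encoded as a bitmask over the sorted
  group labels, canonicalized to the side excluding the first label.
  A bipartition set determines an unrooted tree uniquely, so the
  serialized set is a perfect identity key, it is invariant to tip
  order by construction, and it is the same representation the
  weighting engine uses per combination — one code path, tested
  against an independent graph-isomorphism oracle (Robinson–Foulds
  distance on reconstructed trees).
* **Wilson stopping rule.** The sampling mode stops when the 95%
  Wilson score interval around every topology's weight has full width
  below 0.05. The Wilson interval is the right choice here because
  windows near fixation are the interesting ones: at $\hat p \in
  \{0, 1\}$ the Wald interval collapses to zero width and would stop
  after a single draw, while the Wilson width at $n = 100$ is ≈ 0.037
  — small enough to stop a monophyletic window after one 100-draw
  batch, large enough to keep sampling anything ambiguous.
* **Peak threshold.** A strict threshold of 1.0 on smoothed values is
  exact only with exact weightings; sampled weightings fluctuate below
  1 even at true fixation. Both thresholds are exposed; 0.95 is the
  recommended operating point with sampled weights, and 0.9 is used in
  the recovery experiments, where smoothing across four overlapping
  windows already suppresses isolated background windows.
* **Smoothing at edges.** Regions near scaffold ends covered by fewer
  than four windows are averaged over the windows that exist — no
  padding, no shrinkage toward 0.
* **Element boundaries.** Peaks and elements are reported from the
  genomic positions of the bounding SNPs of their contributing
  regions, 1-based inclusive; BED export converts to 0-based
  half-open. Where published prior intervals exist, elements are
  clipped to them, and co-located signals separated by a dip arrive
  pre-split from `call_peaks()` — delimitation never re-merges across
  a gap.

## The simulator: what it emulates, what it does not

`simulate_introgression()` generates data with the structure the scan
assumes, plus ground truth. The genome is `n_blocks` blocks of
`block_snps` candidate sites (1 bp apart; geometry is irrelevant to a
SNP-index scan). Each block draws one genealogy over the six groups:
the species topology with probability $1 - \mathtt{ils\_rate}$,
otherwise uniform over the 104 alternatives — a direct stand-in for
incomplete lineage sorting. Inside an implanted tract the genealogy is
forced to the donor–recipient cherry with all other groups in species
position, i.e. a topology from the comparison's target set.

Mutations follow the genealogy: each of the nine branches of the
six-group topology receives Poisson(`branch_scale`) mutations, each at
a fresh site (infinite sites within a block), shared by all haplotypes
of the groups on one side of that branch. Within-group variation and
heterozygosity come from Poisson(`hap_scale`) private mutations per
haplotype; diploids pair two independently simulated haplotypes.
Missingness and sub-threshold read depths are injected at configured
rates so the filter cascade has work to do.

Defaults are the scan's study conditions: six groups × 3 diploid
samples, 200 blocks × 100 slots, `ils_rate` 0.2, `branch_scale` 3
(≈ 27 segregating sites per block, verified by a Poisson moment test),
`hap_scale` 0.5, 2% missingness, 2% low-DP calls, and an 8-block tract
— roughly 800 bp, matching the sub-kilobase-to-few-kb elements the
scan is meant to resolve. Block-wise genealogy sampling replaces a
full coalescent-with-recombination deliberately: the scan consumes
only local genealogy structure, and blocks give exact truth labels for
scoring. What the simulator does **not** emulate: recombination within
blocks and tract-boundary decay, mutation-rate heterogeneity, realistic
allele-frequency spectra, selection, and linkage beyond the block —
so passing recovery tests demonstrates the pipeline's logic and
resolution, not its power on any particular empirical dataset.

Branch lengths are fixed per configuration rather than drawn
exponentially, keeping the signal-to-noise of an experiment
interpretable; randomness enters through Poisson mutation counts.

## Problem sizes and determinism

The bundled experiments use 200-block genomes (≈ 9,000 simulated SNPs,
≈ 4,500 after filtering, ≈ 170 windows of 729 combinations each),
which one scan completes in a few seconds; recovery and null-control
runs repeat this over five seeds each. Every stochastic step — the
simulator, pseudo-haploidization, subtree sampling — takes an explicit
integer seed, and the same seed reproduces byte-identical VCF output
and identical scan results.

## Known limitations

* Six groups are assumed throughout the scan layer (the weighting
  engine itself is generic in $k$, but target sets are defined for the
  six-taxon design; enumeration beyond $k = 8$ is impractical).
* The NJ substitute for maximum-likelihood trees is adequate for
  grouping signal but not for branch-length-sensitive analyses; use
  the newick-ingest path when window trees matter beyond topology.
* Peaks are descriptive, not tested: the weighting is a summary
  statistic and the package deliberately attaches no p-values.
* One tip per individual discards within-individual phase information;
  recent admixture with heterozygous tract carriers halves the
  apparent signal rather than revealing two haplotypes.
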