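---
title: "Methods: surveying a chimeric mitochondrial CMS locus"
author: "chimeraCMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying a chimeric mitochondrial CMS locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraCMS)
```

## The scientific setting

Gametophytic cytoplasmic male sterility (CMS) in rice is caused by chimeric
mitochondrial open reading frames of the *orfH79* family. The locus analysed
here has a fixed four-part architecture: a duplicated copy of the
mitochondrial *atp6* gene (**B-atp6**, 619 bp), a conserved 52-bp
**downstream segment (DS)** ending in `GGGGGCGGGACAAA`, a highly **variable
spacer (VS**, 176 bp) carrying indels and many SNPs, and the ORF itself and
its sequence variants (**GSV**, ~214--240 bp), whose first 34 bases are
identical to part of the COXII gene. The 5' start of the conserved region
(`GGGCGGGGG`) and a motif near the 3' end of DS (`GGGGGCGGG`) form a
*mirror repeat* -- one is the character reversal of the other, like
123456789 / 987654321 -- a signature of the putative chimeric junctions.

In a survey of wild-rice (*Oryza rufipogon*) populations, the locus is
amplified per individual; carriers are sequenced and collapsed into
haplotypes; the architecture of each haplotype is annotated; ORF haplotypes
are translated into protein haplotypes; genetic structure is quantified by
a hierarchical analysis of molecular variance (AMOVA) with permutation
tests; and relationships among haplotypes are estimated by maximum
likelihood under the HKY85 substitution model. This package implements
that pipeline end to end, together with a synthetic-survey generator that
reproduces the survey's design so every stage can be exercised and tested
offline.

## The synthetic survey generator

`makeReferenceChimera()` builds a reference locus with the documented
anchors: segment lengths 619 / 52 / 176 / 214 bp, the `GGGCGGGGG` motif at
positions 1--9, the conserved ending `GGGGGCGGGACAAA` at positions 658--671
(so the mirror motif occupies 658--666), an ATG-initiated ORF free of
internal stop codons, and a COXII reference whose first 34 bases match the
ORF and then diverge. All other positions are uniform random draws; the
junction motifs are guaranteed to occur nowhere else. The default ORF
length is 214 bp: the surveyed amplicon excludes 26 bases of the ORF that
were not covered by the sequencing design, and a full-length 240-bp ORF is
available via `gsvLength = 240`. Which end of the ORF the 26 bases are
trimmed from is ambiguous in the source material, so the generator simply
treats the modelled 214 bp as the analysed segment; no orientation flag is
hidden inside the arithmetic.

`paperSurveyDesign()` fixes the survey layout: 17 populations, five of
which carry the locus -- PS, GZ, TL, HK with 15 sequenced individuals each
and YJ with 5 (65 carrier records in total); PS and GZ are fixed for
haplotype H1, TL and HK for H2, YJ for H3; the AMOVA grouping is
{YJ} versus {PS, GZ, TL, HK}. Every population is fixed for a single
haplotype, as observed in the survey. Non-carrier populations contribute
records holding only the conserved *atp6* copy, flagged assay-negative:
absence of the locus is data, not an error.

Haplotype H2 is the reference; H1 and H3 carry fixed edit sets in the
variable spacer totalling **5 indel events** (a 4-bp deletion and a 3-bp
insertion in H1; 2-bp and 5-bp deletions and a 2-bp insertion in H3) and
**34 SNP sites** (16 in H1, 18 in H3, disjoint and clear of every
deletion), consistent with the locus's character of about five indels and
more than 30 SNPs in the spacer. The ORF carries one *synonymous*
substitution in H1 (a fixed CTC Leu codon becomes CTT) and two
*nonsynonymous* ones in H3 (GAC→AAC, TGC→CGC), so the three nucleotide
haplotypes collapse to exactly two protein haplotypes -- a non-trivial
planted truth for the translation stage. Because the edits are expressed
in reference coordinates and applied right-to-left, the generator can also
emit the *true gapped alignment* of the spacer, which is what the
variation catalog is tested against.

What the generator does **not** emulate: PCR and sequencing error,
within-population polymorphism, recombination between haplotypes, and
RNA editing. Tests passing on generator output therefore demonstrate the
correctness of the algorithms under the survey's idealized design, not
robustness to noisy real-world reads.

`simulateHKYAlignment()` provides the separate evolutionary truth for the
phylogenetics module: site-independent simulation of a root sequence down
a tree under HKY85, using the same scaled rate matrix as the likelihood
(branch lengths in expected substitutions per site).

## Haplotypes, identity, and the variable-site matrix

`collapseHaplotypes()` partitions records by exact string equality after
normalization (upper-casing; `?` and `N` both treated as missing;
optional trimming of leading/trailing missing states). Near-duplicate
clustering is deliberately out of scope -- the survey collapses identical
sequences only. Labels are assigned by descending abundance with ties
broken lexicographically by the representative sequence, which makes
labelling deterministic.

`identityPercent()` is a Needleman--Wunsch global alignment (match +1,
mismatch −1, gap −2, no end-gap forgiveness) followed by
identical-columns / alignment-length × 100. The full alignment length,
including gap columns, is the default denominator because it is the usual
"global alignment" convention and yields whole-number identities of the
kind survey tables print; `denominator = "shorter"` is available. The
alignment engine (Biostrings) resolves co-optimal alignments
deterministically, so reported identities are reproducible.

`variableSites()` renders the columns with at least two distinct
non-missing states in the dot notation of survey tables: the reference row
literal, `.` for identical-to-reference, `?` for unknown. Positions are
1-based columns of the input alignment, which must be pre-aligned --
multiple-sequence alignment construction is not this package's business.

## Structure annotation

`annotateStructure()` locates B-atp6 and DS by semi-global (glocal)
alignment of each reference segment against the query -- the same
Needleman--Wunsch core and scoring as `identityPercent()` -- accepting an
anchor when alignment identity ≥ 0.95 (the default threshold; the source
material states none, and 0.95 comfortably separates the conserved
segments, which are >99% identical across haplotypes, from chance
alignments). The ORF start is found from `gsv_ref` when given, otherwise
as the first ATG at or after the COXII-prefix match; the spacer is the
interval between the DS end and the ORF start. A segment that cannot be
anchored is reported as *missing* rather than raising an error, so the
same annotator runs over carriers and assay-negative individuals. The
B-atp6 length is treated as 619 bp throughout (a single conflicting
statement of 610 bp in the source material is taken as a typo).

`findMirrorMotifs()` reports exact occurrences of a motif and of its
character reversal -- **not** the reverse complement; the junction pair
GGGCGGGGG / GGGGGCGGG is a mirror pair. `catalogVsVariation()` counts an
*indel event* as a maximal run of gap columns in any row, deduplicated by
gap pattern (a run shared by several rows counts once), and a *SNP site*
as a gap-free column with two or more distinct non-missing states. Whether
"five indels" means events or gap columns is ambiguous, so both counts are
reported (`indelEvents()`, `gapColumns()`).

## Translation

`translateDNA()` uses the standard genetic code (plant mitochondria use
the standard code for these codons; a different codon table can be
supplied). Internal stops are rendered `*` and translation continues,
codons containing missing states become `X`, and a trailing partial codon
is dropped. Possible C→U RNA editing is not modelled -- translations are of
the genomic sequence. `proteinHaplotypes()` groups ORF haplotypes by
identical translation in frame 1.

## Hierarchical AMOVA

With squared distances $d^2_{ij}$, pair-sum sums of squares are

$$SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij},\qquad
  SS_{within} = \sum_{g}\frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},$$

partitioned among groups, among populations within groups, and within
populations, with d.f. $(G-1,\,P-G,\,N-P)$. Variance components
$V_a, V_b, V_c$ use the standard weighted-size coefficients
$n', n'', n'''$ for unbalanced designs, and the fixation indices are
$\Phi_{CT}=V_a/V$, $\Phi_{SC}=V_b/(V_b+V_c)$,
$\Phi_{ST}=(V_a+V_b)/V$ with $V=V_a+V_b+V_c$.

The default distance is **haplotype-binary** ($d^2 = 1$ between distinct
haplotypes, else 0): under the surveyed design this reproduces the
published AMOVA table exactly (sums of squares 3.462 / 15 / 0, components
0.16667 / 0.33333 / 0, percentages 33.33 / 66.67 / 0, $\Phi_{CT}=0.33333$,
$\Phi_{SC}=\Phi_{ST}=1$), whereas squared nucleotide-difference distances
(`mode = "nt_differences"`) rescale the components without changing the
$\Phi$ statistics here.

Significance uses the three standard permutation schemes: individuals
among populations ignoring groups ($\Phi_{ST}$), individuals among
populations within groups ($\Phi_{SC}$), and whole populations among
groups ($\Phi_{CT}$), with $p = (k+1)/(n_{perm}+1)$ counting permuted
statistics $\ge$ the observed one -- a statistic exceeding all 1000
permutations reports $p = 1/1001 < 0.001$, never zero.

**A resolution caveat that matters for this design.** The group-level test
permutes *whole populations*; with five populations split 1 : 4 there are
only five distinct arrangements, and random permutation regenerates the
observed one about a fifth of the time with a permuted $\Phi_{CT}$ exactly
equal to the observed value. The attainable $p$ for $\Phi_{CT}$ is
therefore ≈ 0.2, regardless of how strong the grouping is: enumeration
shows every alternative arrangement yields $\Phi_{CT} = -0.071 < 0.333$.
$\Phi_{ST}$ and $\Phi_{SC}$, whose permutations act on 65 individuals, do
attain $p = 1/1001$. A report that all three partitions of this design are
significant at $P < 0.001$ cannot be reproduced for the group level under
the standard scheme, and the package does not massage the convention to
force it; the permutation machinery itself is validated by the other two
statistics and by seeded reproducibility.

Degenerate inputs (zero total variance) report undefined $\Phi$ and no
p-values. With a single group the analysis reduces to one level:
$\Phi_{CT}$ is absent and $\Phi_{SC} = \Phi_{ST}$.

## HKY85 maximum likelihood

The HKY85 rate matrix has off-diagonal entries $\kappa\pi_j$ for
transitions and $\pi_j$ for transversions, scaled to unit mean rate so
branch lengths are expected substitutions per site. Transition
probabilities come from the eigendecomposition of the symmetrized matrix
(numerically stable for a reversible chain); they are stochastic and
satisfy detailed balance, and with $\kappa = 1$ and equal frequencies the
model reduces to JC69, which the tests exploit as a closed form.

`hky85LogLik()` is Felsenstein pruning over compressed site patterns;
missing states (`N`, `?`, and gaps) marginalize over all four bases.
`mlSearch()` hill-climbs from a neighbor-joining start (JC distances;
negative branch lengths clamped to zero): per-edge branch lengths are
optimized by bounded Brent maximization (tolerance 1e-6, upper bound 10
substitutions/site), $\kappa$ likewise on a log scale in [0.05, 50]
(initialized at 4), and all nearest-neighbor-interchange rearrangements
are evaluated, accepting the best improving move; the search stops when no
move gains more than 1e-8 log units. Base frequencies are empirical
counts from the alignment (floored at a tiny positive value). Only
accepted improvements modify the state, so the log-likelihood is
monotonically non-decreasing.

This module's fidelity surface is *model correctness* -- closed forms,
exhaustive small-instance oracles, agreement with an independent
implementation (phangorn, used in tests only), and recovery of known
topologies on simulated data (1000-site alignments on a 6-taxon tree with
internal branches of 0.08 substitutions/site are recovered in ≥ 19 of 20
seeded replicates). Reproducing any particular published tree figure,
drawn with different software, is not a target; nor are rate
heterogeneity, other substitution models, or SPR/TBR searches.
`bootstrapSupports()` resamples sites, rebuilds each replicate by
neighbor joining (optionally re-optimizing branch lengths, which leaves
bipartitions unchanged), and reports the fraction of replicates containing
each bipartition of the point tree.

Likelihood underflow is not rescaled per node; with the tree sizes this
package targets (tens of taxa) per-site likelihoods stay far above the
double-precision floor.

## The pipeline

`runPipeline()` chains the stages -- simulate (or read FASTA plus
population/group tables), collapse, identity and variable sites,
structure annotation and spacer catalog, protein haplotypes, AMOVA, and
the ML tree of the ORF haplotypes -- under one config (an R list or YAML
file) with a single seed feeding every stochastic step, so identical
configs give identical reports. Stage failures are isolated and recorded
as warnings; later independent stages still run. The population map file
wins over `pop=` FASTA header keys when both are present, survey tables
being the primary metadata source. All coordinates reported anywhere in
the package are 1-based inclusive.

```{r pipeline, eval = FALSE}
report <- runPipeline(list(seed = 1), outDir = "run1")
report@stages$amova$table
```

## Problem sizes used in the tests

The test suite exercises the full 65-record survey design (about 1 kb per
record), exhaustive likelihood oracles on 3--4 taxa and up to 5 sites
(where summing over all ancestral states is feasible), 20 seeded
1000-site recovery replicates on 6 taxa, and 1000-permutation AMOVA
tests. These sizes were chosen so that every oracle is exact and the
whole suite runs in well under a minute of compute per module.

## Known limitations

* Exact-match haplotype collapsing: sequencing errors would inflate the
  haplotype count on real reads.
* The annotator needs reference anchors; it does not discover novel
  chimeric junctions de novo.
* The group-level permutation test is coarse with few populations (see
  above).
* Likelihood treats gaps as missing; indel information does not inform
  the tree.
* The online verification tier (re-deriving published identity and
  haplotype counts from deposited database accessions) requires those
  sequences to be fetched and placed under
  `tests/testthat/online/accessions.fasta`; without network access it
  does not run.
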