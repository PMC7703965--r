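---
title: "Minimal SNP marker panels for clonal germplasm collections: methods"
author: "minpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal SNP marker panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minpanel)
```

# The problem

Germplasm collections of clonally propagated crops (apple is the motivating
case) accumulate duplicates, synonyms and mislabelled accessions. A small
panel of well-chosen biallelic SNP markers, assayed with a fluorescence
endpoint chemistry such as KASP, is enough to fingerprint thousands of trees
cheaply — provided the panel discriminates every pair of genuinely distinct
genotypes, and provided the curator can separate genotyping error from true
genetic difference. `minpanel` implements the computational side of that
workflow: genotype-table curation, minimal-panel selection, duplicate
grouping, replicate-based error estimation, cross-platform concordance,
similarity clustering, and a simulator that generates collections with known
truth so every step can be validated.

# Data model

Calls are stored in a `GenotypeMatrix`, a `SummarizedExperiment` with
markers as rows and samples as columns. Each cell is one of four states:
homozygous for the alphabetically first allele (code 0), heterozygous (1),
homozygous for the second allele (2), or missing (`NA`). KASP genotypes are
unordered ("GA" is the same observation as "AG"), so calls are
canonicalized to alphabetical allele order on input; rendering uses the
marker's X/Y orientation. Missing tokens accepted on input are the empty
cell, `NA`, `--` and `NN` (the spreadsheet exports in this field are not
dialect-consistent). Ploidy is sample metadata only: the assay reads out a
diploid-style three-cluster call whatever the true ploidy, so triploids are
represented by their called states, not by three-allele genotypes.

# Fail rates and retention

The per-marker fail rate is the fraction of samples with no call at that
marker; the overall rate is total missing over all cells. Downstream
analyses assume nearly complete profiles, so `filterByMinCalls()` retains
only samples with at least a chosen number of successful calls — 19 of 21
is the conventional threshold for a 21-marker panel, tolerating two fails
so a single bad well does not discard a tree, while profiles with three or
more fails are too ambiguous to group reliably.

# Greedy panel selection

`greedySelect()` implements iterative pairwise-discrimination selection. A
marker *discriminates* a sample pair when both calls are present and the
genotype states differ; a heterozygote differs from either homozygote, and
a missing call never discriminates (what the missing value would have been
is unknowable). The first marker is the one with the highest minor allele
frequency — the single most informative marker under random pairing — and
each later step adds the marker that splits the most still-unresolved
pairs, until all pairs are resolved, no marker adds a split, or a size cap
is hit. Ties are broken by higher MAF, then lexicographically smaller
marker id, making the output deterministic for identical inputs.

Pairs left unresolved at completion are exactly the pairs no marker in the
matrix can split: clones, sports invisible to the panel, or samples masked
by missing data. `bruteForceMinimumPanel()` enumerates subsets by
increasing size (guarded at $10^6$ subsets) as an exhaustive reference: on
every feasible instance the greedy panel is at least as large as the true
minimum, and the test suite checks the greedy gains step by step against a
naive re-enumeration of the pair matrices.

`rankAndAugment()` reproduces the manual post-processing step of panel
design: remaining markers are ranked by differentiation score (additional
pairs split), and top-ranked markers from unrepresented chromosomes are
appended so the panel spreads across the genome — insurance against
structural variation at any single locus.

The pairwise state is held as index vectors over the $\binom{n}{2}$ pairs
and shrinks as pairs resolve, so later iterations get cheaper; the
selection loop is vectorized per marker. The suite exercises instances up
to a few thousand pairs; the design scales to collection-sized inputs
because per-iteration cost is proportional to (remaining markers) x
(unresolved pairs).

# Duplicate grouping and replicate merging

`groupProfiles()` treats a profile strictly: missing is its own state, so
two samples group together only when every marker state matches. This is
deliberate — with a miscall rate of order 1% a 21-marker profile is wrong
in roughly one sample in five, but merging across missing or discordant
calls without evidence would silently collapse genuinely distinct sports
and synonyms. The `compatible` mode (missing matches anything, transitive)
is available for exploratory screening and warns that it can over-merge.

The principled adjustment is `mergeReplicateGroups()`: groups merge only
when they share a declared replicate label *and* their representative
profiles differ at no more than `maxDiff` markers (default 1 — the
single-miscall case). Unlabelled near-identical profiles are left apart.
`findSystematicNulls()` flags markers missing in *every* member of a
multi-sample group: a reproducible no-call is evidence of a null allele
(primer-site variation) and belongs to the group's profile rather than to
its error budget.

# Error model

Replicates of one genotype should have identical profiles, so every
difference among declared replicates is counted as a calling error. For a
pair, errors are the pairwise differences and the denominator is the
non-missing calls summed over both profiles (42 for two complete 21-marker
profiles — a single difference is 1/42 ≈ 2.4%). For three or more members
the strict-majority consensus is taken as correct; markers with no strict
majority get a missing consensus and are skipped in error counting, and
the denominator is the non-missing calls summed over all members (63
complete; 62 when one call is missing). This follows the worked-replicate
arithmetic in which the denominator counts calls actually made, not
member-count x marker-count.

`overallErrorRate()` aggregates groups under two assumptions. Under
`all_genuine` every nominal replicate is trusted, so mislabelled samples
inflate the estimate — an intentionally conservative upper bound. Under
`diff_threshold` (default: more than 2 differences), divergent members are
presumed mislabelled and excluded; both members of a discordant pair are
excluded because neither can be presumed correct, and surviving groups are
re-scored after exclusion. On simulated collections with injected miscall
rates the screened estimate recovers the generating rate within binomial
error even when 5% of labels are scrambled, while the all-genuine estimate
overshoots — the qualitative ordering the method predicts, made testable.

# Similarity, clustering, bootstrap

Similarity between two samples is shared calls over mutually called
markers; markers missing in either sample are excluded. Distances on
complete $m$-marker profiles are therefore multiples of $1/m$ — about 0.05
per SNP difference at $m = 21$, which is the natural resolution limit of a
small panel. Pairs with *no* mutually called marker have undefined
similarity and block clustering with an explicit error; imputing them
would fabricate relatedness.

Clustering is ordinary agglomerative `hclust`; the default linkage is
UPGMA (average), a documented choice (the source workflow does not state
its linkage) and configurable. Support is estimated by an ordinary
Felsenstein bootstrap over markers: resample the $m$ markers with
replacement, rebuild the tree, and score each reference clade by the
percentage of replicate trees containing exactly the same leaf set.
Multiscale (AU) bootstrap p-values are intentionally not implemented; the
plain marker bootstrap answers the curator's question (is this cluster
supported by more than one or two SNPs?) with fewer assumptions. Clades of
identical profiles always get 100%; at 21 markers, clusters held together
across ≥4 SNP differences lose support rapidly, which is the correct
reading: a 21-marker dendrogram is a description of profile similarity,
not a phylogeny. Accordingly `cutClusters()` requires an explicit height;
no default cut is asserted. Trees export to newick (supports as internal
node labels) and NEXUS via `ape`.

# The simulator

`simulateCollection()` generates collections with known truth: founder
genotypes drawn marker-wise from Hardy–Weinberg proportions at a MAF
sampled per marker; clone groups copying founders; sport mutations (true
somatic changes) at a per-call rate; triploid-like founders whose
homozygous calls are shifted heterozygous with probability
`hetInflation`; then observation noise — miscalls flipping uniformly to
one of the other two called states, followed by no-calls — logged
change by change; finally, optional label scrambling to emulate
mislabelled accessions.

Defaults were fixed once to mirror a curated apple collection on a
21-marker panel: mostly singletons with some groups of 2–3; `mafRange`
0.2–0.5, which gives an expected diploid heterozygosity of
$E[2p(1-p)] \approx 0.44$; `triploidFraction` 0.12 and `hetInflation`
0.32, lifting triploid-like heterozygosity to $0.44 + 0.56 \times 0.32
\approx 0.62$; `missingRate` 0.035 (the typical assay fail rate) and
`miscallRate` 0.002 (the low end of replicate-based error estimates).
What the simulator does *not* emulate: linkage disequilibrium between
markers (panel markers are chosen to be independent), pedigree structure,
genuine three-allele triploid genotypes, and plate- or DNA-quality batch
effects. Tests passing on simulated data therefore validate the
*arithmetic and algorithms*, not the biological realism of any particular
collection.

# Numerical and design notes

* Tie-breaks in selection (MAF, then marker id) and the strict-majority
  rule in consensus calling are the only places ties can arise; both are
  deterministic.
* Strand harmonization refuses palindromic SNPs (A/T, C/G) without an
  explicit allele mapping: complementation cannot reveal the strand there,
  and guessing would silently corrupt hom/het comparisons.
* Empty inputs fail loudly (empty matrix, all-missing profiles, groups
  below minimum size) rather than returning degenerate zeros.
* Problem sizes in the test suite — instances up to 12 samples x 10
  markers for exhaustive cross-checks, 200 simulated clone pairs for
  error-rate recovery, 1000 bootstrap replicates on 5 samples — were
  chosen so exhaustive oracles stay tractable while binomial intervals are
  tight enough to be meaningful.

# Limitations

Panel selection is greedy, not optimal; the exhaustive search is a test
oracle, not a production path, and no ILP formulation is provided. Error
attribution between the two members of a discordant pair is impossible by
design. Heterozygosity from ~21 markers screens for ploidy but cannot
assign it. The package does not call genotypes from raw fluorescence, does
not design primers, and does not decide which of two conflicting named
accessions is true to type — those require wet-lab evidence or registry
information.
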