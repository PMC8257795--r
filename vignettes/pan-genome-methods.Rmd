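---
title: "Methods: synteny-constrained pan-genomics, introgression and F1 QTL mapping"
author: "CaryaPan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-constrained pan-genomics, introgression and F1 QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaryaPan)
```

CaryaPan implements the comparative- and quantitative-genomics computations
used to analyse a panel of outbred tree genomes descended from a
whole-genome duplication (WGD), with pecan (*Carya illinoinensis*) as the
motivating system: four chromosome-scale genomes whose sixteen chromosomes
form eight homeologous pairs created by a ~60-Myr-old WGD, a pan-genome
anchored to one reference cultivar's gene order, interspecific
introgressions from related *Carya* species detected by a local-ancestry
hidden Markov model, and a 143-progeny F1 pseudo-testcross used to map a
large-effect insect-resistance QTL. This vignette explains each model, its
assumptions, the tunable parameters, what the synthetic-data generators do
and do not emulate, and the numerical and design choices a maintainer would
want to know about.

## Gene ranks: the coordinate system

All synteny operations work in **gene-rank space**: within each chromosome,
genes are numbered 0, 1, 2, ... by ascending start coordinate (ties broken
by gene id; strand is ignored). Rank space removes the enormous variation
in intergenic distance, so chaining and density parameters can be expressed
in gene counts. Internally all base-pair intervals are 0-based half-open;
conversion to and from the 1-based GFF3/VCF conventions happens only at the
file boundary (`parseAnnotation()`, `parseGenotypes()`), which keeps
off-by-one errors out of the analysis code. Genotypes are coded as
**reference-allele counts** (0/1/2), the convention the ancestry model
expects.

## Collinear blocks and homeolog rearrangements

Protein-similarity hits between two chromosomes become anchors
`(query rank, target rank)`. A collinear block is a chain of anchors that
is strictly increasing in query rank, monotone (increasing or decreasing)
in target rank, with consecutive anchors at most `max_gap` ranks apart on
both axes, and at least `min_size` anchors long. `chainCollinearBlocks()`
extracts chains greedily (longest first; ties by smaller starting query
rank; each anchor joins at most one block) with an O(n^2) dynamic program;
the tests verify every extracted chain against an exhaustive enumeration on
small instances and a DAG longest-path oracle at 40 anchors.

Two parameter sets mirror the two analysis regimes:

* **homeolog (paralog) runs** — `chainParams()`: `max_gap = 50`,
  `min_size = 10`, preceded by DBSCAN density refinement (Euclidean in rank
  space, `radius = 50`, `min_hits = 10`, border points joining the first
  core cluster in scan order — the metric and tie rule are our explicit
  choices, since density refinement tools leave them unstated);
* **pan-genome (ortholog) runs** — `panChainParams()`: `max_gap = 20`,
  `min_size = 10`, one hit per gene per genome.

Before homeolog chaining, within-genome hits are pruned to pairs whose two
genes share an orthogroup. Orthogroups themselves
(`clusterOrthogroups()`) are the connected components of the graph whose
edges are **reciprocally retained** hits after pruning to the top two
bitscores per query gene and target genome ("top two" because a WGD genome
must be allowed to contribute both the ortholog and the homeolog). This is
a deterministic simplification of MCL-style orthology clustering; it is
exactly testable and recovers the simulator's truth, but on real data it
will merge families more aggressively than MCL would.

`countHomeologBlocks()` counts blocks for every unordered pair of distinct
chromosomes; the total, corrected by the base chromosome number, estimates
the number of rearrangements since the WGD, and
`rearrangementInterval(n_blocks, n_chroms, wgd_age_myr)` converts that to
an average waiting time. For pecan's printed values — 25 blocks over 16
chromosomes and a 60-Myr-old WGD — this gives one rearrangement every
6.7 Myr. Block counts are corrected by the total chromosome number in a
comparison (rather than per-pair) because that convention reproduces the
printed statistic. Each planted reciprocal translocation or long inversion
adds exactly **two** blocks, which the recovery tests exploit.

## The synteny-constrained pan-genome

`buildPangenome()` runs the pipeline: chain blocks for every genome pair;
drop cross-genome hits outside every block's bounding box (small
translocations below the minimum block size are deliberately not captured)
and mask homeologous (off-diagonal within-genome) hits from orthologous
pairing; re-cluster orthogroups on the surviving network; condense tandem
arrays (same orthogroup, same chromosome, ranks within the chaining gap)
into single members; and place each orthogroup on the reference gene order:

* single-copy in the reference: the gene's rank;
* multi-copy: the copy with the highest summed within-genome bitscore
  (ties by physical centrality, then gene length);
* absent from the reference: the mean, over genomes, of each
  representative's position linearly interpolated between the two nearest
  anchors of its enclosing block; orthogroups with no syntenic anchor go to
  an `"unplaced"` bucket rather than erroring.

Entries are totally ordered by (chromosome, position, id); orthogroup ids
are numbered from the lexicographically smallest member so the output is
identical under any permutation of the input rows.

Presence-absence variation (`pavTable()`) marks each orthogroup complete,
incomplete, or private to one genome; an optional outgroup genome is
excluded from the accounting. `absenceRuns()` reports maximal runs of five
or more consecutive entries absent in a focal genome.
`classifyAbsence()` aligns a CDS against the syntenic region of a genome
lacking the annotation (local alignment) and classifies the absence:
`very_similar` (coverage > 99% and identity >= 95%), `diverged`
(coverage >= 75% and identity >= 75%), else `absent`. The published
category ranges overlap at their endpoints; the boundary policy above is
fixed here and tested for monotonicity. Identity is computed as
matches/(matches+mismatches) — the inverted formula that sometimes appears
in print is treated as a typographical slip.

`intervalPrivateEnrichment()` tests whether entries private to a genome
are over-represented in an interval (e.g. an introgression block) with an
exact two-sided hypergeometric test (tail summation of outcomes no more
likely than observed); a 46-orthogroup interval with 8 private entries
gives the 17.4% private fraction. `projectToAltHaplotype()` compares the
primary and alternative haplotype assemblies of one outbred genome: alt
contigs are placed at the midpoint of their members' primary syntenic
positions, entries are classified (`both`, `primary_only_with_alt_contig`,
`primary_only_no_alt_contig`, with `alt_only` genes reported separately),
and peptide identity for `both` pairs is
100 x identical / (aligned + internal gaps), terminal gaps excluded.

## Ka/Ks and sliding-window landscapes

`alignCodons()` aligns two CDS through their proteins (global BLOSUM62)
and back-translates; trailing partial codons are trimmed with a warning, a
terminal stop is dropped, and an internal stop is an error naming the
codon. `kaksNG86()` implements Nei-Gojobori (1986): fractional
synonymous-site counting averaged over both sequences (mutations to stop
codons count as non-synonymous, so sites per codon always sum to 3),
difference counts averaged over all minimal mutational pathways with
stop-codon intermediates excluded (if every pathway is blocked, all
pathways are used with stop steps counted non-synonymous), and the
Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3) with proportions >= 3/4
flagged saturated. The implementation is pairwise rather than
phylogenetic: multi-sequence orthogroups are reduced to pairwise
comparisons, which is adequate for the closely related genomes this
targets (genome-wide mean Ks of a few parts per thousand) but not for deep
divergences.

`slidingQuantile()` converts per-gene Ks values to empirical quantiles
q = (mid-rank - 0.5)/n within each (genome, chromosome) and averages them
in 100-gene windows sliding by one gene. The mid-rank quantile and
mean aggregation are our choices (unstated in the original figure legend);
they make the track bounded in [0, 1], robust to ties, and invariant to
monotone transforms of Ks. Chromosomes shorter than the window emit no
windows, with a warning.

## Local ancestry and introgression blocks

Variants are pruned (`pruneVariants()`) to biallelic sites with no missing
calls, minor allele count >= 3, and pairwise r^2 <= 0.999 within trailing
100-SNP windows (the earlier site is kept — the greed direction is fixed
here for determinism). Global ancestry proportions come from non-negative
least squares of the sample's allele-frequency vector on the source
frequency vectors, normalised to sum to one; if all sources are identical
the proportions are non-identifiable and a uniform vector is returned with
a warning.

`ancestryPosteriors()` is a hidden Markov model over diploid ancestry
states — the 10 unordered pairs of 4 sources, assuming haplotype
exchangeability. Emissions treat the two alleles as independent Bernoulli
draws at the source reference-allele frequencies, each misread with
probability `genotyping_error` (default 1e-3, the published setting).
Transitions let each haplotype switch ancestry over d morgans with
probability 1 - exp(-switch_rate x d), drawing the new ancestry from the
prior proportions. The published analysis used a multi-pulse admixture
model (pulses at 2-5 generations, Ne 1000); we collapse that to this
one-parameter switch-rate chain because a single rate is identifiable at
desk scale and the forward-backward recursion can be verified against
exhaustive path-sum enumeration (the tests do both). Source frequencies
are estimated with a pseudocount of 0.5 per allele so no frequency is
exactly 0 or 1.

`decodeAndCull()` converts posteriors to hard calls (argmax; ties to the
larger prior, then the lower state index) and then culls short runs: for
L = 2 ... 500, any maximal run shorter than L is merged into the flanking
run with more markers (ties to the left). The published description of
this culling is terse; the flank-majority reassignment implemented here is
one consistent reading, is deterministic and idempotent, and is tested
against an independent run-list implementation. Blocks of >= 500 markers
survive. `highConfidenceIntrogressions()` intersects, per donor, the
non-background intervals across a reference genotype and all its
relatives, so only introgressions shared by the whole pedigree branch
remain; `introgressionSummary()` reports Mb and percent of genome per
donor.

## Pseudo-testcross QTL mapping

Markers heterozygous in the focal parent and homozygous in the other
segregate like a backcross. `filterMarkers()` applies the quoted
thresholds (MAF < 0.05, heterozygous call frequency > 0.8, missing > 0.1,
more than two alleles; then the 1% most extreme mean read depths).
`phaseTestcross()` clusters markers into the two parental haplotypes per
chromosome by the sign of pairwise genotype correlations (greedy
seed-and-extend from the first marker — a documented substitute for the
original clustering, which is not restated in print), then orients each
chromosome's clusters with the grandparental genotype table so haplotype
"A" carries the alternate alleles attributed to the first origin (e.g.
'Mahan'). `binMarkers()` keeps one marker per phase and 25-kb bin — the
one most concordant with the majority haplotype over ten flanking markers
each side (observed, not imputed, flanking calls; ties keep the lower
coordinate).

`estimateMap()` estimates adjacent recombination fractions under a
symmetric genotyping-error model: the observed mismatch frequency is
m = r((1-e)^2 + e^2) + (1-r)2e(1-e), inverted at the maximum-likelihood
point (this closed form is the fixed point of the EM iteration for this
model), clamped to [0, 0.4999], and converted to cM with the Kosambi
function d = 25 ln((1+2r)/(1-2r)); `error_prob` defaults to 0.0165 as in
the published map.

`scanLod()` inserts pseudomarkers every 0.1 cM (haplotype probabilities by
error-aware two-point interpolation from the flanking observed markers —
exact under the backcross Markov property when genotypes are complete) and
scans with a single-variance-component linear mixed model:
leave-one-chromosome-out (LOCO) kinship from centred genotype
cross-products, null heritability fit per chromosome on a 0.01 grid by
restricted likelihood, and LOD = (n/2) log10(RSS0/RSS1) in the rotated
generalised-least-squares model. This grid-GLS construction is a
deterministic simplification of a full REML mixed-model scan; it is exact
for the null eigenstructure it uses and reproduces the closed-form
expectation LOD ~ -(n/2) log10(1 - R^2) at a planted marker.
`permutationThreshold()` permutes the phenotype (10,000 permutations in
the published analysis; 1,000 in the tests), recomputes the genome-wide
maximum LOD over the marker frame with the null heritability refit per
permutation, and takes the 95th percentile. Phenotypes are analysed
untransformed; significance rests on the permutations.

`bayesInterval()` normalises 10^LOD over the peak chromosome and returns
the smallest contiguous run of scan positions containing the peak whose
mass reaches 95%, projected to physical coordinates through the marker
cM-bp map. `rankCandidates()` then prioritises interval genes by
haplotype divergence: alternative-assembly-only genes, both-haplotype
pairs with peptide identity below 98%, and primary-only genes spanned by
an alternative contig are high priority; primary-only genes with no
alternative contig likely sit in homozygous (collapsed) regions and are
low priority. LRR/immune domain tags can be attached from a user-supplied
table.

## The synthetic-data generators

All generators are seed-deterministic and return ground truth sufficient
to score recovery without re-simulation. They emulate the *statistical
structure* the analyses assume, not the biology:

* `simulatePangenome()` — an ancestral gene order, optionally duplicated
  by a WGD into homeolog chromosome pairs with extra planted divergence;
  shared inversion/reciprocal-translocation events between homeolog
  copies; per-genome gene loss, tandem duplication and private-gene gain;
  bitscores decreasing linearly in planted divergence. Inversions must
  span more than twice the chaining gap (the generator enforces
  `genes_per_chrom >= 210`): a shorter inverted segment lets a
  same-orientation chain bridge the flanks through the point where the
  anti-diagonal crosses the main diagonal, and the breakpoints would not
  register as separate blocks. Not emulated: gene-length variation,
  rate heterogeneity among genes, annotation noise, or hit noise — so
  exact truth recovery in the tests shows algorithmic correctness, not
  robustness to noisy orthology.
* `simulateCdsEvolution()` — places an exact count of synonymous and
  non-synonymous substitutions at distinct codons (never creating stops)
  to hit target Ka/Ks; per-site uniform, no codon-usage bias, because the
  test target is NG86 correctness, not realism.
* `simulateAdmixturePanel()` — source allele frequencies drift from a
  common ancestor under a Balding-Nichols beta model with parameter
  `fst_like_divergence` (0 = identical sources; >= 1 = fixed differences,
  each marker diagnostic for one source); a test genome and its relatives
  share planted homozygous donor blocks; genotypes are binomial draws plus
  per-allele error. Eight samples per source are genotyped (our choice; a
  realistic panel size for the resequencing design emulated). Crossovers
  are not simulated within the panel — ancestry truth is block-wise by
  construction.
* `simulateF1Cross()` — 143 progeny by default; crossovers Poisson with
  one event per morgan and no interference (the map function is tested as
  a transform of recombination fractions, so interference is deliberately
  absent even though distances are reported in Kosambi units); marker alt
  alleles assigned to either parental haplotype at random ('Mahan' /
  'Major' truth labels); phenotype = effect x [Mahan haplotype at the
  QTL] + Gaussian noise, with the effect scaled to a requested fraction of
  variance.

## Problem sizes used by the test and acceptance suites

The suites are sized to run comfortably on one CPU: pan-genome recovery
uses 2-8 chromosomes with 100-250 genes each over 1-4 genomes; NG86 is
verified on 200 random 50-codon pairs and Ks recovery on 2,000-codon pairs
over 20 seeds; the ancestry model on 1,000-2,000-marker chromosomes with
800-marker planted blocks; the QTL pipeline on 143 progeny, 120 markers
over three 80-cM chromosomes, 1,000 permutations, and 50 replicates for
the recovery rates. The full test suite completes in under two minutes.

## Numerical choices and degenerate inputs

* Chain extraction ties: same orientation preferred, then smaller starting
  query rank; deterministic predecessor choice inside the DP.
* `rearrangementInterval()` returns `NA` with `n_rearrangements = 0` as
  the explicit "no rearrangements" sentinel instead of dividing by zero.
* Hypergeometric two-sided p sums probabilities <= 1.0000001 x the
  observed outcome's probability (the standard guard against floating-point
  ties).
* Forward-backward uses per-step scaling; posterior rows are renormalised
  and validated to sum to 1 within 1e-9.
* Recombination fractions are capped at 0.4999 before the Kosambi
  transform; adjacent marker pairs with no co-observed progeny are flagged
  unlinked.
* The heritability grid is 0 to 0.99 in steps of 0.01; eigenvalues are
  floored at 0.
* `globalAncestry()` and the HMM guard the non-identifiable
  all-sources-identical case explicitly (uniform output with a warning;
  posterior equal to the prior).

## Known limitations

* **Bayes interval coverage.** The 95% credible interval derived from the
  normalised 10^LOD profile is intrinsically anti-conservative for
  large-effect QTL: in the recovery suite (R^2 = 0.45, n = 143, 50
  replicates) the planted locus falls inside the interval in roughly
  85-90% of replicates even though the scan peak clears the permutation
  threshold in all of them, and an idealized dense-marker simulation of
  the same statistic outside this package behaves the same way. Users
  should read the interval as a well-defined summary of the LOD profile,
  not as a calibrated 95% frequentist interval.
* Orthogroup clustering by connected components is more aggressive than
  MCL; on noisy real hit tables it will chain families together.
* The ancestry model's single switch rate cannot represent multi-pulse
  admixture histories; timing of admixture is out of scope.
* The pairwise NG86 estimator ignores codon-frequency bias and is not
  suitable for saturated comparisons (it flags and abstains instead).
* Haplotype phasing assumes dense, mostly error-free pseudo-testcross
  markers; chromosomes with fewer than two informative markers are
  rejected rather than guessed.
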