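---
title: "Methods: haplotype sharing and rare-variant association in multiplex pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype sharing and rare-variant association in multiplex pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## Scope and model

`famvar` implements a family-based discovery pipeline for rare disease
variants: phase multiplex pedigrees by Mendelian inheritance, enumerate
chromosomal segments co-inherited by subsets of affected relatives,
restrict sequencing/annotation to captured gene regions in those
segments, test candidate variants for allelic association in a large
case/control cohort, and report how candidates segregate back in the
families. The underlying genetic model is that in high-risk families a
predisposing allele descends identical-by-descent (IBD) from a common
ancestor, so affected relatives share the surrounding haplotype; no
penetrance or likelihood model is imposed — sharing is treated
deterministically, and association strength is measured by the
minor-allele odds ratio rather than by genome-wide significance.

## Phasing

Phasing is purely Mendelian and trio-local. For a child and its two
parents, a marker's parental origin is forced when (a) the child is
homozygous, or (b) the child is heterozygous and at least one parent is
homozygous. Founders are phased only at homozygous markers. Everything
else is left `NA` ("unknown") — the method never imputes from population
LD, so resolved entries can be wrong only if the input genotypes are
wrong. This is the reason the pipeline insists on Mendelian-consistent
input: `phase_pedigree()` errors on an inconsistent trio rather than
phasing around it, and `mendelian_filter()` removes a flagged marker for
the entire dataset because a transmission error at one trio makes the
marker untrustworthy everywhere. Only nuclear-family (level-1)
consistency is checked; full-pedigree genotype elimination would catch a
few more configurations but is unnecessary for excluding biallelic SNPs.

On simulated three-generation pedigrees with founder minor-allele
frequencies of 0.2–0.5, roughly 75–85% of entries phase fully, and — by
the soundness property above — resolved entries match simulation truth
exactly.

## Shared segments

A segment shared by a subset S of affected individuals is a maximal run
of consecutive markers at which every member of S carries an identical
allele on one of its parental chromosomes, with the chromosome choice
per member held fixed across the run. Sharing is therefore
identity-by-state on phased haplotypes: with dense markers and a real
pedigree, extended IBS runs essentially coincide with IBD, and no IBD
probability model is needed. Implementation notes:

* Unknown-phase entries are wildcards — compatible with any shared
  allele, but they do not count toward a run's support.
* A run must contain at least `min_markers` (default 25) markers at
  which *all* members are resolved and identical. With ~0.1 cM marker
  spacing, 25 witnessed markers is a few cM — long enough that chance
  IBS runs of that support are rare, short enough not to miss the
  multi-cM segments a pedigree can transmit intact.
* `tolerance` (default 0) inconsistent markers may be absorbed per run;
  the default is strict because a single opposite-homozygote mismatch on
  error-free data is proof of non-sharing. The knob exists for
  genotyping-error robustness experiments.
* Segment boundaries are reported at the outermost *supporting*
  markers, not extended into flanking unresolved or non-sharing
  territory — a conservative convention that slightly under-covers the
  true IBD interval (by about the local inter-marker spacing) and never
  over-covers it.
* Enumeration is over the 2^|S| chromosome-choice vectors; overlapping
  candidates from different choices are deduplicated by containment.
  Ties between equally supported overlapping segments order by bp span,
  longest first, then leftmost. A guard refuses subsets larger than 12
  (4,096 vectors).

`sharing_profile()` evaluates all `choose(N, k)` subsets of the N
affecteds for k from N down to `floor_k` (default N−3, mirroring the
deepest sharing levels worth reporting, e.g. "5 of 8"), with a subset cap
to keep the combinatorics bounded. Region selection for capture requires
a minimum sharing fraction per pedigree class; two-generation pedigrees
— whose shared regions can span half a chromosome because few meioses
separate the affecteds — contribute a region only where it overlaps a
qualifying region from a different family, and only the intersection is
kept.

## Variant handling

Capture regions per transcript: the promoter (2,000 bp upstream of the
TSS, strand-aware), all exons, and 10 intronic bases at each splice
junction (the "exon–intron boundary" width is a declared choice; it is
exposed as `boundary_pad`). Variants are normalized to the left-aligned
minimal representation before cross-caller comparison, and a variant is
kept when at least 2 of the 3 call sets contain its normalized key.

Classification translates reference and alternate codons with the
standard genetic code. The conservative/non-conservative missense split
uses a declared physicochemical grouping (aliphatic A/V/L/I/M, aromatic
F/W/Y, polar S/T/N/Q/C, positive K/R/H, negative D/E, special G/P):
within-class substitutions are conservative. The table is an argument
(`aa_classes`) because no universally agreed grouping exists. Splice
windows: the two canonical intronic bases at each junction are
splice-site changes; exonic positions within 3 bp of an internal
junction add a splice-site label on top of the coding label (this is how
a first-base-of-exon missense variant gets a "missense, splicing" double
call). CDS indels are frameshift when the length change is not a
multiple of 3, otherwise in-frame ("other"); downstream stop-gain after
a frameshift is not chased. Fusion or overlapping transcripts are
classified per supplied transcript, with no automatic worst-effect
selection.

## Case/control association

Sample QC mirrors array practice: PCA on a filtered SNP set (autosomes,
call rate > 0.95, MAF > 0.05, LD r² < 0.25 in 50-SNP windows), with
dosages mean-imputed, centered and scaled to unit variance per SNP
("default settings" of commercial PCA tools are not public; unit
variance is the declared choice). Ancestry outliers are samples whose
Euclidean distance from the median centroid of (PC1, PC2) exceeds
Q3 + 1.5×IQR of the distance distribution. The quartile estimator is
type-7 (linear interpolation, R's default) and is exposed because
outlier counts near the threshold depend on it. Relatedness is handled
by keeping exactly one subject per known family — the one nearest the
median centroid, ties broken by sample-id order.

Per variant, the allelic test is run on the 2×2 allele table with the
minor allele defined in the combined case+control cohort, so odds ratios
are uniformly "per minor allele":

* OR = (a·d)/(b·c); if b·c = 0 with a·d > 0 the OR is infinite and the
  CI undefined (a case-unique variant).
* Woolf CI with z = 1.96 on the log scale.
* Fisher's exact two-sided p by summation of hypergeometric point
  probabilities ≤ the observed one, with the conventional 1 + 1e-7
  relative guard against floating-point ties.
* Pearson chi-squared without continuity correction (Yates' correction
  would not reproduce standard allelic-test output on these tables).
* No multiple-testing correction: candidates are prioritized by effect
  size (case-unique, or OR strictly greater than 1.5), not by p-value —
  rare variants are underpowered for p-value ranking, and for rare
  outcomes the OR approximates relative risk.

The exact Hardy–Weinberg test conditions on the observed allele counts
and sums the probabilities of heterozygote counts no more probable than
the observed one (no mid-p); monomorphic markers return p = 1, and a
chi-squared variant is available by flag.

## Synthetic data

The generators exist so every pipeline stage can be validated against
known truth without any external dataset.

`simulate_pedigree()` gene-drops founder haplotypes (per-marker MAFs
drawn from a range, default 0.2–0.5) through the pedigree under the
Haldane map function (crossover probability ½(1−e^(−2d/100)) between
markers d cM apart, no interference — the simplest standard model, and
sufficient for segment-length realism). A planted risk segment forces
one founder haplotype down each designated carrier's lineage over the
interval; the founder's own gametes recombine exactly at the interval
boundaries, so the planted interval *is* the IBD extent of the risk
haplotype, and designated non-carrier affecteds are steered to the other
parental haplotype there. Genotyping error and missingness are applied
only to the emitted genotype matrix; the truth record keeps error-free
phases and founder-haplotype identities.

The validation simulations use a 4-generation, 23-member template with
six affected great-grandchildren (`multiplex_pedigree(generations = 4)`),
300 markers at 0.1 cM spacing and a 10 Mb planted segment. The depth
matters: in a 3-generation family, severing the risk haplotype at the
founder leaves all branch flanks on the founder's other haplotype, which
is itself a genuinely shared segment, and in roughly (1/2)^6 of runs it
extends the detected region well past the planted interval. With four
generations the probability of that configuration is negligible (~3e-5),
and the real extended pedigrees this emulates are themselves multi-
generation. Problem sizes (20 recovery seeds, 10 phasing seeds, 1,000
CI-coverage replicates at 1,500 cases / 6,000 controls, control MAF
0.005, true OR 2) were fixed as the study conditions for the validation
suite.

`simulate_cohort()` draws case genotypes at the allele frequency solved
from the control MAF and the target allelic OR, with genotypes in
Hardy–Weinberg proportions within each group — consistent with the
allele-level test being validated. Ancestry outliers get
Balding–Nichols-diverged allele frequencies at a given Fst; family
blocks copy a founder member's genotypes with a set probability.

What the generators do **not** emulate — and hence what passing tests do
not demonstrate about real data: LD between markers (founder haplotypes
are drawn independently per marker), genotyping-batch artifacts,
population admixture gradients (clusters are discrete), locus
heterogeneity within a family, and reduced penetrance (planted carriers
are exactly the designated affecteds). Real-data behavior of, for
example, the ancestry-outlier counts therefore cannot be predicted from
these tests beyond the rule's arithmetic.

## Degenerate inputs and numerical conventions

* Missing genotypes are `NA` throughout, never a third allele code.
* Mendelian checking skips sex chromosomes and never flags missing
  genotypes; an empty genotype matrix is an error.
* `hwe_test` and `fisher_exact_2x2` compare probabilities with a tiny
  relative guard so analytically tied tables are counted as ties in
  floating point.
* Coordinates are 1-based inclusive internally (VCF convention); BED
  export subtracts 1 from starts and is an involution with `read_bed()`.
  The genome build is a label only — no liftover.
* PCA drops zero-variance SNPs after imputation; identical samples give
  identical scores.
* `relatedness_prune` and `ancestry_outliers` are deterministic given
  their inputs; all simulation is seeded and generators are pure
  functions of (spec, seed).

## Limitations

Phasing resolution is bounded by trio informativeness — deep ancestors
with no genotyped parents phase only at homozygous markers, and sharing
through them is detected via their descendants. Sharing is IBS-based, so
on very sparse maps or tiny subsets chance sharing can reach
`min_markers`; the default of 25 presumes array-density data.
X-chromosome phasing, linkage LOD scores, population-based (LD) phasing,
CNV detection and in-silico damage prediction are out of scope; CNV
carrier status can be supplied as an external flag table and flows
through segregation reporting unchanged.
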