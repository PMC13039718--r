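---
title: "Assembly-based SV discovery and sub-pangenome analysis: models and methods"
author: "subpansv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-based SV discovery and sub-pangenome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

subpansv is a desk-scale re-implementation of an assembly-based structural
variant (SV) discovery and sub-pangenome analysis workflow for a panel of
inbred crop accessions, of the kind used to dissect large inversions,
premature-stop alleles and copy-number-variable resistance clusters in
Solanaceae germplasm. This vignette records the models, the tunable
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate. Nothing stated here goes beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## The pipeline at a glance

1. `simulate_panel()` builds a panel of haploid-representative genomes with
   a fully recorded ground truth.
2. `wga_align()` compares each accession to the reference: unique k-mer
   anchoring, collinear chaining, and a best-first synteny net.
3. `call_variants_from_net()` extracts insertions, deletions, inversions,
   translocations, SNVs and small indels from each net;
   `merge_callsets()` produces one genotyped, non-redundant callset;
   `annotate_sv()` assigns feature classes; `consensus_filter()` applies
   the multi-caller support rule used for short-read callsets.
4. `popgen` functions summarize the genotype matrix: MAF/missingness
   filtering, LD pruning, outgroup polarization, allele-frequency spectra,
   windowed pi / Weir-Cockerham Fst / Tajima's D, LD decay, PCA,
   standardized kinship, neighbor-joining trees.
5. `pangene` functions classify gene-family occupancy, compute pan/core
   rarefaction curves, Nei-Gojobori Ka/Ks, and hypergeometric term
   enrichment.
6. `assoc` functions run the kinship-corrected linear mixed model,
   coverage-ratio copy-number genotyping, junction-based inversion
   genotyping, incidence-rate processing and epistatic genotype-combination
   tests.
7. `svexpr` functions contrast tissue expression profiles between genes
   with and without nearby genotype-discordant SVs, and apply the
   p / fold-change / TPM filter for SV-genotype differential expression.

`run_pipeline()` orchestrates all stages with one seed and a checksummed
manifest; the exported functions, scripts and this vignette are the
package's interface (there is no shell executable — the artifact is an
analysis library, not a command-line tool).

## Whole-genome comparison

**Anchoring.** Seeds are k-mers (default k = 21, odd, 15-51) that occur
exactly once in the reference and exactly once in the query counting both
strands — the unique-match discipline that keeps repeat copies from
seeding false anchors. Seeds sharing a diagonal within k bp are merged
(their union is a verified exact match) and extended outward base by base;
N never matches. K-mers are encoded as exact 2-bit numeric codes (4^21 <
2^53), so matching is hashing on doubles rather than strings.

**Chaining.** A sparse dynamic program over anchors of one
(reference chromosome, query chromosome, strand) bucket maximizes anchored
length minus gap costs. A gap between linked anchors costs
`gap_open + gap_extend_per_bp * max(ref_gap, qry_gap, 0)` — the maximum
rather than the sum, so a clean insertion or deletion pays for one gap
only. Links are forbidden when either gap exceeds `max_gap` (default
100 kb, matching the largest per-event size class) **or** when both gaps
exceed `max_mutual_gap` (default 10 kb). The second rule matters: a large
inversion produces equal-sized gaps on both coordinates, and without it
the flanking forward-strand chain would silently bridge the inverted
segment and the inversion would never reach the net. Chains are extracted
greedily by descending score; chains scoring below 200 are treated as
noise. The predecessor search is capped at 200 anchors, ample at the
anchor densities the generator produces.

**Netting.** Chains tile the reference best-first by score (ties: smaller
query start). A chain overlapping already-claimed reference territory is
trimmed at anchor boundaries, keeping its longest surviving contiguous
run; fully displaced chains are reported as unnetted (this is where the
second copy of a duplication ends up). Every reference base gets exactly
one coverage class: aligned (inside a netted anchor), gap (between anchors
of a netted chain), or unaligned.

## Variant extraction and merging

Within each netted chain, consecutive anchor gaps are interpreted as:
insertion when `qry_gap - ref_gap >= 50` (the full query gap sequence is
kept as the ALT allele), deletion when `ref_gap - qry_gap >= 50`, and
otherwise (both sides below 50 bp) aligned base by base into SNVs and
left-aligned small indels. A netted minus-strand chain spanning more than
10 kb is an inversion; a netted chain placed on a different query
chromosome than the reference chromosome's dominant partner and spanning
more than 100 kb is a translocation. Positions follow VCF: the last
matching base before the event, 1-based.

Cross-sample merging is single-linkage clustering of same-type records
whose start breakpoints lie within 1 kb and whose sizes agree by at least
50% reciprocally. The 1 kb / 50-bp values follow the published
SURVIVOR-style merge line; the 0.5 reciprocal size rule is this package's
declared choice, configurable, since size-consistency behavior is not
printed in that line. The merged record takes the coordinates of the
contributing accession earliest in lexicographic order (a deterministic
tie-break); per-accession genotypes are 1 for contributors, missing where
the accession's net leaves the region unaligned (absence of evidence),
and 0 otherwise (absence of the allele). Merging is idempotent and
permutation-stable, which the tests assert directly.

**Feature classes.** Precedence: satellite (at least 80% of the variant
sequence is a tandem dinucleotide run, measured as the lag-2 self-match
fraction), tandem duplication (the variant sequence matches its flanking
context at 80% identity over 80% of its length; a local alignment fallback
absorbs the breakpoint rotation that tandem repeats allow), LTR-TE /
DNA-TE (for deletions, 50% coverage by reference TE annotations of the
class; for insertions, terminal-repeat structure of the inserted sequence
itself — long terminal direct repeats or 10-bp terminal inverted
repeats), gene fragment (50% exon coverage), complex (two or more classes
each covering 20%, implementing "more than two genomic features" as
at-least-two), else unclassified.

**Breakpoint ambiguity.** Insertions of tandem duplications and satellite
expansions have no unique breakpoint: any placement inside the repeated
unit yields the same sequence, and terminal-repeat TEs allow a rotation of
the reported allele. Accuracy is therefore measured with a positional
tolerance of one unit length for those two classes and exact (+-10 bp)
tolerance for everything else.

## Population-genetic estimators

All estimators are haploid adaptations, stated explicitly because the
common tools assume diploids: n is the number of non-missing accessions,
one haplotype each.

- **pi** per window: sum over sites of `2 p (1-p) n/(n-1)` divided by
  window length; equals the average pairwise difference per site (the
  tests verify the identity against an all-pairs count).
- **Fst**: Weir-Cockerham (1984) reduced to two variance components
  (among- and within-population allele-frequency variance; no
  within-individual term for haploids), window-weighted as the ratio of
  summed components, unclamped.
- **Tajima's D** with the standard a1..e2 constants; windows without
  segregating sites are missing, not zero.
- **LD r-squared** from haplotype counts directly (no EM — genotypes are
  haploid), binned by distance; the decay summary reports the first bin
  whose mean falls below a query level.
- **PCA / kinship** standardize each site to mean zero and unit variance
  (missing imputed to the site mean; monomorphic sites dropped);
  K = Z'Z/m has average diagonal near 1 and is the random-effect
  covariance of the mixed model.
- **Polarization** takes the outgroup allele as ancestral; sites with a
  missing outgroup call stay unknown and are excluded from derived
  spectra. Missing-data handling is complete-case for pi/Fst/D and
  mean-imputation only for PCA/kinship, matching common tool behavior
  while keeping the estimators unbiased.
- **Neighbor joining** is delegated to ape; the package contributes the
  allele-sharing distance and input validation.

## The linear mixed model

For each variant, `y = W a + x b + u + e` with `u ~ (0, sigma_g^2 K)`.
K is eigendecomposed once; data are rotated; the variance ratio
`lambda = sigma_g^2 / sigma_e^2` is profiled on the REML likelihood of the
rotated data by a log-spaced grid over 1e-5..1e5 refined with
golden-section search; GLS estimates and a two-sided Wald test (t with
n - c degrees of freedom) follow. Two modes: `pervariant` re-optimizes
lambda for every variant (GEMMA-like exactness, the default);
`null` optimizes lambda once under the covariates-only model and reuses
it, which turns the scan into vectorized weighted regression (EMMAX-like)
and is what the calibration experiments use at 50,000 tests. With K the
identity both collapse to OLS exactly, which the tests assert against
`lm()`. REML (not ML) is the declared likelihood flavor.

One practical caveat the miniature experiments exposed: when the kinship
matrix is computed from the same (small) chromosome being scanned, a large
inversion's tag-variant block dominates K and the model absorbs its own
signal (proximal contamination). The inversion-localization experiments
therefore use leave-one-chromosome-out kinship — relatedness estimated
from the chromosome not being scanned — which is also the better analogue
of a genome-wide K in which any single locus carries negligible weight.

Significance thresholds: the fixed secondary criterion is
-log10(p) = 5; the effective-tests mode estimates the number of
independent tests from the eigenvalues of the variant correlation matrix
(Li-Ji style, with eigenvalues rounded to 8 decimals before the
integer/fractional split so exact multiplicities are not destroyed by
floating-point noise).

## Trait genotyping and phenotype models

- **Copy number**: normalized ratio = mean target depth / mean single-copy
  control depth; class "+" strictly above the threshold (defaults 2 for
  the EPS-like locus, 15 for the ROQ-like locus). Scale-invariant by
  construction.
- **Inversion genotyping** from junction-orientation support: 1/1 when
  inverted-orientation support reaches 3 reads and reference-orientation
  support stays below 3; 0/0 mirrored; missing otherwise.
- **Incidence**: dead-or-wilt fraction per accession and batch (scores
  1 = resistant, 0 = dead/wilt); accession-batches under 20 seedlings are
  flagged. "Normalized" incidence for group comparisons is per-batch
  z-scores averaged across batches — the publication-side normalization is
  not specified, so this is a declared, configurable choice (raw means and
  rank normalization are offered).
- **Genotype combinations**: the eight TGG/TGA x E+/- x R+/- labels;
  groups under 10 accessions are excluded; pairwise two-sided Wilcoxon
  rank-sum tests (exact null up to group size 12 without ties, normal
  approximation with tie correction above) and a greedy compact-letter
  display at alpha = 0.05.

## SV-expression integration

Expression variation between two accessions is the Pearson distance
(1 - r) of their tissue profiles, computed per gene over the shared tissue
set; zero-variance profiles are excluded and counted. Genes are
partitioned by the presence of at least one insertion/deletion SV whose
genotype differs between the pair within 2 kb of the gene body; each
set's mean distance gets a percentile bootstrap CI (genes resampled with
replacement, default 10,000 draws) and the sets are compared by Wilcoxon.
The SV-genotype differential-expression rule is: two-sided t-test
p <= 0.05, fold change (larger group mean over smaller; direction
reported separately) >= 1.5, and the larger group-mean TPM >= 10 — the
TPM threshold applies to the maximum of the two group means, a declared
interpretation of a threshold whose attachment is not printed.

## The synthetic panel: what it emulates, and what it does not

`sim_config()` defaults define the study conditions: 8 inbred
(haploid-representative) accessions, 2 chromosomes of 1 Mb, 200 planted
SVs (deletions; TE insertions with LTR-like 300-bp terminal direct
repeats or DNA-type 10-bp terminal inverted repeats and lognormal lengths
peaking at 12 kb; tandem duplications; dinucleotide-satellite expansions;
one >100 kb translocation), one large inversion at carrier fraction
0.5044 linked to a binary fruit-colour trait, SNVs at 5 per kb and small
indels at 0.5 per kb with carrier counts drawn from a 1/i spectrum, a
copy-number-variable resistance cluster (high-copy fractions 36.21% and
28.16%, matching the published allele prevalences), and one outgroup
carrying the ancestral allele at every planted site plus outgroup-private
divergence so that a realistic fraction of sites cannot be polarized.

Placement rejects overlaps with a 500-bp buffer between events so the
truth stays unambiguous for the caller. Inside the inversion (and 2 kb
around its breakpoints) 70% of planted small variants respect the
haplotype structure an inversion imposes: they either arose on the
inverted founder copy (carriers = inversion carriers, 30% of linked
sites) or keep segregating only among non-carriers. This is what makes
the inversion miniature behave like the real system: tag variants
localize the trait signal at the locus, and carrier diversity collapses
inside the interval.

The colour model makes inversion carriers purple except for a 3.48%
exception rate (a stand-in for a second-locus loss-of-function on the
carrier background — the generative process behind the real exceptions is
not knowable from the source material, so this is a configurable stand-in,
not an inference) while non-carriers are purple at 49.11%. The incidence
model is epistatic: with the stop-codon allele (TGA) and neither
copy-number expansion, the group mean is 0.85; TGA with either expansion
0.60; functional (TGG) with either expansion 0.15; TGG without expansions
0.50. Batch effects (-0.05, 0, 0.02, 0.03) and binomial sampling of 24
seedlings per accession-batch add realistic noise; with the noise SD set
to 0 the rates equal the linear predictor exactly, which the closed-form
tests use.

Not emulated: read-level data (FASTQ), recombination/coalescent
genealogies, diploid heterozygosity, assembly errors, and repeat-induced
misassembly. Passing tests therefore demonstrate correctness of the
algorithms on clean assemblies with isolated, non-overlapping events —
they do not certify performance on real assemblies, where alignment
ambiguity in nested repeats is the dominant error source.

## Problem sizes and numerical choices

The test suite exercises a 6-accession 2 x 300 kb fixture for module
tests and the full 8-accession 2 x 1 Mb panel (200 SVs) for the
acceptance checks; mixed-model calibration uses n = 200 accessions with
50,000 variant-tests under a two-subpopulation null (background
heritability 0.4) and 100 seeds of causal-variant recovery at n = 200,
m = 300. These sizes were chosen so the whole suite completes in a few
minutes on one core while keeping every Monte-Carlo band comfortably
away from its threshold.

Numerical details worth knowing: k-mer codes are exact for k <= 26;
eigenvalues are clamped at zero before use; the golden-section tolerance
on log10(lambda) is 1e-4; the Jukes-Cantor correction is undefined at
proportions >= 3/4 and reported missing (so single-codon toys can have
missing Ks); Nei-Gojobori pathway averaging excludes paths through stop
codons unless every path is blocked; rounding of published percentages is
to 2 decimals, matching the printed values.

## Known limitations

- Translocation detection requires the moved segment to exceed 100 kb and
  relies on the dominant-chromosome heuristic; reciprocal or nested
  rearrangements are out of scope.
- Small-variant extraction aligns only gaps below 50 bp on both sides;
  divergent unalignable blocks between those sizes are skipped rather
  than force-aligned.
- The LMM uses a t-approximation for the Wald test and profiles lambda on
  a grid+golden scheme; likelihood-ratio and score tests are not
  implemented.
- Gene-family input is a membership count matrix; ortholog clustering
  itself is upstream tooling and deliberately not re-implemented.
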