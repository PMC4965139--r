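---
title: "Calling, typing and selection analysis of an A-to-I RNA editome"
author: "editome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, typing and selection analysis of an A-to-I RNA editome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The problem

Adenosine-to-inosine (A-to-I) RNA editing rewrites individual adenosines in
messenger RNA; because inosine pairs like guanosine, an edited site appears
in RNA-seq reads as an A>G mismatch against the genome (T>C when the host
gene lies on the minus strand). In coding sequence an edit may leave the
protein unchanged (synonymous) or substitute an amino acid (non-synonymous),
so the editome is a natural substrate for natural selection. `editome`
implements, as reusable R functions over pileup-derived read-count tables,
a complete desk-scale analysis of a multi-species insect editome:

1. a six-criterion editing-site **caller** with three independent
   false-positive estimators and a genotyping confirmation rule;
2. **annotation**: coverage-based UTR refinement and synonymous /
   non-synonymous classification of each CDS edit;
3. **conservation typing** of coding events over homologous gene families
   into three types;
4. the core **selection statistic** — observed versus all-possible editing
   frequencies — plus Nei–Gojobori Ka/Ks with 11-codon windows;
5. tissue/stage **presence profiling** with binary hierarchical clustering;
6. hypergeometric / binomial **enrichment** with Benjamini–Hochberg control;
7. a **synthetic-data generator** that emulates the statistical structure of
   the real data so every stage is testable without downloads.

Read alignment, FPKM quantification, ortholog clustering and RNA secondary
structure are out of scope: count tables, expression values and family
membership are consumed as inputs.

## The caller and its false-positive estimators

A site becomes a candidate event when, in at least 50% of samples
(`ceiling(sample_fraction * n)`; a single sample suffices when n = 1), it
has read depth ≥ 5, at least one supporting read more than 10 bp from both
read ends, at least two non-identical supporting reads, and a variance rate
within [1%, 90%] — both bounds inclusive, reading "between 1% and 90%"
inclusively — and the change is A>G in the orientation of the host gene.
Sites inside annotated genes inherit the gene strand; intergenic sites are
retained when the genomic change is A>G or T>C on either strand and are
reported with strand `"."`, since an unstranded library cannot resolve
them. "Non-identical reads" means reads with distinct alignment signatures
(start, CIGAR); the count-table dialect carries this as a precomputed
column, as it does the interior-read count, because read identity is not
reconstructable from a pileup. Whether the end-distance criterion requires
one or all supporting reads to be interior is genuinely ambiguous; we
adopt "at least one interior supporting read". A SNP-calling variant of the
filter (rate > 1% with no upper bound) is available as
`snpCallerParams()`.

Three estimators bound the false-positive rate:

* **Mismatch spectrum** (`mismatchSpectrum`, `backgroundFpRate`): with the
  change-type filter disabled, the proportions of the 12 ordered base
  changes are tabulated. Assuming all non-canonical mismatches are noise
  with equal per-type error rates, the expected spurious fraction inside
  the A>G class is `((1 - p_AG)/11) / p_AG`.
* **Editing-null contrast** (`nullSampleValidation`): at sites called in
  the wild type, a paired ADAR-null sample should show only the reference
  adenosine; covered positions with any non-reference reads are suspects.
  Uncovered positions are excluded from the denominator.
* **SNP cross-check** (`snpCrosscheck`): events coinciding with genomic
  A/G variants are flagged as possible polymorphisms.

The genotyping rule (`confirmByGenotyping`) confirms a site when cDNA shows
the edited allele (G/(A+G) ≥ 0.10) while gDNA is homozygous reference
(A/(A+G) > 0.90), or when the cDNA/gDNA odds ratio exceeds 3; zero
denominators in the odds ratio fall back to the threshold branch.

## Annotation

Gene models are held in a `GeneModelSet` (a `GRanges` of 1-based inclusive
CDS/UTR intervals plus a per-gene table); all internal arithmetic converts
through one adapter (`.cdsCoordinate`). `refineUtrs` extends each CDS into
contiguously covered flanking bases (depth ≥ 1, configurable), capped at
600 bp for 5'UTRs and 1400 bp for 3'UTRs — caps chosen because 95% of known
fly UTRs fall within them — and truncated at the nearest neighbouring gene
so refinement cannot run through an adjacent locus. Refinement is
idempotent and leaves models that already carry UTRs untouched.
`annotateRegion` gives every site exactly one label with precedence
CDS > UTR5 > UTR3 > ncRNA > intronic > intergenic, which matches
single-label accounting when isoforms or neighbouring genes overlap.
`classifyRecoding` substitutes G at the adenosine within its codon and
compares translations under the standard nuclear code; stop-loss changes
are labelled `stop_change` and kept out of both recoding bins.

## Conservation typing

Coding events are placed on their family's protein alignment
(`mapSiteToColumn`: the aligned column of the event's codon) and classified
(`classifyEventTypes`):

* **Type I** — the host gene is a singleton family;
* **Type III** — events sharing an aligned amino-acid column across at
  least two distinct members of a multi-member family (clustered
  deterministically as `family:column`);
* **Type II** — the remaining events in multi-member families.

The three types partition the CDS events, and classification is invariant
to input order. Conservation is judged at the aligned amino-acid column,
not the nucleotide, which is robust to synonymous divergence between
members; within-species paralog pairs may form a type III cluster, since
"at least two members" does not require two species. `bbhPairs` provides
bidirectional-best-hit ortholog pairing for outgroup-based Ka/Ks, with
lexicographic, flagged tie-breaking.

## The selection statistic

For each type, `enumeratePotentialEdits` classifies the A>G change of
*every* adenosine in the edited genes' CDS, giving the pool of possible
synonymous and non-synonymous edits; `selectionTest` compares the observed
frequencies `observed/possible` between the two classes with a 2×2
chi-square. The uncorrected Pearson statistic is the headline number and
the Yates-corrected one is reported alongside, because the original
convention is unstated and both satisfy the published bounds; Fisher's
exact test is substituted automatically when an expected cell drops below
5. A type whose non-synonymous frequency falls below its synonymous one is
purifying-like; the reverse is positive-like.

Ka/Ks (`ng86KaKs`) uses the Nei–Gojobori (1986) counting method with
Jukes–Cantor correction: per-codon synonymous site fractions averaged over
both sequences, multi-difference codons averaged over all minimal
substitution pathways (pathways through stop codons excluded, with a
fallback to all pathways when none is stop-free), mutations *to* stop
codons counted as non-synonymous when counting sites. We chose the
deterministic counting method over a maximum-likelihood codon model
deliberately: it is self-contained, exactly testable against pathway
enumeration, and adequate for the qualitative Ka/Ks < 1 contrast the
analysis needs; no branch-model or rate-correction refinements are
applied. Saturation (p ≥ 0.75 in a class) yields `NA` with a warning
rather than silently extrapolating. `windowKaKs` centres an 11-codon
window on each editing site's codon, truncating at sequence ends and
dropping gapped columns; windows with Ks = 0 are reported with an
undefined ratio rather than dropped.

## Profiles and enrichment

Presence of an event in a sample (`detectInSample`) requires depth ≥ 5, an
interior supporting read and two non-identical edited reads — the caller's
support criteria without the rate window. `editingLevel` is the edited-read
fraction. `clusterBinary` reproduces the published clustering recipe —
complete linkage on Euclidean distances over the binary presence matrix —
with labels sorted first so ties break deterministically;
`dendrogramNewick` exports trees. Median per-sample levels are computed
over detected events only, matching per-tissue box-plot conventions.
`kendallTauB` implements the tie-corrected tau-b used for the
editing-versus-enzyme-expression correlation; enzyme expression is
normalised to a configurable reference sample (`normalizeToReference`).
`stageDiff` differences presence calls between two conditions and
annotates gains/losses with type, level and host-gene expression; where an
expression summary is needed from coverage we adopt mean per-base depth
over the CDS, log-transformed by the caller of the plotting code.

`goEnrichment` tests each term by the exact hypergeometric tail in both
directions with BH adjustment; terms need at least 2 set genes and 5
universe genes (a stricter preset requiring > 4 set genes is available),
and ontology root terms are excluded. Annotations are used as given — no
ancestor propagation, and no length-bias correction. `domainEnrichment`
tests event counts inside a domain family's intervals against the
background proportion of domain length in total gene length via the exact
binomial tail (a position-hypergeometric formulation is available behind
`method = "hypergeometric"`); families need more than 4 events.

## The synthetic-data generator

`simConfig()`/`generateTruth()`/`simulateReadCounts()` create a ground
truth whose statistical structure mirrors the real study: seven species;
families built by duplicating an ancestor CDS and applying
synonymous-biased point mutations per branch (rate 0.01/site, 80%
synonymous), so alignments are gap-free and exercisable without an
aligner; about 10% singleton families; per-gene event rates of 1.5 (type
I, matching ~206 events over 133 singleton genes), 1.0 (type II) and 0.5
(type III); recoding bias — the odds multiplier on non-synonymous
candidate adenosines — of 0.3 for types I/II and 2.0 for type III, so the
generator plants the purifying/positive contrast the pipeline should
recover; editing levels from Beta(2, 2) (no distributional form is
published; the Beta law is an explicit, configurable assumption);
negative-binomial depth with mean 50 and size 10, an Illumina-scale error
rate of 0.1%, sparse A/G SNPs at heterozygous or homozygous frequency, and
one ADAR-null sample modelled as the wild type with all levels forced to
zero. Stop-loss adenosines are never chosen as targets by default. Type
III clusters reserve their alignment column family-wide and type II events
avoid used columns, so the generated truth re-classifies to its own labels
exactly. Edited-read counts are binomial at the true level over the drawn
depth; every record carries distinct-read and interior-read counts so the
caller's support criteria are exercisable end to end.

What the generator does *not* emulate — alignment artifacts, splicing,
indels, coverage autocorrelation along transcripts, strand-biased error —
bounds what green tests mean: they validate the statistical machinery and
its contracts on data satisfying the model's assumptions, not robustness
to real mapping pathology.

## Numerical and design choices

* Coordinates are GFF3 1-based inclusive externally; conversions live in
  one internal adapter.
* Variance-rate bounds are inclusive at both ends.
* The caller's alt base is the largest non-reference count, ties broken in
  A,C,G,T order.
* Determinism: every stochastic routine derives from the single config
  seed (truth from `seed`, read simulation from `seed + 1`), and reruns
  are byte-identical, including the pipeline's JSON summary.
* Degenerate inputs fail loudly: empty sample lists, zero-coverage levels,
  all-tied tau-b vectors, zero possible counts and unwritable bundle
  directories all raise errors rather than returning silent zeros.

## Problem sizes used by the test suite

The suite regenerates everything it needs: most unit fixtures are tiny
hand-built loci; property suites use 60-family bundles (~160 genes), the
parameter-recovery check runs the full caller→typing→selection chain on
twenty 300-family bundles at the default study conditions, the recoding
equivalence suite uses 10,000 random codons against a whole-protein
translation oracle, and the Ka/Ks suite enumerates all sense-codon pairs
with up to two differences against an exhaustive pathway oracle. These
sizes were chosen so that each statistical check has clear power while the
whole suite stays comfortably interactive.

## Known limitations

* Strand assignment for intergenic sites is a convention, not an
  inference; antisense transcription is invisible to the pipeline.
* Conservation typing requires family alignments as inputs and judges
  identity at the amino-acid column; nucleotide-level conservation is not
  distinguished.
* GO annotations are tested as given, without graph propagation.
* The enrichment modules assume a closed universe; genes absent from it
  are an error, not silently dropped.
* The Ka/Ks module is a counting method: for deeply diverged pairs a
  likelihood codon model would be preferable.
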