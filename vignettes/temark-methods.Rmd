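---
title: "Methods: TE discovery, dating, marker design and diversity analysis"
author: "temark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE discovery, dating, marker design and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(temark)
  library(GenomicRanges)
})
```

temark is a toolkit for genome-wide transposable-element (TE) marker
development in plant genomes: it discovers full-length LTR
retrotransposons structurally, annotates other repeats by homology, dates
LTR insertions from the divergence between their paired terminal repeats,
designs six classes of TE-based PCR markers, and analyses the resulting
dominant (band presence/absence) genotype data with Jaccard distances,
neighbour-joining trees and a Bayesian clustering model.  This vignette
explains the models and conventions behind each stage, the parameters that
matter, and what the synthetic-data tests do and do not demonstrate.

## Coordinates and containers

All intervals inside the package are Bioconductor-native: 1-based,
inclusive `GRanges`.  GFF3 input and output therefore round-trips without
any coordinate shifting.  The only 0-based quantity is a *junction
position*: a junction sits between two bases, and we store it as the
number of bases to its left, which equals both the 1-based end coordinate
of the left-hand block and the BED-style boundary coordinate used when
junctions are exported as BED.

## Structural discovery of full-length LTR retrotransposons

A full-length element is defined structurally: two long terminal repeats
(LTRs) of 100–3,500 bp, each starting with `TG` and ending with `CA`,
separated by an internal region of at most 10,000 bp, usually flanked by a
4–6 bp target-site duplication (TSD), with a primer-binding site (PBS)
just inside the 5' LTR and a polypurine tract (PPT) just inside the 3'
LTR.

`findLtrPairs()` implements a seed-and-extend search:

1. every exact 20-mer that recurs at a compatible distance seeds a
   candidate LTR pair (both copies lie on one diagonal because the
   pairwise alignment of two LTRs of the same element is gapless under
   the substitution-only divergence model we target);
2. each seed is extended in both directions while the identity in a 20 bp
   sliding window stays at or above `min_ltr_identity` (default 0.80);
3. boundaries are snapped to the nearest position where *both* copies
   present the terminal dinucleotides (`TG` at the start, `CA` at the
   end) within ±15 bp — requiring the motif on both copies makes a
   spurious snap vanishingly unlikely (probability 16^-2 per offset);
4. candidates violating any part of the structural definition are
   dropped, and overlapping candidates are resolved by the
   identity x LTR-length score, ties to the leftmost start.

Two readings of the "maximum distance between LTRs" bound are defensible:
the gap between the LTRs or the whole element span.  The default is the
gap (`distance_mode = "gap"`), which accommodates the long (>20 kb)
elements seen in grass genomes; `distance_mode = "span"` is available.

TSD detection searches lengths from 6 down to 4 for an exact match
between the windows immediately flanking the element.  PBS detection
looks for a contiguous match of at least 12 bp between the 20 bp window
downstream of the 5' LTR and the reverse complement of a tRNA 3'
terminus; the bundled tRNA library is a minimal synthetic set (three
entries ending in CCA) that users should replace with a species-specific
library for real genomes.  PPT detection reports the longest run of at
least 15 bp with purine fraction at or above 0.80 (inclusive) in the
20 bp upstream of the 3' LTR.  Superfamily classification translates the
internal region in all six frames and orders short peptide consensus
motifs: integrase before reverse transcriptase means Copia, the reverse
means Gypsy, anything else is unknown.  The built-in motifs are a minimal
consensus set; `classifySuperfamily()` accepts user-supplied motif
vectors.

## Homology annotation and repeat junctions

`maskWithLibrary()` delegates the local alignment to NCBI `blastn`
(word size 11, low-complexity filtering disabled so that simple repeats
are not masked away), keeps hits with e-value at most 1e-5, and flags the
best hit per locus as a *top* hit only when its e-value is at most 1e-50
— the two-tier cutoff that suppresses false-positive repeat junctions.
Collinear same-family fragments within 50 bp are merged
(`mergeFragments()`), and `callSoloPartial()` classifies LTR-class hits
confined (at least 90%) to the library entry's annotated LTR sub-interval
as solo LTRs; hits covering less than 90% of their library entry
(inclusive boundary) are partial.  There is no published threshold for
the full/partial boundary, so 0.9 is a configurable curation convention.

Junctions are emitted at every boundary of the overlap-resolved
annotation set: boundaries abutting unannotated sequence are
`repeat_unique`, boundaries shared by two annotations are
`repeat_repeat` (emitted once), and contig-end boundaries are
suppressed.

## Insertion-time dating

The two LTRs of an element are identical at insertion and accumulate
substitutions independently, so the insertion age is `T = d / (2r)` for
divergence `d` and substitution rate `r`.  `dateElements()` aligns the
LTR pair globally (match +2, mismatch -2, gap open -5, gap extend -1) and
supports four divergence measures: raw `p`, Jukes–Cantor, Kimura
two-parameter (the default — LTRs are non-coding, so a transition/
transversion-aware nucleotide distance is the natural choice) and
`ngKs`, the Nei–Gojobori (1986) synonymous distance computed by reading
the LTR alignment in frame — provided because Ka/Ks-calculator-based
pipelines have dated LTRs this way; codon columns showing a stop on
either sequence are excluded before the NG86 machinery applies.  The
default rate is 1.3e-8 substitutions/site/year, a commonly used rate for
grass intergenic DNA; it is configurable and no published rate is implied
for any particular genome.  Saturated pairs are reported with a status
flag, never dropped silently.

The NG86 implementation counts synonymous sites per codon as the
per-position fraction of counted one-step changes that are synonymous,
excluding changes to stop codons from the counted set; observed
substitutions are averaged over all mutational pathways between each
codon pair, excluding pathways through stops and renormalising.  These
conventions are the original ones and make the counts deterministic;
tests verify exact agreement with an independent pathway-enumeration
oracle.

## The six marker classes

The marker taxonomy is operational, fixed by this package (upstream
pipelines never published formal definitions; the ISBP-over-RJM
precedence below is our convention):

* **RJM** – one primer wholly inside a repeat of any class, its mate in
  the unique flank; the amplicon spans exactly one repeat/unique
  junction.
* **ISBP** – the same geometry where the repeat side is an LTR
  retrotransposon; takes precedence over RJM at such junctions.
* **RJJM** – the amplicon spans exactly two adjacent junctions (e.g. a
  short repeat with unique flanks).
* **RBIP** – three primers: flanking primers converging across the
  insertion site plus a `te_internal` primer in the 5' LTR.  Both
  diagnostic products are recorded: occupied site (flank + TE) and empty
  site (flank + flank).  The empty allele assumes clean excision leaving
  one TSD copy (`empty_site_tsd = "zero"` models footprint-free loss).
* **IRAP** – outward-facing primers in the facing LTRs of two elements
  whose gap is at most 3,000 bp.
* **REMAP** – an LTR primer paired with an anchored microsatellite
  primer (the SSR motif repeated to at least 18 bp plus one 3' anchor
  base) for SSRs within 2,000 bp of an LTR terminus.

Primer picking enumerates all window substrings satisfying length
(18–27, optimum 20), GC (40–60%) and homopolymer (max 4) constraints,
computes melting temperatures with unified nearest-neighbour
thermodynamics (50 mM monovalent salt, 50 nM oligo; the Wallace rule is
available for cross-checks) and minimises
`|Tm - 60| + 0.5 |len - 20|`, ties to the leftmost start.  Products must
fall in 100–1,000 bp for junction markers and RBIP; IRAP and REMAP
products are bounded by their own distance caps instead, since a
1,000 bp cap would contradict the 3,000 bp IRAP gap allowance.

`inSilicoPcr()` finds all binding sites (the 3'-terminal base must match
even when internal mismatches are allowed) and reports every convergent
pair within the size cap.  Every designed marker satisfies a *closure*
property — it re-amplifies exactly its recorded product on the source
genome — and `checkUniqueness()` re-screens each marker genome-wide with
2 mismatches tolerated, flagging it unique only when all products fall
in a single locus.  Markers amplifying multiple loci are kept but
flagged, so unique fractions can be reported.

## Nested TEs, intronic insertions, densities

A TE is *nested* when it lies strictly inside a different-family
annotation, or when it exactly fills the gap between two collinear
same-family fragments of a split host.  Events are grouped per host, so
several inserts in one host form one event.  Intron-insertion tables
count, per chromosome and per class (superfamily for retroelements,
subclass for DNA transposons), the genes whose introns a TE overlaps by
at least 1 bp; a gene counts once per class regardless of how many
insertions hit it.  Whether such tables should count genes or events is
ambiguous in common usage, so both modes are implemented
(`mode = "genes"` is the default, following the "interrupted genes"
reading).  `densitySummary()` reports per-chromosome counts, class
percentages and per-Mb densities.

## Diversity and population structure

Dominant marker data are 0/1 band scores; co-migrating bands are assumed
to come from one locus, implemented as single-linkage clustering of band
sizes with a 10 bp link tolerance.  Pairwise similarity is Jaccard's
coefficient (shared presences over all loci where at least one of the
pair shows a band; 0/0 and missing loci excluded), and trees are built
by neighbour joining.  Two variants are provided: classic Saitou–Nei NJ
(via ape) and UNJ, the variant in which every taxon receives equal
weight — pair selection uses the cluster-level NJ criterion (consistent
on additive matrices), while branch-length estimation and the distance
reduction weight clusters by taxon counts.  Negative branch lengths are
clamped to zero with a warning.  Bootstrap support resamples loci with
replacement (1,000 replicates by default) and reports the percentage of
replicate trees containing each bipartition of the full-data tree.

`structureNoAdmixture()` is a Gibbs sampler for the no-admixture model
recommended for dominant loci: each individual carries one latent
cluster (uniform prior) and each cluster has independent Beta(lambda,
lambda) band-frequency priors with lambda = 1.0 by default.  Band
frequencies are modelled directly as Bernoulli parameters rather than
through diploid genotype deconvolution — with dominant data the
heterozygote is unobservable and the band-frequency parameterisation is
the identifiable one.  The correlated allele-frequency (F-model) prior
of STRUCTURE is *not* implemented; its prior settings are accepted in
the configuration for compatibility and ignored with a warning.
Ln P(D) is estimated as `mean(lnL) - var(lnL)/2` over post-burn-in
sweeps (the STRUCTURE approximation, kept for delta-K comparability),
and label switching is resolved per sweep by canonical relabelling
before membership probabilities are averaged.  Chains are initialised
from a k-means partition of the band matrix (missing entries imputed
with locus means): under this Gibbs scheme a cluster that empties can
essentially never refill, so a data-informed start avoids chains stuck
in merged-cluster modes; run-to-run variation in Ln P(D) then reflects
Monte-Carlo noise around the dominant mode, which keeps the delta-K
denominator meaningful.  Default chain lengths are 200,000 burn-in plus
200,000 recorded sweeps; the package's own validation uses
5,000 + 5,000, which is ample for the strongly structured matrices it
simulates.  The Evanno delta-K statistic
(`|L''(K)| / sd(L(K))`, maximised over interior K) selects the number of
clusters from replicate runs.

## The synthetic-data generator

Every stage is validated against genomes and genotype matrices with
planted ground truth.  `plantLtrElement()` builds
`[TSD][LTR5][internal][LTR3][TSD]` with the internal region carrying a
PBS complementary to the bundled tRNA-iMet terminus, superfamily-ordered
domain motifs (encoded with randomly chosen synonymous codons so that
repeated elements do not share nucleotide-level k-mers) and a 16 bp
purine PPT; the 3' LTR is the 5' LTR mutated at a chosen per-site
substitution rate with the terminal dinucleotides protected, so planted
elements always satisfy the structural definition and boundary-detection
accuracy can be scored separately from the terminus rule.  DNA
transposons carry inverted terminal repeats and exact TSDs and may be
planted inside existing elements, recording the nesting.  Genotype
matrices plant K clusters of individuals with block-structured band
frequencies (`freq_in` = 0.9 at a cluster's own loci, `freq_out` = 0.1
elsewhere in the reference conditions).

The reference validation conditions are: 200 kb genomes with 10 planted
elements (LTR 300 bp, internal 2 kb, divergence 0.02, TSD 5 bp) across
20 seeds for detection (recall and precision at least 0.9, boundaries
within 5 bp); 50 replicate elements at divergences 0.01/0.02/0.05 for
dating (median within 15% of `d/2r`); and 90 individuals x 100 loci with
planted K = 3 for clustering (delta-K argmax = 3 in at least 8 of 10
repetitions, assignment accuracy at least 95%).

The generator deliberately omits several features of real genomes:
indels (divergence is substitution-only, which is why the detector's
gapless extension is appropriate for the tests), TE family phylogenies
and solo-LTR formation by recombination, GC heterogeneity and
low-complexity tracts, and linkage or admixture in the genotype model.
Passing the planted-truth tests therefore demonstrates algorithmic
correctness under the stated model, not sensitivity parity with
LTR_FINDER/RepeatMasker on real, indel-rich, deeply decayed repeat
landscapes.

## Numerical and degenerate-input conventions

Saturated distances (p >= 0.75 for JC, log-domain violations for K2P,
pS or pN >= 0.75 for NG86) raise errors at the operation level and are
reported with a `saturated` status in batch dating.  Alignment
tie-breaking is delegated to the deterministic dynamic-programming
implementation; NJ tie-breaking takes the lowest-index pair; overlap
resolution everywhere is best-score-first with leftmost-start ties.
Empty inputs return empty, typed results (no candidate LTRs, header-only
marker tables); an all-zero individual pair makes the Jaccard
coefficient undefined and raises an error naming the pair; delta-K
requires at least two runs and non-zero run-to-run variance at interior
K.  Beta draws in the Gibbs sampler are clamped away from 0/1 by 1e-12
to keep log-likelihoods finite; all sampler randomness derives from R's
RNG stream, so `set.seed()` reproduces chains exactly.

## Known limitations

* The structural detector targets substitution-diverged LTR pairs; long
  indels between the LTRs of one element break the single-diagonal
  assumption and can split or miss elements.
* E-values come from BLAST; no attempt is made to re-derive
  Karlin–Altschul parameters, and sensitivity is bounded by blastn's
  seeding.
* Primer thermodynamics ignore secondary structure and primer-dimer
  screening; no exact Primer3 parity is attempted.
* The clustering model is the independent-frequency no-admixture model;
  admixed individuals and correlated frequencies (the F-model) are out
  of scope, as are linkage models.
* Absolute insertion ages inherit the uncertainty of the substitution
  rate; only the divergence-to-age arithmetic and the recovery of
  planted divergences are validated.
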