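---
title: "Screening proteomes for opsin-related proteins: methods and design"
author: "orpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for opsin-related proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orpscan)
```

## The problem

Type 1 (microbial) opsins photosense through retinal bound covalently to a
conserved helix-7 lysine (bacteriorhodopsin numbering K216). Opsin homologs
that lack this lysine — opsin-related proteins, ORPs — cannot form the
Schiff-base linkage and, where their retinal-binding pocket has eroded as
well, are unlikely to hold retinal at all. The screen implemented here asks,
for any annotated proteome: which proteins are opsin homologs; which of
those lack the Schiff-base lysine; what replaced it; what do the
retinal-pocket and signal-transduction positions look like; what genes are
the ORP loci sitting next to; and can the genome even make retinal
(*crtY* + *brp*)? Absorbance spectra of purified candidates can then settle
whether a protein is retinal-bound (a 480–580 nm band) or apo.

## Homology search and the domain gate

Queries are aligned to one packaged exemplar per haloarchaeal opsin family
(BR, BR2, HR, SRI, SRII, SR3, MR) by semi-global (free-end-gap) alignment,
BLOSUM62, gap open 11, gap extension 1 (a length-k gap costs 11 + k).
Semi-global is the right mode because the opsin domain spans most of these
short (~230–300 aa) proteins. A hit must satisfy three conditions, each a
config key of `screenConfig()`:

* identity over aligned columns ≥ `minIdentity` (0.25),
* query coverage ≥ `minCoverage` (0.5),
* a profile score ≥ a decoy-calibrated cutoff.

The profile is a per-column log-odds model (uniform 1/20 background,
pseudocount 0.5, columns over 50% gaps dropped) built from the packaged
panel alignment, and plays the role of a rhodopsin-domain scan. Because
E-value statistics for gapped profile scores have no closed form, the cutoff
is calibrated empirically: 200 seed-fixed dipeptide-shuffled decoys (shuffling
two-residue blocks preserves local composition bias) are scored against the
profile, and the gate is the decoy mean + 4 SD (`preset = "standard"`) or
+ 6 SD (`"strict"`). The strict preset is used for the retinal-biosynthesis
genes, where a conservative call is wanted; since those ship as single
exemplars rather than alignments, their gates are calibrated on pairwise
alignment scores of shuffled decoys instead of profile scores. The
calibration seed (101) is itself a config key, so gates are reproducible and
independent of the data seed.

## Anchoring, fingerprints, classification

Every hit is anchored to the SRII exemplar by semi-global alignment, giving
a map from reference numbering to query positions. The fingerprint schema
reads eleven positions: signaling Y51, R72, D189, Y199; retinal pocket W76,
V108, F127, W171, Y174, W178; and the Schiff-base lysine column, reported
under the conventional label 216. Numbering schemes drift between family
members, so the Schiff column is defined *structurally* — it is the lysine
column of the packaged reference alignment — and the packaged SRII exemplar
is constructed so that the schema numbering holds literally. Anchoring
refuses queries below 15% identity ("unanchorable"), since a map that poor
carries no positional information.

Classification is a partition:

* K at the Schiff column → canonical; the family label is that of the
  nearest reference by alignment score (a desk-scale stand-in for tree
  clade affiliation, corroborated by the NJ monophyly check below);
* any other residue → ORP; R → group A, a residue in the hydrophobic set
  → group B, anything else → group unassigned;
* a gap → unassigned entirely: a truncated protein is not evidence of a
  substituted Schiff base.

The hydrophobic set defaults to {L, I, V, M, F, A} and is a config key.
G is excluded because glycine appears as a planted pocket replacement at
other fingerprint columns and its flexibility makes it a poor "hydrophobic
residue" witness; W is excluded as aromatic-bulky. The per-class
conservation report (modal residue and fraction per schema position) makes
the pocket-erosion pattern visible across classes.

## Genome context

For each ORP locus the neighborhood is the `windowGenes` (10) genes on each
side on the same contig, with signed gene-rank distances. Products are
categorized by case-insensitive substring match against an editable
vocabulary TSV, first match wins in priority order transducer >
taxis_operon > stress. The rules: a transducer within rank
`adjacencyRank` (1) → `transducer_adjacent`; else ≥ 2 taxis-operon genes
within `proximityRank` (10) → `taxis_operon_proximal`; else ≥ 1 stress gene
within the same window → `stress_proximal`; else `unlinked`. "Adjacent"
means zero intervening genes, either strand — strand is recorded but not
required, because the biological claim is adjacency, not operon prediction.
These two ranks are deliberately exposed as config keys since "adjacent"
and "proximal" are conventions, not measurements.

## Pathway co-occurrence

A genome is retinal-capable iff both *crtY* and *brp* pass the strict gate;
*crtE*, *crtB*, *crtI* are detected and reported too, so the expectation
that capable genomes carry the full complement stays checkable on any
input, and a partial complement (e.g. *brp* without *crtY*) is flagged.
The cross-tabulation builds a genomes × {families, ORP groups, crtY, brp}
count matrix (serializable as TSV and iTOL `DATASET_BINARY`) and reports
the genomes whose opsin complement is ORP-only, and among them the count
lacking retinal capability — the co-occurrence signal that makes
retinal-independent function plausible.

## Distance phylogenetics

Hits are projected onto reference coordinates (the anchoring alignment
already provides the residue per reference column), giving an equal-length
pseudo-alignment without a separate MSA step. Distances are p-distances
with pairwise gap deletion — fragmentary queries would otherwise erase
whole columns for everyone — with optional Poisson correction −ln(1−p)
(an error at p ≥ 1, "saturated"). Trees come from neighbor joining
(`ape::nj` behind the package's validated surface); negative branch-length
estimates are clamped to zero with the clamped amount moved to the sibling
edge, the standard practice, with a warning. Monophyly of a label set is
tested as an unrooted bipartition: root at any leaf outside the set, then
test the rooted clade. NJ is consistent on additive distances, which the
test suite exercises by exact recovery of random trees.

## Spectral calling

Spectra are background-subtracted and normalized to the expression
control's A280 (or to the sample's own A280 when no control is supplied —
flagged `selfNormalized`, an extension for runs without a control). The
bound/apo decision uses *integrated band prominence*: the mean absorbance
over the 480–580 nm window minus a baseline interpolated from two flank
anchors (mean absorbance within 15 nm of each window edge), standardized by
its exactly propagated noise SD, with the raw noise SD estimated from the
detrended 600–800 nm region, which lies outside opsin absorption. The call
threshold is `minProminenceSD` = 3.

Why integrated rather than "highest point in the window"? A max statistic
over ~50 grid points multiple-tests itself: with i.i.d. noise its
false-positive rate at 3 SD is ~7%, an order of magnitude above the ~0.1%
a 3-SD rule advertises, and smoothing wide enough to fix that smears
out-of-window shoulders into the window. A canonical opsin band (σ ≈ 30 nm)
spans most of the window anyway, so integrating is the matched detector:
the statistic is a single linear functional of the data, its null SD is
exact, the false-positive rate on flat noise is the nominal Φ(−3) ≈ 0.13%
(measured 0.1% over 1000 simulated spectra), and a band centered below the
window only raises the left flank anchor and is rejected. λmax is read from
the boxcar-smoothed (30 nm) in-window maximum, which stays unbiased even
when the band's tail crosses the window edge — the chord-excess argmax does
not. Detection is invariant under positive scaling of the whole spectrum,
and the window, noise region, threshold and smoothing width are config keys.

## The synthetic study

`generateBundle()` emulates the statistical structure the screen assumes,
with planted truth for every stage. Defaults define the study conditions:
25 opsins (BR 3, BR2 2, HR 3, SRI 3, SRII 3, SR3 2, MR 1, ORP_A 4,
ORP_B 4), 10 dipeptide-shuffled decoys, 10 genomes of which the trailing 3
are ORP-only and pathway-free, a 5% per-residue background substitution
rate on family backbones, 2% on planted crt genes, spectra on the
250–800 nm / 2 nm grid with noise SD 0.005 and a 0.3-amplitude band for the
bound control. Fingerprint positions are protected — restored after
background mutation — except where the class plan rewrites them: group A
plants Schiff→R, 76→D, 174→L, 178→A and leaves Y51/R72 exposed to drift;
group B plants Schiff→L, 174→L, 178→G, 127→T and preserves all four
signaling positions. Both groups are planted from a shared ORP ancestor
(the SRII backbone with 10% extra divergence, fingerprint intact), so the
planted ORPs form a distinct lineage sister to the sensory opsins rather
than scattering among SRII-derived sequences — matching the evolutionary
scenario the screen is meant to detect. Neighborhoods are laid out in
25-gene blocks per planted locus (category genes within rank 6 of their own
target, blocks far enough apart that neighborhoods cannot bleed), with
neutral filler products chosen to avoid every vocabulary keyword.

Everything derives from one config seed; the same seed and config give
bit-identical FASTA, GFF and spectra. What passing on this bundle shows:
the pipeline's rules and plumbing are correct, recovery is complete at
realistic within-family divergence, and degrades monotonically as the
background rate rises toward 30%. What it does not show: performance on
real annotation noise (miscalled starts, fragmentary genes, vocabulary
mismatches), on indel-rich divergence (the generator plants substitutions
only), or on families absent from the reference panel. The packaged panels
are themselves synthetic constructions (filenames say so); screening real
proteomes should substitute real family exemplars via the `path` arguments.

## Numerical choices and degenerate inputs

* Alignment scores are integers under BLOSUM62; ties between references go
  to the lexicographically smallest id for determinism.
* Non-canonical residues B/Z/U/J become X (scored 0 against the profile,
  substitution-matrix X column otherwise) with a warning.
* Empty proteomes search to empty results; an empty proteome *set* is an
  error before any stage runs.
* Per-genome failures inside `runScreen()` are caught, recorded in the
  summary, and do not stop the other genomes.
* Distance computation errors on pairs with zero comparable columns rather
  than inventing a distance; Poisson correction errors at p ≥ 1.
* A two-taxon NJ "tree" is represented as two half-length pendant edges so
  path length equals the input distance.
* All validation problem sizes (length ≤ 4 oracle pairs over a 3-letter
  alphabet, 50 additive trees at n ≤ 8, the 35-protein bundle, 200
  noise spectra) were chosen as the smallest sizes that still exercise
  every code path of the stage under test.

## Known limitations

Family assignment by nearest reference is a heuristic; it is corroborated,
not replaced, by the NJ monophyly check, and genuinely novel families
outside the panel will be absorbed by their nearest relative or dropped at
the gate. The profile gate is calibrated against shuffled decoys, not true
non-opsin membrane proteins, so its separation on real proteomes depends on
the panel's breadth. Context classification is keyword-based and inherits
the annotation vocabulary's quality. The spectral caller assumes
approximately white noise in the 600–800 nm region and a single band in the
window; structured baselines (scattering tails) would need the background
spectrum to carry them.
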