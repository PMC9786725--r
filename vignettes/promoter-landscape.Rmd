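---
title: "Methods: the baculovirus promoter landscape in baculoprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the baculovirus promoter landscape in baculoprom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculoprom)
```

# The setting

Baculovirus late genes are transcribed by the viral RNA polymerase, which
initiates within a 5′-TAAG-3′ motif; the first A of the motif is the +1 of
the transcript, and the 5′UTR runs from there to the ATG start codon. Host
RNA polymerase II promoters, by contrast, are marked by TATA and CAGT
(initiator) motifs. On a circular genome of ~150 ORFs such as AcMNPV,
transcript abundance spans orders of magnitude, and the questions this
package operationalises are: which sequence features co-vary with
abundance class — promoter motif usage, 5′UTR length and A+T content,
distance to homologous-repeat (hr) enhancer/origin elements, candidate
regulatory octamers upstream of the TSS, and the conservation of the
sequence context around the translation and transcription start sites.

The package is an analysis layer, not an annotation tool: it consumes an
annotated genome (GenBank flat file), a per-ORF RPKM table and a TSS
table, and computes classes, regions, scans, statistics, distances and
consensus calls deterministically from them.

# Coordinate conventions

All coordinates are 1-based, fully closed intervals on the plus strand
(the GenBank convention). A minus-strand ORF's *coding start* is the
genomic position of the A of its ATG, i.e. the numerically larger end of
the plus-strand interval. On circular genomes an interval may wrap the
origin; it is represented as `(start, end, wraps = TRUE)` with
`end < start`, and its sequence is the chromosome tail followed by the
head. The one origin-spanning feature a GenBank `join()` can describe is
unrolled past the origin internally.

Anchored numbering never uses a position 0:

* **TIS flank**: the A of the ATG is +1, the base before it −1. The
  default window −10..+6 covers all positions discussed for translation
  initiation context (notably −7..−2 upstream and +4/+5 inside the CDS).
* **TSS flank**: the first A of TAAG is +1, the T of TAAG is −1, so TAAG
  occupies −1, +1, +2, +3. The default window −15..+15 covers the
  positions relevant to late promoter activity (−12..+12).
* **5′UTR**: the bases strictly between the last G of TAAG and the A of
  ATG, both excluded; length may be 0.
* **Upstream window**: the `window` bases immediately 5′ of the T of
  TAAG, TAAG excluded. The shipped default is 225 nt: the literature
  describes the searched region as approximately 225 nt, so the round
  figure is the default and the width is a parameter.

When an ORF carries several TSS annotations, extraction and consensus
default to the TSS nearest the ATG — the biologically conventional choice
for late genes, and the documented tie-break for everything downstream.

# Expression classes

The shipped scheme has five classes with bounds read as lower-inclusive
and upper-exclusive: Very High (RPKM ≥ 50,000), High [20,000, 50,000),
Medium [10,000, 20,000), Low [1,000, 10,000), Very Low (< 1,000).
Published range tables of this kind are often typographically inconsistent
about which end is closed; lower-inclusive is the reading consistent with
an unambiguous "≥ 50,000" top class, so a boundary value such as 20,000
falls in the higher class. The scheme is a plain data.frame and fully
configurable; validity checks enforce contiguous, non-overlapping coverage
of `[0, ∞)`. ORFs without an RPKM value are reported as unclassified
rather than forced into a class — real annotation sets routinely contain
more ORFs than the abundance table covers, and silently dropping or
force-classing them would bias every per-class statistic.

# Motif scanning

The scanner counts substitutions only (Hamming distance, no indels): at
every start position the window is compared to the query and reported when
the mismatch count is within the tolerance. Design choices, each of which
affects printed totals and is therefore explicit:

* **Overlapping matches all count.** Background rates are per-position
  quantities; deduplicating overlaps would make them depend on match
  geometry.
* **Both-strand scans are two independent strand scans.** A position where
  both strands match counts twice; palindrome-aware deduplication is
  deliberately not performed. Reverse-complementing the query therefore
  exactly swaps the per-strand counts — a tested invariant.
* **Circular genome scans include origin-spanning windows** (start
  positions stay in `[1, L]`); extracted regions are already linearised,
  so region scans are linear.
* **Degenerate IUPAC letters are allowed only at 0 mismatches**: a
  degenerate position matches its base set, but combining degeneracy with
  a mismatch budget would make the mismatch count ambiguous, so it is
  rejected.

The per-position chance of a fuzzy hit under an i.i.d. background is the
composition probability summed over the query's Hamming ball; for an
octamer at d ≤ 2 the ball has `1 + 8·3 + 28·9 = 277` members, so a uniform
background yields 277/4⁸ ≈ 0.0042 per position per strand. This closed
form (generalised to arbitrary base composition in
`expectedHitProbability()`) is what the null-genome calibration tests the
scanner against, and it is the right yardstick for judging counts in a
225-nt window: an A+T-rich viral genome yields roughly 2–3 fuzzy octamer
matches per window by chance.

## Octamer spacing conventions

Distances between a matched octamer and its anchors are reported under a
single documented convention: the count of nucleotides strictly between
the octamer's 3′ end and the anchor base (A of ATG; T of TAAG). Under this
gap convention the tiling identity
`atg_gap − taag_gap = 4 + UTR length`
holds exactly for any octamer upstream of the TAAG, which makes the
arithmetic self-checking. Published spacing figures sometimes measure the
TAAG distance from the octamer's 5′ end instead; `taagFrom = "5p"`
reports that offset (it exceeds the 3′ gap by the octamer length), and the
genome-anchored checks use the 3′-gap convention for ATG distances and the
5′-end offset for TAAG distances, the combination under which all six
published p6.9/vp39 spacings are reproduced simultaneously.

# Composition statistics

A+T content is `(#A + #T) / length`, undefined for zero-length UTRs.
Between-class comparisons default to two-sided Welch t-tests: the classes
are small and unbalanced (5 to 65 members) with no variance-equality
justification. The literature this mirrors does not name its test, so the
Mann–Whitney U alternative is exposed via `method = "wilcox"`, and both
all-pairs and versus-reference modes exist because the compared pair set
is equally unstated. P-values are uncorrected by default (matching the
per-pair starring convention of the figures this reproduces); Holm
correction is one argument away. Stars: `*` p < 0.05, `**` p < 0.01.
Classes with fewer than two finite values are excluded with a warning
rather than producing degenerate tests.

# hr distances

The literal distance is `pos5′(hr) − pos5′(ORF)` with the ORF 5′ end taken
strand-aware (the coding start, not the plus-strand interval minimum).
Published sign glosses of this construction ("in front of" / "behind")
conflict with the subtraction itself for some layouts; the subtraction is
the only operational statement, so the implementation follows it literally
and documents the resulting meaning: positive when the ORF start sits at a
smaller genomic coordinate than the hr. Because a literal difference on a
circular chromosome can be large when the short way around is small, a
circular variant wraps the difference into `(−L/2, L/2]`; nearest-hr
assignment always uses the wrapped magnitude (proximity on a circle is
otherwise ill-defined) and breaks exact ties toward the lexicographically
lower hr id.

# Anchored consensus

TIS- and TSS-flank windows have fixed width and a fixed anchor, so
stacking them positionally *is* the multiple alignment — anchored
equal-length windows admit no meaningful gaps, and replacing a heuristic
gapped MSA with positional stacking makes the construction deterministic
and exactly reproducible. Per column: the top base is emitted when its
fraction reaches the plurality threshold (default 0.5; ties are resolved
to the minimal IUPAC code covering the tied bases, never arbitrarily);
otherwise the minimal IUPAC code covering all bases at or above the
secondary threshold (default 0.25), or N. Conservation flags mark top
fractions ≥ 0.5 (conserved) and ≥ 0.8 (highly conserved); the thresholds
behind published "highlighted"/"boxed" renderings are unstated, so 0.5/0.8
are explicit defaults, not claims. A "Curated" set — the Very High and
High classes minus the two hyperexpressed very-late genes (polh, p10),
whose promoter context is atypical — can be built with `curatedClass()`.

# The synthetic generator

`generateSynthetic()` lays out a circular chromosome of strand-alternating,
non-overlapping ORFs; each ORF, in coding orientation, is a 225-nt
upstream window, TAAG, a 5′UTR and an ATG..stop CDS. Every planted item is
recorded in a manifest, and accidental exact copies of planted octamers in
the random background are scrubbed, so 0-mismatch scans recover the
manifest exactly. Defaults describe the study design the analysis targets,
chosen once:

* 149 ORFs with class quotas 5/6/17/65/56 (Very High .. Very Low) — the
  class sizes of the reference transcriptome design;
* background composition 59% A+T (AcMNPV-like);
* RPKM drawn log-uniform strictly inside each class's bounds (only the
  classing matters downstream, not the within-class shape);
* 5′UTR lengths uniform on 4–120 nt, identical across classes — so length
  comparisons are null by construction;
* the Very High class's UTR composition shifted +0.15 in A+T — the
  effect-size scale of the A+T elevation the analysis is meant to detect;
* TATA/CAGT planting probabilities decreasing with abundance class
  (0.55/0.30/0.10/0/0 from Very Low to Very High) and TAAG always present
  — the qualitative motif-by-class pattern;
* 8 hr blocks of 400 nt built from an A+T-rich 30-mer repeat unit.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: overlapping and nested ORFs (ubiquitous in
real baculovirus genomes; kept out so ground truth stays unambiguous),
polycistronic transcripts, multiple TSSs per ORF, non-i.i.d. background
(dinucleotide bias, repeats beyond the hr units), and any transcription
kinetics. Synthetic recovery demonstrates the pipeline's arithmetic and
bookkeeping, not biological inference.

`nullGenome()` generates featureless i.i.d. backgrounds for the hit-rate
calibration.

# Numerical and size choices

Determinism: every stochastic routine takes a seed and saves/restores the
RNG state, so regeneration is bit-identical and pipeline reruns produce
byte-identical JSON summaries (the config hash covers analysis parameters
only, not output paths). Degenerate inputs are handled explicitly:
zero-length UTRs are legal (undefined A+T), sequences shorter than a query
scan to an empty result, empty TSS tables degrade the pipeline to the
stages that need no TSS, and windows that leave a linear genome truncate
with a `short` flag (upstream windows) or error (fixed-width flanks).

The test suite and acceptance script run on deliberately modest problem
sizes — the full 149-ORF design (~190-kb genome) where quotas matter,
20-ORF genomes elsewhere, a 100-kb null genome for rate calibration, 1000
simulations for the type-I error check — sizes at which every check runs
in seconds while keeping the binomial/SD arithmetic meaningful.

# Limitations

No PWM/HMM motif models or de-novo motif discovery: the analysis queries
fixed octamers and canonical promoter motifs only. No GFF3/BED input in
this version; hr annotations absent from a GenBank file are supplied via a
plain table (which wins, with a warning, when both exist — published hr
coordinate sets differ, so the explicit table is authoritative). No
information-content logo mathematics beyond plain column frequencies, and
no phylogenetic weighting of consensus rows. The genome-anchored reference
checks require the user to supply the reference GenBank file and a TSS
table (`inst/scripts/fetch_reference.R` documents the download); the
package itself performs no network access.
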