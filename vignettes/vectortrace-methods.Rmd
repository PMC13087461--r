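---
title: "Methods: AAV integration detection and HDR editing quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AAV integration detection and HDR editing quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectortrace)
```

## Scope and model

`vectortrace` implements the computational side of a CRISPR-Cas9/AAV6
homology-directed-repair (HDR) gene-correction workflow in which a
promoterless, codon-optimized cDNA with a polyA signal, flanked by 1-kb
homology arms (HAs), is knocked into an endogenous locus. Two sequencing
experiments are modelled end to end:

1. **AAV integration assay.** Genomic DNA is sheared to ~10-kb fragments,
   cleaved in vitro by Cas9 with an array of guides tiling the vector
   (ITR, 5'HA, cDNA, 3'HA), enriched and nanopore-sequenced. Reads are
   aligned to a *combined reference* — the host genome with the vector
   appended as one extra contig — and a read spanning a vector-host
   junction aligns in pieces, the partner piece recorded in its SA:Z tag.
   The caller decomposes each primary record plus SA entries into chimeric
   segments, converts CIGARs to read/reference intervals, emits a junction
   event for each adjacent vector/host segment pair, clusters events into
   integration sites and classifies sites as targeted (within the HA span
   of the locus) or other.
2. **Editing quantification.** A three-primer PCR (two outer genomic
   primers flanking the HAs plus one primer inside the donor cDNA)
   produces a long outer-primer product from unedited/NHEJ alleles and a
   shorter outer-by-cDNA product from knock-in alleles; episomal vector,
   lacking outer primer sites, never amplifies. HDR efficiency is the HDR
   band intensity over the total; indel frequency is called from
   upper-band amplicon reads in a window around the cut site.

Because no sequencing data are deposited for this kind of experiment at
desk scale, a truth-annotated synthetic-data generator is a first-class
module: every caller is tested against datasets whose junctions, allele
fractions and error processes are known exactly.

## Coordinates and conventions

All internal coordinates are 0-based, half-open. Conversion to the 1-based
SAM convention happens only in the SAM reader/writer and in
`parse_sa_tag()`. The cut site is the blunt SpCas9 cut 3 bp 5' of the NGG
PAM, i.e. between protospacer bases 17 and 18; a "cut site" is always the
0-based boundary between the two flanking bases. Junction coordinates are
the reference coordinates *facing* the breakpoint on each side, so a
seamless insertion at position *p* yields 5' and 3' junction events whose
host coordinate is exactly *p*.

## Synthetic-data generator

The generator defines the study conditions; its defaults are fixed and not
tuned per analysis:

* **Cell population** — `cell_population_spec()` defaults to
  WT 0.4 / NHEJ 0.4 / HDR 0.2, matching the reported scale of ~20% HDR
  efficiency and ~40% indel frequency at the target locus.
  `episome_copies_per_genome` defaults to 0, mirroring the 21-day culture
  washout of residual episomal AAV; positive values are used in
  negative-control tests.
* **Long-read errors** — `error_model()` defaults to substitutions 0.02,
  single-base insertions 0.005 and deletions 0.005 per base
  (nanopore-like, ~3% total). Amplicon simulation defaults to a
  high-accuracy profile (substitutions 0.002, indels 1e-4 per base)
  because PCR products are sequenced on short-read/Sanger platforms, not
  on the nanopore device.
* **Fragmentation** — breakpoints follow a Poisson process with mean
  spacing `mean_len` (default target 10 kb), so fragment lengths are
  exponential and tile the molecule exactly. `cas9_enrich()` models
  preferential adapter ligation at Cas9 cut ends: guide-overlapping
  fragments are cleaved at the guide site and retained with probability
  `p_cut` (0.9), others with `p_cut / capture_bias` (`capture_bias` 20 —
  the on-target yield of such libraries is not published, so this is a
  declared fixture choice).
* **Molecule models** — the locus chromosome exists as a WT/NHEJ copy and
  an HDR knock-in copy (cDNA+polyA inserted seamlessly at the cut; HA
  sequence is host sequence, so HDR junctions are host-vector boundaries
  at the insert only, with no ITR). NHEJ alleles are modelled as
  junction-identical to WT in the long-read assay: a few-bp indel is far
  below junction-caller resolution. Random (non-targeted) integrations
  insert a configurable vector subinterval — by default an ITR-containing
  end, the common integration mode — at a stated host position, on either
  strand, and the variant chromosome replaces the plain copy across the
  population (the fraction of cells carrying a random event is not
  specified by the assay being emulated; detection only requires
  junction-spanning reads). Episomes are free full-length vector
  molecules.
* **Truth output** — each read carries a truth record (segments on the
  combined reference partitioning the read; per-read junctions) recorded
  from the molecule geometry itself, independent of any caller code, and
  the simulator emits a truth SAM (primary + supplementary records with
  exact CIGARs including the simulated errors, plus SA:Z tags). This
  replaces an external aligner so the whole pipeline is testable offline;
  consequently called junction coordinates on simulated data are exact and
  the "noisy recovery" experiments probe the filter/clustering logic, not
  alignment uncertainty. Against real BWA/minimap2 alignments, breakpoint
  coordinates would additionally wobble by microhomology and alignment
  ambiguity — that aspect of real data is *not* covered by these tests.

A single seeded RNG stream per operation (restored on exit) makes every
generator byte-deterministic.

## Junction caller parameters

The assay publication states no filter thresholds, so the defaults are
declared here and exposed in `run_config()`:

| parameter | default | why |
|---|---|---|
| `min_mapq` | 20 | drop ambiguous placements |
| `min_segment_len` | 200 bp | a junction claim needs substantial anchors on both references at ~2-3% error |
| `max_junction_gap` | 100 bp | unaligned bases tolerated between segments on the read |
| `max_overlap` | 50 bp | reads whose segments overlap more than this (microhomology tolerance) are ambiguous chimeras and skipped |
| `merge_distance` | 50 bp | single-linkage clustering radius per chromosome |
| `min_support` | 1 read | single-read events are reported (a single random integration event is a meaningful observation in this assay) |
| `targeted_window` | 1000 bp | slack around the HA span for the targeted/other call |

The site representative is the lower median of member coordinates
(deterministic for ties); support counts distinct reads. ITR-containing
junctions are visible through `vector_segment`, looked up from the base
adjacent to the breakpoint.

## Three-primer assay parameters

In-silico PCR enumerates primer sites with at most `max_mismatches`
(default 1) mismatches, requiring the 3'-terminal 3 nt to match exactly
(extension requirement); products must be 50-3500 bp. The 3.5-kb ceiling
models short-product amplification bias and is what suppresses the
outer-primer product across the knock-in allele (~4.4 kb in the packaged
fixture geometry), reproducing the two-band gel pattern: ~2.5 kb
(WT/NHEJ) and ~1.6 kb (HDR). Band "intensity" from simulated data is the
read count per product class; an optional molar correction (divide by
length) is off by default since gel densitometry quantifies mass.

Indel calling uses a banded global aligner (affine gaps; match 2,
mismatch -4, gap open -6, gap extend -1, a k-gap scoring
`open + k * extend`) with deterministic tie-breaking: diagonal over gap,
then gap-in-read over gap-in-reference. The band half-width (50) must
exceed the true indel size for the banded score to equal the unbanded
optimum; reads whose length differs from the reference by more than the
band, or whose alignment identity falls below 0.7, are excluded and
counted separately. A read is indel-positive when an insertion or
deletion of at least `min_indel_len` (1) overlaps the +/-5 bp cut-site
window — the CRISPResso-style convention. Junction fidelity is judged on
the read *consensus* (majority base per position; indel events shared by
more than half of reads), so independent sequencing errors do not produce
an "imprecise" verdict.

## Off-target screen

Candidate sites are NGG-adjacent 20-mers within `max_mismatches` (default
4) Hamming distance of the guide, on either strand, mismatches counted in
the protospacer only; risk scoring of dedicated prediction tools is out
of scope, and the annotation column is filled from a user-supplied
feature table when given. The background flag threshold is 0.001 (0.1%),
the background level reported for such screens. Each site's indel
fraction is computed by the same windowed caller on per-site amplicons.

## Problem sizes in the packaged tests

Tests and the acceptance script run on seeded toy genomes (tens of kb,
three chromosomes) chosen so that every stage is exercised at meaningful
coverage: the noisy-recovery experiment uses 6,000 reads giving at least
100 junction-spanning reads per simulated integration; estimator-recovery
experiments use 5,000 amplicon reads per condition; the off-target screen
simulates 14 planted candidate sites with 2,000 reads each. These sizes
are the package's own choices for stable statistics at desk scale.

## Known limitations

* The truth-SAM route bypasses real alignment; breakpoint wobble,
  reference bias and supplementary-alignment loss in real aligners are
  not modelled (an external aligner can be swapped in by aligning the
  emitted FASTQ and feeding the BAM-derived SAM to `read_sam()`).
* Nanopore error structure is i.i.d. per base here; homopolymer-biased
  errors and chimeric library artifacts are not emulated.
* Vector concatemers and partial/rearranged integrations are not
  modelled; random integrations are clean subinterval insertions.
* The mismatch enumerator is a screen, not a risk model: it has no
  cleavage-likelihood score.
* Guide sequences and primer sequences of the original experiment are not
  published; fixtures use seeded stand-ins with the same geometry (1-kb
  HAs, ~1.7-kb cDNA, 2.5/1.6-kb products), so numeric agreement with the
  original gels is structural, not sequence-level.
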