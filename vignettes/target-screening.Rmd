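---
title: "Screening species-specific CRISPR-Cas12a targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening species-specific CRISPR-Cas12a targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscreen)
```

## The problem

Morphology and the universal ITS barcode often cannot separate closely
related fungi — a well-known pair being *Aspergillus flavus* and
*A. oryzae*, whose ITS sequences are identical. A genome-wide alternative
is to look for short sequences that occur in the genome of the species of
interest but have no sufficiently similar counterpart in the genomes of the
species it must be distinguished from. If such a marker is adjacent to a
CRISPR-Cas12a PAM, the marker doubles as a detection reagent: a crRNA
matching it directs Cas12a to cleave the amplified marker, and the
enzyme's collateral ssDNA cleavage then produces a fluorescent readout.
`pamscreen` implements the computational half of this workflow.

## The screening model

**Candidate targets.** Cas12a requires a TTTV PAM (V = A, C or G). Every
k-mer (default k = 25) on either strand of the focal genome that begins
with TTTV is a candidate target; the 21-nt remainder after the PAM is the
protospacer a crRNA would match. Enumeration is a sliding window over all
(L − k + 1) positions per strand; overlapping windows are all kept, and
`copy_number` records how often each k-mer occurs in its own genome
(both strands). With i.i.d. base frequencies the expected density of
candidate sites is

p = q_T^3 (1 − q_T) per strand-position, with q_T the T frequency,

so the mean spacing between sites is about L / (2 (L − k + 1) p). At GC
0.5 this is one site per ~43 bp; genome-wide counts reported for real
fungal genomes (one site per a few tens of bp) match the two-strand form
of this calculation, which is why both strands are always scanned.

**Specificity.** A candidate is screened against each comparator genome by
finding every PAM-bearing site whose post-PAM segment is within a Hamming
distance `max_mm` (default 5) of the protospacer. Distances are counted
over the protospacer only and the PAM must match the pattern exactly —
the convention of PAM-aware off-target searchers. Classification:

* `ultra_specific` — no comparator site within `max_mm` at all;
* `specific` — every comparator's closest site is at distance
  ≥ `specific_min_distance` (default 3);
* `non_specific` — otherwise.

The default of 3 encodes the experimental observation that a site three
mismatches away from the spacer no longer activates Cas12a, while the
ultra class encodes the stricter "no off-target within five mismatches"
selection used for adulterant discrimination. A `require_pam = FALSE`
escape hatch compares every window regardless of its leading bases, for
sensitivity analysis of the PAM-required reading.

**Activation model.** `simulate_cas12a()` is deliberately qualitative: the
assay is predicted activated iff the best PAM-matched site in the
substrate is within `activation_max_mm` mismatches of the spacer.
Activation at 0 mismatches and non-activation at 3 are the anchored
observations; behaviour at 1–2 mismatches is experimentally undetermined,
and the default threshold 2 is simply the largest value consistent with
both anchors. It is configurable, and no fluorescence magnitudes or
kinetics are modelled — those depend on reporter chemistry and instrument,
not on the sequence logic this package captures.

## Algorithms and numerical choices

The production search uses pigeonhole seeding: the 21-nt protospacer is
split into `max_mm + 1` disjoint seeds, so any qualifying site must match
one seed exactly. Seed occurrences are looked up in a hash index of the
comparator built once per screen, and candidates are verified with
2-bit-packed XOR/popcount comparison plus precomputed PAM and N masks.
The contract is exact output equivalence with a plain scan — no
approximation — and the suite asserts set equality against
`brute_force_offtargets()`, an independent pure-R window scan, on
randomized instances. When `max_mm + 1` exceeds the protospacer length the
seeds would be empty and the implementation falls back to verifying every
window.

Other fixed choices:

* Coordinates are 0-based, half-open everywhere internally (BED native;
  GFF3 converted on input) so interval arithmetic is bit-exact.
* Hit order is (contig, start, strand) with '+' before '−'; reports are
  byte-identical across reruns and contain no timestamps.
* Windows containing N are never enumerated and never match at any
  distance: a mismatch count against N is undefined. Residues other than
  A/C/G/T/N are rejected by default, with an explicit `iupac_to_n` opt-in,
  because silent conversion can hide assembly artifacts.
* Self-site exclusion in own-genome histograms is by coordinates, not
  sequence, so duplicated copies elsewhere in the genome still count.
* `k` is configurable over 23–27; the protospacer length and every
  derived invariant follow from `k − 4`.
* Ties for the detection model's best hit break to the leftmost
  forward-strand coordinate, then '+' strand.

## What the synthetic generator does and does not emulate

`make_genome()` draws i.i.d. bases at a requested GC and writes planted
sequences (targets, decoys at exact Hamming distances via `make_decoy()`)
over the background. `make_related_pair()` emulates a closely related
species pair with substitution-only divergence at a controllable identity,
matching the Hamming-distance world of the screen; when asked to plant a
unique island it verifies the island against the finished relative with
the brute-force scan, so planted-truth recovery tests have a real
guarantee behind them. Default study conditions used in the tests are
100-kb pairs at identity 0.90 with one planted island, twenty seeds.

Real genomes are not i.i.d.: they carry repeat families, homopolymers, GC
skew and ITS arrays. The `repeats` preset (tandem-duplicated blocks at 2%
divergence) stresses the seed index with near-duplicates, but passing
tests on synthetic data demonstrate search correctness, not biological
performance: marker counts and specificity fractions on real assemblies
depend on the assembly version and on repeat content. For that reason the
pipeline writes a manifest with input checksums, so any published count
can be attributed to an exact assembly.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
100 randomized oracle-equivalence instances on genomes up to 50 kb;
twenty 100-kb related pairs for planted-truth recovery with every
ultra-specific call re-verified by the independent scan; density checks
on 200-kb genomes against the closed form above (15% band, dominated by
the binomial noise of ~4,700 sites); and amplicon-scale detection panels.
These sizes were chosen so the whole suite documents the method at desk
scale; the same functions run unchanged on real fungal assemblies (tens
of Mb), where the seeded index keeps per-target screening sublinear in
practice.

## Known limitations

* Hamming distance only: bulged (indel) off-target sites are outside the
  model, as implied by a fixed-length mismatch window.
* No activity scoring (CFD/MIT-style) and no kinetics; the activation
  verdict is binary.
* The crRNA module emits spacers only. No scaffold/repeat sequence is
  invented; supply your own via `design_crrna(..., scaffold=)`.
* Amplification is modelled only as slice extraction
  (`extract_flanks()`, default 500 bp each side); primer design and
  isothermal amplification chemistry are out of scope.
* Published genome-scale counts can only be reproduced with the exact
  pinned assemblies, which are not shipped; the corresponding check
  documents the expected figures and requires those files locally.
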