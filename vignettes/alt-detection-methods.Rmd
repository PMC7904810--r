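---
title: "Methods: detecting ALT and neo-telomere junctions with neotel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting ALT and neo-telomere junctions with neotel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

neotel implements the computational side of ALT (alternative lengthening of
telomeres) detection in tumor sequencing data.  The underlying biological
model is neo-telomere formation: ALT-positive cells can add telomeric repeat
sequence to an open chromosomal break, stabilizing a terminal deletion.  At
the read level this leaves two signatures that the locus caller exploits:

1. **Discordant pairs** — fragments straddling the junction far enough that
   one read lies entirely in the telomeric tract.  That read fails to align
   (or aligns with very low confidence) while its mate anchors uniquely in
   the retained flank.
2. **Split reads** — reads crossing the junction itself, soft-clipped at the
   exact junction base, the clipped tail consisting of telomeric repeat.

A junction's *orientation* states where the telomeric sequence sits:
`tel_right` means telomeric bases occupy coordinates at or beyond the
junction (right-clipped reads whose clip reads TTAGGG-type on the forward
strand), `tel_left` the mirror image (left clips reading CCCTAA-type).  All
internal coordinates are 0-based half-open; a junction is the boundary after
the last reference-matching base.  Conversion to SAM's 1-based and BED's
0-based conventions happens only in the I/O layer, so off-by-one handling
lives in exactly one file.

# Read classification rules

Two telomeric-read rules coexist because the upstream assays differ:

* **Fixed count (WGS)**: at least 6 instances of the four most common
  repeat hexamers (TTAGGG, TCAGGG, TGAGGG, TTGGGG) on one strand.
* **Per 100 bp (RNA/ChIP)**: at least `rt` instances per 100 bp of read
  length — `rt = 14` for TERRA extraction (stringent, because polyadenylated
  TERRA is identified purely by sequence content regardless of mapping) and
  `rt = 8` for ChIP telomere reads.

Three decisions here were genuinely open and are fixed as follows:

* "Non-consecutive instances" is read as *occurrences need not be adjacent*;
  they are counted as non-overlapping matches scanning left to right.  For
  same-length hexamers, greedy selection from either end yields the maximum
  set of non-overlapping occurrences, so the count is strand-symmetric by
  construction (verified property-style against a character-by-character
  oracle).
* Forward- and reverse-strand counts are **not summed**; the maximum is
  used.  A genuine telomeric read is strand-coherent, and summing would
  promote chimeric reads with half a tract on each strand.
* The per-100-bp requirement rounds **up** (`ceiling(rt * L / 100)`),
  matching threshold semantics; both the rounding and the thresholds are
  configurable in `neotel_config()`.

N bases never match any pattern.  Satellite (SatII/SatIII) reads are called
by exact substring match of the canonical motif or its reverse complement;
satellite and telomere calls are computed independently and are not mutually
exclusive.

# Telomere content

Content is the number of telomeric reads that are unmapped or have mapping
quality below 8, per million reads with GC content of 48–52%.  The narrow
GC window makes the denominator robust to library GC bias, since the
telomeric G-strand sits at ~50% GC.  Choices: the GC window is inclusive at
both endpoints and GC is computed over non-N bases (both configurable);
duplicates are excluded from numerator and denominator alike; the
"per million" scale is cosmetic — ALT classification uses the tumor/control
log2 ratio, which is scale-free.  Without a matched control the denominator
is the mean content of controls sharing the tumor's sequencing protocol key.

# The locus caller

Stages, with their operating points (all in `neotel_config()`):

| stage | rule | default |
|---|---|---|
| anchors | non-telomeric read, MAPQ > `anchor_min_mapq`, telomeric mate, not proper, not duplicate | MAPQ > 30 |
| regions | single-linkage anchor clusters, gap ≤ `region_size_bp`, span trimmed to one region size | 1 kb |
| region emit | ≥ `min_discordant` tumor anchors, ≤ `max_control_discordant` control anchors in the padded span | 4 and 0 |
| panel filter | drop regions with anchors in ≥ `pon_min_samples` *distinct* panel samples | 15 |
| junctions | ≥ `min_split_reads` soft-clipped reads agreeing exactly, clip containing TTAGGG/CCCTAA | 3 |
| two-sided | opposite orientations within `two_sided_window_bp`, greedy nearest pairing | 10 kb |
| CN context | nearest segment boundary within `cn_boundary_tol_bp` | 50 kb |
| hotspots | cross-sample single linkage ≤ `hotspot_merge_bp`, ≥ `hotspot_min_samples` samples | 1 Mb, 3 |

Design decisions worth spelling out:

* **Clustering, not tiling.**  "1 kb regions" are built by single-linkage
  clustering of anchors with a 1 kb gap, trimmed to the densest 1 kb window
  when a cluster sprawls.  Fixed genome tiles would split junctions landing
  on tile boundaries into two sub-threshold halves.
* **Exact junction agreement.**  Split reads must agree on the junction
  base exactly (`junction_tol_bp = 0`); a tolerance is available for noisy
  data but defaults off, because clipped alignments at a clean junction are
  base-exact.
* **Control exclusion zone.**  Matched-control anchors are counted in the
  region padded by one region size, a symmetric and conservative lookup
  window.
* **Panel of normals counts samples, not reads.**  Thirty artifact reads
  from one noisy control are one sample.  A panel smaller than the threshold
  warns and the filter becomes inert rather than silently passing.
* **Copy-number tolerance** of 50 kb matches the resolution limit of
  segment-based copy-number callers: a junction and its segment boundary can
  legitimately disagree by up to one resolution unit.
* **Hotspot parameters** (1 Mb merge, ≥ 3 samples) are chosen so that a
  recurrent cluster spanning roughly a megaband — the scale of the known
  neuroblastoma 1q42.2 hotspot — forms a single reported region.
* Manual review of near-threshold calls is out of scope; the `regions` and
  `unresolved` audit tables of the result object are the machine-checkable
  replacement.

## Microhomology

At a called junction the telomeric repeat is extended *backwards* across the
junction in its observed phase (the offset of the first clipped base within
the hexamer, majority-voted over split reads), and the score is the length
of the maximal run of retained-flank bases equal to that extension,
immediately adjacent to the junction.  The phase is fixed at the observed
value rather than maximized over phases — the literal reading of
"microhomology to the canonical repeat".  Junctions within 6 bp of a contig
edge are unscorable (`NA`).

## Two-sided events

Two opposite-orientation loci within 10 kb form a two-sided event (greedy
nearest pairing, each locus in at most one event).  A *true insertion* is
evidenced by at least one read pair anchored on both sides of the event
(MAPQ > 30 on both ends).  Absence of such pairs does not prove two
independent healings: for inserts longer than the fragment size, spanning
pairs cannot exist in short-read data.

# Sample-level calls and TMM grouping

C-Circle positivity requires a ≥ 4-fold AUC increase over the no-polymerase
control *and* ≥ 20% of the positive-control AUC.  A no-polymerase AUC of
exactly zero satisfies the fold condition (configurable): with no background
amplification, any signal is genuinely polymerase-dependent.

The TMM label resolves overlapping evidence in a fixed order:
heterogeneous ALT/MNA (C-Circle negative, log2 telomere content > 1, MYCN
amplified) → ALT (C-Circle positive or high telomere content) → MNA →
TERT → OTHER.  ALT outranks MNA and TERT because C-Circle positivity is the
specific ALT marker even in MYCN-amplified tumors, and ALT/TERT
co-occurrence is empirically near-absent; the evidence flags record every
true predicate regardless of the label, so no information is lost to the
ordering.  Gene amplification reconciles "8-fold" and "≥ 8 copies" wordings
as ≥ 8 ploidy-scaled copies (8 in a diploid genome).

# Quantification

TERRA: reads passing the rt = 14 rule, counted independently of mapping
position, per million total reads.  ChIP enrichment per repeat class:

```
log2( (repeat reads in IP / mapped reads in IP) /
      (repeat reads in input / mapped reads in input) )
```

Numerators scan all records including unmapped ones (telomeric reads are
typically unmapped); denominators count mapped, non-duplicate records, as
the normalization is defined.  The fraction-of-reads-in-peaks exclusion
threshold "below one" is interpreted as **below 1 percent** (FRiP < 0.01);
the unit is ambiguous in its source, so the threshold is configurable and
recorded in the output.  Samples at exactly the threshold are retained.

# Cohort statistics

Fisher exact tests use the two-sided "sum of probabilities ≤ observed"
convention — required to reproduce published cohort p-values — with the
sample odds ratio (a·d)/(b·c) reported by default.  The rank-sum test uses
the exact distribution for tie-free samples of combined n ≤ 50 and the
tie/continuity-corrected normal approximation otherwise.  Stage is tested
as stage 1-3 vs stage 4, plus stage 4S vs all other staged tumors; this
pair of contrasts reproduces the published stage p-values exactly, which is
how the contrast definition was validated.

# The simulator: what it emulates, and what it does not

`sim_scenario()` defaults define the study conditions: paired-end 100 bp
reads, 350 ± 30 bp inserts, 30× coverage, 50% GC — typical tumor WGS — on a
10^6 bp genome of three contigs with three implanted junctions
(microhomology 0, 2 and 4 bp; both orientations).  Telomeric tracts are
1,500 bp, 90% TTAGGG / 10% variant hexamers, with the junction-proximal
210 bp kept pure so both classification rules and the phase computation are
exercised deterministically.  Substitution errors run at 0.1% on plain
mapped reads; junction-spanning and telomeric reads are left error-free so
that ground-truth junction positions and support counts stay exact.  The
two-sided insertion scenario implants a head-to-head tract (G-strand half,
then C-strand half): a neo-telomere on each side of the insertion point,
which is what gives the two junctions opposite orientations; spanning
fragments provide the insertion evidence.

The simulator emits aligner-style records directly — clips, mates and
mapping qualities set by construction — rather than running an aligner on
simulated FASTQ.  That keeps runs desk-scale and deterministic, and the
caller consumes alignment semantics, not raw reads.  Consequently the tests
demonstrate correctness of the *calling logic*, not robustness to aligner
idiosyncrasies: real data adds multi-mapping ambiguity, indel-containing
clips, chimeric artifacts, GC-dependent coverage waves and subclonal allele
fractions, none of which the generator produces.  A matched control, a
16-sample panel of normals and a recurrent-artifact mode exist specifically
to exercise the filters that absorb part of that real-world noise.

Problem sizes used throughout the tests and the acceptance script — 10^6 bp
genomes at 30–50×, 10^5–10^6-read quantification sets, 1,000-replicate
calibration runs — are the package's chosen desk-scale operating points:
large enough that binomial noise sits far from every decision threshold
(expected support ≈ 20 reads against thresholds of 3–4), small enough to
run in minutes.

# Known limitations

* No CRAM input; BAM requires Rsamtools.
* The caller does not assemble junctions; a junction must be clip-exact to
  be refined.
* Interstitial telomeric sequence fully embedded in mapped reads never
  produces anchors or qualifying clips, so it cannot generate calls — by
  design — but genuine fusions lacking telomeric sequence are equally
  invisible.
* Locus-resolved TERRA (per chromosome end) and absolute telomere length in
  kb are out of scope.
* Survival analysis and peak calling are upstream/downstream of this
  package and are not reimplemented.
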