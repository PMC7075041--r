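---
title: "Sequence-based STR profiling with CE-compatible allele designation"
author: "strcaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based STR profiling with CE-compatible allele designation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strcaller)
```

## The model

A short tandem repeat (STR) locus is an array of 1–6 bp motifs whose
alleles differ in copy number and internal sequence. Capillary
electrophoresis (CE), the reference technology behind national DNA
databases, measures only amplicon *length* and names alleles by repeat
count, with leftover bases as a decimal suffix (`9.3` = nine full
repeats plus three bases). Sequencing resolves the actual sequence, but
a sequence-based caller is only database-compatible if its numeric
designation equals what CE would have measured — which means counting
*every base inside the repeat region*, including insertions, deletions
and interstitial non-motif stretches, not just clean motif copies.

`strcaller` encodes each locus by the forensic sequence-structure
grammar: space-separated tokens where `[MOTIF]n` is a variable, counted
repeat; an upper-case unbracketed tract is counted once; a lower-case
tract is present in the reference structure but never counted. The
*reference period* is the length of the first bracketed motif; it is
the unit in which leftover bases carry into the repeat count. For every
locus we examined, this matches the CE repeat-unit convention,
including compound loci whose later motifs have a different length.

### Per-read calling

A read oriented to the locus reading sequence is processed in three
steps.

1. *Exact motif search.* Every counted motif is located at every offset
   with zero mismatches. Repetitive DNA cannot be aligned reliably with
   tolerant matching — a single mismatched motif copy must break the
   tiling, not be absorbed — so exactness here is a modelling choice,
   not an optimisation. A read containing no motif occurrence at all is
   discarded (`no_motif`).
2. *Longest tiled interval.* Among all chains of occurrences in which
   each tile begins exactly where the previous one ends, the longest in
   bases is selected (dynamic program over chain ends; ties go to the
   leftmost start, then to fewer tiles, making output platform- and
   order-independent). This locates the repeat array without any prior
   assumption about the allele's size.
3. *Flank anchoring.* The configured 5'/3' flanks are slid over their
   respective sides of the interval and placed at minimal Hamming
   distance, ties broken towards the interval. A placement is accepted
   when its mismatches are at most `ceiling(f × flank length)` with
   `f = 0.1` by default — two mismatches on a typical 20 bp flank —
   tolerating sequencing errors and common flanking SNPs while keeping
   anchors specific. Reads failing a side are rejected
   (`no_flank5`/`no_flank3`); both anchors are required, because a
   one-sided anchor cannot certify that the read spans the whole
   region, and unanchored 3' ends are precisely the failure mode that
   produces confidently wrong, too-short alleles.

The repeat region is every base strictly between the flank matches.
It is decomposed greedily left-to-right against the structure: elements
are tried in structure order compatible with progress so far; a
bracketed repeat consumes as many consecutive copies as possible and
may be re-entered after an interruption; tracts consume one literal
occurrence; unmatched bases accumulate as residual runs, and a residual
run that itself tiles with a counted motif is re-labelled as extra
copies (alleles longer than the reference structure thus decompose
cleanly; ties between motifs are broken in structure order). The
designation is then

- full repeats: bracketed/re-labelled copies, plus `len %/% period` per
  counted tract;
- leftover bases: `len %% period` per counted tract, plus residual
  bases; leftovers pool, carry into full repeats in period units, and
  the remainder is the decimal part. Lower-case tracts contribute
  nothing.

This reproduces both canonical behaviours: `[TTCC]15 TT` designates as
`15.2` (the two inserted bases are counted), and a locus such as
D22S1045 (`[ATT]n ACT [ATT]n`, period 3) designates `[ATT]8 ACT [ATT]2`
as `11` because the full-period `ACT` tract counts as one repeat. One
documented ambiguity: an upper-case tract shorter than the period (e.g.
a `TA` inside a period-4 structure) contributes its length to the
decimal pool whenever present; for partial-repeat alleles the decimal
part is therefore a property of the whole region, not of any single
tract. Note a strict consequence of base counting: a region with a
single trailing extra base designates as `N.1`, a distinct allele from
`N`, even though length-based reports sometimes fold such variants into
the integer allele; downstream designation-level pooling and stutter
correction resolve these in practice.

### From read calls to genotypes

Calls are tallied by (designation, decomposition); sequence-distinct
alleles with equal designation stay separate in the multi-allele report
but pool their depth for genotyping, since CE compatibility is defined
at designation level. Alleles supported by no more than `noise_frac`
(default 1%) of the locus's called reads are removed as noise — the
boundary is removed, so an allele at exactly 1% counts as noise. The
two most-supported designations form the diploid genotype; the stutter
ratio is `depth2/depth1`, and strictly below the threshold (default
0.5, the intra-locus balance used in MPS-STR validation practice) the
second allele is deemed a PCR slippage artifact and the call corrected
to a homozygote. At exactly the threshold the heterozygote stands.
Depth ties prefer the larger designation: stutter is predominantly one
unit *shorter* than its parent, so the longer of two tied candidates is
the conservative heterozygote partner. X/Y loci in males are haploid
(modal allele; everything else is stutter); Y loci in females are
reported `NA`; unknown sex calls Y loci haploid with a warning. An
empty post-filter tally is an `NA` (no call), never an error.

### Quality control

Per locus and sample, the QC matrix records total bases, mean read
quality, allocated/called/rejected-by-reason read counts, per-allele
depths, the stutter ratio, and the mean distances from each genotype
allele's region boundaries to the read ends. The 3'-end distance of
the primary allele (`dis1_mean_3`) deserves emphasis: 3'-quality
trimming produces reads that end inside the repeat region, and although
such reads are rejected (no 3' anchor), loci where the *called* reads
barely clear the region are enriched for truncation-driven errors — a
small `dis1_mean_3` is a red flag. The matrix doubles as a feature
table (`export_feature_table()`) for an external genotype-quality
classifier; training such a model requires CE-labelled truth data and
is out of scope for this package.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `stutter_threshold` | 0.5 | second/first depth ratio below which the second allele is stutter (strict `<`) |
| `noise_frac` | 0.01 | allele-frequency cutoff; alleles at or below it are removed |
| `flank_max_mismatch_frac` | 0.1 | per-flank Hamming tolerance as a fraction of flank length (`ceiling`) |
| `min_overlap`, `max_mismatch_frac` (pair merging) | 10 bp, 0.1 | minimum overlap and mismatch tolerance of the built-in best-overlap fuser |
| flank length (panel design) | 10–30 bp recommended | long enough to be locus-specific, short enough to sit within reads |

Coordinates are 1-based inclusive, matching the region conventions of
standard alignment tooling. Flanks are given in read orientation (after
the orientation flip), because that is the frame in which they are
matched.

## The simulator: what it emulates, and what it does not

`sim_spec()`/`simulate_reads()` generate amplicon reads for a locus
with a known genotype: per read an allele is drawn uniformly; with
probability `stutter_rate` (default 0.1) the repeat count slips by one
unit, minus-one with probability `stutter_dir_minus` (default 0.9,
reflecting that polymerase slippage predominantly deletes a unit);
substitution errors arrive at a flat `error_rate` (default 0.005) with
reduced base quality; fragments are `flank5 + region + flank3`, padded
at the 3' end with random context, read as the 5' prefix (and in paired
mode the reverse-complemented 3' end). Read names carry the simulated
truth for white-box assertions, and everything is reproducible from the
spec's seed.

Deliberately *not* modelled: multi-unit slippage, platform error
profiles (homopolymer indels, 3' quality decay), PCR chimeras, mapping
ambiguity against a full genome, flanking-sequence variants, degraded
or mixed-contributor samples. Passing simulation tests therefore
demonstrates that the calling, filtering and reporting logic is
correct under the stated error model — not that any real platform's
artifact spectrum is fully handled.

## Canonical allele expansion

The simulator needs an inverse of decompose-and-designate. The package
expands a designation as: all full repeats as copies of the *last*
bracketed motif, plus the partial bases as a prefix of the reference
motif, omitting fixed tracts. Keeping fixed counted tracts in the
expansion would force their leftover bases into every allele (TH01's
`ATG` pins the decimal part at 3 mod 4), making many designations
unreachable; the chosen convention reaches every `(full, partial)` with
`partial < period` and satisfies the round-trip identity
`designate(decompose(expand(d))) = d`, which the test suite verifies
for every panel structure and all alleles up to 40 repeats. The
expansion is a canonical representative, not a claim about the real
allele's internal structure.

## Numerical and degenerate-input choices

- Empty region: designation `0`; an empty region between anchored
  flanks is its own rejection class (`empty_region`).
- Empty tally after noise filtering: genotype `NA`; reports keep the
  marker row.
- A single observed allele is reported as a homozygote without
  correction flag (nothing was filtered).
- Read-pair merging scores all overlaps of at least 10 bp by mismatch
  fraction, prefers the longest overlap on ties, and resolves disputed
  bases by higher quality (read 1 on quality ties). Pairs that fail to
  merge are processed as two single reads — single-end mode must work
  anyway, and this preserves depth.
- All report output is deterministic: tallies are ordered by depth,
  then larger designation, then decomposition string; per-locus results
  merge in panel order regardless of thread count.

## Validation scales

The shipped tests validate: the golden designation suite over the
published 9947A control-sample decompositions; equivalence of the
interval search with exhaustive chain enumeration on 10,000 random
reads (≤ 60 bp, up to three motifs); the expand/decompose round trip
(all panel structures × alleles ≤ 40 repeats); genotype recovery on 200
simulated diploid loci at 200 reads per allele, 10% stutter and 0.5%
substitution error, requiring ≥ 99% exact recovery; and
truncated-read behaviour (3'-unanchored reads are rejected rather than
mis-designated, and fully truncated regions drive `dis1_mean_3` to
zero). These problem sizes were chosen as the package's validation
conditions; larger panels and depths scale linearly.

## Known limitations

- No SNP/indel calling inside flanks or repeat units beyond what the
  decomposition string exposes; no isoallele annotation.
- Single-contributor samples only; no mixture deconvolution, no
  population statistics.
- BAM mode inherits the upstream aligner's ability to place repetitive
  reads; poorly mapped loci surface as low `n_allocated`, not as
  corrected calls.
- The QC feature schema is an integration point; no classifier is
  trained or shipped, and classifier transferability across platforms
  should not be assumed.
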