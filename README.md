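# strcaller

Targeted profiling of forensic short tandem repeat (STR) markers from
massively parallel sequencing (MPS) reads, with allele calls that stay
backward-compatible with capillary electrophoresis (CE).

## The problem

Forensic identity panels type STR loci — tandem arrays of 1–6 bp motifs
— whose alleles are registered in national DNA databases as CE repeat
numbers (`17`, `9.3`, …). Sequencing gives richer, sequence-level
alleles, but generic STR genotypers built for whole-genome data struggle
with targeted amplicon reads and do not guarantee that the numeric
allele they report matches what CE would have measured. `strcaller` is
for laboratories moving STR panels onto sequencers who need: per-read
allele calls from amplicon reads, CE-compatible allele designations,
stutter- and noise-filtered genotypes, and a per-locus quality-control
matrix that an external classifier can consume.

## The method

Each panel locus is configured with its repeat-region coordinates, its
sequence-structure nomenclature, its reading orientation and the fixed
flanking sequences adjacent to the repeat region. The nomenclature
grammar follows the forensic sequence-structure convention: bracketed
motifs with suffix `n` are variable counted repeats (`[AATG]n`),
unbracketed upper-case tracts are counted (`ACT`), lower-case tracts are
present but never counted (`tccata`).

Per read, the caller works in three steps:

1. **Exact motif search** — every counted motif is matched at every read
   offset with no mismatches.
2. **Longest tiled interval** — the longest contiguous chain of motif
   tiles (each tile starting where the previous ends) locates the repeat
   array.
3. **Flank anchoring** — each configured flank is slid over its side of
   the interval and placed at the minimal-Hamming-distance offset
   (accepted up to `ceil(0.1 × flank length)` mismatches).

The repeat region is *everything between the two flank matches*, so
insertions and deletions inside the region are counted exactly as CE
would size them. A region is decomposed against the structure and
designated as

    full_repeats . leftover_bases

where motif copies count once, counted tracts contribute
`len %/% period` repeats plus `len %% period` leftover bases, and
residual bases are leftover; pooled leftovers carry into the repeat
count in units of the reference period. For example, a region of
fifteen `TTCC` copies plus `TT` designates as `15.2`, and
`[AATG]6 ATG [AATG]3` designates as the classic TH01 `9.3`.

Per locus, read calls are tallied by (designation, sequence); alleles
supported by ≤ 1% of reads are removed as noise; the two most-supported
designations form the genotype, and when the second-to-first depth
ratio falls below the 0.5 stutter threshold the locus is corrected to a
homozygote. X/Y loci in male samples are called haploid (modal allele).
Three reports are written: `genotypes.tsv`, `multiple_alleles.tsv` and
`qc_matrix.tsv` (quality features including the mean distance from the
allele-1 region end to the read 3' end, `dis1_mean_3`, a strong
predictor of truncated-read miscalls).

A stutter-aware amplicon simulator (`sim_spec()` / `simulate_reads()`)
generates reads with known genotypes, ±1-repeat slippage and flat
substitution errors, so the whole pipeline is testable without any
external data.

## Worked example

Simulate a heterozygous TH01 sample (alleles 8 and 9.3, 200 reads per
allele, 10% stutter) from the shipped example panel and genotype it
(`PKG` is the installed package directory, `find.package("strcaller")`;
the panel's flanks and coordinates are synthetic illustrations):

```sh
Rscript $PKG/exec/strcaller simulate \
    --config $PKG/extdata/example_panel_synthetic.tsv \
    --marker TH01 --alleles 8,9.3 --depth 200 --seed 11 --out-prefix th01
Rscript $PKG/exec/strcaller run \
    --config $PKG/extdata/example_panel_synthetic.tsv \
    --input th01.fastq --out-dir reports --sample demo
```

which logs `locus TH01: 400 reads allocated, 398 called, 2 rejected`
and writes (TH01 row of `genotypes.tsv`, columns as below):

```
marker  status  allele1  allele2  depth1  depth2  stutter_ratio      correction_applied  sequences
TH01    called  9.3      8        150     146     0.973333333333333  FALSE               [AATG]9 AAT;[AATG]8
```

The two true alleles are recovered at a balanced ratio (0.97 ≥ 0.5, so
no stutter correction), and `multiple_alleles.tsv` lists the slipped
artifacts explicitly:

```
marker  allele  reads  role     sequence
TH01    9.3     150    allele   [AATG]9 AAT
TH01    8       146    allele   [AATG]8
TH01    8.3     14     stutter  [AATG]8 AAT
TH01    7       14     stutter  [AATG]7
```

Loci with no assigned reads are reported with status `NA`, not dropped.
The same pipeline runs from a coordinate-sorted indexed BAM (reads are
then allocated by repeat-region coordinates instead of flank
detection), and from paired FASTQ with optional overlap merging
(`--input2`, `--merge-pairs`). The R API mirrors the CLI:
`run_str_pipeline()`, and the per-stage functions (`parse_structure()`,
`decompose_region()`, `designate()`, `call_read()`, `call_genotype()`,
`compute_qc()`) are exported for programmatic use.

### Report columns

- `genotypes.tsv`: `marker, status, allele1, allele2, depth1, depth2,
  stutter_ratio, correction_applied, sequences`.
- `multiple_alleles.tsv`: `marker, allele, reads, role, sequence` (one
  row per surviving allele; `role` is `allele` or `stutter` relative to
  the final genotype).
- `qc_matrix.tsv`: `sample, marker, total_bases, mean_quality,
  n_allocated, n_called, rej_no_motif, rej_no_flank5, rej_no_flank3,
  rej_empty_region, depth1, depth2, stutter_ratio, dis1_mean_5,
  dis1_mean_3, dis2_mean_5, dis2_mean_3`.

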