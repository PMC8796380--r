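# sgedesign

Oligonucleotide variant library design and annotation for saturation
genome editing (SGE), cDNA deep mutational scanning (DMS) and saturation
prime editing.

SGE experiments introduce every possible variant of a genomic region into
its native context via CRISPR/Cas9 and homology-directed repair, then read
out variant fitness by deep sequencing. The step this package automates is
the design of the repair-template oligo pool: given genomic coordinates of
a target region (a *targeton*), transcript annotation and a codon usage
table, it systematically generates, annotates and serialises every variant
oligo the experiment needs. It is aimed at groups designing SGE or DMS
libraries who want a deterministic, scriptable designer that works from
standard files (FASTA + index, GTF/GFF2, VCF) for any species or genome
build.

## The design model

Each targeton is partitioned into up to five adjacent regions,

```
c1 - r1 - r2 - r3 - c2
```

where `r2` is a user-defined core (typically a complete or partial exon),
`r1`/`r3` are extensions of user-chosen lengths (typically flanking
intron), and `c1`/`c2` are constant flanks that systematic mutators never
touch (custom variants from VCFs are still applied there). Every region
gets its own list of *mutator functions*:

| mutator | requires frame | action |
|---|---|---|
| `snv` | no | all 3L single-nucleotide substitutions |
| `1del` | no | all L single-base deletions |
| `2del0`, `2del1` | no | non-overlapping tandem 2-bp deletions from offset 0 / 1 |
| `snvre` | yes | `snv` + completion of synonymous codon sets (incl. TGA↔TAG) + redundant codons for missense SNVs |
| `inframe` | yes | deletion of each complete codon |
| `ala`, `stop` | yes | scan substituting each codon by the top-ranking alanine / stop codon |
| `aa` | yes | substitution by the top-ranking codon of each other amino acid |

Reading frames come from the transcript annotation. For a coding target
starting at `s_target` inside a CDS feature with start `s_exon` and
`f_exon` bases missing from its first codon,

```
f_target = (f_exon + (s_target - s_exon)) mod 3
l_ext5'  = f_target
l_ext3'  = (3 - (l_target + f_target) mod 3) mod 3
```

and the `l_ext` liminal bases are pulled from the spliced transcript, so
codons split across exon junctions are annotated correctly (they receive
SNVs, never codon-level substitutions). PAM/protospacer protection edits
(VCF records grouped by an `SGRNA` INFO tag) are applied to the retrieved
reference first; the protected sequence is the basis for every generated
oligo. Final oligos are assembled as `adapter5 + mutated targeton +
adapter3`, optionally reverse-complemented (adapters excluded) for
minus-strand targets, filtered by a maximum synthesis length (default
300 bp) and deduplicated by exact sequence — the unique count is the
library complexity to synthesise.

## Worked example

Everything below runs on a bundled synthetic fixture (a 1 kb contig with
a three-exon minus-strand transcript and a 400 bp plus-strand contig), so
no downloads are needed:

```r
library(sgedesign)

fx <- generate_fixture("fixture", seed = 1)
res <- run_sge(
  targeton_file = fx$targetons,
  fasta         = fx$fasta,
  gtf           = fx$gtf,
  pam_vcf       = fx$pam_vcf,
  manifest      = fx$manifest,
  adapter5      = "AATGATACGGCGACCACCGA",
  adapter3      = "CAAGCAGAAGACGGCATACGAGAT",
  revcomp_minus_strand = TRUE,
  output_dir    = "library_out"
)

tz <- res$targetons$chrZ_306_550_minus_sgRNA_a
addmargins(table(tz$records$mutator, tz$records$region))
```

```
                c1  c2  r1  r2  r3 Sum
  1del           0   0  25  54  25 104
  2del0          0   0   0   0  12  12
  2del1          0   0  12   0   0  12
  ala            0   0   0  15   0  15
  clinvar_like   1   0   0   2   1   4
  gnomad_like    0   1   1   0   0   2
  inframe        0   0   0  17   0  17
  snv            0   0  75 162  75 312
  snvre          0   0   0  98   0  98
  stop           0   0   0  17   0  17
  Sum            1   1 113 365 113 593
```

This is an exon-covering design: a 245 bp targeton whose 54 bp coding core
(`r2`) is flanked by 25 bp intronic extensions, with the action vector
`r1: 2del1,snv,1del | r2: snvre,inframe,ala,stop,1del | r3: 2del0,snv,1del`.
The counts follow the design laws: `snv` gives 3 per base (75/162/75),
`1del` one per base, the offset tandem deletions give ⌊(25−1)/2⌋ = 12 and
⌊25/2⌋ = 12 pairs, and the codon-level mutators act on the 17 complete
codons of the core (its first and last codons are split across exon
junctions and are skipped). Rows `clinvar_like`/`gnomad_like` are custom
VCF variants, incorporated everywhere including constant regions.

```r
c(total = nrow(tz$oligos) + nrow(tz$excluded),
  kept = nrow(tz$oligos), excluded = nrow(tz$excluded),
  unique = nrow(tz$unique))
#>    total     kept excluded   unique
#>      593      592        1      545
```

One custom insertion pushes its oligo past 300 bp and is segregated into
the excluded file; 545 unique sequences is the complexity of this toy
library. Per targeton the run writes `<stem>_meta.csv` (full annotated
metadata), `<stem>_unique.csv` (sequences to order), `<stem>.vcf`
(all variants, standard VCF anchoring) and, when needed,
`<stem>_excluded.csv`, plus one execution-wide `sequence_qc.csv` with the
retrieved wild-type sequences.

cDNA DMS designs run through `run_cdna()` with a multi-FASTA and a
relative-coordinate annotation CSV; saturation prime editing is the same
`run_sge()` engine with the targeton acting as the pegRNA
reverse-transcriptase template, `adapter5`/`adapter3` carrying the
remaining pegRNA sequence, a tighter `max_length` (e.g. 250) and
`revcomp_minus_strand` for strand-specific templates. A command-line
wrapper with `sge`, `cdna` and `fixture` subcommands is installed at
`inst/scripts/sgedesign.R`.

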