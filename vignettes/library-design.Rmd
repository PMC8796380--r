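---
title: "Designing saturation mutagenesis oligo libraries with sgedesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing saturation mutagenesis oligo libraries with sgedesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgedesign)
```

## The problem

Saturation genome editing (SGE) and related deep mutational scanning
assays measure the functional effect of every possible variant of a
target region. The experimental input is an oligonucleotide pool in which
each molecule is a repair template carrying exactly one variant (plus any
fixed protection edits). Designing that pool by hand is error-prone: the
variants must respect reading frames that may cross exon junctions, every
oligo must share PAM/protospacer protection edits so Cas9 cannot re-cut
repaired alleles, clinically observed variants from public VCFs should be
included, and the metadata must be rich enough to map sequencing reads
back to variants. `sgedesign` generates the pool and its annotations
deterministically from standard input files.

## Targetons and regions

A *targeton* is the genomic span an experiment edits, described by one
row of a tab-delimited parameter file with 1-based inclusive coordinates
(the file is BED-like in shape only; no 0-based interpretation is ever
applied, matching VCF and GTF conventions). The core range `r2` is
extended by an extension vector into `r1` (5' flank, relative to the
positive strand) and `r3` (3' flank); whatever remains of the targeton
becomes the constant flanks `c1`/`c2`:

```
|----- c1 -----|-- r1 --|----- r2 -----|-- r3 --|----- c2 -----|
```

The five regions are adjacent, non-overlapping and exactly tile the
targeton (a property the test suite checks on randomly generated
designs). Mutators are assigned per region; `c1`/`c2` accept none, but
custom VCF variants are still incorporated there, which is useful when
the constant flanks double as cloning-adapter annealing sites.

Each of `r1`, `r2`, `r3` must be homogeneous: all coding or all
non-coding. UTR bases count as non-coding, like intron. A region mixing
the two is rejected rather than silently split, since a mutator list that
makes sense for an exon rarely makes sense for its flanking intron.

## Reading frames across exon junctions

Frames come from a GTF/GFF2 in which only CDS, UTR and stop-codon
features are considered, and each gene may carry only one transcript (a
second transcript would make region-to-frame matching ambiguous). For a
target starting at `s_target` within a CDS feature starting at `s_exon`
with `f_exon` bases of its first codon lying upstream on the transcript:

```
f_target = (f_exon + (s_target - s_exon)) mod 3
l_ext5'  = f_target
l_ext3'  = (3 - (l_target + f_target) mod 3) mod 3
```

The GTF frame/phase column encodes "bases to remove to reach the next
whole codon"; the package converts it to the missing-bases form
(`f_exon = (3 - phase) mod 3`), validates all phases against a walk of
the spliced CDS, and computes any that are absent. On the minus strand
the same arithmetic runs in transcript orientation (distance from the
feature's genomic end); coordinates and stored bases always remain
positive-strand, and translation reverse-complements on the fly.

The `l_ext` *liminal* bases needed to complete partial codons at either
end of a target are taken in transcript order, so a target abutting an
exon junction pulls them from the adjacent exon, never the intron. A
split codon can therefore be annotated, but it is never substituted or
deleted as a unit: codon-level mutators skip liminal codons, while SNVs
inside them are still generated and annotated through the spliced
context. Tests verify both the frame and the context against an
independent oracle that concatenates the CDS features into one spliced
string and walks codons from its start.

The annotated stop codon is a special case the inputs leave open: it is
treated as coding so that SNVs and the `snvre` stop swap can act on it,
but the `inframe`, `ala`, `stop` and `aa` scans skip it — deleting or
substituting the terminator is a different experiment than scanning the
protein body.

## Mutator functions

Counts below are for a region of length `L` with `n` complete codons.

* `snv` — all `3L` substitutions. In coding regions each record carries
  the amino-acid change and its class (synonymous / missense / nonsense),
  looked up in a precomputed strand-aware table of all
  3 positions x 3 alternatives x 64 codons x 2 strands = 1152 events.
  Stop-loss changes are reported in the missense class (the vocabulary is
  deliberately three-valued).
* `1del` — all `L` single-base deletions.
* `2del0` / `2del1` — non-overlapping tandem dinucleotide deletions
  starting at offset 0 or 1; `floor((L - offset)/2)` records, trailing
  unpaired base untouched. The two offsets exist so that a design can
  phase the deletion grid onto splice-site dinucleotides at either end of
  an exon.
* `snvre` — the SNV set plus codon-level expansion. Where an SNV is
  synonymous, every remaining synonymous codon not reachable by a single
  substitution is added as a codon substitution: this completes the
  6-fold degenerate families (Leu, Ser, Arg) and swaps the stop pair
  TGA<->TAG, which are two substitutions apart. Where an SNV is missense,
  one redundant codon encoding the same amino acid is added: the
  top-ranking codon of that amino acid by usage, or the next-ranking one
  when the SNV itself produced the top codon; nothing is added when the
  amino acid is non-degenerate or when another single SNV of the same
  codon already yields the chosen sequence. Synonymous records give
  read-count normalisation controls; redundant missense records separate
  codon effects from amino-acid effects.
* `inframe` — deletion of each complete codon.
* `ala` / `stop` — substitution of each complete codon by the single
  top-ranking alanine / stop codon. A codon already equal to the target
  is skipped, so a wild-type sequence is never emitted as a variant.
* `aa` — substitution of each complete codon by the top-ranking codon of
  each of the 19 other amino acids. Substitution to stop is excluded;
  the dedicated `stop` scan covers truncations.

When a region requests both `snv` and `snvre`, the SNV saturation is
emitted once — `snvre` contains it by definition, and emitting it twice
would double-count the library.

Property-style tests pin these definitions: the count laws hold for
random lengths; for every codon on both strands the union of
SNV-synonymous products and `snvre` additions equals the full synonymous
family with no duplicates; every emitted record changes the sequence; no
mutator emits two identical records.

## Codon usage table

Codon ranking drives `snvre` redundancy and the three scans. The packaged
default (`inst/extdata/default_codon_usage_human.csv`) carries the widely
used human codon usage fractions as compiled from GenBank-derived codon
usage statistics, expressed per amino acid; any organism can be
substituted with a `codon,amino_acid,fraction` CSV. The table must cover
all 64 codons and agree with the standard nuclear genetic code (the only
code supported). Ranking is by decreasing fraction within each amino
acid; exact ties break by lexicographic codon order so that results are
reproducible under any table. Whether fractions are per-amino-acid or
absolute does not change the ranking, since codons are only compared
within an amino acid.

## Protection edits and custom variants

PAM/protospacer protection edits are single-nucleotide substitutions
supplied in a VCF whose records carry an `SGRNA` INFO tag; a targeton
lists the sgRNA ids whose edits it should carry. The edits are applied to
the retrieved reference first, and this protected sequence is the basis
for all systematic and custom mutation, so every oligo of the targeton
shares them. Edits must match the reference allele and may not collide
with each other; applying disjoint edits is order-independent.

Custom variants come from VCFs listed in a manifest CSV, each with a
provenance alias and optionally an INFO tag to use as the variant
identifier (the VCF ID field by default). Multi-allelic records are split
into one event per alternative allele; substitutions, insertions,
deletions and indels are classified from POS/REF/ALT; symbolic alleles
are skipped with a warning. Only variants that start and end within the
targeton are applied, one oligo each. Each custom oligo carries exactly
one variant plus the protection edits; systematic and custom events are
never combined on one molecule.

Custom variants describe the genome, not the protected sequence, so
their reference alleles are checked against the original reference; if a
variant overlaps a protection-edit position it is applied on top of the
protected sequence and a warning is raised — the alternative (refusing
the variant) would silently shrink the library.

## Assembly, filtering and outputs

Variants are applied to the positive-strand protected sequence. For
minus-strand targetons the mutated targeton portion can be
reverse-complemented (`revcomp_minus_strand`), excluding adapters — a
convenience for strand-specific applications such as single-stranded
donor templates and pegRNA reverse-transcriptase templates. Adapters are
appended last. Oligos strictly longer than `max_length` (default 300 bp,
the practical ceiling of array synthesis; 250 bp is typical for
prime-editing templates) are segregated with full metadata into an
excluded file. Deduplication is by exact final sequence; because adapters
are shared prefixes/suffixes they cannot change the result, which the
tests confirm.

Per targeton the run writes a metadata CSV, a unique-sequence CSV and a
VCF, plus the excluded CSV when non-empty; one execution-wide QC CSV
reports each targeton's retrieved wild-type sequence. Two position
dialects coexist deliberately: the metadata reports deletions at the
first deleted base with no alternative sequence and insertions at the
first inserted position with no reference sequence (convenient for
downstream tallying), while the VCF uses standard anchored REF/ALT —
anchoring liminal events on the nucleotide retrieved just upstream of the
targeton. The suite verifies that applying every VCF record to the
protected reference reproduces the corresponding oligo exactly.

Oligo names (`stem_region_mutator_position_event`) are an artifact of
this package, as are the exact metadata column names; both are fixed and
documented rather than configurable.

## cDNA mode

`run_cdna()` runs the same engine on user-supplied sequences (e.g. a CDS
inside an expression vector) with coordinates relative to each FASTA
record. The annotation CSV gives the targeton, `r2` and CDS ranges plus
the extension and action vectors; the frame of `r2` is derived from the
user-defined CDS start as `(r2_start - cds_start) mod 3`, implemented by
constructing a single-feature transcript annotation on the record, so
genomic and cDNA mode share every downstream code path. Custom VCFs and
PAM protection are not supported here (`src_type` is `cdna`; the output
VCF uses the record id as its contig). On identical sequence content the
two modes produce identical variant sets up to the coordinate offset,
which the tests check by running the fixture's plus-strand contig through
both.

## The synthetic fixture

`generate_fixture()` builds a complete input set from a seed, byte-
identically: a 1 kb contig with a minus-strand three-exon transcript and
a 400 bp contig with a plus-strand single-CDS gene, plus GTF, protection
VCF, custom VCFs with manifest, targeton file and a matching cDNA
fixture. Exon sizes were chosen to emulate a published exon-covering
design point: a 54 bp coding core flanked by 25 bp intronic extensions
inside a 245 bp targeton, with the core's first and last codons split
across exon junctions (frame 1 at its transcript 5' end), giving 17
complete codons for the codon-level scans. Coding sequence is drawn from
the 61 sense codons so no spurious internal stops arise; the custom VCFs
include an insertion long enough to breach the 300 bp limit, a variant
crossing the targeton boundary and a symbolic allele, so the filtering
paths are exercised by construction.

The fixture emulates structure, not biology: its sequence composition is
uniform random, its variant density is arbitrary, and it contains no
repeats, homopolymer runs of consequence, or alternative transcripts.
Passing tests therefore demonstrate coordinate, frame and bookkeeping
correctness — not that a design for a real locus is experimentally
sensible (sgRNA choice, off-targets and synthesis QC are out of scope).
Problem sizes throughout tests and the acceptance script are the fixture
scale: ~1.4 kb of genome, two targetons, on the order of a thousand
oligos, which the full suite processes in well under a minute.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere inside the package;
  conversion to 0-based half-open happens only at the FASTA access
  boundary.
* Soft-masked bases are uppercased on read; bases outside `{A,C,G,T,N}`
  are input errors. `N` is tolerated in constant regions but any mutable
  region containing `N` is an error — mutating an unknown base is
  undefined.
* Empty regions, empty mutator lists and empty VCFs are all valid and
  yield empty (not missing) outputs; a run with no targetons writes a
  header-only QC file.
* There is no randomness anywhere in the engine; two runs on identical
  inputs are byte-identical. The only seeded component is the fixture
  generator.
* A length of exactly `max_length` is kept; exclusion is strictly
  greater-than.

## Known limitations

One transcript per gene; standard genetic code only; GFF3, refFlat and
genePred are not parsed; structural/symbolic variants are skipped, not
designed around; no cross-targeton deduplication for tiled designs
(deduplication is per targeton, since each targeton is synthesised and
cloned as its own pool); sgRNA selection and downstream score analysis
are out of scope.
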