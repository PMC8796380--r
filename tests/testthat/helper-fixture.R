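# Fixture inputs are generated once per test session and shared read-only.
fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("sgedesign-fixture-", seed))
    fixture_cache[[key]] <- generate_fixture(dir, seed = seed)
  }
  fixture_cache[[key]]
}

# Full SGE run on the shared fixture, cached (several test files inspect it).
shared_run <- function(seed = 42L) {
  key <- paste0("run", seed)
  if (is.null(fixture_cache[[key]])) {
    fx <- shared_fixture(seed)
    out <- file.path(tempdir(), paste0("sgedesign-run-", seed))
    fixture_cache[[key]] <- suppressWarnings(run_sge(
      fx$targetons, fx$fasta, gtf = fx$gtf, pam_vcf = fx$pam_vcf,
      manifest = fx$manifest, output_dir = out,
      adapter5 = "AATGATACGGCGACCACCGA",
      adapter3 = "CAAGCAGAAGACGGCATACGAGAT",
      revcomp_minus_strand = TRUE
    ))
  }
  fixture_cache[[key]]
}

# Raw fixture chromosome as a plain string (independent slicing oracle).
fixture_chrom_string <- function(fx, chrom) {
  ss <- Biostrings::readDNAStringSet(fx$fasta)
  as.character(ss[[chrom]])
}

# Independent oracle: splice all CDS features (plus stop feature) of the
# fixture gene into one transcript-order string by direct slicing of the
# chromosome string, together with the genomic position of each base.
spliced_cds_oracle <- function(chrom_str, features, strand) {
  # features: list of c(start, end) in genomic coordinates, any order
  ord <- order(vapply(features, `[`, integer(1), 1L),
               decreasing = (strand == "minus"))
  pos <- integer(0)
  for (f in features[ord]) {
    p <- seq.int(f[1L], f[2L])
    if (strand == "minus") p <- rev(p)
    pos <- c(pos, p)
  }
  bases <- vapply(pos, function(p) substr(chrom_str, p, p), character(1))
  if (strand == "minus") bases <- chartr("ACGT", "TGCA", bases)
  list(pos = pos, seq = paste(bases, collapse = ""))
}

# Brute-force translation oracle for a positive-strand codon read on a
# given strand (string reversal + chartr, no package code).
oracle_translate <- function(codon, strand) {
  if (strand == "minus") {
    codon <- paste(rev(strsplit(chartr("ACGT", "TGCA", codon), "")[[1]]),
                   collapse = "")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal single-feature transcript annotation built without a GTF file.
make_test_annotation <- function(chrom, start, end, strand, phase = 0L,
                                 gene_id = "g", transcript_id = "t") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- as.integer(phase)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$transcript_id <- transcript_id
  sgedesign:::new_transcript_annotation(gene_id, transcript_id, gr)
}

# Annotation tables are deterministic; build once per session.
shared_tables <- function() {
  if (is.null(fixture_cache$tables)) {
    ctable <- load_codon_table()
    fixture_cache$tables <- list(
      codon_table = ctable,
      snv_table = build_snv_annotation_table(c("plus", "minus")),
      snvre_tables = build_snvre_tables(ctable, c("plus", "minus"))
    )
  }
  fixture_cache$tables
}

# Transcript-space codon produced by applying one record to a single-codon
# region (positive-strand region sequence, any strand).
applied_tx_codon <- function(rec, region_seq, region_start, strand) {
  mutated <- apply_variant(region_seq, region_start, rec)
  if (strand == "minus") {
    paste(rev(strsplit(chartr("ACGT", "TGCA", mutated), "")[[1]]),
          collapse = "")
  } else {
    mutated
  }
}
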