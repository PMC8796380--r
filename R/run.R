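#' Generate a saturation genome editing library
#'
#' End-to-end driver: parses the targeton file, retrieves and
#' PAM/protospacer-protects each targeton's reference sequence, partitions
#' it into c1-r1-r2-r3-c2, runs the per-region mutator lists and the
#' custom-variant sources, assembles, length-filters and deduplicates the
#' oligos, and writes the per-targeton metadata/unique/VCF/excluded files
#' plus one execution-wide sequence QC report. The run is fully
#' deterministic: identical inputs produce byte-identical outputs.
#'
#' @param targeton_file Path to the targeton parameter TSV
#'   (see [parse_targeton_file()]).
#' @param fasta Path to the reference FASTA (indexed, or indexable).
#' @param gtf Optional transcript annotation GTF/GFF2 (required when any
#'   CDS mutator is requested).
#' @param pam_vcf Optional PAM/protospacer protection VCF
#'   (see [load_protection_edits()]).
#' @param manifest Optional custom-variant manifest CSV
#'   (see [parse_manifest()]).
#' @param codon_table Optional codon usage CSV; packaged human default
#'   otherwise.
#' @param adapter5,adapter3 Optional adapter sequences appended to every
#'   oligo.
#' @param max_length Maximum oligo length (default 300 bp); longer oligos
#'   are segregated into the excluded output.
#' @param revcomp_minus_strand Reverse-complement the targeton portion of
#'   minus-strand targetons (adapters excluded).
#' @param output_dir Directory for output files.
#' @return Invisibly, a list with one entry per targeton (`stem`,
#'   `records`, `oligos`, `excluded`, `unique`, `wildtype`, `protected`,
#'   `files`) plus `qc_file`.
#' @export
run_sge <- function(targeton_file, fasta, gtf = NULL, pam_vcf = NULL,
                    manifest = NULL, codon_table = NULL,
                    adapter5 = "", adapter3 = "", max_length = 300L,
                    revcomp_minus_strand = FALSE, output_dir = ".") {
  specs <- parse_targeton_file(targeton_file)
  fa <- open_fasta(fasta)
  contigs <- fasta_contigs(fa)
  annotations <- if (!is.null(gtf)) load_annotation(gtf) else NULL
  protection <- if (!is.null(pam_vcf)) load_protection_edits(pam_vcf)
                else list()
  sources <- if (!is.null(manifest)) parse_manifest(manifest) else list()
  ctable <- load_codon_table(codon_table)
  strands <- unique(vapply(specs, function(s) s$ref_strand, character(1)))
  tables <- list(
    codon_table = ctable,
    snv_table = build_snv_annotation_table(strands),
    snvre_tables = build_snvre_tables(ctable, strands)
  )
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  qc_ids <- qc_seqs <- character(0)
  for (spec in specs) {
    res <- run_one_targeton(spec, fa, contigs, annotations, protection,
                            sources, tables, adapter5, adapter3,
                            max_length, revcomp_minus_strand, output_dir)
    results[[res$stem]] <- res
    qc_ids <- c(qc_ids, res$stem)
    qc_seqs <- c(qc_seqs, res$wildtype$bases)
  }
  qc_file <- file.path(output_dir, "sequence_qc.csv")
  write_qc_report(qc_file, qc_ids, qc_seqs)
  invisible(list(targetons = results, qc_file = qc_file))
}

run_one_targeton <- function(spec, fa, contigs, annotations, protection,
                             sources, tables, adapter5, adapter3,
                             max_length, revcomp_minus_strand, output_dir) {
  stem <- targeton_file_stem(spec)
  wt <- fetch_range(fa, spec$range)

  edits <- NULL
  for (id in spec$sgrna_ids) {
    if (!id %in% names(protection)) {
      input_error("targeton ", format(spec$range), " references unknown ",
                  "sgRNA id '", id, "' (no matching protection record)")
    }
    e <- protection[[id]]
    e <- e[e$chrom == spec$ref_chr, , drop = FALSE]
    edits <- rbind(edits, e)
  }
  protected <- apply_protection(wt, edits)
  protection_positions <- if (is.null(edits)) integer(0) else edits$pos

  part <- partition_targeton(spec)
  ann <- find_annotation(annotations, spec$range)
  if (!is.null(ann) && ann$strand != spec$ref_strand) {
    input_error("targeton ", format(spec$range), " declares strand ",
                spec$ref_strand, " but overlapping transcript ",
                ann$transcript_id, " is on the ", ann$strand, " strand")
  }
  coding_flags <- validate_region_homogeneity(part, ann)
  wants_cds <- any(vapply(spec$actions, function(a) any(is_cds_mutator(a)),
                          logical(1)))
  if (wants_cds && is.null(ann)) {
    input_error("targeton ", format(spec$range), " requests CDS mutators ",
                "but no transcript annotation overlaps it")
  }
  lookup <- make_base_lookup(fa, spec$ref_chr, overlay = protected)
  region_seqs <- contexts <- list()
  for (rg in c("r1", "r2", "r3")) {
    r <- part[[rg]]
    if (is.null(r)) {
      region_seqs[[rg]] <- ""
      contexts[rg] <- list(NULL)
      next
    }
    o1 <- r$start - spec$range$start + 1L
    region_seqs[[rg]] <- substr(protected$bases, o1,
                                o1 + range_length(r) - 1L)
    if (isTRUE(coding_flags[[rg]])) {
      contexts[[rg]] <- region_frame_context(ann, r, lookup)
    } else {
      contexts[rg] <- list(NULL)
    }
  }
  records <- run_action_vector(spec, part, region_seqs, contexts,
                               coding_flags, tables)
  for (src in sources) {
    cv <- load_custom_variants(src, spec$range)
    if (nrow(cv)) {
      cv$region <- region_of_position(part, cv$pos)
    }
    records <- rbind(records, cv)
  }
  oligos <- assemble_oligos(records, protected, original = wt,
                            protection_positions = protection_positions,
                            stem = stem, strand = spec$ref_strand,
                            revcomp_minus_strand = revcomp_minus_strand,
                            adapter5 = adapter5, adapter3 = adapter3,
                            src_type = "ref")
  fl <- filter_max_length(oligos, max_length)
  dedup <- deduplicate_oligos(fl$kept)
  files <- write_outputs(output_dir, stem, fl$kept, fl$excluded,
                         dedup$unique, protected, spec$ref_chr,
                         contig_length = unname(contigs[spec$ref_chr]))
  list(stem = stem, spec = spec, partition = part,
       coding_flags = coding_flags, records = records,
       oligos = fl$kept, excluded = fl$excluded, unique = dedup$unique,
       wildtype = wt, protected = protected, files = files)
}

region_of_position <- function(part, pos) {
  out <- rep(NA_character_, length(pos))
  for (rg in c("c1", "r1", "r2", "r3", "c2")) {
    r <- part[[rg]]
    if (is.null(r)) next
    hit <- pos >= r$start & pos <= r$end
    out[hit & is.na(out)] <- rg
  }
  out
}
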