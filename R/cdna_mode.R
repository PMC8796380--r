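CDNA_COLUMNS <- c("record_id", "targeton_start", "targeton_end",
                  "r2_start", "r2_end", "cds_start", "cds_end",
                  "ext_vector", "action_vector")

#' Parse cDNA library inputs
#'
#' The cDNA mode runs the mutator engine over user-supplied sequences
#' (e.g. a CDS inside an expression vector) using relative, 1-based
#' coordinates within each FASTA record and no genomic reference. The
#' annotation CSV gives, per design row: the FASTA record, the targeton
#' and r2 ranges, the CDS range of the record (from which the reading
#' frame of r2 is derived as `(r2_start - cds_start) mod 3`), the r1/r3
#' extension vector and the three-part action vector.
#'
#' @param multi_fasta Path to the cDNA multi-FASTA.
#' @param annotation_csv Path to the cDNA annotation CSV with columns
#'   `record_id`, `targeton_start`, `targeton_end`, `r2_start`, `r2_end`,
#'   `cds_start`, `cds_end`, `ext_vector`, `action_vector`.
#' @return List with `sequences` (named character vector) and `specs`
#'   (list of `targeton_spec`-like objects carrying a `cds` range).
#' @export
parse_cdna_inputs <- function(multi_fasta, annotation_csv) {
  if (!file.exists(multi_fasta)) {
    input_error("cDNA FASTA not found: ", multi_fasta)
  }
  seqs <- Biostrings::readDNAStringSet(multi_fasta)
  seqs <- setNames(toupper(as.character(seqs)),
                   sub("\\s.*$", "", names(seqs)))
  if (!file.exists(annotation_csv)) {
    input_error("cDNA annotation file not found: ", annotation_csv)
  }
  df <- read.csv(annotation_csv, stringsAsFactors = FALSE,
                 colClasses = "character")
  missing <- setdiff(CDNA_COLUMNS, names(df))
  if (length(missing)) {
    input_error("cDNA annotation is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!row$record_id %in% names(seqs)) {
      input_error("cDNA annotation row ", i, " references FASTA record '",
                  row$record_id, "', which is not in ", multi_fasta)
    }
    trow <- data.frame(ref_chr = row$record_id, ref_strand = "+",
                       ref_start = row$targeton_start,
                       ref_end = row$targeton_end,
                       r2_start = row$r2_start, r2_end = row$r2_end,
                       ext_vector = row$ext_vector,
                       action_vector = row$action_vector,
                       sgrna_ids = "", stringsAsFactors = FALSE)
    spec <- parse_targeton_row(trow, i)
    cds_start <- as.integer(row$cds_start)
    cds_end <- as.integer(row$cds_end)
    if (is.na(cds_start) || is.na(cds_end) || cds_start > cds_end) {
      input_error("cDNA annotation row ", i, ": invalid CDS range")
    }
    if (spec$range$end > nchar(seqs[[row$record_id]])) {
      input_error("cDNA annotation row ", i, ": targeton extends past the ",
                  "end of record '", row$record_id, "'")
    }
    spec$cds <- gnm_range(row$record_id, cds_start, cds_end, "plus")
    spec
  })
  list(sequences = seqs, specs = specs)
}

# Synthetic single-feature transcript annotation for one cDNA record.
cdna_annotation <- function(record_id, cds_range) {
  ann <- structure(
    list(gene_id = record_id, transcript_id = record_id,
         chrom = record_id, strand = "plus",
         cds = data.frame(start = cds_range$start, end = cds_range$end,
                          phase = 0L),
         utr = data.frame(start = integer(0), end = integer(0),
                          phase = integer(0)),
         stop = NULL),
    class = "transcript_annotation"
  )
  ann$map <- build_cds_map(ann)
  ann
}

#' Generate a cDNA deep mutational scanning library
#'
#' Runs the same mutator/assembly/output engine as [run_sge()] over
#' user-supplied cDNA records. All coordinates in the outputs are relative
#' to the FASTA record (`src_type = "cdna"`); the output VCF uses the
#' record id as its contig. PAM protection and custom variant VCFs are
#' not supported in this mode.
#'
#' @inheritParams parse_cdna_inputs
#' @inheritParams run_sge
#' @param manifest Must be `NULL`: custom VCF variants are not supported
#'   for cDNA libraries.
#' @return Invisibly, the same structure as [run_sge()].
#' @export
run_cdna <- function(multi_fasta, annotation_csv, codon_table = NULL,
                     adapter5 = "", adapter3 = "", max_length = 300L,
                     output_dir = ".", manifest = NULL) {
  if (!is.null(manifest)) {
    input_error("custom variant sources are not supported in cDNA mode")
  }
  inputs <- parse_cdna_inputs(multi_fasta, annotation_csv)
  ctable <- load_codon_table(codon_table)
  tables <- list(
    codon_table = ctable,
    snv_table = build_snv_annotation_table("plus"),
    snvre_tables = build_snvre_tables(ctable, "plus")
  )
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  qc_ids <- qc_seqs <- character(0)
  for (spec in inputs$specs) {
    record_seq <- inputs$sequences[[spec$ref_chr]]
    stem <- paste(spec$ref_chr, spec$range$start, spec$range$end, "plus",
                  sep = "_")
    wt <- structure(
      list(range = spec$range,
           bases = substr(record_seq, spec$range$start, spec$range$end),
           preceding_base = if (spec$range$start > 1L) {
             substr(record_seq, spec$range$start - 1L,
                    spec$range$start - 1L)
           } else NA_character_),
      class = "ref_sequence"
    )
    ann <- cdna_annotation(spec$ref_chr, spec$cds)
    part <- partition_targeton(spec)
    coding_flags <- validate_region_homogeneity(part, ann)
    lookup <- function(pos) {
      vapply(pos, function(p) substr(record_seq, p, p), character(1))
    }
    region_seqs <- contexts <- list()
    for (rg in c("r1", "r2", "r3")) {
      r <- part[[rg]]
      if (is.null(r)) {
        region_seqs[[rg]] <- ""
        contexts[rg] <- list(NULL)
        next
      }
      region_seqs[[rg]] <- substr(record_seq, r$start, r$end)
      if (isTRUE(coding_flags[[rg]])) {
        contexts[[rg]] <- region_frame_context(ann, r, lookup)
      } else {
        contexts[rg] <- list(NULL)
      }
    }
    records <- run_action_vector(spec, part, region_seqs, contexts,
                                 coding_flags, tables)
    oligos <- assemble_oligos(records, wt, stem = stem, strand = "plus",
                              adapter5 = adapter5, adapter3 = adapter3,
                              src_type = "cdna")
    fl <- filter_max_length(oligos, max_length)
    dedup <- deduplicate_oligos(fl$kept)
    files <- write_outputs(output_dir, stem, fl$kept, fl$excluded,
                           dedup$unique, wt, spec$ref_chr,
                           contig_length = nchar(record_seq))
    results[[stem]] <- list(stem = stem, spec = spec, records = records,
                            oligos = fl$kept, excluded = fl$excluded,
                            unique = dedup$unique, wildtype = wt,
                            protected = wt, files = files)
    qc_ids <- c(qc_ids, stem)
    qc_seqs <- c(qc_seqs, wt$bases)
  }
  qc_file <- file.path(output_dir, "sequence_qc.csv")
  write_qc_report(qc_file, qc_ids, qc_seqs)
  invisible(list(targetons = results, qc_file = qc_file))
}
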