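event_summary <- function(rec) {
  switch(rec$type,
    "snv" = paste0(rec$ref, ">", rec$alt),
    "codon_substitution" = paste0(rec$ref, ">", rec$alt),
    "deletion" = paste0("del", nchar(rec$ref)),
    "codon_deletion" = paste0("del", nchar(rec$ref)),
    "insertion" = paste0("ins", nchar(rec$alt)),
    "indel" = paste0(substr(rec$ref, 1L, 8L), ">",
                     substr(rec$alt, 1L, 8L)),
    "var"
  )
}

#' Assemble final oligonucleotide sequences
#'
#' Builds one oligonucleotide per variant record: the record is applied to
#' the PAM/protospacer-protected positive-strand targeton sequence; for
#' minus-strand targetons the mutated targeton portion can be
#' reverse-complemented (adapters excluded); adapter sequences are
#' appended last.
#'
#' Custom variants describe the genome, not the protected sequence, so
#' their reference alleles are verified against the original (unprotected)
#' reference and they are applied on top of the protected sequence; a
#' collision with a protection-edit position is reported as a warning.
#'
#' @param records Variant record data frame (systematic and/or custom).
#' @param protected Protected `ref_sequence` of the targeton.
#' @param original Original (unprotected) `ref_sequence`; defaults to
#'   `protected` when no protection was applied.
#' @param protection_positions Integer positions carrying protection edits.
#' @param stem Targeton file stem (see [targeton_file_stem()]).
#' @param strand Targeton strand.
#' @param revcomp_minus_strand Reverse-complement the targeton portion of
#'   minus-strand targetons.
#' @param adapter5,adapter3 Adapter sequences appended 5' and 3' of every
#'   oligonucleotide (empty for none).
#' @param src_type `"ref"` for genomic libraries, `"cdna"` for cDNA.
#' @return Data frame of oligo records (one row per variant) with the
#'   final sequence, its length, and full variant metadata.
#' @export
assemble_oligos <- function(records, protected, original = protected,
                            protection_positions = integer(0), stem,
                            strand = "plus", revcomp_minus_strand = FALSE,
                            adapter5 = "", adapter3 = "", src_type = "ref") {
  strand <- normalize_strand(strand)
  t_start <- protected$range$start
  n <- nrow(records)
  body <- character(n)
  names_out <- character(n)
  do_rc <- strand == "minus" && isTRUE(revcomp_minus_strand)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    is_custom <- !(rec$mutator %in% ALL_MUTATORS)
    if (is_custom) {
      span <- event_span(rec)
      if (rec$type %in% c("snv", "indel", "deletion", "substitution")) {
        o <- rec$pos - t_start + 1L
        have <- substr(original$bases, o, o + nchar(rec$ref) - 1L)
        if (have != rec$ref) {
          input_error("custom variant '", rec$mutator, "' at ", rec$pos,
                      " does not match the reference: expected '", rec$ref,
                      "', reference has '", have, "'")
        }
      }
      if (length(protection_positions) &&
          any(protection_positions >= span[1L] &
              protection_positions <= span[2L])) {
        warning("custom variant at ", rec$pos, " overlaps a protection ",
                "edit; the variant is applied on top of the protected ",
                "sequence", call. = FALSE)
      }
    }
    body[i] <- apply_variant(protected$bases, t_start, rec,
                             check_ref = !is_custom)
    region_tag <- if (is.na(rec$region)) "t" else rec$region
    names_out[i] <- paste(stem, region_tag, rec$mutator, rec$pos,
                          event_summary(rec), sep = "_")
  }
  oriented <- if (do_rc) revcomp(body) else body
  final <- paste0(adapter5, oriented, adapter3)
  out <- records
  out$oligo_name <- if (n) make.unique(names_out, sep = "_") else character(0)
  out$src_type <- rep_len(src_type, n)
  out$mseq <- body
  out$sequence <- final
  out$length <- nchar(final)
  out$revcomp_applied <- rep_len(do_rc, n)
  out
}

#' Filter oligos by maximum synthesis length
#'
#' Oligos strictly longer than `max_length` (default 300 bp, the common
#' upper bound of array-based synthesis) are routed to the excluded set
#' with full metadata and a warning; a length exactly equal to the limit
#' is kept.
#'
#' @param oligos [assemble_oligos()] result.
#' @param max_length Maximum allowed oligo length in bases.
#' @return List with data frames `kept` and `excluded`.
#' @export
filter_max_length <- function(oligos, max_length = 300L) {
  stopifnot(max_length >= 1L)
  over <- oligos$length > max_length
  if (any(over)) {
    warning(sum(over), " oligonucleotide(s) exceed ", max_length,
            " bp and are excluded from the standard outputs", call. = FALSE)
  }
  list(kept = oligos[!over, , drop = FALSE],
       excluded = oligos[over, , drop = FALSE])
}

#' Deduplicate oligos by final sequence
#'
#' Distinct mutators can produce identical final sequences (e.g. adjacent
#' deletions of a homopolymer); the unique set is what is actually
#' synthesised, and its size is the library complexity. Deduplication is
#' by exact final sequence string (after any reverse complement and
#' adapters; adapters are shared prefixes/suffixes and do not affect the
#' result).
#'
#' @param oligos Kept oligo data frame.
#' @return List with `unique` (data frame `oligo_name`, `sequence`,
#'   `multiplicity`; first occurrence kept) and `n_total`.
#' @export
deduplicate_oligos <- function(oligos) {
  if (!nrow(oligos)) {
    return(list(unique = data.frame(oligo_name = character(0),
                                    sequence = character(0),
                                    multiplicity = integer(0)),
                n_total = 0L))
  }
  first <- !duplicated(oligos$sequence)
  counts <- table(oligos$sequence)
  uniq <- data.frame(oligo_name = oligos$oligo_name[first],
                     sequence = oligos$sequence[first],
                     stringsAsFactors = FALSE)
  uniq$multiplicity <- as.integer(counts[uniq$sequence])
  list(unique = uniq, n_total = nrow(oligos))
}

# Standard VCF 4.2 anchoring of a package-dialect variant record, using
# protected-reference bases (and the retrieved preceding base for liminal
# events).
vcf_fields <- function(rec, protected, chrom) {
  t_start <- protected$range$start
  t_end <- protected$range$end
  base_at <- function(p) {
    if (p >= t_start && p <= t_end) {
      o <- p - t_start + 1L
      substr(protected$bases, o, o)
    } else if (p == t_start - 1L && !is.na(protected$preceding_base)) {
      protected$preceding_base
    } else {
      stop("cannot anchor variant: position ", p,
           " is outside the retrieved sequence")
    }
  }
  type <- rec$type
  if (type %in% c("snv", "codon_substitution", "indel", "substitution")) {
    list(pos = rec$pos, ref = rec$ref, alt = rec$alt)
  } else if (type %in% c("deletion", "codon_deletion")) {
    if (rec$pos > 1L) {
      a <- base_at(rec$pos - 1L)
      list(pos = rec$pos - 1L, ref = paste0(a, rec$ref), alt = a)
    } else {
      a <- base_at(rec$pos + nchar(rec$ref))
      list(pos = rec$pos, ref = paste0(rec$ref, a), alt = a)
    }
  } else if (type == "insertion") {
    if (rec$pos > 1L) {
      a <- base_at(rec$pos - 1L)
      list(pos = rec$pos - 1L, ref = a, alt = paste0(a, rec$alt))
    } else {
      a <- base_at(1L)
      list(pos = 1L, ref = a, alt = paste0(rec$alt, a))
    }
  } else {
    stop("unknown variant type '", type, "'")
  }
}

write_variant_vcf <- function(path, records, protected, chrom,
                              contig_length = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.na(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length)
    } else {
      sprintf("##contig=<ID=%s>", chrom)
    },
    paste0("##INFO=<ID=SRC,Number=1,Type=String,Description=",
           "\"Mutator function or custom variant source alias\">"),
    paste0("##INFO=<ID=VID,Number=1,Type=String,Description=",
           "\"Source variant identifier\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  lines <- character(0)
  if (nrow(records)) {
    fields <- lapply(seq_len(nrow(records)), function(i) {
      vcf_fields(records[i, ], protected, chrom)
    })
    pos <- vapply(fields, `[[`, numeric(1), "pos")
    ord <- order(pos)
    lines <- vapply(ord, function(i) {
      f <- fields[[i]]
      rec <- records[i, ]
      info <- paste0("SRC=", rec$mutator)
      if (!is.na(rec$id)) info <- paste0(info, ";VID=", rec$id)
      paste(chrom, f$pos, if (is.na(rec$id)) "." else rec$id,
            f$ref, f$alt, ".", ".", info, sep = "\t")
    }, character(1))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

META_COLUMNS <- c("oligo_name", "src_type", "region", "mutator",
                  "variant_id", "position", "ref", "alt", "var_type",
                  "ref_aa", "alt_aa", "consequence", "sequence", "length")

format_meta <- function(oligos) {
  df <- data.frame(
    oligo_name = oligos$oligo_name, src_type = oligos$src_type,
    region = ifelse(is.na(oligos$region), "const", oligos$region),
    mutator = oligos$mutator, variant_id = oligos$id,
    position = oligos$pos, ref = oligos$ref, alt = oligos$alt,
    var_type = oligos$type, ref_aa = oligos$ref_aa,
    alt_aa = oligos$alt_aa, consequence = oligos$consequence,
    sequence = oligos$sequence, length = oligos$length,
    stringsAsFactors = FALSE
  )
  df[, META_COLUMNS]
}

#' Write the per-targeton output files
#'
#' Writes the targeton-specific files, all named after the targeton stem:
#' full metadata CSV (`<stem>_meta.csv`, package position dialect:
#' deletions start at the first deleted base with no alternative sequence,
#' insertions at the first inserted position with no reference sequence),
#' unique-sequence CSV for synthesis (`<stem>_unique.csv`), a VCF 4.2 of
#' all generated variants (`<stem>.vcf`, standard anchoring, using the
#' retrieved preceding base for liminal events), and — only when
#' over-length oligos exist — an excluded-sequence CSV
#' (`<stem>_excluded.csv`).
#'
#' @param output_dir Output directory (created if needed).
#' @param stem Targeton file stem.
#' @param kept,excluded Split oligo data frames from [filter_max_length()].
#' @param unique_oligos `unique` element of [deduplicate_oligos()].
#' @param protected Protected `ref_sequence` (VCF anchoring).
#' @param chrom Contig name for the VCF.
#' @param contig_length Optional contig length for the VCF header.
#' @return Named character vector of written paths.
#' @export
write_outputs <- function(output_dir, stem, kept, excluded, unique_oligos,
                          protected, chrom, contig_length = NA) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meta = file.path(output_dir, paste0(stem, "_meta.csv")),
             unique = file.path(output_dir, paste0(stem, "_unique.csv")),
             vcf = file.path(output_dir, paste0(stem, ".vcf")))
  write.csv(format_meta(kept), paths[["meta"]], row.names = FALSE,
            quote = FALSE, na = "")
  write.csv(unique_oligos[, c("oligo_name", "sequence")], paths[["unique"]],
            row.names = FALSE, quote = FALSE)
  all_records <- rbind(kept, excluded)
  write_variant_vcf(paths[["vcf"]], all_records, protected, chrom,
                    contig_length)
  if (nrow(excluded)) {
    paths[["excluded"]] <- file.path(output_dir,
                                     paste0(stem, "_excluded.csv"))
    write.csv(format_meta(excluded), paths[["excluded"]],
              row.names = FALSE, quote = FALSE, na = "")
  }
  paths
}
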