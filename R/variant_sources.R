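#' Parse a custom-variant manifest
#'
#' The manifest is a CSV listing custom variant VCF files, each with a
#' short alias that preserves variant provenance in the outputs, and an
#' optional INFO tag from which per-variant identifiers are parsed (the
#' VCF ID field is used by default).
#'
#' @param csv_source Path to the manifest CSV (columns `alias`, `vcf_path`
#'   and optional `id_info_tag`). Relative VCF paths are resolved against
#'   the manifest's directory.
#' @return List of `custom_variant_source` objects.
#' @export
parse_manifest <- function(csv_source) {
  if (!file.exists(csv_source)) {
    input_error("manifest file not found: ", csv_source)
  }
  df <- read.csv(csv_source, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!nrow(df)) return(list())
  if (!all(c("alias", "vcf_path") %in% names(df))) {
    input_error("manifest must have columns alias, vcf_path")
  }
  if (anyDuplicated(df$alias)) {
    input_error("duplicate alias in manifest: ",
                paste(unique(df$alias[duplicated(df$alias)]), collapse = ","))
  }
  base_dir <- dirname(normalizePath(csv_source))
  lapply(seq_len(nrow(df)), function(i) {
    path <- df$vcf_path[i]
    if (!file.exists(path)) path <- file.path(base_dir, df$vcf_path[i])
    if (!file.exists(path)) {
      input_error("VCF file for alias '", df$alias[i], "' not found: ",
                  df$vcf_path[i])
    }
    tag <- if ("id_info_tag" %in% names(df)) df$id_info_tag[i] else NA
    if (!is.na(tag) && !nzchar(trimws(tag))) tag <- NA
    structure(list(alias = df$alias[i], vcf_path = path,
                   id_info_tag = if (is.na(tag)) NULL else trimws(tag)),
              class = "custom_variant_source")
  })
}

read_vcf_records <- function(vcf_path) {
  v <- tryCatch(
    VariantAnnotation::readVcf(vcf_path, genome = "user"),
    error = function(e) input_error("cannot read VCF '", vcf_path, "': ",
                                    conditionMessage(e))
  )
  v
}

#' Load custom variants overlapping a targeton
#'
#' Reads the source VCF, splits multi-allelic records into one event per
#' alternative allele, classifies each event (substitution, insertion,
#' deletion or indel) from the POS/REF/ALT fields, normalises anchored
#' indel positions to the package dialect (deletions start at the first
#' deleted base; insertions at the first inserted position) and keeps only
#' the events that start and end within the targeton. Symbolic or
#' structural alternative alleles are skipped with a warning.
#'
#' @param source A `custom_variant_source` (see [parse_manifest()]).
#' @param targeton_range The targeton [gnm_range()].
#' @return Variant record data frame (`mutator` column carries the source
#'   alias).
#' @export
load_custom_variants <- function(source, targeton_range) {
  v <- read_vcf_records(source$vcf_path)
  rr <- SummarizedExperiment::rowRanges(v)
  info_df <- VariantAnnotation::info(v)
  out <- list(empty_variants())
  for (i in seq_along(rr)) {
    chrom <- as.character(GenomicRanges::seqnames(rr)[i])
    if (chrom != targeton_range$chrom) next
    pos <- GenomicRanges::start(rr)[i]
    ref <- toupper(as.character(VariantAnnotation::ref(v)[[i]]))
    alts <- VariantAnnotation::alt(v)[[i]]
    vid <- NA_character_
    if (!is.null(source$id_info_tag)) {
      if (source$id_info_tag %in% names(info_df)) {
        val <- info_df[[source$id_info_tag]][i]
        if (is.list(val)) val <- paste(unlist(val), collapse = ",")
        if (length(val) && !is.na(val)) vid <- as.character(val)
      }
    } else {
      nm <- names(rr)[i]
      if (!is.null(nm) && nzchar(nm) && !grepl("^[^:]+:\\d+_", nm)) {
        vid <- nm
      }
    }
    for (j in seq_along(alts)) {
      alt <- toupper(as.character(alts[[j]]))
      if (!nzchar(alt) || grepl("[^ACGTN]", alt)) {
        warning("skipping symbolic/structural ALT '", alt, "' at ",
                chrom, ":", pos, " in ", source$alias, call. = FALSE)
        next
      }
      rec <- classify_vcf_event(pos, ref, alt)
      span <- event_span(rec)
      if (span[1L] < targeton_range$start || span[2L] > targeton_range$end) {
        next  # variant must start and end within the targeton
      }
      rec$mutator <- source$alias
      rec$id <- vid
      rec$region <- NA_character_
      out[[length(out) + 1L]] <- rec[, VARIANT_COLUMNS]
    }
  }
  do.call(rbind, out)
}

# Classify a VCF POS/REF/ALT triple and normalise it to the package
# position dialect.
classify_vcf_event <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    type <- if (nr == 1L) "snv" else "indel"
    return(new_variants("custom", pos, ref, alt, type))
  }
  if (nr > na && substr(ref, 1L, na) == alt) {
    deleted <- substr(ref, na + 1L, nr)
    return(new_variants("custom", pos + na, deleted, "", "deletion"))
  }
  if (na > nr && substr(alt, 1L, nr) == ref) {
    inserted <- substr(alt, nr + 1L, na)
    return(new_variants("custom", pos + nr, "", inserted, "insertion"))
  }
  # unanchored length change: generic replacement
  new_variants("custom", pos, ref, alt, "indel")
}

# Genomic span affected by a variant record (insertion occupies its
# insertion point).
event_span <- function(rec) {
  if (rec$type == "insertion") {
    c(rec$pos, rec$pos)
  } else {
    c(rec$pos, rec$pos + nchar(rec$ref) - 1L)
  }
}

#' Load PAM/protospacer protection edits
#'
#' Protection edits are single-nucleotide substitutions shared by all
#' oligonucleotides of a targeton, preventing Cas9 re-cleavage of
#' successfully edited alleles. They are supplied as a VCF in which every
#' record carries an `SGRNA` INFO tag, grouping edits by sgRNA identifier.
#'
#' @param vcf_source Path to the protection VCF.
#' @return Named list mapping sgRNA id to a data frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
load_protection_edits <- function(vcf_source) {
  v <- read_vcf_records(vcf_source)
  rr <- SummarizedExperiment::rowRanges(v)
  if (!length(rr)) return(list())
  info_df <- VariantAnnotation::info(v)
  if (!"SGRNA" %in% names(info_df)) {
    input_error("protection VCF must define an SGRNA INFO tag")
  }
  edits <- list()
  for (i in seq_along(rr)) {
    sgrna <- info_df$SGRNA[i]
    if (is.list(sgrna)) sgrna <- paste(unlist(sgrna), collapse = ",")
    if (is.na(sgrna) || !nzchar(sgrna)) {
      input_error("protection VCF record at position ",
                  GenomicRanges::start(rr)[i], " is missing the SGRNA tag")
    }
    ref <- toupper(as.character(VariantAnnotation::ref(v)[[i]]))
    alts <- VariantAnnotation::alt(v)[[i]]
    if (length(alts) != 1L) {
      input_error("protection edits must be bi-allelic single nucleotide ",
                  "variants (record at ", GenomicRanges::start(rr)[i], ")")
    }
    alt <- toupper(as.character(alts[[1L]]))
    if (nchar(ref) != 1L || nchar(alt) != 1L || !alt %in% DNA_BASES) {
      input_error("protection edits must be single nucleotide ",
                  "substitutions (record at ", GenomicRanges::start(rr)[i],
                  " has REF '", ref, "', ALT '", alt, "')")
    }
    row <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)[i]),
                      pos = GenomicRanges::start(rr)[i],
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
    edits[[sgrna]] <- rbind(edits[[sgrna]], row)
  }
  edits
}

#' Apply protection edits to a retrieved reference sequence
#'
#' Substitutes each edit into the targeton's wild-type sequence. The
#' result is the protected reference: the basis for all subsequent
#' systematic and custom mutations, so every oligonucleotide of the
#' targeton shares the edits.
#'
#' @param reference A `ref_sequence` from [fetch_range()].
#' @param edits Data frame of edits (columns `pos`, `ref`, `alt`), e.g.
#'   the rows of [load_protection_edits()] for the targeton's sgRNA ids.
#' @return The protected `ref_sequence`.
#' @export
apply_protection <- function(reference, edits) {
  if (is.null(edits) || !nrow(edits)) return(reference)
  if (anyDuplicated(edits$pos)) {
    input_error("two protection edits at one position: ",
                paste(edits$pos[duplicated(edits$pos)], collapse = ","))
  }
  bases <- reference$bases
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (p < reference$range$start || p > reference$range$end) {
      input_error("protection edit at ", p, " is outside targeton ",
                  format(reference$range))
    }
    o <- p - reference$range$start + 1L
    have <- substr(bases, o, o)
    if (have != edits$ref[i]) {
      input_error("protection edit reference mismatch at ", p,
                  ": edit expects '", edits$ref[i], "', reference has '",
                  have, "'")
    }
    substr(bases, o, o) <- edits$alt[i]
  }
  out <- reference
  out$bases <- bases
  out
}
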