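ALL_CODONS <- as.character(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                 DNA_BASES, paste0))

revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Load and validate a codon usage table
#'
#' The table drives codon ranking for the redundant-codon, alanine-scan,
#' stop-scan and amino-acid-scan mutators. The packaged default is a human
#' codon usage table (per-amino-acid fractions); any organism can be
#' substituted via a three-column CSV (`codon`, `amino_acid`, `fraction`).
#' Stop codons use amino acid symbol `*`. Codons are ranked within each
#' amino acid by decreasing fraction, ties broken by lexicographic codon
#' order so that ranking is deterministic.
#'
#' @param path Path to a codon usage CSV, or `NULL` for the packaged human
#'   default.
#' @return A `codon_table`: a data frame with columns `codon`, `amino_acid`,
#'   `fraction` and `rank` (1 = most frequent within its amino acid).
#' @export
load_codon_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_codon_usage_human.csv",
                        package = "sgedesign", mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("codon", "amino_acid", "fraction")
  if (!all(need %in% names(df))) {
    input_error("codon table must have columns ", paste(need, collapse = ", "))
  }
  df$codon <- toupper(df$codon)
  df$amino_acid <- toupper(df$amino_acid)
  if (anyDuplicated(df$codon)) {
    input_error("duplicate codon(s) in codon table: ",
                paste(unique(df$codon[duplicated(df$codon)]), collapse = ","))
  }
  missing <- setdiff(ALL_CODONS, df$codon)
  if (length(missing)) {
    input_error("codon table is missing codon(s): ",
                paste(missing, collapse = ","))
  }
  if (any(!is.finite(df$fraction)) || any(df$fraction < 0)) {
    input_error("codon fractions must be non-negative numbers")
  }
  expected <- unname(Biostrings::GENETIC_CODE[df$codon])
  bad <- df$amino_acid != expected
  if (any(bad)) {
    input_error("codon/amino-acid pairing inconsistent with the standard ",
                "genetic code: ", paste(df$codon[bad], collapse = ","))
  }
  df <- df[order(df$amino_acid, -df$fraction, df$codon), ]
  df$rank <- stats::ave(seq_len(nrow(df)), df$amino_acid,
                        FUN = seq_along)
  rownames(df) <- NULL
  class(df) <- c("codon_table", "data.frame")
  df
}

#' Translate a codon on a given strand
#'
#' Codons are stored as positive-strand genomic 3-mers; a codon of a
#' minus-strand transcript is reverse-complemented before lookup in the
#' standard genetic code, so the same nucleotide triplet translates
#' differently on the two strands.
#'
#' @param codon Character vector of 3-mers over `{A,C,G,T}`.
#' @param strand `"plus"` or `"minus"`.
#' @return One-letter amino acid codes (`*` for stop).
#' @export
translate_codon <- function(codon, strand = "plus") {
  strand <- normalize_strand(strand)
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) ||
      any(!strsplit(paste(codon, collapse = ""), "")[[1]] %in% DNA_BASES)) {
    input_error("codons must be 3-mers over {A,C,G,T}")
  }
  if (strand == "minus") codon <- revcomp(codon)
  unname(Biostrings::GENETIC_CODE[codon])
}

# Codons of the table sorted by rank for one amino acid.
ranked_codons <- function(codon_table, aa) {
  rows <- codon_table[codon_table$amino_acid == aa, ]
  rows$codon[order(rows$rank)]
}

top_codon <- function(codon_table, aa) {
  rc <- ranked_codons(codon_table, aa)
  if (!length(rc)) input_error("no codons for amino acid '", aa, "'")
  rc[[1L]]
}

# All synonymous alternatives of a codon (transcript-space strings).
synonymous_alternatives <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa],
          codon)
}

classify_consequence <- function(ref_aa, alt_aa) {
  ifelse(ref_aa == alt_aa, "synonymous",
         ifelse(alt_aa == "*", "nonsense", "missense"))
}

#' Build the strand-aware SNV annotation table
#'
#' Enumerates, for each requested strand and each of the 64 positive-strand
#' codons, the three alternative bases at each of the three codon positions
#' (9 single-nucleotide events per codon per strand), together with the
#' resulting codon, amino acid change and consequence class. With both
#' strands requested this is the full 3 x 3 x 64 x 2 = 1152-record table
#' from which SNV consequence annotation is looked up at run time.
#'
#' Codons are keyed as genomic (positive-strand, left-to-right) 3-mers;
#' `position_in_codon` is 0-based in that genomic order. Amino acids are
#' obtained by translating the codon on the record's strand, so the same
#' nucleotide change carries different consequences on the two strands.
#'
#' @param strands Character vector, subset of `c("plus", "minus")`.
#' @return A data frame of class `snv_table` with a `key` column used for
#'   constant-time lookup.
#' @export
build_snv_annotation_table <- function(strands = c("plus", "minus")) {
  strands <- vapply(strands, normalize_strand, character(1), USE.NAMES = FALSE)
  if (!length(strands)) input_error("at least one strand is required")
  recs <- list()
  for (strand in strands) {
    for (codon in ALL_CODONS) {
      ref_aa <- translate_codon(codon, strand)
      for (p in 0:2) {
        ref_base <- substr(codon, p + 1L, p + 1L)
        for (alt_base in setdiff(DNA_BASES, ref_base)) {
          alt_codon <- codon
          substr(alt_codon, p + 1L, p + 1L) <- alt_base
          alt_aa <- translate_codon(alt_codon, strand)
          recs[[length(recs) + 1L]] <- data.frame(
            strand = strand, ref_codon = codon, position_in_codon = p,
            ref_base = ref_base, alt_base = alt_base, alt_codon = alt_codon,
            ref_aa = ref_aa, alt_aa = alt_aa,
            consequence = classify_consequence(ref_aa, alt_aa),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  tbl <- do.call(rbind, recs)
  tbl$key <- paste(tbl$strand, tbl$ref_codon, tbl$position_in_codon,
                   tbl$alt_base, sep = ":")
  rownames(tbl) <- NULL
  class(tbl) <- c("snv_table", "data.frame")
  tbl
}

lookup_snv_record <- function(snv_table, strand, ref_codon, position_in_codon,
                              alt_base) {
  key <- paste(strand, ref_codon, position_in_codon, alt_base, sep = ":")
  hit <- snv_table[match(key, snv_table$key), ]
  if (anyNA(hit$strand)) {
    stop("internal error: SNV annotation record not found for ", key)
  }
  hit
}

#' Build the synonymous-substitution tables
#'
#' For each strand and each positive-strand codon, lists every synonymous
#' alternative codon (expressed positive-strand) ranked by codon usage, and
#' the top-ranking alternative. Non-degenerate codons (ATG, TGG on the
#' coding strand) map to empty sets.
#'
#' @param codon_table A [load_codon_table()] result.
#' @param strands Character vector, subset of `c("plus", "minus")`.
#' @return A list of class `snvre_tables` with per-strand lists mapping
#'   codon to a character vector of ranked synonymous alternatives, plus
#'   `top`: the single top-ranking alternative (or `NA`).
#' @export
build_snvre_tables <- function(codon_table, strands = c("plus", "minus")) {
  strands <- vapply(strands, normalize_strand, character(1), USE.NAMES = FALSE)
  if (!length(strands)) input_error("at least one strand is required")
  out <- list()
  for (strand in strands) {
    syn <- list()
    top <- character(0)
    for (codon in ALL_CODONS) {
      # transcript-space codon for this strand
      tx <- if (strand == "minus") revcomp(codon) else codon
      alts_tx <- synonymous_alternatives(tx)
      if (length(alts_tx)) {
        aa <- unname(Biostrings::GENETIC_CODE[tx])
        ranked <- intersect(ranked_codons(codon_table, aa), alts_tx)
        alts_g <- if (strand == "minus") revcomp(ranked) else ranked
        syn[[codon]] <- alts_g
        top[[codon]] <- alts_g[[1L]]
      } else {
        syn[[codon]] <- character(0)
        top[[codon]] <- NA_character_
      }
    }
    out[[strand]] <- list(synonymous = syn, top = top)
  }
  class(out) <- "snvre_tables"
  out
}
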