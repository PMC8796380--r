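#' Open an indexed reference FASTA
#'
#' Thin wrapper around [Rsamtools::FaFile()] that builds the `.fai` index if
#' it is missing and fails early when the file does not exist.
#'
#' @param path Path to a FASTA file.
#' @return An `FaFile` handle.
#' @export
open_fasta <- function(path) {
  if (!file.exists(path)) input_error("FASTA file not found: ", path)
  if (!file.exists(paste0(path, ".fai"))) {
    Rsamtools::indexFa(path)
  }
  Rsamtools::FaFile(path)
}

fasta_contigs <- function(fasta) {
  idx <- Rsamtools::scanFaIndex(fasta)
  setNames(GenomicRanges::end(idx), as.character(GenomicRanges::seqnames(idx)))
}

#' Retrieve a reference subsequence
#'
#' Fetches the positive-strand bases for a 1-based inclusive genomic range.
#' Unless the range starts at position one, the single nucleotide preceding
#' it is also retrieved; this base anchors liminal deletions and insertions
#' in the output VCF. Soft-masked (lowercase) bases are uppercased; bases
#' outside `{A,C,G,T,N}` are rejected.
#'
#' @param fasta An `FaFile` (see [open_fasta()]) or a path to a FASTA file.
#' @param range A [gnm_range()].
#' @return An object of class `ref_sequence` with fields `range`, `bases`
#'   (character scalar) and `preceding_base` (character scalar, or `NA` when
#'   `range$start == 1`).
#' @export
fetch_range <- function(fasta, range) {
  if (is.character(fasta)) fasta <- open_fasta(fasta)
  stopifnot(inherits(range, "gnm_range"))
  contigs <- fasta_contigs(fasta)
  if (!range$chrom %in% names(contigs)) {
    input_error("chromosome '", range$chrom, "' not present in FASTA (",
                paste(names(contigs), collapse = ", "), ")")
  }
  clen <- contigs[[range$chrom]]
  if (range$end > clen) {
    input_error("range end ", range$end, " exceeds length of contig '",
                range$chrom, "' (", clen, ")")
  }
  fetch_start <- if (range$start > 1L) range$start - 1L else range$start
  gr <- GenomicRanges::GRanges(range$chrom,
                               IRanges::IRanges(fetch_start, range$end))
  raw <- toupper(as.character(Rsamtools::scanFa(fasta, param = gr)[[1L]]))
  bad <- setdiff(unique(strsplit(raw, "")[[1L]]), c(DNA_BASES, "N"))
  if (length(bad)) {
    input_error("reference bases outside {A,C,G,T,N} in ", format(range),
                ": ", paste(bad, collapse = ","))
  }
  if (range$start > 1L) {
    preceding <- substr(raw, 1L, 1L)
    bases <- substr(raw, 2L, nchar(raw))
  } else {
    preceding <- NA_character_
    bases <- raw
  }
  structure(
    list(range = range, bases = bases, preceding_base = preceding),
    class = "ref_sequence"
  )
}

#' @export
print.ref_sequence <- function(x, ...) {
  cat("<ref_sequence> ", format(x$range), " (", nchar(x$bases), " bp)\n",
      sep = "")
  invisible(x)
}

# Base at a genomic position, preferring an (optionally edited) targeton
# sequence and falling back to the FASTA for positions outside it.
make_base_lookup <- function(fasta, chrom, overlay = NULL) {
  force(fasta); force(chrom); force(overlay)
  function(pos) {
    out <- character(length(pos))
    in_overlay <- rep(FALSE, length(pos))
    if (!is.null(overlay)) {
      in_overlay <- pos >= overlay$range$start & pos <= overlay$range$end
      if (any(in_overlay)) {
        off <- pos[in_overlay] - overlay$range$start + 1L
        out[in_overlay] <- substring(overlay$bases, off, off)
      }
    }
    if (any(!in_overlay)) {
      for (i in which(!in_overlay)) {
        r <- gnm_range(chrom, pos[i], pos[i])
        out[i] <- fetch_range(fasta, r)$bases
      }
    }
    out
  }
}

#' Write the sequence quality-control report
#'
#' One execution-wide CSV reporting the retrieved wild-type sequence for
#' every processed targeton, so that library designs can be eyeballed or
#' diffed against an independent sequence source.
#'
#' @param path Output CSV path.
#' @param targeton_ids Character vector of targeton identifiers (file stems).
#' @param sequences Character vector of wild-type sequences, parallel to
#'   `targeton_ids`.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(path, targeton_ids, sequences) {
  if (length(targeton_ids) != length(sequences)) {
    input_error("one wild-type sequence per targeton is required")
  }
  df <- data.frame(targeton_id = as.character(targeton_ids),
                   sequence = as.character(sequences),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
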