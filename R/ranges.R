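#' Genomic range (1-based, inclusive)
#'
#' The universal coordinate carrier of the package. Ranges are always
#' expressed on the positive strand with `start <= end`, regardless of the
#' strand of any overlapping transcript; the `strand` field records the
#' orientation of the associated feature (e.g. the transcript a targeton
#' belongs to), not the orientation of the coordinates.
#'
#' @param chrom Chromosome / contig identifier.
#' @param start 1-based inclusive start position (`>= 1`).
#' @param end 1-based inclusive end position (`>= start`).
#' @param strand `"plus"` or `"minus"` (the GTF/BED symbols `"+"`/`"-"` are
#'   also accepted and normalised).
#' @return An object of class `gnm_range`.
#' @export
gnm_range <- function(chrom, start, end, strand = "plus") {
  strand <- normalize_strand(strand)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end)) {
    input_error("range start/end must be integers")
  }
  if (start < 1L) input_error("range start must be >= 1, got ", start)
  if (end < start) {
    input_error("range end (", end, ") must be >= start (", start, ")")
  }
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         strand = strand),
    class = "gnm_range"
  )
}

normalize_strand <- function(strand) {
  s <- switch(as.character(strand),
    "plus" = "plus", "+" = "plus",
    "minus" = "minus", "-" = "minus",
    NULL
  )
  if (is.null(s)) input_error("invalid strand: ", strand)
  s
}

#' @export
format.gnm_range <- function(x, ...) {
  sprintf("%s:%d-%d(%s)", x$chrom, x$start, x$end, x$strand)
}

#' @export
print.gnm_range <- function(x, ...) {
  cat("<gnm_range> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Length of a genomic range in bases
#' @param r A `gnm_range`.
#' @return Integer length `end - start + 1`.
#' @export
range_length <- function(r) {
  if (is.null(r)) return(0L)
  r$end - r$start + 1L
}

#' Does a range fully contain positions or another range?
#' @param r A `gnm_range`.
#' @param pos Integer positions, or a `gnm_range`.
#' @keywords internal
range_contains <- function(r, pos) {
  if (inherits(pos, "gnm_range")) {
    return(identical(r$chrom, pos$chrom) && pos$start >= r$start &&
             pos$end <= r$end)
  }
  pos >= r$start & pos <= r$end
}
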