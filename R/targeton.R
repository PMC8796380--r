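TARGETON_COLUMNS <- c("ref_chr", "ref_strand", "ref_start", "ref_end",
                      "r2_start", "r2_end", "ext_vector", "action_vector",
                      "sgrna_ids")

#' Parse the targeton parameter file
#'
#' The targeton file is BED-like (tab-delimited, one design row per line)
#' but uses 1-based inclusive genomic coordinates throughout, matching VCF
#' and GTF conventions; it is never interpreted as 0-based BED. Required
#' columns: `ref_chr`, `ref_strand`, `ref_start`, `ref_end`, `r2_start`,
#' `r2_end`, `ext_vector` (two comma-separated non-negative lengths, r1 and
#' r3), `action_vector` (three `|`-separated comma lists of mutator names
#' for r1, r2, r3; a list may be empty) and `sgrna_ids` (comma-separated,
#' may be empty).
#'
#' @param tsv_source Path to the tab-delimited targeton file (header row
#'   required).
#' @return List of `targeton_spec` objects.
#' @export
parse_targeton_file <- function(tsv_source) {
  if (!file.exists(tsv_source)) {
    input_error("targeton file not found: ", tsv_source)
  }
  df <- read.delim(tsv_source, stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(TARGETON_COLUMNS, names(df))
  if (length(missing)) {
    input_error("targeton file is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    parse_targeton_row(row, i)
  })
}

split_list <- function(x) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
}

parse_targeton_row <- function(row, row_number) {
  where <- paste0("targeton file row ", row_number)
  ext <- suppressWarnings(as.integer(split_list(row$ext_vector)))
  if (length(ext) != 2L || anyNA(ext) || any(ext < 0L)) {
    input_error(where, ": ext_vector must be two non-negative integers ",
                "(r1 length, r3 length)")
  }
  actions_raw <- strsplit(row$action_vector, "|", fixed = TRUE)[[1L]]
  length(actions_raw) <- 3L  # pad with NA for trailing empty lists
  actions <- lapply(actions_raw, split_list)
  names(actions) <- c("r1", "r2", "r3")
  for (rg in names(actions)) {
    unknown <- setdiff(actions[[rg]], ALL_MUTATORS)
    if (length(unknown)) {
      input_error(where, ": unknown mutator name(s) for ", rg, ": ",
                  paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(actions[[rg]])) {
      input_error(where, ": duplicate mutator name(s) for ", rg)
    }
  }
  strand <- tryCatch(normalize_strand(row$ref_strand),
                     error = function(e) {
                       input_error(where, ": ", conditionMessage(e))
                     })
  num <- function(field) {
    v <- suppressWarnings(as.integer(row[[field]]))
    if (is.na(v)) input_error(where, ": ", field, " must be an integer")
    v
  }
  ref_start <- num("ref_start"); ref_end <- num("ref_end")
  r2_start <- num("r2_start"); r2_end <- num("r2_end")
  if (r2_start > r2_end) {
    input_error(where, ": r2_start must be <= r2_end")
  }
  if (ref_start > r2_start - ext[1L]) {
    input_error(where, ": r1 extension (", ext[1L],
                ") extends past ref_start")
  }
  if (r2_end + ext[2L] > ref_end) {
    input_error(where, ": r3 extension (", ext[2L], ") extends past ref_end")
  }
  structure(
    list(ref_chr = row$ref_chr, ref_strand = strand,
         range = gnm_range(row$ref_chr, ref_start, ref_end, strand),
         r2 = gnm_range(row$ref_chr, r2_start, r2_end, strand),
         ext_vector = c(r1 = ext[1L], r3 = ext[2L]),
         actions = actions,
         sgrna_ids = split_list(row$sgrna_ids),
         row_number = row_number),
    class = "targeton_spec"
  )
}

#' Partition a targeton into c1-r1-r2-r3-c2
#'
#' r1 and r3 are derived by extending the r2 range by the extension vector;
#' c1 and c2 are the remaining flanks of the targeton. The five regions are
#' adjacent, non-overlapping, in genomic order, and their union is the
#' targeton range. Constant regions c1/c2 never receive systematic
#' mutators (custom variants are still applied there).
#'
#' @param spec A `targeton_spec`.
#' @return A `region_partition`: named list of [gnm_range()]s (or `NULL`
#'   for empty regions) `c1`, `r1`, `r2`, `r3`, `c2`.
#' @export
partition_targeton <- function(spec) {
  chrom <- spec$ref_chr; strand <- spec$ref_strand
  rng <- function(s, e) {
    if (e < s) NULL else gnm_range(chrom, s, e, strand)
  }
  r1_start <- spec$r2$start - spec$ext_vector[["r1"]]
  r3_end <- spec$r2$end + spec$ext_vector[["r3"]]
  part <- list(
    c1 = rng(spec$range$start, r1_start - 1L),
    r1 = rng(r1_start, spec$r2$start - 1L),
    r2 = spec$r2,
    r3 = rng(spec$r2$end + 1L, r3_end),
    c2 = rng(r3_end + 1L, spec$range$end)
  )
  structure(part, class = "region_partition")
}

#' Flag target regions as coding or non-coding
#'
#' No discrete target region (r1, r2, r3) may span both coding and
#' non-coding sequence; constant regions c1/c2 may. UTR positions count as
#' non-coding, like intronic positions.
#'
#' @param partition A [partition_targeton()] result.
#' @param ann A `transcript_annotation`, or `NULL` when no transcript
#'   overlaps the targeton (all regions non-coding).
#' @return Named logical vector with entries `r1`, `r2`, `r3` (`NA` for
#'   empty regions).
#' @export
validate_region_homogeneity <- function(partition, ann) {
  out <- c(r1 = NA, r2 = NA, r3 = NA)
  for (rg in names(out)) {
    r <- partition[[rg]]
    if (is.null(r)) next
    coding <- is_coding_position(ann, seq.int(r$start, r$end))
    if (all(coding)) {
      out[[rg]] <- TRUE
    } else if (!any(coding)) {
      out[[rg]] <- FALSE
    } else {
      input_error("region ", rg, " (", format(r), ") spans both coding and ",
                  "non-coding sequence; discrete target regions must be ",
                  "homogeneous")
    }
  }
  out
}

#' File stem identifying a targeton
#'
#' All per-targeton output files are named after this stem, which reports
#' chromosome, coordinates, strand and any sgRNA identifiers:
#' `chr{chrom}_{start}_{end}_{plus|minus}[_{sgrna ids}]`. A chromosome name
#' already carrying a `chr` prefix is not double-prefixed.
#'
#' @param spec A `targeton_spec`.
#' @return Character scalar.
#' @export
targeton_file_stem <- function(spec) {
  chrom <- spec$ref_chr
  if (!startsWith(chrom, "chr")) chrom <- paste0("chr", chrom)
  stem <- paste(chrom, spec$range$start, spec$range$end, spec$ref_strand,
                sep = "_")
  if (length(spec$sgrna_ids)) {
    stem <- paste(c(stem, spec$sgrna_ids), collapse = "_")
  }
  stem
}
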