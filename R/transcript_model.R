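UTR_TYPES <- c("UTR", "five_prime_utr", "three_prime_utr", "5UTR", "3UTR")

#' Load transcript annotation from a GTF/GFF2 file
#'
#' Only CDS, UTR and stop-codon features are considered; all other feature
#' types (exon, gene, transcript, ...) are ignored. Exactly one transcript
#' per gene is allowed, so that target regions match a unique reading
#' frame. UTR positions are treated like intronic (non-coding) positions;
#' the stop-codon feature is carried as coding sequence so that SNVs (and
#' the stop-swap part of the snvre mutator) can act on it, but codon-level
#' scans skip it.
#'
#' The GTF frame/phase column (number of bases to remove from the feature
#' 5' end to reach the next complete codon) is validated against a walk of
#' the spliced CDS and used to derive the number of bases missing from the
#' first codon of each feature; missing (`.`) phases are computed from the
#' walk.
#'
#' @param gtf_source Path to a GTF/GFF2 file.
#' @return A named list (class `annotation_set`) of `transcript_annotation`
#'   objects, one per gene.
#' @export
load_annotation <- function(gtf_source) {
  if (!file.exists(gtf_source)) {
    input_error("GTF file not found: ", gtf_source)
  }
  n_rows <- length(grep("^[^#]", readLines(gtf_source, warn = FALSE),
                        value = TRUE))
  if (n_rows == 0L) {
    return(structure(list(), class = "annotation_set"))
  }
  g <- tryCatch(
    rtracklayer::import(gtf_source, format = "gtf"),
    error = function(e) input_error("malformed GTF file '", gtf_source,
                                    "': ", conditionMessage(e))
  )
  keep <- as.character(g$type) %in% c("CDS", "stop_codon", UTR_TYPES)
  g <- g[keep]
  if (!length(g)) return(structure(list(), class = "annotation_set"))
  if (is.null(g$gene_id) || is.null(g$transcript_id) ||
      anyNA(g$gene_id) || anyNA(g$transcript_id)) {
    input_error("GTF features must carry gene_id and transcript_id ",
                "attributes")
  }
  out <- list()
  for (gene in unique(g$gene_id)) {
    gg <- g[g$gene_id == gene]
    txs <- unique(gg$transcript_id)
    if (length(txs) > 1L) {
      input_error("gene '", gene, "' has ", length(txs), " transcripts (",
                  paste(txs, collapse = ", "), "); one transcript per gene ",
                  "is allowed to avoid ambiguities in matching target regions")
    }
    out[[gene]] <- new_transcript_annotation(gene, txs, gg)
  }
  structure(out, class = "annotation_set")
}

new_transcript_annotation <- function(gene_id, transcript_id, gg) {
  strands <- unique(as.character(GenomicRanges::strand(gg)))
  if (length(strands) != 1L || !strands %in% c("+", "-")) {
    input_error("gene '", gene_id, "' must have a single strand of +/-")
  }
  chroms <- unique(as.character(GenomicRanges::seqnames(gg)))
  if (length(chroms) != 1L) {
    input_error("gene '", gene_id, "' spans multiple contigs")
  }
  strand <- normalize_strand(strands)
  type <- as.character(gg$type)
  feat_df <- function(sel) {
    df <- data.frame(start = GenomicRanges::start(gg)[sel],
                     end = GenomicRanges::end(gg)[sel],
                     phase = if (!is.null(gg$phase)) as.integer(gg$phase)[sel]
                             else rep(NA_integer_, sum(sel)))
    df[order(df$start), , drop = FALSE]
  }
  cds <- feat_df(type == "CDS")
  utr <- feat_df(type %in% UTR_TYPES)
  stop_f <- feat_df(type == "stop_codon")
  if (nrow(stop_f) > 1L) {
    # stop codon may itself be split across exons; keep all pieces
    stop_f <- stop_f[order(stop_f$start), , drop = FALSE]
  }
  if (nrow(cds) > 1L) {
    if (any(cds$start[-1L] <= cds$end[-nrow(cds)])) {
      input_error("gene '", gene_id, "' has overlapping CDS features")
    }
  }
  ann <- structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         chrom = chroms, strand = strand,
         cds = cds, utr = utr,
         stop = if (nrow(stop_f)) stop_f else NULL),
    class = "transcript_annotation"
  )
  ann$map <- build_cds_map(ann)
  ann
}

# Transcript-order coordinate map of the coding sequence: genomic position
# of every CDS base in 5'->3' transcript order, with the stop-codon feature
# appended, plus the number of bases missing from the first codon (nonzero
# when the annotated CDS starts mid-codon).
build_cds_map <- function(ann) {
  tx_order <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    if (ann$strand == "plus") df[order(df$start), , drop = FALSE]
    else df[order(-df$start), , drop = FALSE]
  }
  cds <- tx_order(ann$cds)
  if (!nrow(cds)) {
    return(list(pos = integer(0), is_stop = logical(0), offset = 0L))
  }
  feat_pos <- function(row) {
    if (ann$strand == "plus") seq.int(row$start, row$end)
    else seq.int(row$end, row$start)
  }
  pos <- integer(0)
  cum_before <- integer(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    cum_before[i] <- length(pos)
    pos <- c(pos, feat_pos(cds[i, ]))
  }
  phase1 <- cds$phase[1L]
  if (is.na(phase1)) phase1 <- 0L
  offset <- (3L - phase1) %% 3L  # bases missing from the 5'-most codon
  # validate remaining phases against the spliced-CDS walk
  for (i in seq_len(nrow(cds))[-1L]) {
    p <- cds$phase[i]
    if (is.na(p)) next
    expected <- (3L - ((offset + cum_before[i]) %% 3L)) %% 3L
    if (p != expected) {
      input_error("gene '", ann$gene_id, "': CDS frame/phase ", p,
                  " of feature starting at ", cds$start[i],
                  " is inconsistent with the spliced CDS (expected ",
                  expected, ")")
    }
  }
  is_stop <- rep(FALSE, length(pos))
  if (!is.null(ann$stop)) {
    stop_rows <- tx_order(ann$stop)
    spos <- unlist(lapply(seq_len(nrow(stop_rows)),
                          function(i) feat_pos(stop_rows[i, ])))
    pos <- c(pos, spos)
    is_stop <- c(is_stop, rep(TRUE, length(spos)))
  }
  list(pos = pos, is_stop = is_stop, offset = offset)
}

#' Reading frame at a coding genomic position
#'
#' Returns the number of bases missing from the 5' end of the codon
#' containing `s_target`, measured along the transcript: 0 means the
#' position starts a codon, 1 that one codon base lies transcript-upstream
#' of it, 2 that two do. For a plus-strand feature with `f_exon` bases
#' missing from its first codon this is `(f_exon + (s_target - s_exon))
#' mod 3`; for minus-strand transcripts distance is measured from the
#' feature's genomic end, the transcript 5' side.
#'
#' @param ann A `transcript_annotation`.
#' @param s_target Genomic position (1-based).
#' @return Integer frame in `{0,1,2}`.
#' @export
frame_at <- function(ann, s_target) {
  idx <- match(as.integer(s_target), ann$map$pos)
  if (is.na(idx)) {
    stop(errorCondition(
      paste0("position ", s_target, " is non-coding for transcript ",
             ann$transcript_id),
      class = c("sgedesign_noncoding", "sgedesign_input_error", "error")
    ))
  }
  (ann$map$offset + idx - 1L) %% 3L
}

#' Liminal codon extension lengths
#'
#' Number of extra bases needed 5' and 3' of a coding target of length
#' `l_target` whose first codon is missing `f_target` bases, so that the
#' extended span covers whole codons: `l_ext5 = f_target` and
#' `l_ext3 = (3 - (l_target + f_target) mod 3) mod 3`.
#'
#' @param l_target Target length in bases (`>= 1`).
#' @param f_target Frame in `{0,1,2}`.
#' @return Integer vector `c(l_ext5, l_ext3)`.
#' @export
codon_extensions <- function(l_target, f_target) {
  stopifnot(l_target >= 1L, f_target %in% 0:2)
  l5 <- as.integer(f_target)
  l3 <- (3L - (as.integer(l_target) + l5) %% 3L) %% 3L
  c(l_ext5 = l5, l_ext3 = l3)
}

#' Frame context of a coding target range
#'
#' Computes the reading frame of a coding target and retrieves the liminal
#' bases required to complete its partial 5' and 3' codons. The extra bases
#' are taken in transcript order, so a target abutting an exon junction
#' pulls them from the adjacent exon (spliced context), never from the
#' intron.
#'
#' @param ann A `transcript_annotation`.
#' @param target_range A [gnm_range()] fully within the coding sequence.
#' @param base_lookup Function mapping genomic positions to positive-strand
#'   bases (see [fetch_range()]; internally an edited targeton sequence may
#'   overlay the FASTA).
#' @return A `frame_context` object; see [new_frame_context()].
#' @export
region_frame_context <- function(ann, target_range, base_lookup) {
  map <- ann$map
  tx_target <- if (ann$strand == "plus") {
    seq.int(target_range$start, target_range$end)
  } else {
    seq.int(target_range$end, target_range$start)
  }
  idx <- match(tx_target, map$pos)
  if (anyNA(idx)) {
    input_error("target ", format(target_range),
                " is not fully within the coding sequence of transcript ",
                ann$transcript_id)
  }
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    input_error("target ", format(target_range),
                " is not contiguous in transcript coordinates")
  }
  L <- length(idx)
  f <- (map$offset + idx[1L] - 1L) %% 3L
  ext <- codon_extensions(L, f)
  i5 <- seq_len(ext[["l_ext5"]]) - ext[["l_ext5"]] + idx[1L] - 1L
  i3 <- idx[L] + seq_len(ext[["l_ext3"]])
  if (any(i5 < 1L) || any(i3 > length(map$pos))) {
    input_error("liminal codon of target ", format(target_range),
                " is incomplete in transcript ", ann$transcript_id,
                " (context extends past the first/last CDS feature)")
  }
  tx_base <- function(indices) {
    if (!length(indices)) return("")
    b <- base_lookup(map$pos[indices])
    if (ann$strand == "minus") b <- complement_base(b)
    paste(b, collapse = "")
  }
  new_frame_context(
    region = target_range, strand = ann$strand, frame = f,
    ext5_pos = map$pos[i5], ext5_tx = tx_base(i5),
    ext3_pos = map$pos[i3], ext3_tx = tx_base(i3),
    region_is_stop = map$is_stop[idx]
  )
}

#' Construct a frame context directly
#'
#' Low-level constructor used by the cDNA mode (where frame is derived from
#' user-supplied coordinates instead of a GTF) and by tests. Liminal bases
#' (`ext5_tx`/`ext3_tx`) are given in transcript orientation; genomic
#' positions are positive-strand, listed in transcript order.
#'
#' @param region The coding target [gnm_range()].
#' @param strand Transcript strand, `"plus"` or `"minus"`.
#' @param frame Bases missing from the target's 5' codon, in `{0,1,2}`.
#' @param ext5_pos,ext3_pos Genomic positions of the liminal bases.
#' @param ext5_tx,ext3_tx Liminal bases (transcript orientation strings).
#' @param region_is_stop Logical vector flagging target positions that fall
#'   in an annotated stop-codon feature (transcript order).
#' @return A `frame_context` object.
#' @export
new_frame_context <- function(region, strand, frame,
                              ext5_pos = integer(0), ext5_tx = "",
                              ext3_pos = integer(0), ext3_tx = "",
                              region_is_stop = NULL) {
  strand <- normalize_strand(strand)
  L <- range_length(region)
  ext <- codon_extensions(L, frame)
  if (nchar(ext5_tx) != ext[["l_ext5"]] || nchar(ext3_tx) != ext[["l_ext3"]]) {
    input_error("liminal context lengths do not match the frame: need ",
                ext[["l_ext5"]], "/", ext[["l_ext3"]], " bases, got ",
                nchar(ext5_tx), "/", nchar(ext3_tx))
  }
  if (is.null(region_is_stop)) region_is_stop <- rep(FALSE, L)
  tx_pos <- if (strand == "plus") seq.int(region$start, region$end)
            else seq.int(region$end, region$start)
  structure(
    list(region = region, strand = strand, frame = as.integer(frame),
         l5 = ext[["l_ext5"]], l3 = ext[["l_ext3"]],
         ext5_pos = as.integer(ext5_pos), ext5_tx = ext5_tx,
         ext3_pos = as.integer(ext3_pos), ext3_tx = ext3_tx,
         region_tx_pos = tx_pos, region_is_stop = region_is_stop),
    class = "frame_context"
  )
}

#' Liminal context bases of a coding target
#'
#' Convenience accessor returning the 5' and 3' liminal bases of a coding
#' target as positive-strand genomic bases with their genomic positions.
#'
#' @inheritParams region_frame_context
#' @param fasta_source FASTA path or `FaFile` used to look bases up.
#' @return List with data frames `ext5` and `ext3` (columns `pos`, `base`;
#'   positive-strand bases, rows in transcript order).
#' @export
liminal_context <- function(ann, fasta_source, target_range) {
  lookup <- make_base_lookup(
    if (is.character(fasta_source)) open_fasta(fasta_source) else fasta_source,
    target_range$chrom
  )
  ctx <- region_frame_context(ann, target_range, lookup)
  strip <- function(pos, tx) {
    b <- strsplit(tx, "")[[1L]]
    if (ctx$strand == "minus") b <- complement_base(b)
    data.frame(pos = pos, base = b, stringsAsFactors = FALSE)
  }
  list(ext5 = strip(ctx$ext5_pos, ctx$ext5_tx),
       ext3 = strip(ctx$ext3_pos, ctx$ext3_tx),
       frame = ctx$frame)
}

# Is each genomic position coding (CDS or stop feature) for this transcript?
is_coding_position <- function(ann, pos) {
  if (is.null(ann)) return(rep(FALSE, length(pos)))
  pos %in% ann$map$pos
}

# The unique transcript annotation overlapping a targeton, or NULL.
find_annotation <- function(annotations, range) {
  if (is.null(annotations) || !length(annotations)) return(NULL)
  hits <- Filter(function(ann) {
    feats <- rbind(ann$cds[, c("start", "end")],
                   ann$utr[, c("start", "end")],
                   if (!is.null(ann$stop)) ann$stop[, c("start", "end")])
    identical(ann$chrom, range$chrom) && nrow(feats) > 0 &&
      any(feats$start <= range$end & feats$end >= range$start)
  }, annotations)
  if (length(hits) > 1L) {
    input_error("targeton ", format(range), " overlaps ", length(hits),
                " genes (", paste(names(hits), collapse = ", "),
                "); one transcript per targeton is required")
  }
  if (length(hits)) hits[[1L]] else NULL
}
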