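VARIANT_COLUMNS <- c("region", "mutator", "id", "pos", "ref", "alt", "type",
                     "ref_aa", "alt_aa", "consequence")

empty_variants <- function() {
  data.frame(region = character(0), mutator = character(0), id = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             type = character(0), ref_aa = character(0),
             alt_aa = character(0), consequence = character(0),
             stringsAsFactors = FALSE)
}

new_variants <- function(mutator, pos, ref, alt, type,
                         ref_aa = NA_character_, alt_aa = NA_character_,
                         consequence = NA_character_, id = NA_character_,
                         region = NA_character_) {
  n <- length(pos)
  if (!n) return(empty_variants())
  data.frame(region = rep_len(region, n), mutator = rep_len(mutator, n),
             id = rep_len(id, n), pos = as.integer(pos),
             ref = ref, alt = alt, type = rep_len(type, n),
             ref_aa = rep_len(ref_aa, n), alt_aa = rep_len(alt_aa, n),
             consequence = rep_len(consequence, n),
             stringsAsFactors = FALSE)
}

check_region_seq <- function(region_seq) {
  if (!nchar(region_seq)) return(invisible(TRUE))
  chars <- unique(strsplit(region_seq, "")[[1L]])
  bad <- setdiff(chars, DNA_BASES)
  if (length(bad)) {
    input_error("region sequence contains bases outside {A,C,G,T}: ",
                paste(bad, collapse = ","))
  }
  invisible(TRUE)
}

# Transcript-space layout of a coding region plus its liminal context:
# the full in-frame sequence, the genomic position of every base (in
# transcript order) and the codon grid.
codon_layout <- function(region_seq, context) {
  tx_region <- if (context$strand == "minus") revcomp(region_seq)
               else region_seq
  full_tx <- paste0(context$ext5_tx, tx_region, context$ext3_tx)
  full_pos <- c(context$ext5_pos, context$region_tx_pos, context$ext3_pos)
  stopifnot(nchar(full_tx) == length(full_pos),
            nchar(full_tx) %% 3L == 0L)
  list(full_tx = full_tx, full_pos = full_pos,
       tx_chars = strsplit(full_tx, "")[[1L]],
       n_codons = nchar(full_tx) %/% 3L)
}

# Complete (non-liminal) codons of a coding region: codons whose three
# bases all fall inside the region itself.
complete_codons <- function(region_seq, context) {
  lay <- codon_layout(region_seq, context)
  L <- range_length(context$region)
  lo <- context$l5 + 1L
  hi <- context$l5 + L
  out <- list()
  for (k in seq_len(lay$n_codons)) {
    idx <- (3L * k - 2L):(3L * k)
    if (idx[1L] < lo || idx[3L] > hi) next  # liminal codon
    gpos <- lay$full_pos[idx]
    g_start <- min(gpos)
    tx_codon <- paste(lay$tx_chars[idx], collapse = "")
    reg_idx <- idx - context$l5
    out[[length(out) + 1L]] <- data.frame(
      codon_index = k, tx_codon = tx_codon, g_start = g_start,
      g_ref = if (context$strand == "minus") revcomp(tx_codon) else tx_codon,
      is_stop_feature = any(context$region_is_stop[reg_idx]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(codon_index = integer(0), tx_codon = character(0),
                      g_start = integer(0), g_ref = character(0),
                      is_stop_feature = logical(0)))
  }
  do.call(rbind, out)
}

# Annotate SNVs at given genomic positions/alts with codon consequence via
# the precomputed SNV annotation table.
annotate_snvs <- function(pos, alt, region_seq, context, snv_table) {
  lay <- codon_layout(region_seq, context)
  pos_chars <- if (context$strand == "minus") complement_base(lay$tx_chars)
               else lay$tx_chars
  n <- length(pos)
  ref_aa <- alt_aa <- consequence <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tx_i <- context$l5 + match(pos[i], context$region_tx_pos)
    k <- (tx_i - 1L) %/% 3L + 1L
    idx <- (3L * k - 2L):(3L * k)
    gpos <- lay$full_pos[idx]
    ord <- order(gpos)
    codon_g <- paste(pos_chars[idx][ord], collapse = "")
    p_in_codon <- which(sort(gpos) == pos[i]) - 1L
    rec <- lookup_snv_record(snv_table, context$strand, codon_g,
                             p_in_codon, alt[i])
    ref_aa[i] <- rec$ref_aa
    alt_aa[i] <- rec$alt_aa
    consequence[i] <- rec$consequence
  }
  list(ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence)
}

#' Single-nucleotide saturation mutator ('snv')
#'
#' Emits every possible single-base substitution at every position of the
#' region: exactly `3 * L` records for a region of length `L`. In coding
#' regions the records are annotated with the amino-acid change and its
#' consequence class (synonymous/missense/nonsense); SNVs in partial,
#' liminal codons are annotated using the adjacent exonic bases supplied by
#' the frame context.
#'
#' @param region_seq Positive-strand region sequence.
#' @param region_start Genomic start of the region (1-based).
#' @param context Optional [new_frame_context()] for coding regions.
#' @param snv_table Optional [build_snv_annotation_table()] result
#'   (required when `context` is given).
#' @param mutator_label Label recorded in the `mutator` column.
#' @return Variant record data frame.
#' @export
mutate_snv <- function(region_seq, region_start, context = NULL,
                       snv_table = NULL, mutator_label = "snv") {
  check_region_seq(region_seq)
  L <- nchar(region_seq)
  if (!L) return(empty_variants())
  bases <- strsplit(region_seq, "")[[1L]]
  pos <- rep(region_start + seq_len(L) - 1L, each = 3L)
  ref <- rep(bases, each = 3L)
  alt <- unlist(lapply(bases, function(b) setdiff(DNA_BASES, b)),
                use.names = FALSE)
  rec <- new_variants(mutator_label, pos, ref, alt, "snv")
  if (!is.null(context)) {
    if (is.null(snv_table)) {
      input_error("an SNV annotation table is required to annotate coding ",
                  "regions")
    }
    ann <- annotate_snvs(rec$pos, rec$alt, region_seq, context, snv_table)
    rec$ref_aa <- ann$ref_aa
    rec$alt_aa <- ann$alt_aa
    rec$consequence <- ann$consequence
  }
  rec
}

#' Single-nucleotide deletion mutator ('1del')
#'
#' Deletes each nucleotide of the region in turn: `L` records.
#'
#' @inheritParams mutate_snv
#' @return Variant record data frame (`type = "deletion"`; deleted bases in
#'   `ref`, empty `alt`).
#' @export
mutate_single_del <- function(region_seq, region_start) {
  check_region_seq(region_seq)
  L <- nchar(region_seq)
  if (!L) return(empty_variants())
  pos <- region_start + seq_len(L) - 1L
  new_variants("1del", pos, strsplit(region_seq, "")[[1L]], "", "deletion")
}

#' Tandem dinucleotide deletion mutators ('2del0'/'2del1')
#'
#' Deletes non-overlapping adjacent base pairs walking 5' to 3' from the
#' given offset (0 or 1 bases into the region); a trailing unpaired base is
#' left untouched. `floor((L - offset) / 2)` records.
#'
#' @inheritParams mutate_snv
#' @param offset 0 (pairs start at the first base) or 1 (the first base is
#'   skipped).
#' @return Variant record data frame.
#' @export
mutate_tandem_del <- function(region_seq, region_start, offset = 0L) {
  check_region_seq(region_seq)
  stopifnot(offset %in% c(0L, 1L))
  L <- nchar(region_seq)
  n <- max(0L, (L - as.integer(offset)) %/% 2L)
  if (!n) return(empty_variants())
  starts <- as.integer(offset) + 2L * (seq_len(n) - 1L) + 1L
  ref <- substring(region_seq, starts, starts + 1L)
  new_variants(paste0("2del", offset), region_start + starts - 1L, ref, "",
               "deletion")
}

#' SNV plus redundant-codon expansion mutator ('snvre')
#'
#' Runs the full SNV saturation (records labelled `snv`, consequence
#' annotated) and then expands it at the codon level (records labelled
#' `snvre`):
#'
#' * for every complete codon where some SNV is synonymous, every remaining
#'   synonymous codon not reachable by a single SNV is emitted as a codon
#'   substitution — completing the synonymous sets of 6-fold degenerate
#'   codons and the stop-codon pair TGA<->TAG;
#' * for every missense SNV outcome on a complete codon, one redundant
#'   codon substitution encoding the same amino acid through the most
#'   frequent codon (or the next most frequent when the SNV already
#'   produced the most frequent); nothing is emitted when the target amino
#'   acid is non-degenerate or when another SNV of the same codon already
#'   yields the chosen redundant codon.
#'
#' Partial (liminal) codons receive SNVs only; codon substitutions are
#' never applied to them.
#'
#' @inheritParams mutate_snv
#' @param snvre_tables A [build_snvre_tables()] result (synonymous sets).
#' @param codon_table A [load_codon_table()] result (codon ranking).
#' @return Variant record data frame.
#' @export
mutate_snvre <- function(region_seq, region_start, context, snv_table,
                         snvre_tables, codon_table) {
  if (is.null(context)) input_error("'snvre' requires a coding region")
  snv_part <- mutate_snv(region_seq, region_start, context, snv_table,
                         mutator_label = "snv")
  codons <- complete_codons(region_seq, context)
  extra <- list()
  for (i in seq_len(nrow(codons))) {
    wt_tx <- codons$tx_codon[i]
    wt_aa <- unname(Biostrings::GENETIC_CODE[wt_tx])
    # the nine transcript-space codons one SNV away
    nine <- character(0)
    for (p in 1:3) {
      for (b in setdiff(DNA_BASES, substr(wt_tx, p, p))) {
        v <- wt_tx; substr(v, p, p) <- b
        nine <- c(nine, v)
      }
    }
    alts_tx <- character(0)
    # (a) complete the synonymous set beyond single-SNV reach
    alts_tx <- c(alts_tx, setdiff(synonymous_alternatives(wt_tx), nine))
    # (b) redundant codons for missense SNV outcomes
    for (alt_codon in nine) {
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      if (classify_consequence(wt_aa, alt_aa) != "missense") next
      ranked <- ranked_codons(codon_table, alt_aa)
      cand <- ranked[ranked != alt_codon]
      if (!length(cand)) next          # non-degenerate target amino acid
      cand <- cand[[1L]]
      if (cand %in% nine) next         # snv alone already yields it
      alts_tx <- c(alts_tx, cand)
    }
    alts_tx <- unique(alts_tx)
    if (!length(alts_tx)) next
    alt_g <- if (context$strand == "minus") revcomp(alts_tx) else alts_tx
    alt_aas <- unname(Biostrings::GENETIC_CODE[alts_tx])
    extra[[length(extra) + 1L]] <- new_variants(
      "snvre", rep(codons$g_start[i], length(alts_tx)),
      rep(codons$g_ref[i], length(alts_tx)), alt_g, "codon_substitution",
      ref_aa = wt_aa, alt_aa = alt_aas,
      consequence = classify_consequence(wt_aa, alt_aas)
    )
  }
  rbind(snv_part, do.call(rbind, c(list(empty_variants()), extra)))
}

#' In-frame codon deletion mutator ('inframe')
#'
#' Deletes each complete codon of the region in turn, producing in-frame
#' triplet deletions; partial (liminal) codons and the annotated stop
#' codon are never deleted.
#'
#' @inheritParams mutate_snvre
#' @return Variant record data frame (`type = "codon_deletion"`).
#' @export
mutate_inframe <- function(region_seq, region_start, context) {
  if (is.null(context)) input_error("'inframe' requires a coding region")
  codons <- complete_codons(region_seq, context)
  codons <- codons[!codons$is_stop_feature, , drop = FALSE]
  new_variants("inframe", codons$g_start, codons$g_ref, "", "codon_deletion",
               ref_aa = unname(Biostrings::GENETIC_CODE[codons$tx_codon]))
}

#' Alanine / stop codon scan mutators ('ala'/'stop')
#'
#' Replaces each complete codon with the single top-ranking alanine (or
#' stop) codon of the codon usage table. Codons already equal to that
#' top-ranking codon are skipped, so no wild-type sequence is ever emitted
#' as a variant; partial codons and the annotated stop codon are skipped.
#'
#' @inheritParams mutate_snvre
#' @param target `"alanine"` or `"stop"`.
#' @return Variant record data frame.
#' @export
mutate_codon_scan <- function(region_seq, region_start, context, codon_table,
                              target = c("alanine", "stop")) {
  if (is.null(context)) {
    input_error("codon scans require a coding region")
  }
  target <- match.arg(target)
  aa_t <- if (target == "alanine") "A" else "*"
  top_tx <- top_codon(codon_table, aa_t)
  codons <- complete_codons(region_seq, context)
  codons <- codons[!codons$is_stop_feature & codons$tx_codon != top_tx, ,
                   drop = FALSE]
  if (!nrow(codons)) return(empty_variants())
  alt_g <- if (context$strand == "minus") revcomp(top_tx) else top_tx
  wt_aa <- unname(Biostrings::GENETIC_CODE[codons$tx_codon])
  new_variants(if (target == "alanine") "ala" else "stop",
               codons$g_start, codons$g_ref, alt_g, "codon_substitution",
               ref_aa = wt_aa, alt_aa = aa_t,
               consequence = classify_consequence(wt_aa, aa_t))
}

#' Amino-acid scan mutator ('aa')
#'
#' Replaces each complete codon with the most frequent codon of every other
#' amino acid (19 substitutions per codon under the standard code).
#' Substitution to stop is not included (the dedicated stop scan covers
#' truncations); partial codons and the annotated stop codon are skipped.
#'
#' @inheritParams mutate_snvre
#' @return Variant record data frame.
#' @export
mutate_aa_scan <- function(region_seq, region_start, context, codon_table) {
  if (is.null(context)) input_error("'aa' requires a coding region")
  aas <- sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*"))
  codons <- complete_codons(region_seq, context)
  codons <- codons[!codons$is_stop_feature, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(codons))) {
    wt_aa <- unname(Biostrings::GENETIC_CODE[codons$tx_codon[i]])
    targets <- setdiff(aas, wt_aa)
    alt_tx <- vapply(targets, top_codon, character(1),
                     codon_table = codon_table)
    alt_g <- if (context$strand == "minus") revcomp(alt_tx) else alt_tx
    out[[length(out) + 1L]] <- new_variants(
      "aa", rep(codons$g_start[i], length(targets)),
      rep(codons$g_ref[i], length(targets)), unname(alt_g),
      "codon_substitution", ref_aa = wt_aa, alt_aa = targets,
      consequence = "missense"
    )
  }
  do.call(rbind, c(list(empty_variants()), out))
}

#' Run a targeton's action vector
#'
#' Applies each region's mutator list to the (PAM-protected) region
#' sequence and concatenates the resulting variant records, tagged by
#' region and mutator. Constant regions receive no systematic mutators.
#' CDS-specific mutators on a non-coding region are an input error. When a
#' region requests both `snv` and `snvre` the SNV set is emitted once
#' (snvre already includes it).
#'
#' @param spec A `targeton_spec`.
#' @param partition The [partition_targeton()] result.
#' @param region_seqs Named list (`r1`, `r2`, `r3`) of positive-strand
#'   region sequences (from the protected reference).
#' @param contexts Named list of [new_frame_context()] objects for coding
#'   regions (`NULL` entries for non-coding regions).
#' @param coding_flags Result of [validate_region_homogeneity()].
#' @param tables List with `snv_table`, `snvre_tables`, `codon_table`.
#' @return Variant record data frame.
#' @export
run_action_vector <- function(spec, partition, region_seqs, contexts,
                              coding_flags, tables) {
  out <- list(empty_variants())
  for (rg in c("r1", "r2", "r3")) {
    mutators <- spec$actions[[rg]]
    if (!length(mutators)) next
    r <- partition[[rg]]
    if (is.null(r)) {
      input_error("mutators requested for empty region ", rg,
                  " of targeton ", format(spec$range))
    }
    seq_r <- region_seqs[[rg]]
    ctx <- contexts[[rg]]
    coding <- isTRUE(coding_flags[[rg]])
    if (grepl("N", seq_r, fixed = TRUE)) {
      input_error("region ", rg, " of targeton ", format(spec$range),
                  " contains N bases; mutating unknown bases is undefined")
    }
    if ("snvre" %in% mutators) mutators <- setdiff(mutators, "snv")
    for (m in mutators) {
      if (is_cds_mutator(m) && !coding) {
        input_error("CDS mutator '", m, "' assigned to non-coding region ",
                    rg, " of targeton ", format(spec$range))
      }
      rec <- switch(m,
        "snv" = mutate_snv(seq_r, r$start,
                           context = if (coding) ctx else NULL,
                           snv_table = tables$snv_table),
        "1del" = mutate_single_del(seq_r, r$start),
        "2del0" = mutate_tandem_del(seq_r, r$start, 0L),
        "2del1" = mutate_tandem_del(seq_r, r$start, 1L),
        "snvre" = mutate_snvre(seq_r, r$start, ctx, tables$snv_table,
                               tables$snvre_tables, tables$codon_table),
        "inframe" = mutate_inframe(seq_r, r$start, ctx),
        "ala" = mutate_codon_scan(seq_r, r$start, ctx, tables$codon_table,
                                  "alanine"),
        "stop" = mutate_codon_scan(seq_r, r$start, ctx, tables$codon_table,
                                   "stop"),
        "aa" = mutate_aa_scan(seq_r, r$start, ctx, tables$codon_table),
        input_error("unknown mutator '", m, "'")
      )
      if (nrow(rec)) rec$region <- rg
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Apply a variant record to a sequence
#'
#' Applies one variant record (package position dialect: deletions start at
#' the first deleted base, insertions at the first inserted position) to a
#' positive-strand sequence starting at `seq_start`.
#'
#' @param seq Sequence string.
#' @param seq_start Genomic position of the first base of `seq`.
#' @param rec One-row variant record data frame.
#' @param check_ref Verify the record's `ref` against the sequence.
#' @return The mutated sequence string.
#' @export
apply_variant <- function(seq, seq_start, rec, check_ref = TRUE) {
  o <- rec$pos - seq_start + 1L
  len <- nchar(seq)
  type <- rec$type
  if (type %in% c("snv", "codon_substitution", "indel", "substitution")) {
    n <- nchar(rec$ref)
    if (o < 1L || o + n - 1L > len) {
      stop("variant at ", rec$pos, " does not fit the sequence")
    }
    if (check_ref && substr(seq, o, o + n - 1L) != rec$ref) {
      stop("reference mismatch at ", rec$pos, ": expected '", rec$ref,
           "', sequence has '", substr(seq, o, o + n - 1L), "'")
    }
    paste0(substr(seq, 1L, o - 1L), rec$alt, substr(seq, o + n, len))
  } else if (type %in% c("deletion", "codon_deletion")) {
    n <- nchar(rec$ref)
    if (o < 1L || o + n - 1L > len) {
      stop("deletion at ", rec$pos, " does not fit the sequence")
    }
    if (check_ref && substr(seq, o, o + n - 1L) != rec$ref) {
      stop("reference mismatch at ", rec$pos, ": expected '", rec$ref,
           "', sequence has '", substr(seq, o, o + n - 1L), "'")
    }
    paste0(substr(seq, 1L, o - 1L), substr(seq, o + n, len))
  } else if (type == "insertion") {
    if (o < 1L || o > len + 1L) {
      stop("insertion at ", rec$pos, " does not fit the sequence")
    }
    paste0(substr(seq, 1L, o - 1L), rec$alt, substr(seq, o, len))
  } else {
    stop("unknown variant type '", type, "'")
  }
}
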