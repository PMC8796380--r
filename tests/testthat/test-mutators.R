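plain_ctx <- function(start, len, strand = "plus", frame = 0L,
                      ext5 = "", ext3 = "") {
  # liminal genomic positions adjacent to the region (contiguous exon)
  l5 <- nchar(ext5); l3 <- nchar(ext3)
  p5 <- if (l5) {
    p <- if (strand == "plus") start - l5:1 else start + len - 1L + l5:1
    if (strand == "plus") p else sort(p, decreasing = TRUE)
  } else integer(0)
  p3 <- if (l3) {
    if (strand == "plus") start + len - 1L + 1:l3 else start - 1:l3
  } else integer(0)
  new_frame_context(gnm_range("T", start, start + len - 1L, strand),
                    strand, frame, ext5_pos = p5, ext5_tx = ext5,
                    ext3_pos = p3, ext3_tx = ext3)
}

test_that("basic mutator counts obey the enumeration laws", {
  set.seed(3)
  for (L in c(0:6, 11L, 24L, 25L, 54L)) {
    s <- if (L) random_dna(L) else ""
    expect_identical(nrow(mutate_snv(s, 101L)), 3L * L)
    expect_identical(nrow(mutate_single_del(s, 101L)), L)
    expect_identical(nrow(mutate_tandem_del(s, 101L, 0L)), L %/% 2L)
    expect_identical(nrow(mutate_tandem_del(s, 101L, 1L)),
                     max(0L, (L - 1L) %/% 2L))
  }
  # the published 25 bp intronic flank yields 75 SNVs and 12 offset pairs
  s25 <- random_dna(25)
  expect_identical(nrow(mutate_snv(s25, 1L)), 75L)
  expect_identical(nrow(mutate_tandem_del(s25, 1L, 1L)), 12L)
  expect_identical(nrow(mutate_tandem_del(s25, 1L, 0L)), 12L)
  expect_identical(nrow(mutate_tandem_del("AC", 1L, 1L)), 0L)
})

test_that("mutator records are distinct and never reproduce the wild type", {
  set.seed(8)
  for (rep in 1:10) {
    L <- sample(3:30, 1)
    s <- random_dna(L)
    for (recs in list(mutate_snv(s, 201L), mutate_single_del(s, 201L),
                      mutate_tandem_del(s, 201L, 0L),
                      mutate_tandem_del(s, 201L, 1L))) {
      if (!nrow(recs)) next
      key <- paste(recs$pos, recs$ref, recs$alt)
      expect_identical(anyDuplicated(key), 0L)
      for (i in seq_len(nrow(recs))) {
        expect_false(apply_variant(s, 201L, recs[i, ]) == s)
      }
    }
  }
  # 1del covers every offset exactly once
  d <- mutate_single_del(random_dna(10), 301L)
  expect_identical(d$pos, 301L + 0:9)
})

test_that("snv annotation uses liminal context across split codons", {
  tabs <- shared_tables()
  # plus strand, frame 1: first base completes a codon with one upstream base
  s <- "TGCCA"                     # with upstream A: codons ATG | CCA
  ctx <- plain_ctx(100L, 5L, "plus", 1L, ext5 = "A")
  recs <- mutate_snv(s, 100L, context = ctx, snv_table = tabs$snv_table)
  expect_identical(nrow(recs), 15L)
  expect_false(anyNA(recs$consequence))
  # position 100 sits in codon A|TG (Met): G>A at 101 gives ATA (Ile)
  r <- recs[recs$pos == 101L & recs$alt == "A", ]
  expect_identical(r$ref_aa, "M")
  expect_identical(r$alt_aa, "I")
  expect_identical(r$consequence, "missense")
  # minus strand single codon: positive-strand CAT reads ATG
  ctxm <- plain_ctx(200L, 3L, "minus", 0L)
  rm_ <- mutate_snv("CAT", 200L, context = ctxm, snv_table = tabs$snv_table)
  expect_identical(unique(rm_$ref_aa), "M")
  # C>T at 202 (middle base A -> revcomp T…): check one explicit case:
  # pos 200 base C -> A gives AAT, transcript ATT (Ile)
  r2 <- rm_[rm_$pos == 200L & rm_$alt == "A", ]
  expect_identical(r2$alt_aa, "I")
})

test_that("snvre completes the synonymous set for all codons and strands", {
  tabs <- shared_tables()
  for (strand in c("plus", "minus")) {
    for (tx_codon in sgedesign:::ALL_CODONS) {
      region_seq <- if (strand == "minus") {
        paste(rev(strsplit(chartr("ACGT", "TGCA", tx_codon), "")[[1]]),
              collapse = "")
      } else tx_codon
      ctx <- plain_ctx(500L, 3L, strand, 0L)
      recs <- mutate_snvre(region_seq, 500L, ctx, tabs$snv_table,
                           tabs$snvre_tables, tabs$codon_table)
      syn_products <- character(0)
      for (i in seq_len(nrow(recs))) {
        if (identical(recs$consequence[i], "synonymous")) {
          syn_products <- c(syn_products,
                            applied_tx_codon(recs[i, ], region_seq, 500L,
                                             strand))
        }
      }
      # brute-force expectation: every other codon of the same amino acid
      expected <- setdiff(
        names(Biostrings::GENETIC_CODE)[
          Biostrings::GENETIC_CODE ==
            unname(Biostrings::GENETIC_CODE[tx_codon])], tx_codon)
      expect_identical(sort(syn_products), sort(expected))
      expect_identical(anyDuplicated(syn_products), 0L)
    }
  }
})

test_that("snvre swaps the two-substitution stop pair TGA <-> TAG", {
  tabs <- shared_tables()
  ctx <- plain_ctx(10L, 3L, "plus", 0L)
  recs <- mutate_snvre("TGA", 10L, ctx, tabs$snv_table, tabs$snvre_tables,
                       tabs$codon_table)
  subs <- recs[recs$type == "codon_substitution", ]
  expect_true("TAG" %in% subs$alt)
  recs2 <- mutate_snvre("TAG", 10L, ctx, tabs$snv_table, tabs$snvre_tables,
                        tabs$codon_table)
  expect_true("TGA" %in% recs2[recs2$type == "codon_substitution", ]$alt)
})

test_that("no redundant codon is emitted for non-degenerate products", {
  tabs <- shared_tables()
  ctx <- plain_ctx(10L, 3L, "plus", 0L)
  # ACG -> ATG (Met) by snv; Met has no alternative codon
  recs <- mutate_snvre("ACG", 10L, ctx, tabs$snv_table, tabs$snvre_tables,
                       tabs$codon_table)
  met_subs <- recs[recs$type == "codon_substitution" & recs$alt_aa == "M", ]
  expect_identical(nrow(met_subs), 0L)
})

test_that("redundant codons follow the most-frequent / next-most-frequent rule", {
  tabs <- shared_tables()
  ctx <- plain_ctx(10L, 3L, "plus", 0L)
  # GCC -> TCC (Ser) by snv; top Ser codon AGC is not single-SNV reachable
  recs <- mutate_snvre("GCC", 10L, ctx, tabs$snv_table, tabs$snvre_tables,
                       tabs$codon_table)
  ser <- recs[recs$type == "codon_substitution" & recs$alt_aa == "S", ]
  expect_true("AGC" %in% ser$alt)
  # AGG -> AGC (top Ser) by snv; the redundant falls to the next (TCC)
  recs2 <- mutate_snvre("AGG", 10L, ctx, tabs$snv_table, tabs$snvre_tables,
                        tabs$codon_table)
  ser2 <- recs2[recs2$type == "codon_substitution" & recs2$alt_aa == "S", ]
  expect_true("TCC" %in% ser2$alt)
  expect_false("AGC" %in% ser2$alt)
})

test_that("inframe deletes exactly the complete codons", {
  set.seed(4)
  ctx9 <- plain_ctx(30L, 9L, "plus", 0L)
  recs9 <- mutate_inframe(random_dna(9), 30L, ctx9)
  expect_identical(nrow(recs9), 3L)
  expect_identical(recs9$pos, c(30L, 33L, 36L))
  expect_true(all(nchar(recs9$ref) == 3L))
  # 8 bp at frame 1: split first codon, 2 complete codons remain
  ctx8 <- plain_ctx(30L, 8L, "plus", 1L, ext5 = "A")
  recs8 <- mutate_inframe(random_dna(8), 30L, ctx8)
  expect_identical(nrow(recs8), 2L)
  expect_error(mutate_inframe("ACGT", 30L, NULL), "coding")
})

test_that("codon scans substitute the top-ranked target codon and skip wild type", {
  # constructed table: GCC is the top alanine, TGA the top stop
  tabs <- shared_tables()
  ctx <- plain_ctx(60L, 6L, "plus", 0L)
  recs <- mutate_codon_scan("GATGCC", 60L, ctx, tabs$codon_table, "alanine")
  # GAT -> GCC; the second codon GCC equals the top alanine and is skipped
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$pos, 60L)
  expect_identical(recs$alt, "GCC")
  expect_identical(recs$consequence, "missense")
  stops <- mutate_codon_scan("GATGCC", 60L, ctx, tabs$codon_table, "stop")
  expect_identical(nrow(stops), 2L)
  expect_true(all(stops$alt == "TGA"))
  expect_true(all(stops$consequence == "nonsense"))
  # 18 codons, none equal to the target codon -> 18 records
  s18 <- paste(rep("GAT", 18), collapse = "")
  ctx18 <- plain_ctx(60L, 54L, "plus", 0L)
  expect_identical(nrow(mutate_codon_scan(s18, 60L, ctx18,
                                          tabs$codon_table, "alanine")), 18L)
})

test_that("amino-acid scan hits every other amino acid once per codon", {
  tabs <- shared_tables()
  ctx <- plain_ctx(60L, 3L, "plus", 0L)
  recs <- mutate_aa_scan("GAT", 60L, ctx, tabs$codon_table)
  expect_identical(nrow(recs), 19L)
  expect_false("D" %in% recs$alt_aa)       # wild type never a target
  expect_identical(anyDuplicated(recs$alt_aa), 0L)
  expect_true(all(recs$consequence == "missense"))
  s6 <- "GATCTG"
  ctx6 <- plain_ctx(60L, 6L, "plus", 0L)
  expect_identical(nrow(mutate_aa_scan(s6, 60L, ctx6, tabs$codon_table)),
                   38L)
})

test_that("the action vector dispatches mutators and enforces coding rules", {
  tabs <- shared_tables()
  fx <- shared_fixture()
  anns <- load_annotation(fx$gtf)
  spec <- parse_targeton_file(fx$targetons)[[1]]
  part <- partition_targeton(spec)
  flags <- validate_region_homogeneity(part, anns$g1)
  z <- fixture_chrom_string(fx, "Z")
  seqs <- lapply(part[c("r1", "r2", "r3")], function(r) {
    substr(z, r$start, r$end)
  })
  lookup <- function(pos) vapply(pos, function(p) substr(z, p, p),
                                 character(1))
  ctxs <- list(r1 = NULL, r3 = NULL,
               r2 = region_frame_context(anns$g1, part$r2, lookup))
  recs <- run_action_vector(spec, part, seqs, ctxs, flags, tabs)
  counts <- table(recs$mutator, recs$region)
  expect_identical(unname(counts["snv", c("r1", "r2", "r3")]),
                   c(75L, 162L, 75L))
  expect_identical(unname(counts["1del", c("r1", "r2", "r3")]),
                   c(25L, 54L, 25L))
  expect_identical(unname(counts["2del1", "r1"]), 12L)
  expect_identical(unname(counts["2del0", "r3"]), 12L)
  expect_identical(unname(counts["inframe", "r2"]), 17L)
  expect_identical(unname(counts["stop", "r2"]), 17L)
  # CDS mutator on an intronic region is an input error
  bad <- spec
  bad$actions$r1 <- c("ala")
  expect_error(run_action_vector(bad, part, seqs, ctxs, flags, tabs),
               "non-coding region r1")
  # empty action vector -> no records
  none <- spec
  none$actions <- list(r1 = character(0), r2 = character(0),
                       r3 = character(0))
  expect_identical(nrow(run_action_vector(none, part, seqs, ctxs, flags,
                                          tabs)), 0L)
})
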