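fake_ref <- function(bases, start = 101L, strand = "plus",
                     preceding = "G") {
  structure(list(range = gnm_range("Z", start,
                                   start + nchar(bases) - 1L, strand),
                 bases = bases, preceding_base = preceding),
            class = "ref_sequence")
}

test_that("assembly concatenates adapters around the mutated targeton", {
  ref <- fake_ref("ACGTACGTAC")
  recs <- mutate_snv("ACGTACGTAC", 101L)[1:4, ]
  out <- assemble_oligos(recs, ref, stem = "s", strand = "plus",
                         adapter5 = "AAAA", adapter3 = "TTTT")
  for (i in seq_len(nrow(out))) {
    body <- apply_variant(ref$bases, 101L, recs[i, ])
    expect_identical(out$sequence[i], paste0("AAAA", body, "TTTT"))
  }
  # no adapters: sequence is the mutated targeton only
  bare <- assemble_oligos(recs, ref, stem = "s", strand = "plus")
  expect_identical(bare$sequence, bare$mseq)
  expect_identical(anyDuplicated(out$oligo_name), 0L)
})

test_that("minus-strand revcomp excludes adapters and is an involution", {
  ref <- fake_ref("ACGTACGTAC", strand = "minus")
  recs <- mutate_single_del("ACGTACGTAC", 101L)
  rc_on <- assemble_oligos(recs, ref, stem = "s", strand = "minus",
                           revcomp_minus_strand = TRUE,
                           adapter5 = "AAAA", adapter3 = "TTTT")
  rc_off <- assemble_oligos(recs, ref, stem = "s", strand = "minus",
                            revcomp_minus_strand = FALSE,
                            adapter5 = "AAAA", adapter3 = "TTTT")
  revcomp_str <- function(x) {
    vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch)
      paste(rev(ch), collapse = ""), character(1))
  }
  expect_identical(rc_on$sequence,
                   paste0("AAAA", revcomp_str(rc_off$mseq), "TTTT"))
  expect_identical(revcomp_str(revcomp_str(rc_on$mseq)), rc_on$mseq)
  expect_true(all(rc_on$revcomp_applied))
  expect_false(any(rc_off$revcomp_applied))
})

test_that("the length filter excludes strictly-over-length oligos", {
  ref <- fake_ref(strrep("A", 10))
  recs <- mutate_snv(ref$bases, 101L)[1, ]
  base <- assemble_oligos(recs, ref, stem = "s", strand = "plus")
  oligos <- rbind(base, base, base)
  oligos$length <- c(299L, 300L, 301L)
  expect_warning(fl <- filter_max_length(oligos, 300L), "excluded")
  expect_identical(fl$kept$length, c(299L, 300L))    # 300 kept: strict >
  expect_identical(fl$excluded$length, 301L)
  quiet <- filter_max_length(oligos[1, ], 300L)
  expect_identical(nrow(quiet$excluded), 0L)
})

test_that("deduplication matches a set-of-strings oracle", {
  # deleting either A of the AA homopolymer gives the same product
  ref <- fake_ref("AAT")
  recs <- mutate_single_del("AAT", 101L)
  oligos <- assemble_oligos(recs, ref, stem = "s", strand = "plus")
  dd <- deduplicate_oligos(oligos)
  expect_identical(dd$n_total, 3L)
  expect_setequal(dd$unique$sequence, unique(oligos$sequence))
  expect_identical(nrow(dd$unique), 2L)
  expect_identical(dd$unique$multiplicity[dd$unique$sequence == "AT"], 2L)
  # all-distinct input: unique count equals total
  ref2 <- fake_ref("ACGT")
  o2 <- assemble_oligos(mutate_snv("ACGT", 101L), ref2, stem = "s",
                        strand = "plus")
  expect_identical(nrow(deduplicate_oligos(o2)$unique), nrow(o2))
})

test_that("adapters do not change the deduplication result", {
  ref <- fake_ref("AATAA")
  recs <- rbind(mutate_single_del("AATAA", 101L),
                mutate_tandem_del("AATAA", 101L, 0L))
  plain <- deduplicate_oligos(
    assemble_oligos(recs, ref, stem = "s", strand = "plus"))
  withad <- deduplicate_oligos(
    assemble_oligos(recs, ref, stem = "s", strand = "plus",
                    adapter5 = "CCCC", adapter3 = "GGGG"))
  expect_identical(nrow(plain$unique), nrow(withad$unique))
  expect_identical(plain$unique$multiplicity, withad$unique$multiplicity)
})

test_that("three files are written, four when oligos are excluded", {
  ref <- fake_ref("ACGTACGTAC")
  recs <- mutate_snv(ref$bases, 101L)
  oligos <- assemble_oligos(recs, ref, stem = "tg", strand = "plus")
  dir_ok <- file.path(tempdir(), "out-none")
  fl <- list(kept = oligos, excluded = oligos[0, ])
  paths <- write_outputs(dir_ok, "tg", fl$kept, fl$excluded,
                         deduplicate_oligos(fl$kept)$unique, ref, "Z")
  expect_named(paths, c("meta", "unique", "vcf"))
  expect_true(all(file.exists(paths)))
  dir_ex <- file.path(tempdir(), "out-some")
  fl2 <- list(kept = oligos[-1, ], excluded = oligos[1, ])
  paths2 <- write_outputs(dir_ex, "tg", fl2$kept, fl2$excluded,
                          deduplicate_oligos(fl2$kept)$unique, ref, "Z")
  expect_named(paths2, c("meta", "unique", "vcf", "excluded"))
  expect_true(all(file.exists(paths2)))
})

test_that("metadata reports the package position dialect for indels", {
  run <- shared_run()
  tz <- run$targetons$chrZ_306_550_minus_sgRNA_a
  meta <- read.csv(tz$files[["meta"]], stringsAsFactors = FALSE)
  # deletions: position = first deleted base, ref = deleted bases, no alt
  del <- meta[meta$var_type == "deletion" & meta$mutator == "1del", ][1, ]
  expect_identical(del$alt, "")
  off <- del$position - 306L + 1L
  expect_identical(substr(tz$protected$bases, off,
                          off + nchar(del$ref) - 1L), del$ref)
  # insertions: position = first inserted position, no ref
  ins <- meta[meta$var_type == "insertion", ][1, ]
  expect_identical(ins$ref, "")
  expect_identical(nchar(ins$alt), 2L)  # the TT insertion from the manifest
})

test_that("applying the output VCF reproduces every oligo body", {
  run <- shared_run()
  for (tz in run$targetons) {
    vcf <- VariantAnnotation::readVcf(tz$files[["vcf"]], genome = "fixture")
    rr <- SummarizedExperiment::rowRanges(vcf)
    t_start <- tz$protected$range$start
    backbone <- paste0(tz$protected$preceding_base, tz$protected$bases)
    b_start <- t_start - 1L
    rebuilt <- vapply(seq_along(rr), function(i) {
      pos <- GenomicRanges::start(rr)[i]
      ref <- as.character(VariantAnnotation::ref(vcf)[[i]])
      alt <- as.character(VariantAnnotation::alt(vcf)[[i]][[1]])
      o <- pos - b_start + 1L
      stopifnot(substr(backbone, o, o + nchar(ref) - 1L) == ref)
      paste0(substr(backbone, 1L, o - 1L), alt,
             substr(backbone, o + nchar(ref), nchar(backbone)))
    }, character(1))
    # strip the anchoring preceding base before comparing with oligo bodies
    rebuilt_bodies <- substr(rebuilt, 2L, nchar(rebuilt))
    expected <- c(tz$oligos$mseq, tz$excluded$mseq)
    expect_identical(sort(rebuilt_bodies), sort(expected))
  }
})
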