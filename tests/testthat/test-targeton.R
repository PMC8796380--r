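make_spec_row <- function(ref_chr = "17", ref_strand = "-",
                          ref_start = 43115634, ref_end = 43115878,
                          r2_start = 43115726, r2_end = 43115779,
                          ext_vector = "25,25",
                          action_vector = paste0(
                            "2del1,snv,1del|snvre,inframe,ala,stop,1del|",
                            "2del0,snv,1del"),
                          sgrna_ids = "sgRNA_ex2") {
  df <- data.frame(ref_chr = ref_chr, ref_strand = ref_strand,
                   ref_start = ref_start, ref_end = ref_end,
                   r2_start = r2_start, r2_end = r2_end,
                   ext_vector = ext_vector, action_vector = action_vector,
                   sgrna_ids = sgrna_ids, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("an exon-covering design row parses into a valid spec", {
  specs <- parse_targeton_file(make_spec_row())
  expect_length(specs, 1L)
  spec <- specs[[1]]
  expect_identical(spec$ref_strand, "minus")
  expect_identical(range_length(spec$range), 245L)
  expect_identical(range_length(spec$r2), 54L)
  expect_identical(spec$ext_vector, c(r1 = 25L, r3 = 25L))
  expect_identical(spec$actions$r2, c("snvre", "inframe", "ala", "stop", "1del"))
  expect_identical(spec$sgrna_ids, "sgRNA_ex2")
})

test_that("coordinate violations and unknown mutators are named errors", {
  expect_error(parse_targeton_file(make_spec_row(r2_start = 43115900,
                                                 r2_end = 43115950)),
               "r3 extension")
  expect_error(parse_targeton_file(make_spec_row(r2_start = 43115780,
                                                 r2_end = 43115779)),
               "r2_start must be <= r2_end")
  expect_error(parse_targeton_file(
    make_spec_row(action_vector = "snv|wibble|1del")),
    "row 1: unknown mutator")
  expect_error(parse_targeton_file(
    make_spec_row(action_vector = "snv,snv|1del|")),
    "duplicate mutator")
})

test_that("empty mutator lists leave a region present but unmutated", {
  specs <- parse_targeton_file(make_spec_row(action_vector = "|1del|"))
  spec <- specs[[1]]
  expect_length(spec$actions$r1, 0L)
  expect_identical(spec$actions$r2, "1del")
  expect_length(spec$actions$r3, 0L)
  part <- partition_targeton(spec)
  expect_identical(range_length(part$r1), 25L)
})

test_that("partition reproduces the published region lengths", {
  spec <- parse_targeton_file(make_spec_row())[[1]]
  part <- partition_targeton(spec)
  lens <- vapply(part, range_length, integer(1))
  expect_identical(unname(lens[c("r1", "r2", "r3")]), c(25L, 54L, 25L))
  expect_identical(unname(lens[["c1"]] + lens[["c2"]]), 141L)
  expect_identical(sum(lens), 245L)
})

test_that("partition conserves length and order for random specs", {
  set.seed(5)
  for (i in 1:40) {
    start <- sample.int(1000, 1)
    r2s <- start + sample.int(60, 1)
    r2e <- r2s + sample.int(90, 1) - 1L
    e1 <- sample.int(30, 1) - 1L
    e3 <- sample.int(30, 1) - 1L
    end <- r2e + e3 + sample.int(40, 1) - 1L
    if (start > r2s - e1) next
    strand <- sample(c("+", "-"), 1)
    spec <- parse_targeton_file(make_spec_row(
      ref_chr = "Z", ref_strand = strand, ref_start = start, ref_end = end,
      r2_start = r2s, r2_end = r2e,
      ext_vector = paste(e1, e3, sep = ","), action_vector = "snv||",
      sgrna_ids = ""))[[1]]
    part <- partition_targeton(spec)
    lens <- vapply(part, range_length, integer(1))
    expect_identical(sum(lens), range_length(spec$range))
    present <- Filter(Negate(is.null), part)
    bounds <- unlist(lapply(present, function(r) c(r$start, r$end)))
    expect_true(all(diff(bounds) >= 0))        # adjacent, ordered
    expect_identical(bounds[[1]], spec$range$start)
    expect_identical(bounds[[length(bounds)]], spec$range$end)
    # strand does not change the genomic partition
    spec2 <- spec; spec2$ref_strand <- "plus"
    lens2 <- vapply(partition_targeton(spec2), range_length, integer(1))
    expect_identical(lens, lens2)
  }
})

test_that("zero extensions and r2-spanning targetons give empty regions", {
  spec <- parse_targeton_file(make_spec_row(ext_vector = "0,0"))[[1]]
  part <- partition_targeton(spec)
  expect_null(part$r1)
  expect_null(part$r3)
  spec2 <- parse_targeton_file(make_spec_row(
    ref_start = 43115726 - 25, ref_end = 43115779 + 25))[[1]]
  part2 <- partition_targeton(spec2)
  expect_null(part2$c1)
  expect_null(part2$c2)
  expect_identical(range_length(part2$r2), 54L)
})

test_that("region homogeneity flags coding status and rejects mixtures", {
  fx <- shared_fixture()
  anns <- load_annotation(fx$gtf)
  # exon-2 style design: intronic r1/r3 around a coding r2
  spec <- parse_targeton_file(make_spec_row(
    ref_chr = "Z", ref_start = 306, ref_end = 550,
    r2_start = 401, r2_end = 454, sgrna_ids = ""))[[1]]
  flags <- validate_region_homogeneity(partition_targeton(spec), anns$g1)
  expect_identical(unname(flags), c(FALSE, TRUE, FALSE))
  # r2 crossing the exon boundary mixes coding and non-coding
  bad <- parse_targeton_file(make_spec_row(
    ref_chr = "Z", ref_start = 306, ref_end = 550,
    r2_start = 395, r2_end = 454, sgrna_ids = ""))[[1]]
  expect_error(validate_region_homogeneity(partition_targeton(bad), anns$g1),
               "spans both coding and non-coding")
  # without any transcript every region is non-coding
  flags0 <- validate_region_homogeneity(partition_targeton(spec), NULL)
  expect_identical(unname(flags0), c(FALSE, FALSE, FALSE))
})

test_that("file stems report chromosome, range, strand and sgRNA ids", {
  spec <- parse_targeton_file(make_spec_row())[[1]]
  expect_identical(targeton_file_stem(spec),
                   "chr17_43115634_43115878_minus_sgRNA_ex2")
  plain <- parse_targeton_file(make_spec_row(
    ref_chr = "1", ref_strand = "+", ref_start = 100, ref_end = 200,
    r2_start = 120, r2_end = 150, ext_vector = "0,0",
    action_vector = "snv||", sgrna_ids = ""))[[1]]
  expect_identical(targeton_file_stem(plain), "chr1_100_200_plus")
  two <- parse_targeton_file(make_spec_row(sgrna_ids = "sgA,sgB"))[[1]]
  expect_identical(targeton_file_stem(two),
                   "chr17_43115634_43115878_minus_sgA_sgB")
})
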