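with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  non_stop <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))
  paste(sample(non_stop, n, replace = TRUE), collapse = "")
}

write_fasta <- function(path, seqs, width = 60L) {
  lines <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, paste0(">", nm),
               substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

next_base <- function(b) {
  DNA_BASES[match(b, DNA_BASES) %% 4L + 1L]
}

#' Generate a synthetic mini-genome fixture
#'
#' Builds, deterministically from a seed, a complete self-contained input
#' set for an SGE library run on a toy genome:
#'
#' * contig `Z` (1000 bp) carrying a minus-strand three-exon gene whose
#'   middle exon is a 54 bp coding exon with codons split across both
#'   junctions (frame 2 at its transcript 5' end), plus flanking UTRs and
#'   a stop codon feature;
#' * contig `W` (400 bp) carrying a plus-strand single-CDS gene;
#' * a matching GTF (with decoy `gene`/`exon` rows that the loader must
#'   ignore), a protection VCF with two edits tagged `sgRNA_a`, two custom
#'   variant VCFs (one keyed by an `ALLELEID`-style INFO tag, one by the
#'   ID column; including an over-length insertion, a targeton-boundary
#'   crossing deletion and a symbolic allele), a manifest, a targeton
#'   parameter file mirroring an exon-covering design (25/54/25 with 141
#'   constant bases, 245 bp total), and a cDNA fixture equivalent to the
#'   plus-strand design.
#'
#' The same seed always produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of file paths plus a `design` list of the key
#'   coordinates (used by tests).
#' @export
generate_fixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    # --- minus-strand gene on Z ------------------------------------------
    # transcript CDS: 47 codons (start + 46), then TGA stop
    tx_cds <- paste0("ATG", random_codons(46L))
    e1 <- substr(tx_cds, 1L, 40L)     # transcript-first exon, 40 bp
    e2 <- substr(tx_cds, 41L, 94L)    # middle exon, 54 bp
    e3 <- substr(tx_cds, 95L, 141L)   # transcript-last exon, 47 bp
    z <- random_bases(1000L)
    place <- function(genome, start, end, tx_seq) {
      paste0(substr(genome, 1L, start - 1L), revcomp(tx_seq),
             substr(genome, end + 1L, nchar(genome)))
    }
    z <- place(z, 701L, 740L, e1)
    z <- place(z, 401L, 454L, e2)
    z <- place(z, 154L, 200L, e3)
    z <- place(z, 151L, 153L, "TGA")  # stop codon feature
    # --- plus-strand gene on W -------------------------------------------
    w_cds <- paste0("ATG", random_codons(39L))  # 120 bp
    w <- random_bases(400L)
    w <- paste0(substr(w, 1L, 200L), w_cds, "TAA", substr(w, 324L, 400L))
    seqs <- list(Z = z, W = w)
    fasta <- file.path(dir, "genome.fa")
    write_fasta(fasta, seqs)
    if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
    Rsamtools::indexFa(fasta)

    gtf <- file.path(dir, "transcript.gtf")
    attr1 <- 'gene_id "g1"; transcript_id "t1";'
    attr2 <- 'gene_id "g2"; transcript_id "t2";'
    gtf_row <- function(chrom, type, start, end, strand, phase, attrs) {
      paste(chrom, "fixture", type, start, end, ".", strand, phase, attrs,
            sep = "\t")
    }
    writeLines(c(
      gtf_row("Z", "gene", 100, 780, "-", ".", 'gene_id "g1";'),
      gtf_row("Z", "exon", 701, 780, "-", ".", attr1),
      gtf_row("Z", "exon", 401, 454, "-", ".", attr1),
      gtf_row("Z", "exon", 100, 200, "-", ".", attr1),
      gtf_row("Z", "UTR", 741, 780, "-", ".", attr1),
      gtf_row("Z", "CDS", 701, 740, "-", 0, attr1),
      gtf_row("Z", "CDS", 401, 454, "-", 2, attr1),
      gtf_row("Z", "CDS", 154, 200, "-", 2, attr1),
      gtf_row("Z", "stop_codon", 151, 153, "-", 0, attr1),
      gtf_row("Z", "UTR", 100, 150, "-", ".", attr1),
      gtf_row("W", "exon", 181, 340, "+", ".", attr2),
      gtf_row("W", "UTR", 181, 200, "+", ".", attr2),
      gtf_row("W", "CDS", 201, 320, "+", 0, attr2),
      gtf_row("W", "stop_codon", 321, 323, "+", 0, attr2),
      gtf_row("W", "UTR", 324, 340, "+", ".", attr2)
    ), gtf)

    base_z <- function(p) substr(z, p, p)
    vcf_head <- function(extra_info = character(0)) {
      c("##fileformat=VCFv4.2",
        "##contig=<ID=Z,length=1000>",
        "##contig=<ID=W,length=400>",
        extra_info,
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", sep = "\t"))
    }
    vcf_row <- function(chrom, pos, id, ref, alt, info = ".") {
      paste(chrom, pos, id, ref, alt, ".", ".", info, sep = "\t")
    }

    pam_vcf <- file.path(dir, "protection.vcf")
    writeLines(c(
      vcf_head(paste0('##INFO=<ID=SGRNA,Number=1,Type=String,',
                      'Description="sgRNA identifier">')),
      vcf_row("Z", 410, ".", base_z(410), next_base(base_z(410)),
              "SGRNA=sgRNA_a"),
      vcf_row("Z", 425, ".", base_z(425), next_base(base_z(425)),
              "SGRNA=sgRNA_a")
    ), pam_vcf)

    long_ins <- random_bases(70L)
    clinvar_vcf <- file.path(dir, "custom_clinvar_like.vcf")
    writeLines(c(
      vcf_head(paste0('##INFO=<ID=ALLELEID,Number=1,Type=Integer,',
                      'Description="Allele identifier">')),
      vcf_row("Z", 330, ".", base_z(330), paste0(base_z(330), "TT"),
              "ALLELEID=1002"),
      vcf_row("Z", 420, ".", base_z(420), next_base(base_z(420)),
              "ALLELEID=1001"),
      vcf_row("Z", 440, ".", base_z(440), paste0(base_z(440), long_ins),
              "ALLELEID=1004"),
      vcf_row("Z", 460, ".", substr(z, 460, 461), base_z(460),
              "ALLELEID=1003"),
      vcf_row("Z", 548, ".", substr(z, 548, 553), base_z(548),
              "ALLELEID=1005")
    ), clinvar_vcf)

    gnomad_vcf <- file.path(dir, "custom_gnomad_like.vcf")
    writeLines(c(
      vcf_head(),
      vcf_row("Z", 390, "rs0001", base_z(390), next_base(base_z(390))),
      vcf_row("Z", 500, "rs0003", base_z(500), "<DEL>"),
      vcf_row("Z", 520, "rs0002", base_z(520), next_base(base_z(520)))
    ), gnomad_vcf)

    manifest <- file.path(dir, "manifest.csv")
    writeLines(c(
      "alias,vcf_path,id_info_tag",
      "clinvar_like,custom_clinvar_like.vcf,ALLELEID",
      "gnomad_like,custom_gnomad_like.vcf,"
    ), manifest)

    targetons <- file.path(dir, "targetons.tsv")
    writeLines(c(
      paste(TARGETON_COLUMNS, collapse = "\t"),
      paste("Z", "-", 306, 550, 401, 454, "25,25",
            "2del1,snv,1del|snvre,inframe,ala,stop,1del|2del0,snv,1del",
            "sgRNA_a", sep = "\t"),
      paste("W", "+", 181, 340, 231, 290, "20,20",
            "snv|snvre,ala|1del", "", sep = "\t")
    ), targetons)

    cdna_fasta <- file.path(dir, "cdna.fa")
    write_fasta(cdna_fasta, list(vec1 = w))
    cdna_annotation <- file.path(dir, "cdna_annotation.csv")
    writeLines(c(
      paste(CDNA_COLUMNS, collapse = ","),
      'vec1,181,340,231,290,201,320,"20,20","snv|snvre,ala|1del"'
    ), cdna_annotation)

    list(
      fasta = fasta, gtf = gtf, pam_vcf = pam_vcf, manifest = manifest,
      targetons = targetons, cdna_fasta = cdna_fasta,
      cdna_annotation = cdna_annotation, dir = dir,
      design = list(
        z_len = 1000L, w_len = 400L,
        z_targeton = c(306L, 550L), z_r2 = c(401L, 454L),
        z_cds = list(c(701L, 740L), c(401L, 454L), c(154L, 200L)),
        z_stop = c(151L, 153L),
        w_targeton = c(181L, 340L), w_r2 = c(231L, 290L),
        w_cds = c(201L, 320L),
        protection_positions = c(410L, 425L),
        long_insertion_pos = 441L
      )
    )
  })
}
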