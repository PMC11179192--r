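test_that("load_genome parses, uppercases and validates FASTA records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT desc", "acgu", ">chrU", "ACGTN"), fa)
  g <- load_genome(fa, assembly = "toy")
  expect_s3_class(g, "genome_model")
  expect_equal(unname(g$contigs["chrT"]), "ACGT") # lowercased + U -> T
  expect_equal(nchar(g$contigs[["chrU"]]), 5L)
  expect_equal(g$assembly, "toy")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ACGT", ">chrT", "GGCC"), dup)
  expect_error(load_genome(dup), "duplicate contig")
  expect_error(load_genome(tempfile()), "not found")
})

test_that("extract_introns derives strand-aware inter-exon gaps", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(
    c(
      paste("c1", "src", "exon", 101, 200, ".", "+", ".",
        'gene_id "gA"; transcript_id "tA";',
        sep = "\t"
      ),
      paste("c1", "src", "exon", 301, 400, ".", "+", ".",
        'gene_id "gA"; transcript_id "tA";',
        sep = "\t"
      ),
      paste("c1", "src", "exon", 501, 600, ".", "-", ".",
        'gene_id "gB"; transcript_id "tB";',
        sep = "\t"
      ),
      paste("c1", "src", "exon", 701, 800, ".", "-", ".",
        'gene_id "gB"; transcript_id "tB";',
        sep = "\t"
      ),
      paste("c1", "src", "exon", 901, 950, ".", "+", ".",
        'gene_id "gC"; transcript_id "tC";',
        sep = "\t"
      )
    ),
    gtf
  )
  introns <- extract_introns(gtf)
  expect_equal(nrow(introns), 2L)
  plus <- introns[introns$gene_id == "gA", ]
  expect_equal(c(plus$start, plus$end), c(200L, 300L)) # 0-based half-open
  minus <- introns[introns$gene_id == "gB", ]
  expect_equal(c(minus$start, minus$end), c(600L, 700L))
  # donor of the minus-strand intron sits at the genomic end
  expect_equal(
    splicescreen:::offset_5p(699L, minus$start, minus$end, "-"), 1L
  )
  # single-exon transcript contributes nothing
  expect_false("gC" %in% introns$gene_id)
  # but its span is still known for intergenic triage
  expect_true("gC" %in% gene_spans(introns)$gene_id)
})

test_that("extract_introns is invariant to exon record order and skips overlaps", {
  fx <- toy_fixture()
  ln <- readLines(fx$locus$gtf)
  shuf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(rev(ln), shuf)
  a <- extract_introns(fx$locus$gtf)
  b <- extract_introns(shuf)
  expect_equal(
    as.data.frame(a[order(a$start), ]),
    as.data.frame(b[order(b$start), ])
  )

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(
    c(
      paste("c1", "s", "exon", 1, 100, ".", "+", ".",
        'gene_id "g"; transcript_id "t";',
        sep = "\t"
      ),
      paste("c1", "s", "exon", 50, 150, ".", "+", ".",
        'gene_id "g"; transcript_id "t";',
        sep = "\t"
      )
    ),
    bad
  )
  expect_warning(res <- extract_introns(bad), "overlapping exons")
  expect_equal(nrow(res), 0L)
})

test_that("read_vcf handles coordinates, multi-allelics and symbolic alleles", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(
    c(
      "##fileformat=VCFv4.2",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      "chr15\t74687208\t.\tA\tG\t.\t.\t.",
      "chr1\t100\trs1\tC\tT,G\t.\t.\t.",
      "chr1\t200\t.\tA\tAT\t.\t.\t.",
      "chr1\t300\t.\tG\t<DEL>\t.\t.\t."
    ),
    vcf
  )
  expect_warning(v <- read_vcf(vcf), "symbolic")
  expect_equal(v$contig[1], "chr15")
  expect_equal(v$pos[1], 74687208L)
  expect_equal(c(v$ref[1], v$alt[1]), c("A", "G"))
  # multi-allelic split into two rows of the same record, order preserved
  expect_equal(sum(v$record == 2L), 2L)
  expect_equal(v$alt[v$record == 2L], c("T", "G"))
  # indel retained (triage filters it later), symbolic dropped
  expect_true(any(v$alt == "AT"))
  expect_equal(nrow(v), 4L)
})

test_that("check_reference matches genome bases and degrades gracefully", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ACGTN"), fa)
  g <- load_genome(fa)
  expect_true(check_reference(list(contig = "chrT", pos = 2L, ref = "C"), g))
  expect_false(check_reference(list(contig = "chrT", pos = 2L, ref = "G"), g))
  expect_warning(
    ok <- check_reference(list(contig = "chrZ", pos = 1L, ref = "A"), g),
    "contig"
  )
  expect_false(ok)
  # N in the reference has no defined substitution semantics
  expect_false(check_reference(list(contig = "chrT", pos = 5L, ref = "N"), g))
})

test_that("prediction table round-trips and conserves every input variant", {
  fx <- toy_fixture()
  out <- withr::local_tempfile(fileext = ".tsv")

  write_predictions(splicescreen:::empty_triage(), out)
  empty <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(empty), 0L)
  expect_equal(
    names(empty)[1:5], c("variant_id", "contig", "pos", "ref", "alt")
  )

  pred <- predict_splice_variants(
    fx$variants, fx$genome, fx$introns,
    track = fx$track, bp_store = fx$bp, pwms = fx$pwms
  )
  # conservation of records: every input variant appears exactly once here
  expect_setequal(pred$vid, fx$variants$vid)
  expect_equal(nrow(pred), nrow(fx$variants))
  write_predictions(pred, out)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(pred))
  # triaged-out variants keep basic info, no score, not evaluated
  oow <- tab[tab$variant_id == "v_out_plus", ]
  expect_equal(oow$gene, "GP")
  expect_true(is.na(oow$score))
  expect_equal(oow$effect, "not_evaluated")
  # scored variant fully populated, intron coordinates printed 1-based
  hit <- tab[tab$variant_id == "v_3pAG_plus", ]
  expect_equal(c(hit$intron_start, hit$intron_end), c(351, 550))
  expect_false(is.na(hit$score))
  # SNV fields round-trip bit-exactly
  snv <- tab[tab$variant_id == "v_5p_plus", ]
  orig <- fx$variants[fx$variants$vid == "v_5p_plus", ]
  expect_identical(
    c(snv$contig, as.integer(snv$pos), snv$ref, snv$alt),
    c(orig$contig, orig$pos, orig$ref, orig$alt)
  )
})
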