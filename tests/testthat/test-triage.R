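test_that("filter cascade catches indels, intergenic and mismatching variants", {
  fx <- toy_fixture()
  expect_equal(
    filter_variant(
      list(contig = "chrS", pos = 360L, ref = "A", alt = "AT"),
      fx$genome, fx$introns
    ),
    "not_snv"
  )
  expect_equal(
    filter_variant(
      list(contig = "chrS", pos = 50L, ref = "A", alt = "C"),
      fx$genome, fx$introns
    ),
    "intergenic"
  )
  g400 <- substr(fx$genome$contigs[["chrS"]], 400, 400)
  wrong <- setdiff(c("A", "C", "G", "T"), g400)[1]
  expect_equal(
    filter_variant(
      list(contig = "chrS", pos = 400L, ref = wrong, alt = g400),
      fx$genome, fx$introns
    ),
    "ref_mismatch"
  )
})

test_that("scripted toy variants route exactly as constructed, both strands", {
  fx <- toy_fixture()
  tri <- triage_all(fx$variants, fx$genome, fx$introns)
  got <- tri[match(fx$locus$variants_truth$vid, tri$vid), ]
  expect_equal(got$route, fx$locus$variants_truth$expected_route)
  # minus-strand donor-proximal variant: transcript-orientation offset
  expect_equal(got$off5[got$vid == "v_5p_minus"], 2L)
  # novel AG at acceptor offset -20 sits 19 bases from the canonical G
  expect_equal(got$novel_ag_dist[got$vid == "v_3pAG_plus"], 19L)
  expect_equal(got$novel_ag_dist[got$vid == "v_3pAG_minus"], 19L)
})

test_that("window boundaries are inclusive exactly at the published edges", {
  fx <- toy_fixture()
  uniq <- dplyr::distinct(
    fx$introns, contig, start, end, strand,
    .keep_all = TRUE
  )
  cases_5p <- c(-4L, -3L, 30L, 31L)
  expect_5p <- c("no", "yes", "yes", "no")
  cases_3p <- c(-79L, -78L, -4L, -3L)
  expect_3p <- c("no", "yes", "yes", "no")
  for (i in seq_len(nrow(uniq))) {
    intr <- uniq[i, ]
    for (j in seq_along(cases_5p)) {
      v <- variant_at_offset(fx$genome, intr, cases_5p[j], "5p")
      tri <- triage_all(v, fx$genome, fx$introns)
      tri <- tri[!is.na(tri$intron_start) &
        tri$intron_start == intr$start, , drop = FALSE]
      in_5p <- nrow(tri) > 0 && any(tri$route == "5ss")
      expect_equal(in_5p, expect_5p[j] == "yes",
        info = sprintf(
          "5p offset %d on %s strand intron [%d,%d)",
          cases_5p[j], intr$strand, intr$start, intr$end
        )
      )
    }
    for (j in seq_along(cases_3p)) {
      v <- variant_at_offset(fx$genome, intr, cases_3p[j], "3p")
      tri <- triage_all(v, fx$genome, fx$introns)
      tri <- tri[!is.na(tri$intron_start) &
        tri$intron_start == intr$start, , drop = FALSE]
      in_3p <- nrow(tri) > 0 && any(tri$route %in% c("3ss_AG", "3ss_nonAG"))
      expect_equal(in_3p, expect_3p[j] == "yes",
        info = sprintf(
          "3p offset %d on %s strand intron [%d,%d)",
          cases_3p[j], intr$strand, intr$start, intr$end
        )
      )
    }
  }
})

test_that("novel-AG split agrees with a brute-force dinucleotide diff", {
  fx <- toy_fixture()
  uniq <- dplyr::distinct(fx$introns, contig, start, end, strand, .keep_all = TRUE)
  # brute force: rebuild the full transcript-strand intron sequence for ref
  # and alt, enumerate AG dinucleotide positions inside the acceptor window,
  # and call novel-AG iff the alt set minus the ref set is nonempty
  brute_ag <- function(genome, intron, v) {
    ts_ref <- splicescreen:::intron_seq(genome, intron)
    g0 <- v$pos - 1L
    i <- splicescreen:::variant_ts_index(g0, intron$start, intron$end, intron$strand)
    alt_b <- if (intron$strand == "-") splicescreen:::comp_base(v$alt) else v$alt
    ts_alt <- splicescreen:::substitute_base(ts_ref, i, alt_b)
    L <- nchar(ts_ref)
    ag_set <- function(s) {
      hits <- gregexpr("(?=AG)", s, perl = TRUE)[[1]]
      hits <- hits[hits > 0]
      # keep AGs whose G lies in the acceptor window -78..-4
      g_off <- (hits + 1L) - L - 1L
      hits[g_off >= -78L & g_off <= -4L]
    }
    length(setdiff(ag_set(ts_alt), ag_set(ts_ref))) > 0
  }
  set.seed(11)
  checked <- 0L
  for (rep in 1:60) {
    intr <- uniq[sample.int(nrow(uniq), 1L), ]
    off <- sample(-78:-4, 1L)
    v <- variant_at_offset(
      fx$genome, intr, off, "3p",
      alt = sample(c("A", "C", "G", "T"), 1L)
    )
    if (v$alt == v$ref) next
    tri <- triage_all(v, fx$genome, fx$introns)
    tri <- tri[!is.na(tri$intron_start) & tri$intron_start == intr$start, ]
    if (nrow(tri) == 0L) next
    expected <- brute_ag(fx$genome, as.list(intr), v)
    expect_equal(tri$route[1] == "3ss_AG", expected,
      info = sprintf(
        "offset %d alt %s on [%d,%d)%s",
        off, v$alt, intr$start, intr$end, intr$strand
      )
    )
    checked <- checked + 1L
  }
  expect_gt(checked, 30L)
})

test_that("routes are strand-covariant under reverse complement", {
  fx <- toy_fixture()
  rc <- rc_fixture(fx)
  tri <- triage_all(fx$variants, fx$genome, fx$introns)
  tri_rc <- triage_all(rc$variants, rc$genome, rc$introns)
  key <- order(tri$record)
  key_rc <- order(tri_rc$record)
  expect_equal(tri$route[key], tri_rc$route[key_rc])
  expect_equal(tri$off5[key], tri_rc$off5[key_rc])
  expect_equal(tri$off3[key], tri_rc$off3[key_rc])
})

test_that("overlapping windows in short introns prefer the donor model", {
  ml <- mini_locus(intron_len = 30L)
  intr <- ml$introns[1, ]
  # offset +27 from the donor is also acceptor offset -4 in a 30 bp intron
  v <- variant_at_offset(ml$genome, intr, 27L, "5p", alt = "C")
  if (v$ref == "C") v$alt <- "T"
  expect_equal(
    splicescreen:::offset_3p(v$pos - 1L, intr$start, intr$end, "+"), -4L
  )
  tri <- triage_all(v, ml$genome, ml$introns)
  expect_equal(tri$route, "5ss")
})

test_that("variants in intronless genes and empty batches triage cleanly", {
  fx <- toy_fixture()
  expect_equal(nrow(triage_all(fx$variants[0, ], fx$genome, fx$introns)), 0L)
  # gene span without introns -> out_of_scope with no intron attributed
  introns2 <- fx$introns
  sp <- gene_spans(fx$introns)
  sp <- dplyr::bind_rows(
    sp,
    tibble::tibble(
      gene_id = "GX", contig = "chrS", start = 2200L, end = 2350L, strand = "+"
    )
  )
  attr(introns2, "gene_spans") <- sp
  v <- tibble::tibble(
    contig = "chrS", pos = 2250L,
    ref = substr(fx$genome$contigs[["chrS"]], 2250, 2250),
    alt = "A", vid = "vx", record = 1L
  )
  if (v$ref == "A") v$alt <- "C"
  tri <- triage_all(v, fx$genome, introns2)
  expect_equal(tri$route, "out_of_scope")
  expect_true(is.na(tri$intron_start))
})
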