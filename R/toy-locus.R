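#' Generate the packaged toy locus
#'
#' Builds a ~2.4 kb synthetic contig carrying two three-exon genes (one per
#' strand), mirroring the three-exon minigene topology of splicing reporter
#' assays: 200 bp introns with consensus donors (`CAG|GTAAGT`), a planted
#' branch motif (`TACTAAC`, branch adenosine at acceptor offset -29), a
#' polypyrimidine tract over offsets -25..-5, an AG-free acceptor window
#' -78..-4 (with a `CAT` planted at offsets -22..-20 so a scripted T>G
#' substitution at -20 creates a novel AG), and `CAG` acceptors. Alongside
#' the FASTA and GTF it writes a scripted VCF covering every triage route,
#' a conservation TSV concentrated near splice sites, and experimental +
#' predicted branchpoint BED files.
#'
#' Everything is deterministic given `seed`.
#'
#' @param seed RNG seed for the background sequence.
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return Named list of file paths (`fasta`, `gtf`, `vcf`,
#'   `conservation`, `bp_experimental`, `bp_predicted`, `dir`) plus
#'   `variants_truth`, a tibble mapping each scripted variant ID to its
#'   expected route.
#' @export
make_toy_locus <- function(seed = 42L, dir = tempfile("toy_locus")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L_GENOME <- 2400L

  build_intron <- function(L = 200L) {
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ch[1:6] <- c("G", "T", "A", "A", "G", "T")
    win <- (L - 77L):(L - 3L) # acceptor offsets -78..-4: pyrimidine, AG-free
    ch[win] <- sample(c("C", "T"), length(win), replace = TRUE)
    ch[(L - 33L):(L - 27L)] <- c("T", "A", "C", "T", "A", "A", "C") # branch
    ch[(L - 21L):(L - 19L)] <- c("C", "A", "T") # T>G at -20 creates an AG
    ch[(L - 2L):L] <- c("C", "A", "G") # acceptor
    paste(ch, collapse = "")
  }
  build_exon <- function(L, donor_follows = FALSE) {
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (donor_follows) ch[(L - 2L):L] <- c("C", "A", "G")
    paste(ch, collapse = "")
  }

  withr::with_seed(seed, {
    bg <- paste(sample(c("A", "C", "G", "T"), L_GENOME, replace = TRUE),
      collapse = ""
    )
    cassette <- function() {
      paste0(
        build_exon(150L, donor_follows = TRUE), build_intron(),
        build_exon(100L, donor_follows = TRUE), build_intron(),
        build_exon(150L)
      )
    }
    cas_p <- cassette()
    cas_m <- cassette()
  })
  genome_seq <- paste0(
    substr(bg, 1L, 200L), cas_p, # plus gene at 0-based [200, 1000)
    substr(bg, 1001L, 1300L),
    revcomp(cas_m), # minus gene at 0-based [1300, 2100)
    substr(bg, 2101L, L_GENOME)
  )
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrS synthetic toy locus", genome_seq), fasta)

  exons <- tibble::tibble(
    gene = c(rep("GP", 3L), rep("GM", 3L)),
    start = c(200L, 550L, 850L, 1300L, 1650L, 1950L), # 0-based
    end = c(350L, 650L, 1000L, 1450L, 1750L, 2100L),
    strand = c(rep("+", 3L), rep("-", 3L))
  )
  gtf <- file.path(dir, "toy.gtf")
  gtf_rows <- purrr::map_chr(seq_len(nrow(exons)), function(i) {
    e <- exons[i, ]
    paste(
      "chrS", "toy", "exon", e$start + 1L, e$end, ".", e$strand, ".",
      sprintf('gene_id "%s"; transcript_id "%s.t1";', e$gene, e$gene),
      sep = "\t"
    )
  })
  writeLines(gtf_rows, gtf)

  # Scripted variants; introns: GP [350,550) & [650,850) on +,
  # GM [1450,1650) & [1750,1950) on -.
  base_at <- function(pos) substr(genome_seq, pos, pos)
  other <- function(b, prefer) setdiff(prefer, b)[1]
  v <- list(
    list("v_5p_plus", 355L, base_at(355L), other(base_at(355L), c("A", "C")), "5ss"),
    list("v_3pAG_plus", 531L, "T", "G", "3ss_AG"),
    list("v_3pnon_plus", 536L, base_at(536L), "A", "3ss_nonAG"),
    list("v_out_plus", 390L, base_at(390L), other(base_at(390L), c("A", "C", "G", "T")), "out_of_scope"),
    list("v_indel", 360L, base_at(360L), paste0(base_at(360L), "T"), "not_snv"),
    list("v_intergenic", 50L, base_at(50L), other(base_at(50L), c("A", "C", "G", "T")), "intergenic"),
    list("v_mismatch", 400L, other(base_at(400L), c("A", "C", "G", "T")), base_at(400L), "ref_mismatch"),
    list("v_5p_minus", 1949L, base_at(1949L), "C", "5ss"),
    list("v_3pAG_minus", 1770L, "A", "C", "3ss_AG")
  )
  truth <- tibble::tibble(
    vid = vapply(v, `[[`, character(1), 1L),
    pos = vapply(v, `[[`, integer(1), 2L),
    ref = vapply(v, `[[`, character(1), 3L),
    alt = vapply(v, `[[`, character(1), 4L),
    expected_route = vapply(v, `[[`, character(1), 5L)
  )
  vcf <- file.path(dir, "toy.vcf")
  writeLines(
    c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=chrS,length=2400>",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("chrS\t%d\t%s\t%s\t%s\t.\t.\t.", truth$pos, truth$vid, truth$ref, truth$alt)
    ),
    vcf
  )

  # Conservation: high near splice sites, moderate elsewhere in genes.
  introns0 <- tibble::tibble(
    start = c(350L, 650L, 1450L, 1750L),
    end = c(550L, 850L, 1650L, 1950L)
  )
  cons_pos <- sort(unique(unlist(purrr::map2(
    introns0$start, introns0$end,
    function(s, e) c(seq.int(s - 34L, s + 46L), seq.int(e - 80L, e + 34L))
  ))))
  cons <- tibble::tibble(
    contig = "chrS",
    pos = cons_pos + 1L,
    score = ifelse(
      (cons_pos %% 7L) == 0L, 0.3,
      round(0.85 + 0.1 * sin(cons_pos / 9), 3)
    )
  )
  cons$score <- pmin(pmax(cons$score, 0), 1)
  conservation <- file.path(dir, "toy_conservation.tsv")
  readr::write_tsv(cons, conservation, col_names = FALSE)

  # Branchpoints: experimental at the planted branch A (offset -29),
  # predicted records with scores in every intron.
  bp_exp <- file.path(dir, "toy_bp_experimental.bed")
  writeLines(
    c(
      "chrS\t521\t522\tassay_study\t0\t+",
      "chrS\t1778\t1779\tassay_study\t0\t-"
    ),
    bp_exp
  )
  bp_pred <- file.path(dir, "toy_bp_predicted.bed")
  writeLines(
    c(
      "chrS\t515\t516\tsvm_pred\t0.85\t+",
      "chrS\t821\t822\tsvm_pred\t0.80\t+",
      "chrS\t1784\t1785\tsvm_pred\t0.75\t-",
      "chrS\t1478\t1479\tsvm_pred\t0.70\t-"
    ),
    bp_pred
  )

  list(
    fasta = fasta, gtf = gtf, vcf = vcf, conservation = conservation,
    bp_experimental = bp_exp, bp_predicted = bp_pred, dir = dir,
    variants_truth = truth
  )
}
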