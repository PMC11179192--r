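# Shared fixtures, built once per test session.

fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (!is.null(fixture_env$toy)) {
    return(fixture_env$toy)
  }
  locus <- make_toy_locus(seed = 42)
  genome <- load_genome(locus$fasta, assembly = "toy")
  introns <- extract_introns(locus$gtf)
  variants <- read_vcf(locus$vcf)
  track <- read_conservation(locus$conservation)
  pwms <- suppressWarnings(build_pwms(genome, introns))
  bp <- load_branchpoints(tibble::tibble(
    path = c(locus$bp_experimental, locus$bp_predicted),
    source = c("experimental", "predicted"),
    study = c("assay_study", "svm_pred")
  ))
  fixture_env$toy <- list(
    locus = locus, genome = genome, introns = introns, variants = variants,
    track = track, pwms = pwms, bp = bp
  )
  fixture_env$toy
}

# Reverse-complement transformation of the whole toy locus: genome sequence,
# annotation intervals (strands flip), variant alleles and conservation
# positions. Used by the strand-covariance checks.
rc_fixture <- function(fx) {
  L <- nchar(fx$genome$contigs[["chrS"]])
  genome <- structure(
    list(
      contigs = c(chrS = revcomp(fx$genome$contigs[["chrS"]])),
      assembly = "toy-rc"
    ),
    class = "genome_model"
  )
  introns <- fx$introns
  new_start <- L - fx$introns$end
  introns$end <- L - fx$introns$start
  introns$start <- new_start
  introns$strand <- ifelse(fx$introns$strand == "+", "-", "+")
  sp <- gene_spans(fx$introns)
  sp_rc <- sp
  sp_rc$start <- L - sp$end
  sp_rc$end <- L - sp$start
  sp_rc$strand <- ifelse(sp$strand == "+", "-", "+")
  introns <- dplyr::arrange(introns, contig, start, end, transcript_id)
  attr(introns, "gene_spans") <- sp_rc
  variants <- fx$variants
  variants$pos <- L - fx$variants$pos - nchar(fx$variants$ref) + 2L
  variants$ref <- revcomp(fx$variants$ref)
  variants$alt <- revcomp(fx$variants$alt)
  track <- fx$track
  track$pos <- L - fx$track$pos + 1L
  pwms <- suppressWarnings(build_pwms(genome, introns))
  list(
    genome = genome, introns = introns, variants = variants, track = track,
    pwms = pwms
  )
}

# Independent Fisher oracle: direct enumeration of all tables with the
# observed margins via binomial coefficients (log scale), summing the
# probabilities of tables at most as probable as the observed one.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) {
    return(1)
  }
  supp <- max(0, k - m2):min(k, m1)
  pr <- exp(lchoose(m1, supp) + lchoose(m2, k - supp) - lchoose(n, k))
  p0 <- pr[match(a, supp)]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Gaussian design with a sparse logistic truth, for penalty/recovery tests.
logistic_sim <- function(n, p, beta, beta0 = 0, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
      dimnames = list(NULL, paste0("x", seq_len(p)))
    )
    b <- numeric(p)
    b[seq_along(beta)] <- beta
    y <- stats::rbinom(n, 1L, stats::plogis(beta0 + drop(X %*% b)))
    list(X = X, y = y, beta = b)
  })
}

# Tiny two-exon gene built in code (no files) for boundary-window tests.
mini_locus <- function(intron_len = 200L, exon_len = 120L, seed = 7L) {
  withr::with_seed(seed, {
    seqs <- sample(c("A", "C", "G", "T"), 2L * exon_len + intron_len,
      replace = TRUE
    )
  })
  genome <- structure(
    list(
      contigs = c(chrM = paste(seqs, collapse = "")),
      assembly = "mini"
    ),
    class = "genome_model"
  )
  introns <- tibble::tibble(
    contig = "chrM", start = exon_len, end = exon_len + intron_len,
    strand = "+", gene_id = "G1", transcript_id = "G1.t1"
  )
  attr(introns, "gene_spans") <- tibble::tibble(
    gene_id = "G1", contig = "chrM", start = 0L,
    end = 2L * exon_len + intron_len, strand = "+"
  )
  list(genome = genome, introns = introns)
}

# Variant at a given offset of an intron, taking REF from the genome.
variant_at_offset <- function(genome, intron, offset,
                              end = c("5p", "3p"), alt = NULL, vid = "v") {
  end <- match.arg(end)
  g0 <- if (end == "5p") {
    splicescreen:::genomic_from_offset_5p(offset, intron$start, intron$end, intron$strand)
  } else {
    splicescreen:::genomic_from_offset_3p(offset, intron$start, intron$end, intron$strand)
  }
  ref <- substr(genome$contigs[[intron$contig]], g0 + 1L, g0 + 1L)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  tibble::tibble(
    contig = intron$contig, pos = g0 + 1L, vid = vid,
    ref = ref, alt = alt, record = 1L
  )
}
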