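# Splice-site position weight matrices estimated from the supplied
# annotation. Windows are fixed in transcript orientation:
#   donor:    -3..+6  (3 exonic, 6 intronic bases; GT at +1,+2)
#   acceptor: -20..+3 (20 intronic, 3 exonic bases; AG at -2,-1)
DONOR_WINDOW <- c(-3L, 6L)
ACCEPTOR_WINDOW <- c(-20L, 3L)

#' Estimate donor and acceptor PWMs from an annotation
#'
#' Collects the junction windows of every annotated intron on the
#' transcript strand and estimates position weight matrices with a
#' pseudocount against a uniform background. With fewer than 50 sites the
#' estimate is noisy, so a warning is emitted and the pseudocount widened
#' to 1.
#'
#' @param genome A `genome_model`.
#' @param introns Intron table from [extract_introns()].
#' @param pseudocount Added to every base count before normalization.
#' @return A `pwm_store`: list with `donor` and `acceptor` matrices of
#'   per-position base probabilities (4 rows ACGT, columns sum to 1) plus
#'   the window definitions.
#' @export
build_pwms <- function(genome, introns, pseudocount = 0.1) {
  donor_seqs <- site_windows(genome, introns, "donor")
  acc_seqs <- site_windows(genome, introns, "acceptor")
  n <- length(donor_seqs)
  if (n < 50L) {
    warning("only ", n, " annotated splice sites; widening PWM pseudocount to 1")
    pseudocount <- max(pseudocount, 1)
  }
  structure(
    list(
      donor = pwm_from_seqs(donor_seqs, pseudocount),
      acceptor = pwm_from_seqs(acc_seqs, pseudocount),
      donor_window = DONOR_WINDOW,
      acceptor_window = ACCEPTOR_WINDOW,
      n_sites = n
    ),
    class = "pwm_store"
  )
}

# Junction window sequences on the transcript strand for all introns.
site_windows <- function(genome, introns, end = c("donor", "acceptor")) {
  end <- match.arg(end)
  w <- if (end == "donor") DONOR_WINDOW else ACCEPTOR_WINDOW
  vapply(seq_len(nrow(introns)), function(i) {
    site_window_seq(genome, introns[i, ], end)
  }, character(1))
}

# One junction window sequence; offsets w[1]..w[2] mapped through the
# offset coordinate helpers so strand handling stays in one place.
site_window_seq <- function(genome, intron, end) {
  w <- if (end == "donor") DONOR_WINDOW else ACCEPTOR_WINDOW
  offs <- seq.int(w[1], w[2])
  offs <- offs[offs != 0L]
  g0 <- if (end == "donor") {
    genomic_from_offset_5p(offs, intron$start, intron$end, intron$strand)
  } else {
    genomic_from_offset_3p(offs, intron$start, intron$end, intron$strand)
  }
  ctg <- genome$contigs[[intron$contig]]
  if (min(g0) < 0L || max(g0) >= nchar(ctg)) return(NA_character_)
  b <- substring(ctg, g0 + 1L, g0 + 1L)
  if (intron$strand == "-") b <- comp_base(b)
  paste(b, collapse = "")
}

pwm_from_seqs <- function(seqs, pseudocount) {
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) stop("no sites available for PWM estimation")
  W <- nchar(seqs[1])
  m <- matrix(pseudocount, nrow = 4, ncol = W, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    b <- strsplit(s, "")[[1]]
    keep <- b %in% rownames(m)
    idx <- cbind(match(b[keep], rownames(m)), which(keep))
    m[idx] <- m[idx] + 1
  }
  sweep(m, 2, colSums(m), "/")
}

#' Splice-site strength under the annotation-derived PWM
#'
#' Log2-odds score of a junction window against a uniform background:
#' `sum(log2(p[b, j] / 0.25))` over window positions. `N` bases contribute
#' 0. The `allele` argument substitutes a base at a given junction offset
#' before scoring, which is how alternative-allele site strengths are
#' computed.
#'
#' @param genome A `genome_model`.
#' @param intron One-row intron.
#' @param end `"donor"` or `"acceptor"`.
#' @param pwms A `pwm_store` from [build_pwms()].
#' @param allele Optional list `list(offset =, base =)`: junction offset
#'   (donor offsets for the donor window, acceptor offsets for the
#'   acceptor window) and transcript-strand base to substitute.
#' @return Log2-odds score (bits).
#' @export
site_strength <- function(genome, intron, end = c("donor", "acceptor"), pwms,
                          allele = NULL) {
  end <- match.arg(end)
  s <- site_window_seq(genome, intron, end)
  if (is.na(s)) return(NA_real_)
  w <- if (end == "donor") pwms$donor_window else pwms$acceptor_window
  offs <- seq.int(w[1], w[2])
  offs <- offs[offs != 0L]
  b <- strsplit(s, "")[[1]]
  if (!is.null(allele)) {
    j <- match(allele$offset, offs)
    if (!is.na(j)) b[j] <- allele$base
  }
  m <- if (end == "donor") pwms$donor else pwms$acceptor
  score <- 0
  for (j in seq_along(b)) {
    if (b[j] %in% rownames(m)) score <- score + log2(m[b[j], j] / 0.25)
  }
  score
}
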