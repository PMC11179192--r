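# Nearest-neighbor Watson-Crick stack free energies (kcal/mol, 37 C,
# Turner 2004 set). Entry "XY" is the 5'XY3' dinucleotide on the top strand
# stacked over its complementary bottom-strand dinucleotide.
WC_STACK_DG <- c(
  AA = -0.93, AU = -1.10, AC = -2.24, AG = -2.08,
  UA = -1.33, UU = -0.93, UC = -2.35, UG = -2.11,
  CA = -2.11, CU = -2.08, CC = -3.26, CG = -2.36,
  GA = -2.35, GU = -2.24, GC = -3.42, GG = -3.26
)

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

is_gu_pair <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

#' U2 snRNA pairing energy against the branch region
#'
#' Slides the U2 branch-recognition sequence (default `GUAGUA`) along the
#' candidate branch window and scores every ungapped antiparallel alignment
#' with a nearest-neighbor stacking model: within an alignment, each maximal
#' run of two or more consecutive base pairs contributes the sum of its
#' Watson-Crick stack energies. The most negative run energy over all
#' alignments is returned, or `0` when no alignment forms a stabilizing
#' duplex. More negative values mean tighter U2 pairing, i.e. a stronger
#' branch region.
#'
#' @param window RNA (or DNA; `T` is read as `U`) sequence of the candidate
#'   branch region on the transcript strand, 5' to 3'.
#' @param u2_seq Recognition sequence of U2 snRNA, 5' to 3'.
#' @param allow_gu Also count G-U wobble pairs (scored with the mean WC
#'   stack energy of the flanking pair identities is *not* attempted;
#'   wobble-containing stacks reuse the WC table entry of the top-strand
#'   dinucleotide). Default `FALSE`: Watson-Crick only.
#' @return Duplex free energy in kcal/mol, `<= 0`.
#' @export
u2_pairing_mfe <- function(window, u2_seq = "GUAGUA", allow_gu = FALSE) {
  w <- chartr("T", "U", toupper(window))
  u2 <- chartr("T", "U", toupper(u2_seq))
  k <- nchar(u2)
  n <- nchar(w)
  if (n < k) {
    warning("branch window shorter than the U2 recognition sequence")
    return(0)
  }
  u2v <- strsplit(u2, "")[[1]]
  wv <- strsplit(w, "")[[1]]
  best <- 0
  for (i in seq_len(n - k + 1L)) {
    # u2 position m pairs with window position i + k - m (antiparallel)
    target <- wv[i + k - seq_len(k)]
    ok <- is_wc_pair(u2v, target)
    if (allow_gu) ok <- ok | is_gu_pair(u2v, target)
    if (sum(ok) < 2L) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values & r$lengths >= 2L)) {
      idx <- starts[s]:(ends[s] - 1L)
      e <- sum(WC_STACK_DG[paste0(u2v[idx], u2v[idx + 1L])])
      if (e < best) best <- e
    }
  }
  best
}

# ---- ViennaRNA CLI wrappers -------------------------------------------------

vienna_available <- function(tool = "RNAfold") nzchar(Sys.which(tool))

check_rna_alphabet <- function(seqs) {
  s <- chartr("T", "U", toupper(seqs))
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    stop("sequence with non-ACGU characters cannot be folded (",
         substr(seqs[bad][1], 1, 20), "...)")
  }
  s
}

#' Minimum free energy of RNA secondary structure
#'
#' Folds each sequence with `RNAfold` (ViennaRNA) and returns the minimum
#' free energy of its predicted secondary structure. Vectorized: all
#' sequences are folded in one engine invocation.
#'
#' @param seqs Character vector of RNA/DNA sequences (`T` read as `U`).
#' @return Numeric vector of folding free energies (kcal/mol, `<= 0`).
#' @export
fold_dG <- function(seqs) {
  if (length(seqs) == 0L) return(numeric())
  s <- check_rna_alphabet(seqs)
  if (!vienna_available("RNAfold")) {
    stop("RNAfold (ViennaRNA) not found on PATH; required for folding features")
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">s", seq_along(s), "\n", s), fa)
  out <- system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE)
  elines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(elines) != length(s)) {
    stop("RNAfold returned ", length(elines), " energies for ", length(s), " sequences")
  }
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", elines))
}

#' Structural openness of a sequence span
#'
#' Equilibrium probability, under the ViennaRNA partition-function ensemble
#' (`RNAplfold`), that the `span` bases centered on `pos` are simultaneously
#' unpaired. Values near 1 indicate an accessible, unstructured region.
#'
#' @param seqs Character vector of sequences.
#' @param pos Integer vector (recycled): 1-based center position within each
#'   sequence.
#' @param span Width of the probed region (odd; clamped to the sequence).
#' @return Numeric vector of unpaired probabilities in `[0, 1]`.
#' @export
openness <- function(seqs, pos, span = 11L) {
  if (length(seqs) == 0L) return(numeric())
  s <- check_rna_alphabet(seqs)
  pos <- rep_len(as.integer(pos), length(s))
  if (!vienna_available("RNAplfold")) {
    stop("RNAplfold (ViennaRNA) not found on PATH; required for openness features")
  }
  half <- (span - 1L) %/% 2L
  wd <- tempfile("plfold")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  fa <- file.path(wd, "in.fa")
  writeLines(paste0(">s", seq_along(s), "\n", s), fa)
  maxw <- max(nchar(s))
  owd <- setwd(wd) # RNAplfold writes *_lunp into the working directory
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  system2("RNAplfold",
    c("-W", min(150L, maxw), "-u", span),
    stdin = "in.fa", stdout = FALSE, stderr = FALSE
  )
  vapply(seq_along(s), function(i) {
    lunp <- file.path(wd, paste0("s", i, "_lunp"))
    tab <- utils::read.table(lunp, header = FALSE, comment.char = "#", fill = TRUE)
    L <- nchar(s[i])
    r1 <- max(1L, pos[i] - half)
    r2 <- min(L, pos[i] + half)
    u <- r2 - r1 + 1L
    val <- tab[tab[[1]] == r2, u + 1L]
    if (length(val) != 1L || is.na(val)) NA_real_ else as.numeric(val)
  }, numeric(1))
}
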