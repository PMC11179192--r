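#' Load a reference genome from FASTA
#'
#' Reads every record of a FASTA file into memory, uppercases the sequence
#' and normalizes RNA `U` to `T`. Contig names are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param fasta_path Path to a (plain-text) FASTA file.
#' @param assembly Free-text assembly label recorded with the genome
#'   (e.g. `"hg38"`). The package is assembly-agnostic; the label is carried
#'   into output metadata only.
#' @return A `genome_model` object: a list with `contigs` (named character
#'   vector of uppercase DNA sequences) and `assembly`.
#' @export
load_genome <- function(fasta_path, assembly = "unspecified") {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop(
      "duplicate contig name(s) in FASTA: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    )
  }
  contigs <- chartr("U", "T", toupper(as.character(seqs)))
  names(contigs) <- nm
  if (any(nchar(contigs) == 0L)) {
    stop("empty contig(s) in FASTA: ", paste(nm[nchar(contigs) == 0L], collapse = ", "))
  }
  bad <- vapply(contigs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("contig(s) with non-ACGTN characters: ", paste(nm[bad], collapse = ", "))
  }
  structure(
    list(contigs = contigs, assembly = assembly),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(
    "<genome_model> ", length(x$contigs), " contig(s), ",
    format(sum(nchar(x$contigs)), big.mark = ","), " bp, assembly: ",
    x$assembly, "\n",
    sep = ""
  )
  invisible(x)
}

#' Fetch genomic sequence (plus strand)
#'
#' @param genome A `genome_model`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates; clamped to the contig.
#' @return Uppercase DNA string on the plus strand.
#' @keywords internal
genome_seq <- function(genome, contig, start, end) {
  s <- genome$contigs[[contig]]
  substr(s, max(1L, start), min(nchar(s), end))
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Check a variant's REF allele against the genome
#'
#' A variant whose stated reference allele does not match the loaded genome
#' (including any `N` base, which has no defined substitution semantics)
#' fails the check. An unknown contig yields `FALSE` with a warning rather
#' than an error, so malformed records degrade gracefully in batch runs.
#'
#' @param variant A one-row data frame (or list) with `contig`, `pos`
#'   (1-based) and `ref`.
#' @param genome A `genome_model`.
#' @return `TRUE` iff the genome base(s) at `pos` equal `ref` exactly.
#' @export
check_reference <- function(variant, genome) {
  ctg <- variant$contig
  if (!ctg %in% names(genome$contigs)) {
    warning("contig not in genome: ", ctg)
    return(FALSE)
  }
  g <- genome_seq(genome, ctg, variant$pos, variant$pos + nchar(variant$ref) - 1L)
  nchar(g) == nchar(variant$ref) && g == variant$ref && !grepl("N", g)
}
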