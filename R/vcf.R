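#' Read variants from a VCF file
#'
#' Multi-allelic records are split into one row per alternative allele;
#' records with symbolic or breakend alleles (`<DEL>`, `A[chr1:123[`) are
#' dropped with a warning. Input order is preserved. Indels are retained
#' here and routed out later by triage.
#'
#' @param path Path to a VCF 4.x file (plain text).
#' @return A tibble with `contig`, `pos` (1-based), `vid` (ID column, `"."`
#'   when absent), `ref`, `alt`, and `record` (input record number after
#'   multi-allelic splitting).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(
      contig = character(), pos = integer(), vid = character(),
      ref = character(), alt = character(), record = integer()
    ))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF: non-integer POS at data line ", which(is.na(pos))[1])
  }
  out <- tibble::tibble(
    contig = fix$CHROM,
    pos = pos,
    vid = ifelse(is.na(fix$ID) | fix$ID == "", ".", fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    record = seq_len(nrow(fix))
  ) |>
    dplyr::mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    tidyr::unnest("alt")
  if (anyNA(out$ref) || anyNA(out$alt) || any(out$ref == "") || any(out$alt == "")) {
    stop("malformed VCF: empty REF or ALT at data line ",
         which(is.na(out$ref) | is.na(out$alt) | out$ref == "" | out$alt == "")[1])
  }
  symbolic <- grepl("[][<>]", out$alt) | out$alt == "*"
  if (any(symbolic)) {
    warning(sum(symbolic), " record(s) with symbolic alleles dropped", call. = FALSE)
    out <- out[!symbolic, ]
  }
  out$ref <- toupper(out$ref)
  out$alt <- toupper(out$alt)
  out
}

#' Write the prediction table
#'
#' Tab-separated output, one row per input variant decision (triaged-out
#' variants keep their basic gene/intron information with an empty score and
#' `effect = "not_evaluated"`). Genomic intron coordinates are printed
#' 1-based inclusive.
#'
#' @param records Prediction tibble from [predict_splice_variants()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  cols <- c(
    "variant_id", "contig", "pos", "ref", "alt", "gene", "intron_start",
    "intron_end", "strand", "model", "distance", "branchpoint", "score",
    "effect"
  )
  col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, nrow(records))
  }
  out <- tibble::tibble(
    variant_id = col("vid", "."),
    contig = col("contig", NA_character_),
    pos = col("pos", NA_integer_),
    ref = col("ref", NA_character_),
    alt = col("alt", NA_character_),
    gene = col("gene_id", NA_character_),
    intron_start = col("intron_start", NA_integer_) + 1L,
    intron_end = col("intron_end", NA_integer_),
    strand = col("strand", NA_character_),
    model = col("model", "none"),
    distance = col("distance", NA_integer_),
    branchpoint = col("branchpoint", NA_integer_),
    score = col("score", NA_real_),
    effect = col("effect", "not_evaluated")
  )
  names(out) <- cols
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
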