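#' Read a gene annotation (GTF or GFF3)
#'
#' Imports exon records with their `gene_id` and `transcript_id` attributes.
#' The dialect (GTF vs GFF3) is chosen from the file extension, falling back
#' to sniffing the attribute syntax of the first data line.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A tibble of exon records: `contig`, `start`/`end` (0-based
#'   half-open), `strand`, `gene_id`, `transcript_id`, one row per exon.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- annotation_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  df <- tibble::as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) stop("annotation has no feature type column")
  ex <- dplyr::filter(df, tolower(.data$type) == "exon")
  if (nrow(ex) == 0L) stop("annotation contains no exon features")
  if (fmt == "gff3" && !"transcript_id" %in% names(ex) && "Parent" %in% names(ex)) {
    ex$transcript_id <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  }
  if (fmt == "gff3" && !"gene_id" %in% names(ex) && "gene" %in% names(ex)) {
    ex$gene_id <- ex$gene
  }
  for (req in c("gene_id", "transcript_id")) {
    if (!req %in% names(ex)) stop("exon records lack attribute: ", req)
  }
  tibble::tibble(
    contig = as.character(ex$seqnames),
    start = as.integer(ex$start) - 1L, # to 0-based half-open
    end = as.integer(ex$end),
    strand = as.character(ex$strand),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id)
  )
}

annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "gtf") return("gtf")
  ln <- readLines(path, n = 50L)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) && grepl("=", strsplit(ln[1], "\t")[[1]][9])) "gff3" else "gtf"
}

#' Derive introns from exon annotation
#'
#' One intron per gap between consecutive exons of each transcript.
#' Transcripts whose exons overlap one another are skipped with a warning.
#' Identical introns arising from different transcripts are retained, each
#' with its own `transcript_id`. The result carries every gene's genomic
#' span (over its exons and introns) as the `"gene_spans"` attribute, used
#' by triage to decide whether a variant is intragenic.
#'
#' @param x Path to a GTF/GFF3 file, or an exon tibble from
#'   [read_annotation()].
#' @return A tibble of introns sorted by (`contig`, `start`): columns
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `gene_id`,
#'   `transcript_id`. The donor sits at the genomic `start` for `+` strand
#'   transcripts and at the genomic `end` for `-` strand.
#' @export
extract_introns <- function(x) {
  exons <- if (is.character(x)) read_annotation(x) else tibble::as_tibble(x)
  spans <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      contig = .data$contig[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      .groups = "drop"
    )
  per_tx <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_split()
  introns <- purrr::map_dfr(per_tx, function(tx) {
    tx <- dplyr::arrange(tx, .data$start)
    if (nrow(tx) < 2L) return(NULL)
    if (any(tx$start[-1] < tx$end[-nrow(tx)])) {
      warning(
        "transcript with overlapping exons skipped: ", tx$transcript_id[1],
        call. = FALSE
      )
      return(NULL)
    }
    tibble::tibble(
      contig = tx$contig[1],
      start = tx$end[-nrow(tx)],
      end = tx$start[-1],
      strand = tx$strand[1],
      gene_id = tx$gene_id[1],
      transcript_id = tx$transcript_id[1]
    )
  })
  if (nrow(introns) == 0L) {
    introns <- tibble::tibble(
      contig = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(), transcript_id = character()
    )
  } else {
    short <- introns$end - introns$start < 4L
    if (any(short)) {
      warning(sum(short), " intron(s) shorter than 4 bp dropped", call. = FALSE)
      introns <- introns[!short, ]
    }
  }
  introns <- dplyr::arrange(introns, .data$contig, .data$start, .data$end, .data$transcript_id)
  attr(introns, "gene_spans") <- spans
  introns
}

#' Gene spans attached to an intron table
#' @param introns Result of [extract_introns()].
#' @return Tibble of per-gene genomic spans (0-based half-open).
#' @export
gene_spans <- function(introns) {
  sp <- attr(introns, "gene_spans")
  if (is.null(sp)) {
    sp <- introns |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        contig = .data$contig[1],
        start = min(.data$start),
        end = max(.data$end),
        strand = .data$strand[1],
        .groups = "drop"
      )
  }
  sp
}
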