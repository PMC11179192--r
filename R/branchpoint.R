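#' Load branchpoint records from BED files
#'
#' Each file is 6-column BED (0-based start; the branch adenosine is the
#' single-base interval; strand mandatory) tagged with a source class.
#' Records from `predicted` sources (e.g. SVM-scored branchpoints, which
#' are ingested as data, not recomputed) must carry a numeric score;
#' `experimental` records need none. Exact duplicates of
#' (contig, pos, strand, source) are collapsed keeping the maximum score.
#'
#' @param files A data frame with columns `path`, `source`
#'   (`"experimental"` or `"predicted"`) and optionally `study` (free-text
#'   tag; defaults to the file name), or a named character vector of paths
#'   with names in `experimental`/`predicted`.
#' @return A `bp_store` tibble: `contig`, `pos` (1-based branch adenosine),
#'   `strand`, `source`, `study`, `score`.
#' @export
load_branchpoints <- function(files) {
  if (is.character(files)) {
    files <- tibble::tibble(
      path = unname(files),
      source = names(files) %||% rep("experimental", length(files))
    )
  }
  files <- tibble::as_tibble(files)
  if (!"study" %in% names(files)) files$study <- basename(files$path)
  stopifnot(all(files$source %in% c("experimental", "predicted")))
  recs <- purrr::map_dfr(seq_len(nrow(files)), function(i) {
    f <- files[i, ]
    if (!file.exists(f$path)) stop("branchpoint BED not found: ", f$path)
    bed <- read_bed6(f$path)
    if (any(bed$end - bed$start != 1L)) {
      stop("branchpoint record wider than one base in ", f$path, " (line ",
           which(bed$end - bed$start != 1L)[1], ")")
    }
    if (f$source == "predicted" && anyNA(bed$score)) {
      stop("predicted branchpoint record missing score in ", f$path,
           " (line ", which(is.na(bed$score))[1], ")")
    }
    tibble::tibble(
      contig = bed$contig, pos = bed$start + 1L, strand = bed$strand,
      source = f$source, study = f$study, score = bed$score
    )
  })
  recs <- recs |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand, .data$source) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE, na_rm = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$pos)
  class(recs) <- c("bp_store", class(recs))
  recs
}

read_bed6 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "track") & !startsWith(ln, "#") & nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld < 6L)) {
    stop("malformed BED line ", which(nfld < 6L)[1], " in ", path,
         ": expected 6 columns")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  strand <- vapply(parts, `[[`, "", 6L)
  if (anyNA(start) || anyNA(end) || !all(strand %in% c("+", "-"))) {
    stop("malformed BED line ",
         which(is.na(start) | is.na(end) | !strand %in% c("+", "-"))[1],
         " in ", path)
  }
  tibble::tibble(
    contig = vapply(parts, `[[`, "", 1L),
    start = start, end = end,
    name = vapply(parts, `[[`, "", 4L),
    score = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L))),
    strand = strand
  )
}

#' Query branchpoints in a genomic region
#'
#' @param store A `bp_store`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive region bounds.
#' @return Records with `pos` in `[start, end]`, sorted by position.
#' @export
query_region <- function(store, contig, start, end) {
  store |>
    dplyr::filter(
      .data$contig == !!contig, .data$pos >= !!start, .data$pos <= !!end
    ) |>
    dplyr::arrange(.data$pos)
}

#' Query branchpoints across a gene's introns
#'
#' Gene matching is case-insensitive; an unknown gene raises an error
#' listing near-matches.
#'
#' @param store A `bp_store`.
#' @param introns Intron table from [extract_introns()].
#' @param gene_name Gene identifier.
#' @return Union of [query_region()] over the gene's intron intervals.
#' @export
query_gene <- function(store, introns, gene_name) {
  genes <- unique(c(gene_spans(introns)$gene_id, introns$gene_id))
  hit <- genes[tolower(genes) == tolower(gene_name)]
  if (length(hit) == 0L) {
    near <- agrep(gene_name, genes, ignore.case = TRUE, value = TRUE)
    stop(
      "unknown gene: ", gene_name,
      if (length(near)) paste0(" (did you mean: ", paste(near, collapse = ", "), "?)")
    )
  }
  gi <- dplyr::filter(introns, .data$gene_id %in% hit) |>
    dplyr::distinct(.data$contig, .data$start, .data$end)
  if (nrow(gi) == 0L) return(store[0, ])
  purrr::map_dfr(seq_len(nrow(gi)), function(i) {
    query_region(store, gi$contig[i], gi$start[i] + 1L, gi$end[i])
  }) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$pos)
}

#' Best branchpoint annotation for an intron
#'
#' Experimental records are preferred over predicted ones; among predicted
#' records the highest score wins, ties and experimental multiplicity
#' resolved by the lowest genomic coordinate.
#'
#' @param store A `bp_store` (or `NULL`).
#' @param intron One-row intron (0-based half-open, with `strand`).
#' @return 1-based branch position, or `NA` when no record falls in the
#'   intron.
#' @export
annotate_branchpoint <- function(store, intron) {
  if (is.null(store)) return(NA_integer_)
  hits <- query_region(store, intron$contig, intron$start + 1L, intron$end)
  hits <- dplyr::filter(hits, .data$strand == intron$strand)
  if (nrow(hits) == 0L) return(NA_integer_)
  ex <- dplyr::filter(hits, .data$source == "experimental")
  if (nrow(ex)) return(ex$pos[1])
  pr <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$pos)
  pr$pos[1]
}
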