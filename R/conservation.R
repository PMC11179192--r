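#' Read a per-base conservation track
#'
#' Accepts either a 3-column tab-separated text file (`contig`, `pos`
#' 1-based, `score`) or a bigWig file (dispatched on the `.bw`/`.bigwig`
#' extension and read through rtracklayer). Scores are conservation
#' probabilities in `[0, 1]` (PhastCons-style); positions absent from the
#' track are treated as missing, not zero.
#'
#' @param path Track file path.
#' @return A `conservation_track`: tibble with `contig`, `pos`, `score`.
#' @export
read_conservation <- function(path) {
  if (!file.exists(path)) stop("conservation track not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    gr <- rtracklayer::import(path, format = "BigWig")
    df <- as.data.frame(gr)
    tr <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
      tibble::tibble(
        contig = as.character(df$seqnames[i]),
        pos = seq.int(df$start[i], df$end[i]),
        score = df$score[i]
      )
    })
  } else {
    tr <- readr::read_tsv(
      path,
      col_names = c("contig", "pos", "score"),
      col_types = readr::cols(
        contig = readr::col_character(),
        pos = readr::col_integer(),
        score = readr::col_double()
      ),
      comment = "#"
    )
  }
  if (any(tr$score < 0 | tr$score > 1, na.rm = TRUE)) {
    stop("conservation scores must lie in [0, 1]")
  }
  class(tr) <- c("conservation_track", class(tr))
  tr
}

#' Mean conservation around a position
#'
#' Mean track score over an odd window centered at `pos`; positions missing
#' from the track are excluded from the mean. When every position in the
#' window is missing the value is imputed as 0 (unobserved is not treated
#' as conserved) and flagged via the `"imputed"` attribute, which
#' [build_features()] surfaces as an indicator feature.
#'
#' @param track A `conservation_track` (or `NULL`: always imputed).
#' @param contig,pos Query position (1-based).
#' @param window Odd window width `>= 1`.
#' @return Mean score with attribute `imputed` (logical).
#' @export
conservation_at <- function(track, contig, pos, window = 1L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (is.null(track)) {
    return(structure(0, imputed = TRUE))
  }
  half <- (window - 1L) %/% 2L
  sel <- track$contig == contig & track$pos >= pos - half & track$pos <= pos + half
  sc <- track$score[sel]
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L) {
    return(structure(0, imputed = TRUE))
  }
  structure(mean(sc), imputed = FALSE)
}
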